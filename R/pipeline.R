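#' Pipeline configuration
#'
#' Collects input paths and thresholds for [run_pipeline()]. Any stage whose
#' inputs are absent is skipped; requesting it explicitly without inputs is
#' an error naming the stage and path. The configuration round-trips
#' losslessly through JSON ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param genome_fasta,alignments_tsv,vcf,pool_map Input paths (NULL to
#'   skip the dependent stages). `alignments_tsv` uses the interval-TSV
#'   dialect (see [read_alignment_tsv()]).
#' @param out_dir Output directory.
#' @param enzymes Enzyme pair for digestion (built-in names).
#' @param window Size-selection window `c(min, max)`.
#' @param yield_bp Planned yield for the design stage.
#' @param mapq_gt MAPQ ingestion threshold (keep > this; default 3).
#' @param depth_min Depth threshold for coverage/common sites.
#' @param bin_size Bin width for the bin-count matrix.
#' @param max_missing,min_maf Variant filter thresholds.
#' @param k_per_pool Artificial-pool draw size.
#' @param seed Seed for the artificial-pool grouping.
#' @return Object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(genome_fasta = NULL, alignments_tsv = NULL,
                            vcf = NULL, pool_map = NULL,
                            out_dir = "ddrad_out",
                            enzymes = c("PstI", "MboI"),
                            window = c(300, 400), yield_bp = 250e6,
                            mapq_gt = 3L, depth_min = 1L, bin_size = 1000L,
                            max_missing = 0.05, min_maf = 0.01,
                            k_per_pool = 3L, seed = 1L) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1,
            depth_min >= 1L, bin_size >= 1L, mapq_gt >= -1L)
  structure(list(genome_fasta = genome_fasta,
                 alignments_tsv = alignments_tsv, vcf = vcf,
                 pool_map = pool_map, out_dir = out_dir,
                 enzymes = enzymes, window = as.numeric(window),
                 yield_bp = as.numeric(yield_bp),
                 mapq_gt = as.integer(mapq_gt),
                 depth_min = as.integer(depth_min),
                 bin_size = as.integer(bin_size),
                 max_missing = max_missing, min_maf = min_maf,
                 k_per_pool = as.integer(k_per_pool),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x[!vapply(x, is.null, TRUE)])
}

.require_input <- function(path, stage) {
  if (is.null(path) || !file.exists(path)) {
    stop("stage '", stage, "': missing input file ",
         if (is.null(path)) "(not configured)" else path, call. = FALSE)
  }
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates the platform workflow on the configured inputs: in silico
#' digestion and windowed locus counting (genome), sequencing-design
#' arithmetic, coverage/bins/correlation/PCA/common-sites/pool diagnostics
#' (alignments + pool map), and variant summarization + filtering (VCF).
#' Stage outputs are written under `out_dir` and every headline statistic is
#' collected in `summary.json`. Outputs are written atomically (tempfile +
#' rename) so an interrupted run leaves no half-written summary.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector among `"digest"`, `"design"`,
#'   `"coverage"`, `"variants"`; default runs every stage whose inputs are
#'   configured.
#' @return The summary list, invisibly; side effect: files under `out_dir`.
#' @export
run_pipeline <- function(config, stages = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  auto <- is.null(stages)
  if (auto) {
    stages <- c(if (!is.null(config$genome_fasta)) c("digest", "design"),
                if (!is.null(config$alignments_tsv)) "coverage",
                if (!is.null(config$vcf)) "variants")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(config = unclass(config), stages = stages)
  genome <- NULL
  seqlens <- NULL

  if ("digest" %in% stages) {
    path <- .require_input(config$genome_fasta, "digest")
    genome <- read_genome(path)
    seqlens <- stats::setNames(Biostrings::width(genome), names(genome))
    dg <- digest(genome, as.list(config$enzymes))
    pr <- profile_digest(dg, config$window)
    write_fragments_bed(dg, file.path(config$out_dir, "fragments.bed"))
    write_profile(pr, file.path(config$out_dir, "digest_profile.tsv"))
    summary$digest <- list(
      enzymes = pr$enzymes, window = config$window,
      total_fragments = pr$total,
      ab_ba_total = unname(pr$counts[["AB+BA"]]),
      ab_ba_windowed = unname(pr$windowed[["AB+BA"]]),
      coincident_cuts = dg$coincident_cuts)
  }

  if ("design" %in% stages) {
    n_loci <- if (!is.null(summary$digest)) summary$digest$ab_ba_windowed
              else stop("stage 'design': requires the digest stage",
                        call. = FALSE)
    plan <- design_plan(n_loci, config$window, config$yield_bp)
    summary$design <- list(
      n_loci = plan$n_loci,
      target_bp_min = plan$target_bp_min,
      target_bp_max = plan$target_bp_max,
      yield_bp_per_sample = plan$yield_bp_per_sample,
      expected_depth_min = unname(plan$expected_depth[["depth_min"]]),
      expected_depth_max = unname(plan$expected_depth[["depth_max"]]),
      read_pairs_per_sample = plan$read_pairs_per_sample)
  }

  if ("coverage" %in% stages) {
    path <- .require_input(config$alignments_tsv, "coverage")
    if (is.null(seqlens)) {
      gpath <- .require_input(config$genome_fasta, "coverage")
      genome <- read_genome(gpath)
      seqlens <- stats::setNames(Biostrings::width(genome), names(genome))
    }
    aln <- read_alignment_tsv(path, seqlens, mapq_gt = config$mapq_gt)
    cs <- coverage_summary(aln, depth_min = config$depth_min)
    bc <- bin_counts(aln, bin_size = config$bin_size)
    write_bin_counts(bc, file.path(config$out_dir, "bin_counts.tsv"))
    summary$coverage <- list(
      n_samples = length(unique(aln$segments$sample)),
      merged_breadth_fraction = cs$breadth_fraction,
      merged_mean_depth = cs$mean_depth)
    if (nrow(bc$counts) >= 2L) {
      cm <- correlation_matrix(bc)
      data.table::fwrite(data.table::as.data.table(cm$r, keep.rownames = "sample"),
                         file.path(config$out_dir, "correlations.tsv"),
                         sep = "\t")
      off <- cm$r[upper.tri(cm$r)]
      summary$coverage$correlation <- list(
        method = cm$method, min = min(off, na.rm = TRUE),
        max = max(off, na.rm = TRUE),
        degenerate_samples = cm$degenerate)
    }
    if (nrow(bc$counts) >= 3L) {
      pc <- pca_bins(bc)
      data.table::fwrite(
        data.table::as.data.table(pc$scores, keep.rownames = "sample"),
        file.path(config$out_dir, "pca_scores.tsv"), sep = "\t")
      summary$coverage$pca_variance_pct <- pc$variance_pct
    }
    if (!is.null(config$pool_map)) {
      pm <- read_pool_map(.require_input(config$pool_map, "coverage"))
      pm <- pm[names(pm) %in% unique(aln$segments$sample)]
      per_pool <- vapply(split(names(pm), pm), function(s)
        common_sites(aln, s, config$depth_min), 0L)
      summary$coverage$common_sites_per_pool <- as.list(per_pool)
      summary$coverage$common_sites_all <- common_sites(
        aln, names(pm), config$depth_min)
      pools <- split(names(pm), pm)
      sizes <- lengths(pools)
      if (length(unique(sizes)) == 1L &&
          config$k_per_pool * length(pools) == sizes[[1L]]) {
        pt <- artificial_pool_test(aln, pm, k_per_pool = config$k_per_pool,
                                   seed = config$seed,
                                   depth_min = config$depth_min)
        jsonlite::write_json(
          list(experimental = as.list(pt$experimental),
               artificial = as.list(pt$artificial),
               mean_experimental = pt$mean_experimental,
               mean_artificial = pt$mean_artificial,
               statistic = pt$statistic, p_value = pt$p_value,
               n_pools = pt$n_pools),
          file.path(config$out_dir, "pool_comparison.json"),
          auto_unbox = TRUE, digits = NA)
        summary$coverage$pool_test <- list(
          mean_experimental = pt$mean_experimental,
          mean_artificial = pt$mean_artificial,
          p_value = pt$p_value)
      }
    }
  }

  if ("variants" %in% stages) {
    path <- .require_input(config$vcf, "variants")
    gm <- read_vcf_genotypes(path)
    ts <- tstv(gm)
    ind <- indel_stats(gm)
    sh <- sharing_distribution(gm)
    fl <- filter_dataset(gm, config$max_missing, config$min_maf)
    rs <- rate_summary(gm)
    data.table::fwrite(
      data.table::data.table(k = sh$k, exactly_k = sh$exactly_k,
                             at_least_k = sh$at_least_k),
      file.path(config$out_dir, "sharing.tsv"), sep = "\t")
    if (!is.null(seqlens)) {
      dw <- density_windows(gm, seqlengths = seqlens,
                            window_bp = config$bin_size)
      data.table::fwrite(dw, file.path(config$out_dir, "density.tsv"),
                         sep = "\t")
    }
    write_vcf_genotypes(fl$matrix,
                        file.path(config$out_dir, "filtered.vcf"),
                        contigs = seqlens)
    summary$variants <- list(
      n_variants = n_variants(gm),
      n_samples = length(gm$samples),
      tstv = ts[c("transitions", "transversions", "ratio")],
      indels = ind[c("deletions", "insertions", "del_ins_ratio")],
      rates = rs,
      filtered = fl$summary,
      universal = sum(sh$exactly_k[length(sh$exactly_k)]))
  }

  tmp <- tempfile(tmpdir = config$out_dir, fileext = ".json")
  jsonlite::write_json(summary, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  file.rename(tmp, file.path(config$out_dir, "summary.json"))
  invisible(summary)
}
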