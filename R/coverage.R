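# Per-chromosome depth Rle for a subset of segments. Returns a named list
# of integer Rle, one per chromosome in seqlengths (full length, zero-padded).
.depth_rles <- function(seg, seqlengths) {
  out <- vector("list", length(seqlengths))
  names(out) <- names(seqlengths)
  for (ch in names(seqlengths)) {
    s <- seg[seg$chrom == ch, ]
    if (nrow(s)) {
      ir <- IRanges::IRanges(start = s$start + 1L, end = s$end)
      out[[ch]] <- IRanges::coverage(ir, width = seqlengths[[ch]])
    } else {
      out[[ch]] <- S4Vectors::Rle(0L, seqlengths[[ch]])
    }
  }
  out
}

#' Breadth and depth of coverage
#'
#' Per-position depth is computed from overlapping aligned segments (each
#' mate counted independently). A position is *covered* when its depth is at
#' least `depth_min`; breadth is the covered fraction of the genome and mean
#' depth is averaged over covered positions only, matching the threshold-based
#' phrasing used when reporting reduced-representation coverage.
#'
#' @param x An `alignment_set`.
#' @param samples Samples to include, merged as one pile-up (default: all).
#' @param depth_min Depth threshold for "covered" (default 1).
#' @return Object of class `coverage_summary`: covered_positions,
#'   breadth_fraction, mean_depth (0 when nothing is covered), depth_min,
#'   genome_length, and per-chromosome rows in `$by_chrom`.
#' @export
coverage_summary <- function(x, samples = NULL, depth_min = 1L) {
  stopifnot(inherits(x, "alignment_set"))
  if (sum(as.numeric(x$seqlengths)) == 0) {
    stop("genome length is zero", call. = FALSE)
  }
  seg <- x$segments
  if (!is.null(samples)) seg <- seg[seg$sample %in% samples, ]
  rles <- .depth_rles(seg, x$seqlengths)
  per <- lapply(names(rles), function(chrom) {
    r <- rles[[chrom]]
    cov <- r >= depth_min
    n_cov <- sum(cov)
    rc <- r[cov]
    depth_sum <- sum(as.numeric(S4Vectors::runValue(rc)) *
                     S4Vectors::runLength(rc))
    data.table::data.table(chrom = chrom, length = length(r),
                           covered = n_cov,
                           mean_depth = if (n_cov > 0) depth_sum / n_cov else 0)
  })
  by_chrom <- data.table::rbindlist(per)
  covered <- sum(by_chrom$covered)
  glen <- sum(as.numeric(x$seqlengths))
  mean_depth <- if (covered > 0) {
    sum(by_chrom$mean_depth * by_chrom$covered) / covered
  } else 0
  structure(
    list(covered_positions = covered, breadth_fraction = covered / glen,
         mean_depth = mean_depth, depth_min = depth_min,
         genome_length = glen, by_chrom = by_chrom),
    class = "coverage_summary"
  )
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf(
    "<coverage_summary> breadth %.2f%% (%d / %g bp at depth >= %d), mean depth %.2fx\n",
    100 * x$breadth_fraction, x$covered_positions, x$genome_length,
    x$depth_min, x$mean_depth))
  invisible(x)
}

#' Fixed-width bin count matrix
#'
#' Tiles the genome in `bin_size`-bp windows (last bin of a chromosome may be
#' short) and assigns each aligned segment to exactly one bin --- the bin
#' containing its leftmost aligned base --- so that each sample's row sum
#' equals its retained segment count. This matrix is the unit of the
#' correlation, PCA and pool analyses.
#'
#' @param x An `alignment_set`.
#' @param bin_size Bin width in bp (default 1000).
#' @return Object of class `bin_count_matrix`: `counts` (samples x bins
#'   integer matrix), `bins` (`data.table` chrom/start/end), `bin_size`.
#' @export
bin_counts <- function(x, bin_size = 1000L) {
  stopifnot(inherits(x, "alignment_set"), bin_size >= 1L)
  sl <- x$seqlengths
  nb <- stats::setNames(pmax(1L, as.integer(ceiling(sl / bin_size))),
                        names(sl))
  offsets <- stats::setNames(cumsum(c(0L, nb[-length(nb)])), names(sl))
  bins <- data.table::rbindlist(lapply(names(sl), function(chrom) {
    starts <- seq(0L, by = bin_size, length.out = nb[[chrom]])
    data.table::data.table(chrom = chrom, start = starts,
                           end = pmin(starts + bin_size, sl[[chrom]]))
  }))
  samples <- sort(unique(x$segments$sample))
  counts <- matrix(0L, nrow = length(samples), ncol = nrow(bins),
                   dimnames = list(samples, NULL))
  if (nrow(x$segments)) {
    idx <- offsets[x$segments$chrom] + x$segments$start %/% bin_size + 1L
    tab <- data.table::data.table(sample = x$segments$sample, bin = idx)
    agg <- tab[, .N, by = c("sample", "bin")]
    counts[cbind(match(agg$sample, samples), agg$bin)] <- agg$N
  }
  structure(list(counts = counts, bins = bins, bin_size = bin_size),
            class = "bin_count_matrix")
}

#' @export
print.bin_count_matrix <- function(x, ...) {
  cat(sprintf("<bin_count_matrix> %d sample(s) x %d bins of %d bp\n",
              nrow(x$counts), ncol(x$counts), x$bin_size))
  invisible(x)
}

#' Between-sample correlation of bin counts
#'
#' Pairwise correlations of the bin-count rows quantify how much two
#' libraries sampled the same genomic regions; blocks of highly correlated
#' samples expose library-preparation batches. Samples with constant bin
#' counts have undefined correlations: they are flagged, their entries set
#' `NA`, and they are excluded from the clustering used for display ordering
#' (average linkage on `1 - r`).
#'
#' @param x A `bin_count_matrix` (or bare samples x bins matrix).
#' @param method `"spearman"` (default; robust to per-sample yield
#'   differences) or `"pearson"`.
#' @return Object of class `sample_correlation`: `r` (symmetric, unit
#'   diagonal), `order` (dendrogram leaf order over non-degenerate samples),
#'   `degenerate` (character vector), `method`.
#' @export
correlation_matrix <- function(x, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  m <- if (inherits(x, "bin_count_matrix")) x$counts else as.matrix(x)
  if (nrow(m) < 2L) stop("need >= 2 samples", call. = FALSE)
  constant <- apply(m, 1L, function(v) length(unique(v)) == 1L)
  r <- suppressWarnings(stats::cor(t(m), method = method))
  diag(r) <- 1
  r[constant, ] <- NA_real_; r[, constant] <- NA_real_
  diag(r)[constant] <- 1
  keep <- rownames(m)[!constant]
  ord <- keep
  if (length(keep) > 2L) {
    d <- stats::as.dist(1 - r[keep, keep])
    ord <- keep[stats::hclust(d, method = "average")$order]
  }
  structure(list(r = r, order = ord,
                 degenerate = rownames(m)[constant], method = method),
            class = "sample_correlation")
}

#' @export
print.sample_correlation <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  off <- off[!is.na(off)]
  cat(sprintf("<sample_correlation> %s, %d samples; off-diagonal r in [%.3f, %.3f]%s\n",
              x$method, nrow(x$r),
              if (length(off)) min(off) else NA, if (length(off)) max(off) else NA,
              if (length(x$degenerate))
                sprintf(" (%d constant sample(s) flagged)", length(x$degenerate))
              else ""))
  invisible(x)
}

#' PCA of bin counts
#'
#' Principal component analysis of `log1p`-transformed bin counts, bin-wise
#' centered, unscaled. On multiplexed ddRAD data the first component
#' typically tracks per-sample sequencing yield, later components expose
#' batch structure.
#'
#' @param x A `bin_count_matrix` or samples x bins matrix (>= 3 samples).
#' @param n_components Components to retain (default `min(n-1, 10)`).
#' @return Object of class `bin_pca`: `scores` (samples x PCs),
#'   `variance_pct` (non-increasing, sums <= 100), `sdev`.
#' @export
pca_bins <- function(x, n_components = NULL) {
  m <- if (inherits(x, "bin_count_matrix")) x$counts else as.matrix(x)
  if (nrow(m) < 3L) stop("need >= 3 samples for PCA", call. = FALSE)
  lm <- log1p(m)
  p <- stats::prcomp(lm, center = TRUE, scale. = FALSE)
  var_pct <- 100 * p$sdev^2 / sum(p$sdev^2)
  if (all(p$sdev == 0)) var_pct <- rep(0, length(p$sdev))
  k <- min(if (is.null(n_components)) 10L else n_components,
           length(p$sdev), nrow(m) - 1L)
  structure(list(scores = p$x[, seq_len(k), drop = FALSE],
                 variance_pct = var_pct[seq_len(k)], sdev = p$sdev),
            class = "bin_pca")
}

#' @export
print.bin_pca <- function(x, ...) {
  cat(sprintf("<bin_pca> %d samples, %d PCs; PC1 %.2f%%, PC2 %.2f%%\n",
              nrow(x$scores), ncol(x$scores), x$variance_pct[1L],
              if (length(x$variance_pct) > 1L) x$variance_pct[2L] else NA))
  invisible(x)
}

#' Common sites across a sample group
#'
#' Counts genome positions covered at depth >= `depth_min` in *every* sample
#' of the group: the effective locus set genotypable across that group.
#' Monotone non-increasing as samples are added.
#'
#' @param x An `alignment_set`.
#' @param samples Character vector of samples (>= 1).
#' @param depth_min Per-sample depth threshold (default 1, "at least once").
#' @return Integer count of common positions.
#' @export
common_sites <- function(x, samples, depth_min = 1L) {
  stopifnot(inherits(x, "alignment_set"), length(samples) >= 1L)
  total <- 0L
  for (ch in names(x$seqlengths)) {
    acc <- NULL
    for (s in samples) {
      seg <- x$segments[x$segments$sample == s & x$segments$chrom == ch, ]
      r <- if (nrow(seg)) {
        IRanges::coverage(IRanges::IRanges(seg$start + 1L, seg$end),
                          width = x$seqlengths[[ch]]) >= depth_min
      } else S4Vectors::Rle(FALSE, x$seqlengths[[ch]])
      acc <- if (is.null(acc)) r else acc & r
      if (!any(acc)) break
    }
    total <- total + sum(acc)
  }
  as.integer(total)
}

#' Experimental vs artificial pool comparison
#'
#' Quantifies how much library-preparation batching inflates the shared
#' locus set: common sites are computed for each experimental pool and for
#' the same number of *artificial* pools built by drawing `k_per_pool`
#' samples from every experimental pool (without replacement, each sample
#' used exactly once), then compared with a paired two-sided t-test across
#' pools. A real batch effect makes experimental pools share more sites than
#' the cross-batch artificial pools.
#'
#' @param x An `alignment_set`.
#' @param pool_assignment Named character vector sample -> pool; pools must
#'   be equal-sized with `k_per_pool * n_pools == pool size`.
#' @param k_per_pool Samples drawn from each experimental pool per
#'   artificial pool (default 3).
#' @param seed Integer seed making the artificial grouping reproducible.
#' @param depth_min Depth threshold passed to [common_sites()].
#' @return Object of class `pool_comparison`: per-pool counts, means, the
#'   paired t statistic and p-value, `n_pools`, and the artificial pool
#'   membership.
#' @export
artificial_pool_test <- function(x, pool_assignment, k_per_pool = 3L,
                                 seed = 1L, depth_min = 1L) {
  stopifnot(inherits(x, "alignment_set"))
  pools <- split(names(pool_assignment), pool_assignment)
  n_pools <- length(pools)
  sizes <- lengths(pools)
  if (length(unique(sizes)) != 1L) {
    stop("experimental pools must be equal-sized", call. = FALSE)
  }
  if (k_per_pool * n_pools != sizes[[1L]]) {
    stop("k_per_pool * n_pools must equal the pool size (",
         k_per_pool, " x ", n_pools, " != ", sizes[[1L]], ")", call. = FALSE)
  }
  pool_names <- names(pools)
  # artificial pool j takes the j-th seeded chunk of every experimental pool
  chunks <- withr::with_seed(seed, lapply(pools, function(s) {
    split(sample(s), rep(seq_len(n_pools), each = k_per_pool))
  }))
  artificial <- lapply(seq_len(n_pools), function(j) {
    unlist(lapply(chunks, `[[`, j), use.names = FALSE)
  })
  names(artificial) <- paste0("artificial_", seq_len(n_pools))
  exp_counts <- vapply(pools, function(s) common_sites(x, s, depth_min), 0L)
  art_counts <- vapply(artificial, function(s) common_sites(x, s, depth_min), 0L)
  tt <- if (n_pools >= 2L && stats::sd(exp_counts - art_counts) > 0) {
    stats::t.test(exp_counts, art_counts, paired = TRUE)
  } else NULL
  structure(
    list(experimental = exp_counts, artificial = art_counts,
         mean_experimental = mean(exp_counts),
         mean_artificial = mean(art_counts),
         statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
         p_value = if (is.null(tt)) NA_real_ else tt$p.value,
         n_pools = n_pools, k_per_pool = k_per_pool,
         artificial_membership = artificial, seed = seed),
    class = "pool_comparison"
  )
}

#' @export
print.pool_comparison <- function(x, ...) {
  cat(sprintf(paste0(
    "<pool_comparison> %d pools (k = %d per pool)\n",
    "  common sites: experimental %.0f vs artificial %.0f (%.1f%% more)\n",
    "  paired t-test: t = %.3f, p = %.4g\n"),
    x$n_pools, x$k_per_pool, x$mean_experimental, x$mean_artificial,
    100 * (x$mean_experimental / x$mean_artificial - 1),
    x$statistic, x$p_value))
  invisible(x)
}

#' Write a bin count matrix as TSV (bins as rows)
#'
#' @param x A `bin_count_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bin_counts <- function(x, path) {
  stopifnot(inherits(x, "bin_count_matrix"))
  out <- cbind(x$bins, data.table::as.data.table(t(x$counts)))
  data.table::setnames(out, c(names(x$bins), rownames(x$counts)))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
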