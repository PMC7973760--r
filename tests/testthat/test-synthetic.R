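# scaled-down design used throughout this file: 200-kb genome, 4 pools x 4
# samples, ~500 read pairs/sample, so the full generator runs in seconds
small_design <- function(...) {
  args <- utils::modifyList(
    list(genome_length = 2e5, n_pools = 4L, samples_per_pool = 4L,
         n_loci_per_mb = 300, n_ssr_tracts = 10L, n_snp = 120L,
         n_indel = 25L, n_ssr_variants = 6L, yield_mean_pairs = 500,
         hotspot_copies = 5L),
    list(...))
  do.call(synthetic_design, args)
}

test_that("gen_genome plants exactly the truth-table sites", {
  sg <- gen_genome(small_design(seed = 11L))
  for (enz in sg$design$enzymes) {
    for (ch in names(sg$genome)) {
      found <- find_cut_sites(sg$genome[[which(names(sg$genome) == ch)]],
                              enz)
      planted <- sort(unique(
        sg$sites[sg$sites$enzyme == enz & sg$sites$chrom == ch, ]$cut))
      expect_identical(found, planted, info = paste(enz, ch))
    }
  }
  # loci truth agrees with the package's own digestion
  dg <- digest(sg$genome, as.list(sg$design$enzymes))
  cls <- ddradtools:::.classify_fragments(dg$fragments, "PstI", "MboI")
  ab <- dg$fragments[cls == "AB+BA"]
  truth <- sg$loci[order(sg$loci$chrom, sg$loci$start), ]
  found_keys <- paste(ab$chrom, ab$start, ab$end)
  # every planted locus must appear among AB+BA fragments
  expect_true(all(paste(truth$chrom, truth$start, truth$end) %in%
                    found_keys))
})

test_that("gen_genome: no planted sites yields one fragment per chromosome", {
  d0 <- synthetic_design(genome_length = 5e4, n_chrom = 2L,
                         n_loci_per_mb = 0, rare_sites_per_kb = 0,
                         frequent_sites_per_kb = 0, hotspot_copies = 0L,
                         n_ssr_tracts = 0L, seed = 3L)
  sg0 <- gen_genome(d0)
  expect_identical(nrow(sg0$sites), 0L)
  dg <- digest(sg0$genome, as.list(d0$enzymes))
  expect_identical(nrow(dg$fragments), 2L)
  expect_true(all(dg$fragments$left_end == "CHROM_END"))
})

test_that("generators are byte-identical under the same seed", {
  d <- small_design(seed = 21L)
  sg1 <- gen_genome(d); sg2 <- gen_genome(d)
  expect_identical(as.character(sg1$genome), as.character(sg2$genome))
  expect_identical(sg1$sites, sg2$sites)
  rd1 <- gen_reads(sg1); rd2 <- gen_reads(sg2)
  expect_identical(rd1$alignments$segments, rd2$alignments$segments)
  gt1 <- gen_genotypes(sg1); gt2 <- gen_genotypes(sg2)
  expect_identical(gt1$matrix$a1, gt2$matrix$a1)
  expect_identical(gt1$truth, gt2$truth)
  # different seed changes the genome
  sg3 <- gen_genome(small_design(seed = 22L))
  expect_false(identical(as.character(sg1$genome),
                         as.character(sg3$genome)))
})

test_that("centromere-like spans are free of planted sites", {
  sg <- gen_genome(small_design(seed = 31L))
  cen <- sg$centromeres
  for (i in seq_len(nrow(cen))) {
    in_cen <- sg$sites$chrom == cen$chrom[i] &
      sg$sites$motif_start >= cen$start[i] & sg$sites$motif_start < cen$end[i]
    expect_identical(sum(in_cen), 0L)
  }
})

test_that("planted SSR tracts are recovered by ssr_scan", {
  sg <- gen_genome(small_design(seed = 41L))
  tr <- sg$ssr_tracts
  expect_gt(nrow(tr), 0L)
  for (i in seq_len(nrow(tr))) {
    ch <- which(names(sg$genome) == tr$chrom[i])
    ctx <- as.character(Biostrings::subseq(sg$genome[[ch]], tr$start[i],
                                           tr$end[i]))
    hit <- ssr_scan(ctx)
    expect_true(nrow(hit) >= 1L && tr$motif[i] %in% hit$motif,
                info = paste("tract", i, tr$motif[i]))
  }
})

test_that("gen_reads: yields, windows and read geometry honour the design", {
  d <- small_design(seed = 51L)
  sg <- gen_genome(d)
  rd <- gen_reads(sg)
  expect_identical(nrow(rd$yields), 16L)
  # every segment is at most read_length long and within its fragment class
  seg <- rd$alignments$segments
  expect_true(all(seg$end - seg$start <= d$read_length))
  expect_true(all(seg$end - seg$start > 0L))
  # two segments per pair
  expect_identical(nrow(seg), 2L * sum(rd$yields$pairs))
  # CV 0 gives equal yields
  d0 <- small_design(seed = 52L, yield_cv = 0)
  rd0 <- gen_reads(gen_genome(d0))
  expect_identical(length(unique(rd0$yields$pairs)), 1L)
  # shifted pools (default: second half when fewer than 6 pools) get the
  # shifted window
  expect_identical(d$shifted_pools, c(3L, 4L))
  expect_identical(rd$windows$min_bp,
                   d$window_min + c(0L, 0L, d$pool_window_shift,
                                    d$pool_window_shift))
})

test_that("realized yield CV recovers the configured 28.14% at n = 96", {
  # one pool of 96 samples; CV estimated over samples (sampling error at
  # n = 96 is roughly cv/sqrt(2n) ~ 2 points, well within the +/-5 band)
  d <- synthetic_design(genome_length = 1e5, n_pools = 1L,
                        samples_per_pool = 96L, n_loci_per_mb = 300,
                        pool_window_shift = 0L, yield_mean_pairs = 300,
                        n_ssr_tracts = 5L, hotspot_copies = 0L, seed = 61L)
  rd <- gen_reads(gen_genome(d))
  cv <- stats::sd(rd$yields$pairs) / mean(rd$yields$pairs)
  expect_gt(cv, 0.2814 - 0.05)
  expect_lt(cv, 0.2814 + 0.05)
})

test_that("a large window shift empties the shared site set across batches", {
  d <- small_design(seed = 71L, pool_window_shift = 400L,
                    locus_length_spread = 50L)
  sg <- gen_genome(d)
  rd <- gen_reads(sg)
  # samples from unshifted pool 1 and shifted pool 4 share ~no sites
  s1 <- rd$yields$sample[rd$yields$pool == "pool_1"][1:2]
  s4 <- rd$yields$sample[rd$yields$pool == "pool_4"][1:2]
  cross <- common_sites(rd$alignments, c(s1, s4))
  within <- common_sites(rd$alignments, s1)
  expect_gt(within, 0L)
  expect_lt(cross / max(within, 1L), 0.02)
})

test_that("gen_genotypes: missingness, MAF recovery, and planted truth", {
  # missingness 0 -> sharing mass entirely at k = n_samples
  d0 <- small_design(seed = 81L, missing_rate = 0)
  gt0 <- gen_genotypes(gen_genome(d0))
  sh <- sharing_distribution(gt0$matrix)
  n_s <- length(gt0$matrix$samples)
  expect_identical(sum(sh$exactly_k[-n_s]), 0L)
  # planted fixed MAF 0.30 recovered within binomial sampling error at n=200
  d_maf <- synthetic_design(genome_length = 1e5, n_pools = 1L,
                            samples_per_pool = 200L, n_snp = 150L,
                            n_indel = 0L, n_ssr_variants = 0L,
                            n_ssr_tracts = 0L, hotspot_copies = 0L,
                            maf_fixed = 0.30, missing_rate = 0, seed = 82L)
  gt <- gen_genotypes(gen_genome(d_maf))
  vs <- variant_summaries(gt$matrix)
  # se per variant = sqrt(p(1-p)/(2n)) ~ 0.023; mean over 150 variants
  expect_lt(abs(mean(vs$maf) - 0.30), 0.01)
  expect_true(all(abs(vs$maf - 0.30) < 5 * 0.0229))
  # SSR variants carry planted motifs consistent with genome context
  d_ssr <- small_design(seed = 83L)
  sgs <- gen_genome(d_ssr)
  gts <- gen_genotypes(sgs)
  ssr_rows <- which(gts$matrix$var_type == "SSR")
  expect_gt(length(ssr_rows), 0L)
  for (i in ssr_rows) {
    expect_true(classify_indel_ssr(
      gts$matrix$chrom[i], gts$matrix$pos[i], gts$matrix$ref[i],
      gts$matrix$alt[[i]], sgs$genome),
      info = paste("ssr variant", i))
  }
  # missingness rate recovered by the pipeline's own summary
  d_miss <- synthetic_design(genome_length = 1e5, n_pools = 2L,
                             samples_per_pool = 50L, n_snp = 400L,
                             n_indel = 0L, n_ssr_variants = 0L,
                             n_ssr_tracts = 0L, hotspot_copies = 0L,
                             missing_rate = 0.05, seed = 84L)
  gtm <- gen_genotypes(gen_genome(d_miss))
  rs <- rate_summary(gtm$matrix)
  expect_lt(abs(rs$pct_missing / 100 - 0.05), 0.005)
})

test_that("variant hotspot dominates the density profile", {
  d <- small_design(seed = 91L, n_snp = 400L)
  sg <- gen_genome(d)
  gt <- gen_genotypes(sg)
  sl <- stats::setNames(Biostrings::width(sg$genome), names(sg$genome))
  dens <- density_windows(gt$matrix, seqlengths = sl, window_bp = 1000L)
  top <- dens[which.max(dens$count), ]
  expect_identical(top$chrom, gt$variant_hotspot$chrom)
  expect_identical(top$start, gt$variant_hotspot$start)
  expect_identical(sum(dens$count), n_variants(gt$matrix))
})

test_that("the hotspot region accumulates many-fold more reads per bin", {
  d <- small_design(seed = 95L)
  sg <- gen_genome(d)
  rd <- gen_reads(sg)
  bc <- bin_counts(rd$alignments)
  pooled <- colSums(bc$counts)
  hot <- bc$bins$chrom == sg$hotspot$chrom &
    bc$bins$start >= sg$hotspot$start & bc$bins$start < sg$hotspot$end
  nonzero <- pooled[pooled > 0 & !hot]
  expect_gt(max(pooled[hot]), 5 * stats::median(nonzero))
})

test_that("write_synthetic_dataset materializes a consistent plain-text set", {
  dir <- withr::local_tempdir()
  d <- small_design(seed = 101L)
  objs <- write_synthetic_dataset(d, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "genome.fa", "alignments.tsv", "pools.tsv", "variants.vcf",
    "truth_sites.tsv", "truth_loci.tsv", "truth_ssr.tsv",
    "truth_variants.tsv", "design.json")))))
  g <- read_genome(file.path(dir, "genome.fa"))
  expect_identical(as.character(g), as.character(objs$genome$genome))
  gm <- read_vcf_genotypes(file.path(dir, "variants.vcf"))
  expect_identical(gm$a1, objs$genotypes$matrix$a1)
  pm <- read_pool_map(file.path(dir, "pools.tsv"))
  expect_identical(sort(unique(unname(pm))),
                   sort(unique(objs$reads$yields$pool)))
})
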