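# fixture builder: genotype matrix from a compact spec
# geno: matrix of strings "00" "01" "11" "12" ".." (a1a2 allele indices)
make_gm <- function(geno, ref = NULL, alt = NULL, chrom = NULL, pos = NULL,
                    var_type = NULL) {
  n <- nrow(geno); s <- ncol(geno)
  a1 <- matrix(suppressWarnings(as.integer(substr(geno, 1, 1))), n, s)
  a2 <- matrix(suppressWarnings(as.integer(substr(geno, 2, 2))), n, s)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep(list("G"), n)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  genotype_matrix(chrom, pos, ref, alt, a1, a2,
                  samples = paste0("s", seq_len(s)), var_type = var_type)
}

test_that("ssr_scan honours the per-motif-length thresholds", {
  expect_identical(nrow(ssr_scan(strrep("T", 10))), 1L)
  r <- ssr_scan(strrep("T", 10))
  expect_identical(r$motif, "T")
  expect_identical(r$repeats, 10L)
  expect_true(r$perfect)
  expect_identical(nrow(ssr_scan(strrep("T", 9))), 0L)
  expect_identical(nrow(ssr_scan(strrep("AT", 5))), 0L)   # di needs 6
  expect_identical(nrow(ssr_scan(strrep("AT", 6))), 1L)
  expect_identical(nrow(ssr_scan(strrep("ATG", 5))), 1L)
  expect_identical(nrow(ssr_scan(strrep("ATG", 4))), 0L)
  expect_identical(nrow(ssr_scan(strrep("ACGT", 5))), 1L)
  expect_identical(nrow(ssr_scan(strrep("AACCT", 5))), 1L)
  expect_identical(nrow(ssr_scan(strrep("AGGTTT", 5))), 1L)
  expect_error(ssr_scan("ACGTX"), "non-DNA")
})

test_that("ssr_scan reports maximal runs with correct coordinates", {
  s <- paste0("GCGC", strrep("AT", 7), "GCGC", strrep("A", 12), "C")
  r <- ssr_scan(s)
  expect_identical(nrow(r), 2L)
  at <- r[r$motif == "AT", ]
  expect_identical(at$start, 5L)
  expect_identical(at$end, 4L + 14L)
  expect_identical(at$repeats, 7L)
  pa <- r[r$motif == "A", ]
  expect_identical(pa$repeats, 12L)
  expect_identical(pa$start, 23L)
})

test_that("longer motifs wholly explained by shorter ones are suppressed", {
  r <- ssr_scan(strrep("A", 20))
  expect_identical(r$motif, "A")             # no "AA"/"AAA"/"AAAA" records
  r2 <- ssr_scan(strrep("AT", 8))
  expect_identical(r2$motif, "AT")           # no "ATAT" record
  # N breaks runs and is never part of a repeat
  expect_identical(nrow(ssr_scan(paste0(strrep("T", 5), "N",
                                        strrep("T", 5)))), 0L)
})

test_that("same-motif runs within the interruption merge as imperfect", {
  # two subthreshold poly-T runs, 2-bp interruption, merged 6+6 >= 10
  s <- paste0(strrep("T", 6), "CA", strrep("T", 6))
  r <- ssr_scan(s)
  expect_identical(nrow(r), 1L)
  expect_false(r$perfect)
  expect_identical(r$repeats, 12L)
  expect_identical(r$start, 1L)
  expect_identical(r$end, 14L)
  # gap beyond max_interruption: no merging, both below threshold
  s2 <- paste0(strrep("T", 6), "CACGA", strrep("T", 6))
  expect_identical(nrow(ssr_scan(s2)), 0L)
  expect_identical(nrow(ssr_scan(s2, max_interruption = 5L)), 1L)
})

test_that("classify_indel_ssr detects threshold crossings in context", {
  g <- c(chr1 = paste0(strrep("GCA", 20), strrep("AT", 5), strrep("CGT", 20)))
  # (AT)5 context at 61..70; inserting one AT crosses the 6-unit threshold
  expect_true(classify_indel_ssr("chr1", 60L, ref = "A", alt = "AAT",
                                 genome = g))
  # 1-bp indel in non-repetitive context
  g2 <- c(chr1 = paste0("GACTGACCTGAAGTCCGGATGCCAGT",
                        "TTGCAAGCTTGGCATCCAGAAATTTGGG"))
  expect_false(classify_indel_ssr("chr1", 10L, ref = "G", alt = "GA",
                                  genome = g2))
  expect_error(classify_indel_ssr("chr2", 10L, "A", "AT", g), "chr2")
  expect_error(classify_indel_ssr("chr1", 10000L, "A", "AT", g), "outside")
})

test_that("tstv counts transitions and transversions", {
  r <- tstv(c("A", "C", "A"), c("G", "T", "C"))
  expect_identical(r$transitions, 2L)
  expect_identical(r$transversions, 1L)
  expect_equal(r$ratio, 2.00)
  r2 <- tstv("A", "G")
  expect_true(r2$undefined)
  expect_identical(r2$transversions, 0L)
  # Ts + Tv partitions the processed pairs
  set.seed(1)
  ref <- sample(c("A", "C", "G", "T"), 200, TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                "")
  r3 <- tstv(ref, alt)
  expect_identical(r3$transitions + r3$transversions, 200L)
  # works from a genotype matrix, SNPs only
  gm <- make_gm(matrix(c("00", "01"), 1), ref = "C", alt = list("T"))
  expect_identical(tstv(gm)$transitions, 1L)
})

test_that("indel_stats classifies per alternative allele", {
  r <- indel_stats("A", list("AT"))
  expect_identical(r$insertions, 1L)
  expect_identical(r$deletions, 0L)
  expect_identical(r$length_diff_histogram$diff, 1L)
  # triallelic record contributing one deletion and one insertion
  r2 <- indel_stats("ACGT", list(c("A", "ACGTTT")))
  expect_identical(r2$deletions, 1L)
  expect_identical(r2$insertions, 1L)
  expect_equal(unname(r2$del_ins_ratio), 1.00)
  # equal-length alternative flagged, not counted either way
  r3 <- indel_stats("AC", list(c("GT", "A")))
  expect_identical(r3$flagged_equal_length, 1L)
  expect_identical(r3$deletions, 1L)
  # histogram equals a planted distribution
  set.seed(2)
  diffs <- sample(1:12, 80, TRUE)
  is_del <- sample(c(TRUE, FALSE), 80, TRUE)
  ref <- ifelse(is_del, strrep("A", diffs + 1L), "A")
  alt <- lapply(seq_len(80), function(i)
    if (is_del[i]) "A" else strrep("A", diffs[i] + 1L))
  r4 <- indel_stats(ref, alt)
  expect_identical(r4$deletions, sum(is_del))
  expect_identical(r4$insertions, sum(!is_del))
  expected_hist <- as.vector(table(diffs))
  expect_identical(r4$length_diff_histogram$count, expected_hist)
  expect_equal(sum(r4$classes), 1)
})

test_that("sharing_distribution counts variants by call support", {
  # all present -> mass at k = N
  gm_full <- make_gm(matrix("01", 4, 5))
  sh <- sharing_distribution(gm_full)
  expect_identical(sh$exactly_k, c(0L, 0L, 0L, 0L, 4L))
  # one variant called in exactly 3 of 5 samples
  gm1 <- make_gm(matrix(c("00", "01", "..", "11", ".."), 1, 5))
  expect_identical(sharing_distribution(gm1)$exactly_k,
                   c(0L, 0L, 1L, 0L, 0L))
  # random missingness equals brute-force per-variant count
  set.seed(3)
  g <- matrix(sample(c("00", "01", "11", ".."), 50 * 8, TRUE,
                     prob = c(.4, .2, .2, .2)), 50, 8)
  gm <- make_gm(g)
  sh2 <- sharing_distribution(gm)
  brute <- table(factor(rowSums(g != ".."), levels = 1:8))
  expect_identical(sh2$exactly_k, as.vector(brute, mode = "integer"))
  expect_identical(sum(sh2$exactly_k), sum(rowSums(g != "..") > 0))
  expect_true(all(diff(sh2$at_least_k) <= 0L))
})

test_that("filter_dataset applies strict missingness and inclusive MAF", {
  # 50/50 alleles, no missing: kept at any threshold <= 0.5
  gm_even <- make_gm(matrix(c("00", "11", "00", "11"), 1, 4))
  expect_identical(filter_dataset(gm_even, 0.5, 0.5)$summary$total, 1L)
  # missing exactly at the threshold: excluded (strict <)
  g20 <- matrix("01", 1, 20); g20[1] <- ".."
  gm20 <- make_gm(g20)
  expect_identical(filter_dataset(gm20, 0.05, 0)$summary$total, 0L)
  expect_identical(filter_dataset(gm20, 0.051, 0)$summary$total, 1L)
  # MAF exactly at the threshold: kept (inclusive >=)
  g10 <- matrix("00", 1, 10); g10[1] <- "01"   # MAF 0.05
  gm10 <- make_gm(g10)
  expect_identical(filter_dataset(gm10, 1, 0.05)$summary$total, 1L)
  expect_identical(filter_dataset(gm10, 1, 0.0501)$summary$total, 0L)
  # all-missing variants are excluded and counted
  gm_miss <- make_gm(matrix("..", 2, 4))
  fl <- filter_dataset(gm_miss, 1, 0)
  expect_identical(fl$n_excluded_all_missing, 2L)
  expect_identical(fl$summary$total, 0L)
})

test_that("filter_dataset matches the brute-force oracle on a grid", {
  set.seed(4)
  n_var <- 300L; n_s <- 30L
  g <- matrix(sample(c("00", "01", "11", "02", "12", "22", ".."),
                     n_var * n_s, TRUE,
                     prob = c(.35, .2, .1, .05, .05, .05, .2)), n_var, n_s)
  tri <- sample(c(TRUE, FALSE), n_var, TRUE, prob = c(.3, .7))
  g[!tri, ] <- gsub("2", "1", g[!tri, ])
  alt <- ifelse(tri, list(c("G", "T")), list("G"))
  gm <- make_gm(g, alt = alt)
  a1 <- matrix(suppressWarnings(as.integer(substr(g, 1, 1))), n_var, n_s)
  a2 <- matrix(suppressWarnings(as.integer(substr(g, 2, 2))), n_var, n_s)
  n_alt <- ifelse(tri, 2L, 1L)
  for (mm in c(0.05, 0.2, 0.5)) {
    for (maf in c(0.01, 0.05, 0.25)) {
      expect_identical(filter_dataset(gm, mm, maf)$kept,
                       oracle_filter(a1, a2, n_alt, mm, maf),
                       info = sprintf("mm=%g maf=%g", mm, maf))
    }
  }
})

test_that("rate_summary counts data points, missingness, heterozygosity", {
  g <- matrix(c("00", "01", "..", "11", "00", "01"), 2, 3)
  gm <- make_gm(g)
  rs <- rate_summary(gm)
  expect_equal(rs$data_points, 6)
  expect_equal(rs$pct_missing, 100 / 6)
  expect_equal(rs$pct_heterozygous, 200 / 6)
  gm_ref <- make_gm(matrix("00", 3, 4))
  rs2 <- rate_summary(gm_ref)
  expect_equal(rs2$pct_missing, 0)
  expect_equal(rs2$pct_heterozygous, 0)
})

test_that("density_windows tiles the genome and sums to the variant count", {
  sl <- c(chr1 = 2500L)
  d1 <- density_windows("chr1", 1500L, sl)
  expect_identical(sum(d1$count), 1L)
  expect_identical(d1$count[2], 1L)
  d2 <- density_windows(c("chr1", "chr1"), c(120L, 220L), sl)
  expect_identical(d2$count[1], 2L)
  expect_identical(d2$end[3], 2500L)
  expect_error(density_windows("chr1", 9999L, sl), "outside")
})

test_that("variants_per_common_site floors the division", {
  expect_identical(variants_per_common_site(2026509, 6819), 297L)
  expect_identical(variants_per_common_site(1000, 10), 100L)
  expect_identical(variants_per_common_site(7, 2), 3L)
  expect_error(variants_per_common_site(1000, 0), "> 0")
})

test_that("allele classes and SSR composition partition their totals", {
  gm <- make_gm(matrix("01", 3, 2),
                alt = list("G", c("G", "T"), c("G", "T", "C")))
  ac <- allele_classes(gm)
  expect_identical(unname(ac), c(1L, 1L, 1L))
  expect_identical(sum(ac), 3L)
  recs <- rbind(ssr_scan(strrep("T", 10)), ssr_scan(strrep("AT", 6)),
                ssr_scan(strrep("AG", 7)), ssr_scan(strrep("ATG", 5)))
  comp <- ssr_motif_composition(recs)
  expect_identical(comp$total, 4L)
  expect_identical(sum(comp$by_length$count), comp$total)
  expect_equal(sum(comp$by_length$fraction), 1)
  expect_identical(sum(comp$by_motif$count), comp$total)
})

test_that("VCF round-trip preserves genotypes, alleles and types", {
  set.seed(5)
  g <- matrix(sample(c("00", "01", "11", ".."), 20 * 6, TRUE), 20, 6)
  types <- sample(c("SNP", "InDel", "SSR"), 20, TRUE)
  ref <- ifelse(types == "SNP", "A", "AT")
  alt <- lapply(types, function(t) if (t == "SNP") "G" else "A")
  gm <- make_gm(g, ref = ref, alt = alt, var_type = types)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_genotypes(gm, path, contigs = c(chr1 = 100000L))
  back <- read_vcf_genotypes(path)
  expect_identical(back$a1, gm$a1)
  expect_identical(back$a2, gm$a2)
  expect_identical(back$ref, gm$ref)
  expect_identical(back$alt, gm$alt)
  expect_identical(back$var_type, gm$var_type)
  expect_identical(back$samples, gm$samples)
  # half-calls become missing at construction
  a1 <- matrix(c(0L, NA), 1, 2); a2 <- matrix(c(NA, 1L), 1, 2)
  gm_half <- genotype_matrix("chr1", 5L, "A", list("G"), a1, a2,
                             c("x", "y"))
  expect_true(all(is.na(gm_half$a1)))
})
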