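#' Transition/transversion ratio
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine substitutions
#' (A<->G, C<->T); everything else is a transversion. Operates on biallelic
#' SNP allele pairs; the ratio is reported to two decimals and flagged
#' undefined when no transversions were seen.
#'
#' @param ref,alt Equal-length character vectors of single-base alleles, or
#'   `ref` may be a `genotype_matrix` whose biallelic SNPs are used (then
#'   `alt` is ignored).
#' @return List: `transitions`, `transversions`, `ratio` (NA + flag when
#'   undefined), `undefined`.
#' @examples
#' tstv(c("A", "C", "A"), c("G", "T", "C"))  # 2 Ts, 1 Tv, 2.00
#' @export
tstv <- function(ref, alt = NULL) {
  if (inherits(ref, "genotype_matrix")) {
    gm <- ref
    keep <- gm$var_type == "SNP" & lengths(gm$alt) == 1L
    ref <- gm$ref[keep]
    alt <- vapply(gm$alt[keep], `[[`, "", 1L)
  }
  stopifnot(length(ref) == length(alt))
  ok <- nchar(ref) == 1L & nchar(alt) == 1L
  if (!all(ok)) stop("tstv() expects single-base alleles", call. = FALSE)
  pair <- paste0(pmin(ref, alt), pmax(ref, alt))
  ts <- sum(pair %in% c("AG", "CT"))
  tv <- length(pair) - ts
  list(transitions = ts, transversions = tv,
       ratio = if (tv > 0) round(ts / tv, 2L) else NA_real_,
       undefined = tv == 0L)
}

#' Insertion/deletion statistics
#'
#' Classifies every alternative allele of every InDel against its reference:
#' a deletion when the alternative is shorter, an insertion when longer
#' (a triallelic InDel can contribute one of each, so alleles rather than
#' records are counted). Reports the deletion/insertion ratio (two
#' decimals), the distribution of absolute length differences, and the
#' length-difference classes 1-2, 3-10 and 11+ bp as fractions.
#'
#' @param ref Character vector of reference alleles, or a `genotype_matrix`
#'   (its `InDel` and `SSR` records are used; `alt` then ignored).
#' @param alt List of character vectors of alternative alleles.
#' @return List: `deletions`, `insertions`, `del_ins_ratio`,
#'   `length_diff_histogram` (`data.table` diff/count), `classes` (named
#'   fractions), `n_alleles`, `flagged_equal_length` (alt same length as
#'   ref: not an InDel).
#' @examples
#' indel_stats("A", list("AT"))  # one insertion of 1 bp
#' @export
indel_stats <- function(ref, alt = NULL) {
  if (inherits(ref, "genotype_matrix")) {
    gm <- ref
    keep <- gm$var_type %in% c("InDel", "SSR")
    alt <- gm$alt[keep]
    ref <- gm$ref[keep]
  }
  stopifnot(length(ref) == length(alt))
  rl <- rep(nchar(ref), lengths(alt))
  al <- nchar(unlist(alt, use.names = FALSE))
  diff <- al - rl
  equal <- sum(diff == 0L)
  del <- sum(diff < 0L)
  ins <- sum(diff > 0L)
  adiff <- abs(diff[diff != 0L])
  hist <- data.table::as.data.table(table(diff = adiff))
  if (nrow(hist)) hist[, diff := as.integer(diff)]
  data.table::setnames(hist, c("diff", "count"))
  n <- length(adiff)
  classes <- if (n > 0) {
    c(`1-2` = sum(adiff <= 2L) / n,
      `3-10` = sum(adiff >= 3L & adiff <= 10L) / n,
      `11+` = sum(adiff >= 11L) / n)
  } else c(`1-2` = NA_real_, `3-10` = NA_real_, `11+` = NA_real_)
  list(deletions = del, insertions = ins,
       del_ins_ratio = if (ins > 0) round(del / ins, 2L) else NA_real_,
       length_diff_histogram = hist, classes = classes,
       n_alleles = length(diff), flagged_equal_length = equal)
}

#' Variant-sharing distribution
#'
#' For each k = 1..N, counts variants genotyped (non-missing) in exactly k
#' samples; the total mass equals the number of variants with at least one
#' call. The cumulative "present in >= k samples" curve is monotone
#' non-increasing.
#'
#' @param x A `genotype_matrix`.
#' @param by_type Also return per-variant-type distributions.
#' @return List: `k` (1..N), `exactly_k`, `at_least_k`, `n_uncalled`
#'   (all-missing variants), and `by_type` when requested.
#' @export
sharing_distribution <- function(x, by_type = FALSE) {
  stopifnot(inherits(x, "genotype_matrix"))
  n_s <- length(x$samples)
  n_called <- rowSums(!is.na(x$a1))
  count_k <- function(nc) tabulate(nc[nc > 0L], nbins = n_s)
  exactly <- count_k(n_called)
  out <- list(k = seq_len(n_s), exactly_k = exactly,
              at_least_k = rev(cumsum(rev(exactly))),
              n_uncalled = sum(n_called == 0L))
  if (by_type) {
    out$by_type <- lapply(split(seq_along(n_called), x$var_type),
                          function(i) count_k(n_called[i]))
  }
  out
}

#' Filter a genotype matrix on missingness and MAF
#'
#' Keeps a variant iff its missing fraction is strictly below
#' `max_missing_fraction` *and* its minor allele frequency is at least
#' `min_maf` (the strict/inclusive asymmetry mirrors the usual "< 5% missing
#' data, MAF >= 1%" phrasing). Missing fraction is computed over all
#' samples; MAF over called alleles (see [variant_summaries()]). All-missing
#' variants are excluded and counted separately.
#'
#' @param x A `genotype_matrix`.
#' @param max_missing_fraction Strict upper bound on missing fraction.
#' @param min_maf Inclusive lower bound on MAF.
#' @param maf_mode See [variant_summaries()].
#' @return List: `matrix` (filtered `genotype_matrix`), `summary` (kept
#'   counts per var_type plus total), `n_excluded_all_missing`, `kept`
#'   (logical over input variants).
#' @export
filter_dataset <- function(x, max_missing_fraction = 0.05, min_maf = 0.01,
                           maf_mode = c("second_most", "one_minus_major")) {
  stopifnot(inherits(x, "genotype_matrix"),
            max_missing_fraction >= 0, max_missing_fraction <= 1,
            min_maf >= 0, min_maf <= 1)
  vs <- variant_summaries(x, maf_mode = match.arg(maf_mode))
  all_missing <- vs$n_called == 0L
  kept <- !all_missing &
    vs$missing_fraction < max_missing_fraction &
    !is.na(vs$maf) & vs$maf >= min_maf
  fm <- subset_variants(x, kept)
  counts <- table(factor(fm$var_type, levels = c("SNP", "InDel", "SSR")))
  list(matrix = fm,
       summary = c(as.list(counts), total = n_variants(fm)),
       n_excluded_all_missing = sum(all_missing),
       kept = kept)
}

#' Data-point, missingness and heterozygosity rates
#'
#' Data points are `n_variants * n_samples` genotype cells; the missing and
#' heterozygous percentages are taken over all data points.
#'
#' @param x A `genotype_matrix`.
#' @return List: `data_points`, `pct_missing`, `pct_heterozygous`.
#' @export
rate_summary <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  dp <- as.numeric(n_variants(x)) * length(x$samples)
  if (dp == 0) stop("empty genotype matrix", call. = FALSE)
  n_missing <- sum(is.na(x$a1))
  n_het <- sum(x$a1 != x$a2, na.rm = TRUE)
  list(data_points = dp,
       pct_missing = 100 * n_missing / dp,
       pct_heterozygous = 100 * n_het / dp)
}

#' Per-window variant density
#'
#' Counts variants in fixed-width windows tiling each chromosome (the
#' "SNPs per 1-kb window" view used to spot density hot spots).
#'
#' @param chrom,pos Variant coordinates (`pos` 1-based), or `chrom` may be a
#'   `genotype_matrix`.
#' @param seqlengths Named chromosome lengths.
#' @param window_bp Window width (default 1000).
#' @return `data.table` chrom/start/end/count tiling the genome;
#'   `sum(count)` equals the variant count.
#' @export
density_windows <- function(chrom, pos = NULL, seqlengths, window_bp = 1000L) {
  if (inherits(chrom, "genotype_matrix")) {
    pos <- chrom$pos
    chrom <- chrom$chrom
  }
  stopifnot(length(chrom) == length(pos), window_bp >= 1L)
  if (length(pos) && (any(pos < 1L) || any(pos > seqlengths[chrom]))) {
    stop("variant positions outside chromosome bounds", call. = FALSE)
  }
  out <- data.table::rbindlist(lapply(names(seqlengths), function(ch) {
    nb <- max(1L, as.integer(ceiling(seqlengths[[ch]] / window_bp)))
    starts <- seq(0L, by = window_bp, length.out = nb)
    cnt <- tabulate((pos[chrom == ch] - 1L) %/% window_bp + 1L, nbins = nb)
    data.table::data.table(chrom = ch, start = starts,
                           end = pmin(starts + window_bp, seqlengths[[ch]]),
                           count = cnt)
  }))
  out[]
}

#' Sites scrutinized per variant
#'
#' How many commonly covered genome positions were screened for each variant
#' genotyped across the whole sample set: the floor of common sites divided
#' by universal variants.
#'
#' @param total_common_sites Positions covered in all samples (> 0).
#' @param n_universal_variants Variants genotyped in all samples (> 0).
#' @return Integer ratio (floor).
#' @examples
#' variants_per_common_site(2026509, 6819)  # 297
#' @export
variants_per_common_site <- function(total_common_sites,
                                     n_universal_variants) {
  stopifnot(total_common_sites > 0)
  if (n_universal_variants <= 0) {
    stop("n_universal_variants must be > 0", call. = FALSE)
  }
  as.integer(total_common_sites %/% n_universal_variants)
}

#' Allele-count classes of a genotype matrix
#'
#' Bi-, tri- and tetraallelic record counts (reference + alternatives),
#' partitioning the total.
#'
#' @param x A `genotype_matrix`.
#' @return Named integer vector `c(biallelic, triallelic, tetraallelic)`.
#' @export
allele_classes <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  k <- lengths(x$alt) + 1L
  c(biallelic = sum(k == 2L), triallelic = sum(k == 3L),
    tetraallelic = sum(k == 4L))
}
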