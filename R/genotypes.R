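#' Genotype matrix
#'
#' Variants x samples diploid calls with allele metadata: the unit of the
#' filtering and sharing analyses. Genotypes are stored as two integer
#' allele matrices (`0` = reference, `1..k` = alternative allele index,
#' `NA` = missing; half-calls are treated as missing). Variant types are
#' `SNP` (all alleles length 1), `InDel`, or `SSR` (an InDel whose alleles
#' sit in a microsatellite context, see [classify_indel_ssr()]).
#'
#' @param chrom,pos Variant coordinates (`pos` 1-based).
#' @param ref Reference alleles (A/C/G/T strings).
#' @param alt List of character vectors of alternative alleles (1-3 each).
#' @param a1,a2 Integer allele matrices (variants x samples).
#' @param samples Sample names.
#' @param var_type Optional type vector; inferred from allele lengths when
#'   `NULL` (`SSR` labels require explicit assignment or classification).
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, a1, a2, samples,
                            var_type = NULL) {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n,
            nrow(a1) == n, nrow(a2) == n,
            ncol(a1) == length(samples), ncol(a2) == length(samples))
  alt <- lapply(alt, as.character)
  n_alt <- lengths(alt)
  if (any(n_alt < 1L | n_alt > 3L)) {
    stop("each variant needs 1-3 alternative alleles", call. = FALSE)
  }
  bad <- !grepl("^[ACGT]+$", ref) |
    !vapply(alt, function(a) all(grepl("^[ACGT]+$", a)), TRUE)
  if (any(bad)) stop("alleles must be non-empty A/C/G/T strings",
                     call. = FALSE)
  # half-calls -> fully missing
  half <- xor(is.na(a1), is.na(a2))
  a1[half] <- NA_integer_; a2[half] <- NA_integer_
  if (is.null(var_type)) {
    is_snp <- nchar(ref) == 1L &
      vapply(alt, function(a) all(nchar(a) == 1L), TRUE)
    var_type <- ifelse(is_snp, "SNP", "InDel")
  }
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = alt,
         a1 = a1, a2 = a2, samples = as.character(samples),
         var_type = as.character(var_type)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  tt <- table(x$var_type)
  cat(sprintf("<genotype_matrix> %d variants x %d samples (%s)\n",
              length(x$pos), length(x$samples),
              paste(sprintf("%s: %d", names(tt), tt), collapse = ", ")))
  invisible(x)
}

#' Number of variants in a genotype matrix
#' @param x A `genotype_matrix`.
#' @return Integer variant count.
#' @export
n_variants <- function(x) length(x$pos)

#' Subset a genotype matrix by variant index
#' @param x A `genotype_matrix`.
#' @param i Integer or logical index over variants.
#' @return A `genotype_matrix`.
#' @export
subset_variants <- function(x, i) {
  genotype_matrix(x$chrom[i], x$pos[i], x$ref[i], x$alt[i],
                  x$a1[i, , drop = FALSE], x$a2[i, , drop = FALSE],
                  x$samples, x$var_type[i])
}

#' Read genotypes from a VCF
#'
#' Loads a plain or bgzipped VCF with GT fields via
#' [VariantAnnotation::readVcf()] and converts it to a [genotype_matrix()].
#' Phased and unphased separators are accepted; half-calls become missing.
#' If an INFO field `VT` is present with value `SSR` the variant type is
#' taken from it, otherwise types are inferred from allele lengths.
#'
#' @param path VCF path.
#' @return A `genotype_matrix`.
#' @export
read_vcf_genotypes <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.list(S4Vectors::split(
    as.character(unlist(VariantAnnotation::alt(vcf))),
    rep(seq_len(nrow(gt)), lengths(VariantAnnotation::alt(vcf)))))
  alt <- unname(alt)
  parse_allele <- function(tok) {
    out <- suppressWarnings(as.integer(tok))
    out
  }
  toks <- strsplit(gt, "[/|]")
  a1 <- matrix(vapply(toks, function(t) parse_allele(t[1L]), 0L),
               nrow = nrow(gt), ncol = ncol(gt))
  a2 <- matrix(vapply(toks, function(t)
    if (length(t) >= 2L) parse_allele(t[2L]) else NA_integer_, 0L),
    nrow = nrow(gt), ncol = ncol(gt))
  info <- VariantAnnotation::info(vcf)
  vt <- if ("VT" %in% names(info)) as.character(info$VT) else NULL
  gm <- genotype_matrix(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt, a1 = a1, a2 = a2, samples = colnames(gt),
    var_type = vt)
  gm
}

#' Write a genotype matrix as a minimal VCFv4.2 file
#'
#' Plain-text writer used by the synthetic generator and the filtered
#' pass-through; records carry an INFO `VT` tag with the variant type and
#' unphased GT fields. Round-trips through [read_vcf_genotypes()].
#'
#' @param x A `genotype_matrix`.
#' @param path Output path (`.vcf`).
#' @param contigs Optional named vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(x, path, contigs = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=ddradtools",
           '##INFO=<ID=VT,Number=1,Type=String,Description="Variant type">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", x$samples),
                      collapse = "\t"))
  gt_str <- matrix(".", nrow = n_variants(x), ncol = length(x$samples))
  called <- !is.na(x$a1)
  gt_str[called] <- paste0(x$a1[called], "/", x$a2[called])
  gt_str[!called] <- "./."
  body <- vapply(seq_len(n_variants(x)), function(i) {
    paste(c(x$chrom[i], x$pos[i], ".", x$ref[i],
            paste(x$alt[[i]], collapse = ","), ".", "PASS",
            paste0("VT=", x$var_type[i]), "GT", gt_str[i, ]),
          collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Per-variant summaries used by filtering and rate reporting ------------------

#' Per-variant missingness, MAF and heterozygosity
#'
#' Missing fraction is computed over all samples; MAF defaults to the
#' frequency of the second-most-frequent allele among called alleles (two
#' per called diploid genotype), with `"one_minus_major"` available for the
#' alternative convention on multiallelic sites; het fraction is over called
#' genotypes.
#'
#' @param x A `genotype_matrix`.
#' @param maf_mode `"second_most"` (default) or `"one_minus_major"`.
#' @return `data.table` with columns missing_fraction, maf, het_fraction,
#'   n_called.
#' @export
variant_summaries <- function(x, maf_mode = c("second_most",
                                              "one_minus_major")) {
  maf_mode <- match.arg(maf_mode)
  n_s <- length(x$samples)
  called <- !is.na(x$a1)
  n_called <- rowSums(called)
  # computed from the missing count directly so threshold comparisons at
  # exact fractions (e.g. 6/30 vs a 0.2 bound) are not perturbed by 1 - x
  n_missing <- n_s - n_called
  het <- rowSums(x$a1 != x$a2, na.rm = TRUE)
  maf <- vapply(seq_len(n_variants(x)), function(i) {
    a <- c(x$a1[i, ], x$a2[i, ])
    a <- a[!is.na(a)]
    if (!length(a)) return(NA_real_)
    f <- sort(tabulate(a + 1L, nbins = length(x$alt[[i]]) + 1L) / length(a),
              decreasing = TRUE)
    if (maf_mode == "second_most") {
      if (length(f) >= 2L) f[2L] else 0
    } else 1 - f[1L]
  }, 0)
  data.table::data.table(
    missing_fraction = n_missing / n_s,
    maf = maf,
    het_fraction = ifelse(n_called > 0, het / n_called, NA_real_),
    n_called = n_called)
}
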