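# Independent brute-force oracles. These deliberately avoid Biostrings,
# IRanges and the package's own code paths.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# every 0-based cut position of `recognition` in `sequence` (top strand),
# character-by-character IUPAC comparison; N in the sequence only matches N
oracle_cut_sites <- function(sequence, recognition, cut_offset) {
  s <- strsplit(toupper(sequence), "")[[1L]]
  m <- strsplit(toupper(recognition), "")[[1L]]
  n <- length(s); k <- length(m)
  hits <- integer(0)
  for (i in seq_len(max(0L, n - k + 1L))) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!s[i + j - 1L] %in% IUPAC_SETS[[m[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i - 1L + cut_offset)
  }
  sort(unique(hits))
}

# brute-force double digest of one chromosome: data.frame of fragments
oracle_digest_chrom <- function(sequence, enzymes) {
  cuts <- integer(0); labs <- character(0)
  for (e in enzymes) {
    p <- oracle_cut_sites(sequence, e$recognition, e$cut_offset)
    p <- p[p > 0 & p < nchar(sequence)]
    cuts <- c(cuts, p); labs <- c(labs, rep(e$name, length(p)))
  }
  o <- order(cuts, labs)
  cuts <- cuts[o]; labs <- labs[o]
  keep <- !duplicated(cuts)
  cuts <- cuts[keep]; labs <- labs[keep]
  b <- c(0L, cuts, nchar(sequence))
  data.frame(start = b[-length(b)], end = b[-1L],
             left_end = c("CHROM_END", labs),
             right_end = c(labs, "CHROM_END"),
             stringsAsFactors = FALSE)
}

# naive per-position pileup: integer depth vector of length L
oracle_pileup <- function(starts, ends, L) {
  depth <- integer(L)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) {
      idx <- (starts[i] + 1L):ends[i]
      depth[idx] <- depth[idx] + 1L
    }
  }
  depth
}

# positions (1-based) covered >= depth_min in every sample, via explicit sets
oracle_common_sites <- function(seg_by_sample, L, depth_min = 1L) {
  sets <- lapply(seg_by_sample, function(sg) {
    which(oracle_pileup(sg$start, sg$end, L) >= depth_min)
  })
  length(Reduce(intersect, sets))
}

# brute-force variant filter on explicit allele matrices
oracle_filter <- function(a1, a2, n_alt, max_missing, min_maf) {
  n_var <- nrow(a1); n_s <- ncol(a1)
  keep <- logical(n_var)
  for (i in seq_len(n_var)) {
    miss <- sum(is.na(a1[i, ]))
    alleles <- c(a1[i, ], a2[i, ]); alleles <- alleles[!is.na(alleles)]
    if (!length(alleles)) next
    freq <- sort(table(factor(alleles, levels = 0:n_alt[i])) /
                   length(alleles), decreasing = TRUE)
    maf <- if (length(freq) >= 2L) as.numeric(freq[2L]) else 0
    keep[i] <- (miss / n_s) < max_missing && maf >= min_maf
  }
  keep
}

# random genome with a few planted motifs, for digestion oracle tests
random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# tiny alignment fixture: named list sample -> data.frame(chrom,start,end)
make_toy_alignments <- function(seg_by_sample, L, chrom = "chr1") {
  dt <- data.table::rbindlist(lapply(names(seg_by_sample), function(s) {
    data.table::data.table(sample = s, chrom = chrom,
                           start = seg_by_sample[[s]]$start,
                           end = seg_by_sample[[s]]$end, mapq = 60L)
  }))
  if (!nrow(dt)) {
    dt <- data.table::data.table(sample = character(0), chrom = character(0),
                                 start = integer(0), end = integer(0),
                                 mapq = integer(0))
  }
  alignment_set(dt, stats::setNames(L, chrom))
}
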