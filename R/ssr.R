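# Is the motif irreducible, i.e. not itself a repetition of a shorter unit?
# "ATAT" reduces to "AT"; "AAA" to "A". Checked over proper divisors.
.is_irreducible_motif <- function(motif) {
  m <- nchar(motif)
  if (m == 1L) return(TRUE)
  for (d in seq_len(m - 1L)) {
    if (m %% d == 0L &&
        identical(strrep(substr(motif, 1L, d), m %/% d), motif)) {
      return(FALSE)
    }
  }
  TRUE
}

# Maximal tandem runs of irreducible motifs of length m with >= 2 copies.
# chars: character vector of the sequence. Returns data.table
# (motif, repeats, start, end) with 1-based inclusive coordinates trimmed to
# whole motif copies.
.tandem_runs <- function(chars, m) {
  n <- length(chars)
  if (n < 2L * m) {
    return(data.table::data.table(motif = character(0), repeats = integer(0),
                                  start = integer(0), end = integer(0)))
  }
  ok <- chars %in% c("A", "C", "G", "T")
  eq <- chars[seq_len(n - m)] == chars[seq_len(n - m) + m] &
        ok[seq_len(n - m)]
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= m)   # >= 2 full copies
  rows <- lapply(keep, function(k) {
    i0 <- starts[k]
    tract_len <- r$lengths[k] + m
    repeats <- tract_len %/% m
    motif <- paste(chars[i0:(i0 + m - 1L)], collapse = "")
    if (!.is_irreducible_motif(motif)) return(NULL)
    data.table::data.table(motif = motif, repeats = repeats,
                           start = i0, end = i0 + repeats * m - 1L)
  })
  out <- data.table::rbindlist(rows)
  if (!nrow(out)) {
    out <- data.table::data.table(motif = character(0), repeats = integer(0),
                                  start = integer(0), end = integer(0))
  }
  out
}

#' Scan a sequence for microsatellites (SSRs)
#'
#' Finds maximal perfect tandem runs of every irreducible motif of 1-6 nt
#' and keeps those meeting the MISA-style minimum repeat-unit thresholds:
#' 10 for mononucleotides, 6 for dinucleotides and 5 for tri- to
#' hexanucleotides. Runs of a longer motif wholly explained by a shorter one
#' (e.g. an `AA` unit inside a poly-A run) are suppressed via motif
#' irreducibility. Two runs of the *same* motif separated by at most
#' `max_interruption` bases merge into one *imperfect* SSR when their summed
#' repeat count meets the threshold (Weber-style interrupted repeat).
#'
#' @param sequence DNA string (A/C/G/T, `N` allowed and never part of a
#'   repeat; other characters are an error).
#' @param min_repeats Named integer vector: minimum repeat units per motif
#'   length `"1"`-`"6"`.
#' @param max_interruption Maximum gap (bp) between same-motif runs merged
#'   into an imperfect SSR (default 4).
#' @return `data.table` with columns motif, repeats, start, end (1-based
#'   inclusive), perfect.
#' @examples
#' ssr_scan(strrep("T", 10))      # one mononucleotide SSR
#' ssr_scan(strrep("AT", 5))      # none: dinucleotides need 6 units
#' @export
ssr_scan <- function(sequence,
                     min_repeats = c(`1` = 10L, `2` = 6L, `3` = 5L,
                                     `4` = 5L, `5` = 5L, `6` = 5L),
                     max_interruption = 4L) {
  sequence <- toupper(as.character(sequence))
  stopifnot(length(sequence) == 1L)
  if (!grepl("^[ACGTN]*$", sequence)) {
    stop("sequence contains non-DNA characters", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  runs <- data.table::rbindlist(
    lapply(1:6, function(m) .tandem_runs(chars, m)))
  empty <- data.table::data.table(
    motif = character(0), repeats = integer(0), start = integer(0),
    end = integer(0), perfect = logical(0))
  if (!nrow(runs)) return(empty)
  out <- list()
  for (mf in unique(runs$motif)) {
    thr <- min_repeats[[as.character(nchar(mf))]]
    # merge candidates must carry at least half the threshold on their own:
    # without this floor, incidental 2-copy runs (e.g. the AA inside every
    # AACCT unit) chain into spurious "imperfect" mononucleotide SSRs
    rr <- runs[runs$motif == mf & 2L * runs$repeats >= thr, ]
    if (!nrow(rr)) next
    data.table::setorderv(rr, "start")
    # chain same-motif runs whose gaps are <= max_interruption bases of
    # called sequence (an N in the gap breaks the chain)
    gaps_ok <- if (nrow(rr) > 1L) {
      vapply(seq_len(nrow(rr) - 1L), function(i) {
        gap <- rr$start[i + 1L] - rr$end[i] - 1L
        gap <= max_interruption &&
          !any(chars[seq(rr$end[i] + 1L, length.out = gap)] == "N")
      }, TRUE)
    } else logical(0)
    cluster <- cumsum(c(1L, !gaps_ok))
    for (cl in unique(cluster)) {
      cc <- rr[cluster == cl, ]
      total <- sum(cc$repeats)
      if (total < thr) next
      out[[length(out) + 1L]] <- data.table::data.table(
        motif = mf, repeats = total,
        start = cc$start[1L], end = cc$end[nrow(cc)],
        perfect = nrow(cc) == 1L)
    }
  }
  if (!length(out)) return(empty)
  res <- data.table::rbindlist(out)
  data.table::setorderv(res, c("start", "motif"))
  res[]
}

#' Classify an InDel as microsatellite-associated
#'
#' Re-creates the published procedure of feeding called InDels to a
#' microsatellite finder: each allele (reference and alternatives) is
#' embedded in its flanking genomic context and scanned with [ssr_scan()];
#' the variant is labeled `SSR` when any detected repeat overlaps the
#' allele's position in that constructed sequence. This flank-embedding is
#' one defensible reading of the published pipeline and is documented as
#' such.
#'
#' @param chrom,pos Variant location (`pos` 1-based, VCF convention: `ref`
#'   starts at `pos`).
#' @param ref,alt Reference allele and character vector of alternatives.
#' @param genome Named sequences (as for [digest()]).
#' @param flank Flank length in bp (default 50).
#' @param ... Passed to [ssr_scan()].
#' @return `TRUE` if any allele yields an overlapping SSR, else `FALSE`.
#' @export
classify_indel_ssr <- function(chrom, pos, ref, alt, genome, flank = 50L,
                               ...) {
  genome <- .as_genome(genome)
  if (!chrom %in% names(genome)) {
    stop("chromosome ", chrom, " not in genome", call. = FALSE)
  }
  seq_len_chrom <- Biostrings::width(genome[names(genome) == chrom])[1L]
  ref_end <- pos + nchar(ref) - 1L
  if (pos < 1L || ref_end > seq_len_chrom) {
    stop("variant falls outside chromosome ", chrom,
         "; flanks unavailable", call. = FALSE)
  }
  left_start <- max(1L, pos - flank)
  right_end <- min(seq_len_chrom, ref_end + flank)
  full <- as.character(Biostrings::subseq(genome[[which(names(genome) == chrom)]],
                                          left_start, right_end))
  left_len <- pos - left_start
  right_part <- substr(full, left_len + nchar(ref) + 1L, nchar(full))
  left_part <- substr(full, 1L, left_len)
  for (allele in c(ref, alt)) {
    ctx <- paste0(left_part, allele, right_part)
    hits <- ssr_scan(ctx, ...)
    if (!nrow(hits)) next
    a_start <- left_len + 1L
    a_end <- left_len + nchar(allele)
    if (any(hits$start <= a_end & hits$end >= a_start)) return(TRUE)
  }
  FALSE
}

#' SSR motif composition report
#'
#' Tabulates SSR records by motif and motif length; motifs are reported
#' as found (no reverse-complement merging, so `AG` and `CT` count
#' separately). Length-class counts partition the total and per-length motif
#' fractions sum to 1.
#'
#' @param records `data.table` from [ssr_scan()] (or rows binded from many
#'   scans) with at least a `motif` column; a `perfect` column is summarized
#'   when present.
#' @return List with `total`, `by_length` (`data.table` motif_length, count,
#'   fraction), `by_motif` (`data.table` motif, motif_length, count), and
#'   perfect/imperfect counts when available.
#' @export
ssr_motif_composition <- function(records) {
  dt <- data.table::as.data.table(records)
  stopifnot("motif" %in% names(dt))
  dt[, motif_length := nchar(motif)]
  by_motif <- dt[, .(count = .N), by = c("motif", "motif_length")]
  data.table::setorderv(by_motif, c("motif_length", "motif"))
  by_length <- dt[, .(count = .N), by = "motif_length"]
  data.table::setorderv(by_length, "motif_length")
  by_length[, fraction := count / sum(count)]
  out <- list(total = nrow(dt), by_length = by_length[],
              by_motif = by_motif[])
  if ("perfect" %in% names(dt)) {
    out$perfect <- sum(dt$perfect)
    out$imperfect <- sum(!dt$perfect)
  }
  out
}
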