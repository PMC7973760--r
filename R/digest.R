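#' Locate restriction cut sites in a sequence
#'
#' Scans a nucleotide sequence for every occurrence of an enzyme's IUPAC
#' recognition motif and returns the cut positions as 0-based between-base
#' indices: a motif match starting at 0-based index `i` yields a cut at
#' `i + cut_offset`. Matching is case-insensitive; IUPAC ambiguity codes in
#' the motif are expanded, while ambiguity codes in the *sequence* are taken
#' literally, so an `N` in the genome never matches a non-N motif code.
#' For non-palindromic motifs both strands are scanned and the bottom-strand
#' cut is reported at its top-strand coordinate; the six built-in enzymes are
#' all palindromic, so for them a single top-strand scan suffices.
#'
#' @param sequence A single nucleotide string or a [Biostrings::DNAString].
#' @param enzyme A [restriction_enzyme()] or built-in enzyme name.
#' @return Strictly increasing integer vector of deduplicated 0-based cut
#'   positions.
#' @examples
#' find_cut_sites("AACTGCAGAA", "PstI")  # 7
#' @export
find_cut_sites <- function(sequence, enzyme) {
  enzyme <- .as_enzyme(enzyme)
  subject <- if (inherits(sequence, "DNAString")) sequence
             else Biostrings::DNAString(toupper(as.character(sequence)))
  motif <- Biostrings::DNAString(enzyme$recognition)
  len <- nchar(enzyme$recognition)
  # fixed = "subject": ambiguity codes in the pattern are interpreted,
  # letters in the subject are literal (N never matches a non-N code).
  hits <- Biostrings::matchPattern(motif, subject, fixed = "subject")
  cuts <- BiocGenerics::start(hits) - 1L + enzyme$cut_offset
  if (!.is_palindromic(enzyme$recognition)) {
    rc <- Biostrings::reverseComplement(motif)
    hits2 <- Biostrings::matchPattern(rc, subject, fixed = "subject")
    # bottom-strand cut at offset c from the motif start maps to top-strand
    # coordinate i + (len - c) for a reverse-complement match at i
    cuts2 <- BiocGenerics::start(hits2) - 1L + (len - enzyme$cut_offset)
    cuts <- c(cuts, cuts2)
  }
  sort(unique(as.integer(cuts)))
}

#' In silico restriction digestion
#'
#' Digests each sequence of a genome with one or two restriction enzymes.
#' Cut positions of all enzymes are merged and sorted; the resulting
#' fragments are the intervals between consecutive cuts plus the two terminal
#' intervals, so the fragments of a chromosome tile it exactly. Each internal
#' fragment boundary is labeled with the enzyme that produced the cut;
#' terminal boundaries carry the sentinel `"CHROM_END"`. When both enzymes
#' cut at the same between-base position, one boundary is kept, labeled with
#' the lexicographically smaller enzyme name, and the event is tallied in the
#' `coincident_cuts` diagnostic.
#'
#' @param genome Named character vector, named list of strings, or
#'   [Biostrings::DNAStringSet]. Names are chromosome identifiers.
#' @param enzymes One or two enzymes ([restriction_enzyme()] objects or
#'   built-in names). The degenerate pair `(E, E)` reproduces the single
#'   digest with `E`.
#' @return An object of class `digest_result`: a list with `fragments` (a
#'   `data.table` with columns chrom, start, end, left_end, right_end,
#'   length; coordinates 0-based half-open), `enzymes` (names, A first as
#'   given), `seqlengths` (named), and `coincident_cuts`.
#' @examples
#' g <- c(chr1 = paste0(strrep("A", 100), "CTGCAG", strrep("A", 100)))
#' digest(g, c("PstI", "MboI"))
#' @export
digest <- function(genome, enzymes) {
  genome <- .as_genome(genome)
  if (length(genome) == 0L) stop("genome is empty", call. = FALSE)
  if (inherits(enzymes, "restriction_enzyme")) enzymes <- list(enzymes)
  enzymes <- lapply(enzymes, .as_enzyme)
  if (!length(enzymes) %in% c(1L, 2L)) {
    stop("digest() takes one or two enzymes", call. = FALSE)
  }
  enz_names <- vapply(enzymes, `[[`, "", "name")
  if (length(enzymes) == 2L && enz_names[1L] == enz_names[2L]) {
    enzymes <- enzymes[1L]           # degenerate pair == single digest
  }
  seqlens <- Biostrings::width(genome)
  names(seqlens) <- names(genome)
  coincident <- 0L
  frags <- vector("list", length(genome))
  for (k in seq_along(genome)) {
    chrom <- names(genome)[k]
    L <- seqlens[[k]]
    pos <- integer(0); lab <- character(0)
    for (e in enzymes) {
      p <- find_cut_sites(genome[[k]], e)
      p <- p[p > 0L & p < L]          # cuts at 0 or L do not split anything
      pos <- c(pos, p)
      lab <- c(lab, rep(e$name, length(p)))
    }
    o <- order(pos, lab)              # ties resolved to lexicographic label
    pos <- pos[o]; lab <- lab[o]
    dup <- duplicated(pos)
    coincident <- coincident + sum(dup)
    pos <- pos[!dup]; lab <- lab[!dup]
    bounds <- c(0L, pos, L)
    left  <- c("CHROM_END", lab)
    right <- c(lab, "CHROM_END")
    frags[[k]] <- data.table::data.table(
      chrom = chrom,
      start = bounds[-length(bounds)],
      end = bounds[-1L],
      left_end = left,
      right_end = right
    )
  }
  fragments <- data.table::rbindlist(frags)
  fragments[, `:=`(length = end - start)]
  structure(
    list(fragments = fragments,
         enzymes = vapply(enzymes, `[[`, "", "name"),
         seqlengths = seqlens,
         coincident_cuts = coincident),
    class = "digest_result"
  )
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("<digest_result> %s on %d sequence(s): %d fragments%s\n",
              paste(x$enzymes, collapse = "/"), length(x$seqlengths),
              nrow(x$fragments),
              if (x$coincident_cuts > 0L)
                sprintf(" (%d coincident cuts)", x$coincident_cuts) else ""))
  invisible(x)
}

#' Size-selection window
#'
#' Inclusive fragment-length bounds in bp, `0 <= min_bp <= max_bp`. The
#' platform's double-digest window is 300-400 bp; the single-enzyme ApeKI
#' comparison uses 300-800 bp.
#'
#' @param min_bp,max_bp Inclusive bounds in bp.
#' @return Object of class `size_window`.
#' @export
size_window <- function(min_bp, max_bp) {
  min_bp <- as.numeric(min_bp); max_bp <- as.numeric(max_bp)
  stopifnot(length(min_bp) == 1L, length(max_bp) == 1L,
            !is.na(min_bp), !is.na(max_bp), min_bp >= 0, min_bp <= max_bp)
  structure(list(min_bp = min_bp, max_bp = max_bp), class = "size_window")
}

.as_window <- function(w) {
  if (inherits(w, "size_window")) return(w)
  if (is.numeric(w) && length(w) == 2L) return(size_window(w[1L], w[2L]))
  stop("expected a size_window or numeric length-2 vector", call. = FALSE)
}

# End-class of each fragment. has_chrom_end takes precedence; classes are
# mutually exclusive and partition the fragment set. A = first enzyme of the
# pair, B = second.
.classify_fragments <- function(fragments, enz_a, enz_b) {
  cls <- character(nrow(fragments))
  le <- fragments$left_end; re <- fragments$right_end
  is_end <- le == "CHROM_END" | re == "CHROM_END"
  cls[is_end] <- "has_chrom_end"
  ab <- !is_end & ((le == enz_a & re == enz_b) | (le == enz_b & re == enz_a))
  cls[ab] <- "AB+BA"
  aa <- !is_end & le == enz_a & re == enz_a
  cls[aa] <- "AA"
  if (enz_b != enz_a) {
    bb <- !is_end & le == enz_b & re == enz_b
    cls[bb] <- "BB"
  }
  cls
}

#' Profile a digestion against a size-selection window
#'
#' Classifies every fragment by its end labels: `AB+BA` when the two ends
#' were cut by the two different enzymes of the pair (either order) --- the
#' class actually sequenced in a ddRAD library --- `AA`/`BB` when both ends
#' come from the same enzyme, and `has_chrom_end` (which takes precedence)
#' when a fragment touches a chromosome end. Counts are reported overall and
#' within the inclusive size window, together with a fragment-length
#' histogram.
#'
#' @param x A `digest_result`.
#' @param window A [size_window()] or numeric `c(min, max)`.
#' @return Object of class `digest_profile`: list with `counts` (named,
#'   overall), `windowed` (same classes, length-filtered), `total`,
#'   `window`, `enzymes`, `length_histogram` (data.table length/count).
#' @export
profile_digest <- function(x, window) {
  stopifnot(inherits(x, "digest_result"))
  window <- .as_window(window)
  enz_a <- x$enzymes[1L]
  enz_b <- if (length(x$enzymes) >= 2L) x$enzymes[2L] else x$enzymes[1L]
  fr <- x$fragments
  cls <- .classify_fragments(fr, enz_a, enz_b)
  classes <- c("AB+BA", "AA", "BB", "has_chrom_end")
  overall <- vapply(classes, function(cl) sum(cls == cl), 0L)
  inwin <- fr$length >= window$min_bp & fr$length <= window$max_bp
  windowed <- vapply(classes, function(cl) sum(cls == cl & inwin), 0L)
  hist <- data.table::as.data.table(table(length = fr$length))
  hist[, length := as.integer(length)]
  data.table::setnames(hist, c("length", "count"))
  structure(
    list(counts = overall, windowed = windowed, total = nrow(fr),
         window = window, enzymes = c(enz_a, enz_b),
         length_histogram = hist),
    class = "digest_profile"
  )
}

#' @export
print.digest_profile <- function(x, ...) {
  cat(sprintf("<digest_profile> %s, window [%g, %g] bp\n",
              paste(unique(x$enzymes), collapse = "/"),
              x$window$min_bp, x$window$max_bp))
  m <- rbind(overall = x$counts, windowed = x$windowed)
  print(m)
  invisible(x)
}

#' Rank enzyme pairs by windowed AB+BA fragment yield
#'
#' The best pair for a ddRAD design is the one generating the most AB+BA
#' fragments inside the size-selection window. Pairs are digested, profiled
#' and ordered by that count, descending; ties are broken lexicographically
#' by pair name.
#'
#' @param genome As for [digest()].
#' @param pairs List of length-2 vectors/lists of enzymes (objects or
#'   built-in names).
#' @param window Size-selection window.
#' @return `data.table` with columns pair, enzyme_a, enzyme_b, ab_ba_windowed,
#'   ab_ba_total, total_fragments, ordered best-first, plus attribute
#'   `profiles` (named list of `digest_profile`).
#' @examples
#' g <- c(chr1 = paste(rep("ACGTACGTTA", 50), collapse = ""))
#' rank_pairs(g, list(c("PstI", "MboI"), c("EcoRI", "MspI")), c(300, 400))
#' @export
rank_pairs <- function(genome, pairs, window) {
  stopifnot(length(pairs) >= 1L)
  window <- .as_window(window)
  profiles <- list()
  rows <- lapply(pairs, function(p) {
    ez <- lapply(p, .as_enzyme)
    pr <- profile_digest(digest(genome, ez), window)
    nm <- paste(vapply(ez, `[[`, "", "name"), collapse = "/")
    profiles[[nm]] <<- pr
    data.table::data.table(
      pair = nm,
      enzyme_a = ez[[1L]]$name,
      enzyme_b = if (length(ez) >= 2L) ez[[2L]]$name else ez[[1L]]$name,
      ab_ba_windowed = pr$windowed[["AB+BA"]],
      ab_ba_total = pr$counts[["AB+BA"]],
      total_fragments = pr$total
    )
  })
  out <- data.table::rbindlist(rows)
  data.table::setorderv(out, c("ab_ba_windowed", "pair"),
                        order = c(-1L, 1L))
  data.table::setattr(out, "profiles", profiles)
  out[]
}

#' Single-enzyme digestion profile
#'
#' Convenience wrapper for GBS-style single digests (e.g. ApeKI at
#' 300-800 bp): digest with one enzyme and profile. All internal fragments
#' are class `AA`.
#'
#' @inheritParams rank_pairs
#' @param enzyme One enzyme (object or built-in name).
#' @return A `digest_profile`.
#' @export
single_enzyme_profile <- function(genome, enzyme, window) {
  profile_digest(digest(genome, list(.as_enzyme(enzyme))), window)
}

# Accept character vectors, lists of strings, or DNAStringSet.
.as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    if (is.null(names(genome))) stop("genome sequences must be named",
                                     call. = FALSE)
    return(genome)
  }
  if (is.list(genome)) genome <- unlist(genome)
  if (is.character(genome)) {
    if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
      stop("genome sequences must be named", call. = FALSE)
    }
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  stop("genome must be a named character vector or DNAStringSet",
       call. = FALSE)
}

#' Write digestion fragments as BED
#'
#' BED columns: chrom, start, end, name (`leftEnz_rightEnz`), score (length).
#'
#' @param x A `digest_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(x, path) {
  stopifnot(inherits(x, "digest_result"))
  fr <- x$fragments
  bed <- data.table::data.table(
    chrom = fr$chrom, start = fr$start, end = fr$end,
    name = paste0(fr$left_end, "_", fr$right_end), score = fr$length)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Serialize a digest profile
#'
#' Writes the class counts as TSV (`class`, `overall`, `windowed`) and, with
#' `json = TRUE`, the full profile as JSON; the length histogram goes to
#' `<path>.hist.tsv` for plotting digestion-profile curves.
#'
#' @param x A `digest_profile`.
#' @param path Base output path (TSV written at `path`).
#' @param json Also write `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path, json = TRUE) {
  stopifnot(inherits(x, "digest_profile"))
  tab <- data.table::data.table(class = names(x$counts),
                                overall = as.integer(x$counts),
                                windowed = as.integer(x$windowed))
  data.table::fwrite(tab, path, sep = "\t")
  data.table::fwrite(x$length_histogram, paste0(path, ".hist.tsv"),
                     sep = "\t")
  if (json) {
    jsonlite::write_json(
      list(enzymes = x$enzymes,
           window = c(x$window$min_bp, x$window$max_bp),
           counts = as.list(x$counts), windowed = as.list(x$windowed),
           total = x$total),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a genome FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] (gzip-transparent);
#' sequence names are truncated at the first whitespace, matching common
#' chromosome-naming practice.
#'
#' @param path FASTA path (optionally gzipped).
#' @return A named `DNAStringSet`.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}
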