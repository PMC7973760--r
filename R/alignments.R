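#' Aligned-segment sets
#'
#' Coverage diagnostics operate on an `alignment_set`: a table of aligned
#' segments (sample, chrom, start, end, mapq; 0-based half-open) plus the
#' genome's sequence lengths. Paired mates are deliberately kept as
#' independent segments. Segments at or below the MAPQ threshold (the
#' platform's alignment step kept MAPQ > 3) are dropped at ingestion.
#'
#' @param segments `data.frame`/`data.table` with columns sample, chrom,
#'   start, end and optionally mapq (missing mapq treated as passing).
#' @param seqlengths Named vector of chromosome lengths (bp).
#' @param mapq_gt Keep segments with `mapq > mapq_gt` (default 3).
#' @return Object of class `alignment_set`.
#' @export
alignment_set <- function(segments, seqlengths, mapq_gt = 3L) {
  seg <- data.table::as.data.table(segments)
  need <- c("sample", "chrom", "start", "end")
  if (!all(need %in% names(seg))) {
    stop("segments need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"mapq" %in% names(seg)) seg[, mapq := NA_integer_]
  n0 <- nrow(seg)
  seg <- seg[is.na(mapq) | mapq > mapq_gt]
  if (nrow(seg) && (any(seg$end <= seg$start) || any(seg$start < 0))) {
    stop("segments must satisfy 0 <= start < end", call. = FALSE)
  }
  if (nrow(seg)) {
    unknown <- setdiff(unique(seg$chrom), names(seqlengths))
    if (length(unknown)) {
      stop("segments on chromosomes absent from seqlengths: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    lim <- seqlengths[seg$chrom]
    if (any(seg$end > lim)) {
      stop("segments extend past chromosome ends", call. = FALSE)
    }
  }
  seg[, `:=`(start = as.integer(start), end = as.integer(end))]
  data.table::setkeyv(seg, c("sample", "chrom", "start"))
  structure(list(segments = seg, seqlengths = seqlengths,
                 mapq_gt = mapq_gt, n_filtered = n0 - nrow(seg)),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf(
    "<alignment_set> %d segments, %d sample(s), %d sequence(s) (MAPQ > %d; %d filtered)\n",
    nrow(x$segments), length(unique(x$segments$sample)),
    length(x$seqlengths), x$mapq_gt, x$n_filtered))
  invisible(x)
}

#' Read alignments from the interval-TSV dialect
#'
#' The fixture dialect: tab-separated `sample chrom start end [mapq]`,
#' 0-based half-open, with or without a header line.
#'
#' @param path TSV path.
#' @inheritParams alignment_set
#' @return An `alignment_set`.
#' @export
read_alignment_tsv <- function(path, seqlengths, mapq_gt = 3L) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^sample\t", first)
  cols <- c("sample", "chrom", "start", "end", "mapq")
  dt <- data.table::fread(path, header = has_header, sep = "\t")
  if (!has_header) data.table::setnames(dt, cols[seq_len(ncol(dt))])
  alignment_set(dt, seqlengths, mapq_gt = mapq_gt)
}

#' Read alignments from SAM/BAM files
#'
#' One coordinate-sorted SAM or BAM per sample; sample names default to file
#' basenames. Aligned reference spans are derived from the CIGAR, mates are
#' kept as independent segments, and the MAPQ filter is applied at
#' ingestion. SAM files are converted with [Rsamtools::asBam()] into a
#' temporary directory.
#'
#' @param paths Character vector of SAM/BAM paths.
#' @param seqlengths Named chromosome lengths; defaults to the header of the
#'   first file.
#' @param samples Sample names, default `basename` without extension.
#' @inheritParams alignment_set
#' @return An `alignment_set`.
#' @export
read_alignment_bam <- function(paths, seqlengths = NULL, samples = NULL,
                               mapq_gt = 3L) {
  if (is.null(samples)) samples <- sub("\\.(sam|bam)$", "", basename(paths))
  stopifnot(length(samples) == length(paths))
  bams <- vapply(paths, function(p) {
    if (grepl("\\.sam$", p, ignore.case = TRUE)) {
      Rsamtools::asBam(p, file.path(tempdir(),
                                    paste0(basename(tools::file_path_sans_ext(p)),
                                           "_", as.integer(stats::runif(1, 1, 1e8)))),
                       overwrite = TRUE, indexDestination = FALSE)
    } else p
  }, "")
  if (is.null(seqlengths)) {
    hdr <- Rsamtools::scanBamHeader(bams[1L])[[1L]]$targets
    seqlengths <- hdr
  }
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "cigar", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  segs <- lapply(seq_along(bams), function(i) {
    b <- Rsamtools::scanBam(bams[i], param = param)[[1L]]
    if (!length(b$pos)) return(NULL)
    w <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar)
    data.table::data.table(sample = samples[i],
                           chrom = as.character(b$rname),
                           start = b$pos - 1L, end = b$pos - 1L + w,
                           mapq = b$mapq)
  })
  alignment_set(data.table::rbindlist(segs), seqlengths, mapq_gt = mapq_gt)
}

#' Read a sample-to-pool map
#'
#' Two-column TSV `sample pool` (header optional).
#'
#' @param path TSV path.
#' @return Named character vector: pool id per sample.
#' @export
read_pool_map <- function(path) {
  first <- readLines(path, n = 1L)
  dt <- data.table::fread(path, header = grepl("^sample\t", first),
                          sep = "\t")
  data.table::setnames(dt, c("sample", "pool"))
  stats::setNames(as.character(dt$pool), dt$sample)
}

#' Write an alignment set in the interval-TSV dialect
#'
#' @param x An `alignment_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_tsv <- function(x, path) {
  stopifnot(inherits(x, "alignment_set"))
  data.table::fwrite(x$segments, path, sep = "\t")
  invisible(path)
}
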