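#' Target base-pair range of a size-selected library
#'
#' With `n_loci` AB+BA fragments retained in a size window, the sequenced
#' target is between `n_loci * min_bp` and `n_loci * max_bp` bases. For the
#' peach platform (63,730 loci at 300-400 bp) this is 19.119-25.492 Mb.
#'
#' @param n_loci Number of windowed AB+BA fragments (>= 0).
#' @param window Size-selection window.
#' @return Named numeric `c(min_bp =, max_bp =)`, exact integer products.
#' @examples
#' target_bp_range(63730, c(300, 400))
#' @export
target_bp_range <- function(n_loci, window) {
  window <- .as_window(window)
  stopifnot(length(n_loci) == 1L, n_loci >= 0)
  c(min_bp = n_loci * window$min_bp, max_bp = n_loci * window$max_bp)
}

#' Expected sequencing depth at a given per-sample yield
#'
#' Depth is yield divided by target size. Because the target is a range, the
#' depth is a range too: the low end divides by the *largest* target, the
#' high end by the smallest. Reported to one decimal.
#'
#' @param yield_bp Sequenced bases per sample (> 0).
#' @param target_range Numeric `c(min_bp, max_bp)` from [target_bp_range()].
#' @return Named numeric `c(depth_min =, depth_max =)`, one decimal.
#' @examples
#' expected_depth(250e6, target_bp_range(63730, c(300, 400)))  # 9.8, 13.1
#' @export
expected_depth <- function(yield_bp, target_range) {
  stopifnot(length(yield_bp) == 1L, yield_bp > 0)
  tr <- as.numeric(target_range)
  stopifnot(length(tr) == 2L)
  if (any(tr <= 0)) stop("target bp must be > 0", call. = FALSE)
  c(depth_min = round(yield_bp / max(tr), 1L),
    depth_max = round(yield_bp / min(tr), 1L))
}

#' Required yield for a target depth
#'
#' Inverse of [expected_depth()]: the yield guaranteeing at least
#' `depth` fold coverage even at the largest target size.
#'
#' @param depth Desired fold coverage (> 0).
#' @param target_range As in [expected_depth()].
#' @return Required yield in bp.
#' @export
required_yield <- function(depth, target_range) {
  stopifnot(length(depth) == 1L, depth > 0)
  tr <- as.numeric(target_range)
  if (any(tr <= 0)) stop("target bp must be > 0", call. = FALSE)
  depth * max(tr)
}

#' Convert a yield in bases to a read-pair count
#'
#' Two conventions are implemented because platform write-ups are often
#' ambiguous about whether a quoted yield counts both mates of a pair:
#' under `"both_mates"` a pair contributes `2 * read_length` bases, under
#' `"one_mate"` it contributes `read_length`. The peach platform equates a
#' 250 Mb yield with 1 M 2x250 bp paired-end reads, which is the
#' `"one_mate"` convention (1e6 pairs x 500 b would be 500 Mb), so that is
#' the default.
#'
#' @param yield_bp Yield in bases (>= 0).
#' @param read_length Read length in bp (> 0).
#' @param paired Logical; single-end always counts one mate.
#' @param bases_counted `"one_mate"` (default) or `"both_mates"`.
#' @return Read-pair count (read count when `paired = FALSE`).
#' @examples
#' yield_to_reads(250e6, 250)                                # 1e6 pairs
#' yield_to_reads(5e8, 250, bases_counted = "both_mates")    # 1e6 pairs
#' @export
yield_to_reads <- function(yield_bp, read_length, paired = TRUE,
                           bases_counted = c("one_mate", "both_mates")) {
  bases_counted <- match.arg(bases_counted)
  stopifnot(length(yield_bp) == 1L, yield_bp >= 0, read_length > 0)
  per_unit <- if (paired && bases_counted == "both_mates") 2 * read_length
              else read_length
  yield_bp / per_unit
}

#' Build a full sequencing design plan
#'
#' Combines [target_bp_range()], [expected_depth()] and [yield_to_reads()]
#' into one plan object for a multiplexed run.
#'
#' @param n_loci Windowed AB+BA locus count.
#' @param window Size-selection window.
#' @param yield_bp Planned yield in bases per sample.
#' @param n_samples Samples multiplexed.
#' @param read_length Read length (bp), default 250.
#' @param bases_counted See [yield_to_reads()].
#' @return Object of class `design_plan`.
#' @examples
#' design_plan(63730, c(300, 400), 250e6, n_samples = 191)
#' @export
design_plan <- function(n_loci, window, yield_bp, n_samples = 1L,
                        read_length = 250L,
                        bases_counted = c("one_mate", "both_mates")) {
  bases_counted <- match.arg(bases_counted)
  window <- .as_window(window)
  tr <- target_bp_range(n_loci, window)
  structure(
    list(n_loci = n_loci, window = window,
         target_bp_min = tr[["min_bp"]], target_bp_max = tr[["max_bp"]],
         yield_bp_per_sample = yield_bp,
         expected_depth = expected_depth(yield_bp, tr),
         read_pairs_per_sample = yield_to_reads(yield_bp, read_length,
                                                bases_counted = bases_counted),
         read_length = read_length, bases_counted = bases_counted,
         n_samples = n_samples),
    class = "design_plan"
  )
}

#' @export
print.design_plan <- function(x, ...) {
  cat(sprintf(paste0(
    "<design_plan> %d loci in [%g, %g] bp\n",
    "  target: %.3f-%.3f Mb\n",
    "  yield:  %.1f Mb/sample (%s) = %.3g read pairs of %d bp\n",
    "  depth:  %.1fx-%.1fx  (%d sample%s)\n"),
    x$n_loci, x$window$min_bp, x$window$max_bp,
    x$target_bp_min / 1e6, x$target_bp_max / 1e6,
    x$yield_bp_per_sample / 1e6, x$bases_counted,
    x$read_pairs_per_sample, x$read_length,
    x$expected_depth[["depth_min"]], x$expected_depth[["depth_max"]],
    x$n_samples, if (x$n_samples == 1L) "" else "s"))
  invisible(x)
}
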