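#' Restriction enzyme definitions
#'
#' A restriction enzyme is described by its name, an IUPAC recognition motif,
#' the offset of the top-strand cut from the motif start, and a
#' methylation-sensitivity flag. The flag is metadata only: digestion never
#' models methylation (site masking by CpG methylation is a wet-lab
#' consideration, not part of the in silico model).
#'
#' @param name Short identifier, e.g. `"PstI"`.
#' @param recognition IUPAC motif (uppercase), e.g. `"CTGCAG"`.
#' @param cut_offset Integer offset of the top-strand cut from the motif
#'   start, in bases; `0 <= cut_offset <= nchar(recognition)`. PstI
#'   (`CTGCA^G`) has offset 5, MboI (`^GATC`) offset 0.
#' @param methylation_sensitive Logical metadata flag.
#' @return An object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("PstI", "CTGCAG", 5, TRUE)
#' @export
restriction_enzyme <- function(name, recognition, cut_offset,
                               methylation_sensitive = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  recognition <- toupper(as.character(recognition))
  if (nchar(recognition) < 1L ||
      !grepl("^[ACGTRYSWKMBDHVN]+$", recognition)) {
    stop("invalid IUPAC code in recognition motif '", recognition,
         "' for enzyme ", name, call. = FALSE)
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L ||
      cut_offset > nchar(recognition)) {
    stop("cut_offset must lie in [0, motif length] for enzyme ", name,
         call. = FALSE)
  }
  structure(
    list(name = name, recognition = recognition, cut_offset = cut_offset,
         methylation_sensitive = isTRUE(methylation_sensitive)),
    class = "restriction_enzyme"
  )
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  motif <- paste0(substr(x$recognition, 1L, x$cut_offset), "^",
                  substr(x$recognition, x$cut_offset + 1L,
                         nchar(x$recognition)))
  cat(sprintf("<restriction_enzyme> %s  %s%s\n", x$name, motif,
              if (x$methylation_sensitive) "  [methylation-sensitive]" else ""))
  invisible(x)
}

# REBASE definitions for the six enzymes used in the platform evaluation.
# All are palindromic, so top-strand scanning suffices.
.builtin_enzyme_table <- function() {
  list(
    PstI  = restriction_enzyme("PstI",  "CTGCAG", 5L, methylation_sensitive = TRUE),
    MboI  = restriction_enzyme("MboI",  "GATC",   0L, methylation_sensitive = FALSE),
    MspI  = restriction_enzyme("MspI",  "CCGG",   1L, methylation_sensitive = TRUE),
    EcoRI = restriction_enzyme("EcoRI", "GAATTC", 1L, methylation_sensitive = FALSE),
    SphI  = restriction_enzyme("SphI",  "GCATGC", 5L, methylation_sensitive = TRUE),
    ApeKI = restriction_enzyme("ApeKI", "GCWGC",  1L, methylation_sensitive = TRUE)
  )
}

#' Built-in enzyme table
#'
#' Ships standard REBASE definitions for the enzymes evaluated for the peach
#' ddRAD platform: PstI (CTGCA^G), MboI (^GATC), MspI (C^CGG),
#' EcoRI (G^AATTC), SphI (GCATG^C) and ApeKI (G^CWGC). Users may override or
#' extend the table by passing their own `restriction_enzyme` objects to the
#' digestion functions.
#'
#' @param names Optional character vector selecting a subset (error on
#'   unknown names).
#' @return A named list of `restriction_enzyme` objects.
#' @examples
#' enzyme_table(c("PstI", "MboI"))
#' @export
enzyme_table <- function(names = NULL) {
  tab <- .builtin_enzyme_table()
  if (is.null(names)) return(tab)
  missing <- setdiff(names, names(tab))
  if (length(missing)) {
    stop("unknown enzyme(s): ", paste(missing, collapse = ", "),
         "; define them with restriction_enzyme()", call. = FALSE)
  }
  tab[names]
}

# Resolve an enzyme argument: either a restriction_enzyme or a built-in name.
.as_enzyme <- function(x) {
  if (inherits(x, "restriction_enzyme")) return(x)
  if (is.character(x) && length(x) == 1L) return(enzyme_table(x)[[1L]])
  stop("expected a restriction_enzyme or a built-in enzyme name", call. = FALSE)
}

# IUPAC-aware palindrome test (motif equal to its reverse complement).
.is_palindromic <- function(recognition) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(recognition)))
  identical(recognition, rc)
}
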