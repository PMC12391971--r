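## Motif pattern definitions.
##
## A CRAC motif reads L/V-X1-5-Y-X1-5-K/R from the N- to the C-terminus; the
## CARC motif is its mirrored counterpart K/R-X1-5-Y/F-X1-5-L/V, also written
## N->C. Both consist of three anchor residues (start, central aromatic,
## terminal) separated by two spacers of 1 to 5 arbitrary residues.

#' @keywords internal
STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Non-standard codes tolerated in spacer positions only (never anchors).
#' @keywords internal
TOLERATED_AA <- c("X", "U", "O", "B", "Z", "J")

#' Compile a CARC or CRAC motif pattern
#'
#' Builds the anchor residue sets and spacer-length bounds for one motif
#' class. CRAC is the cholesterol recognition/interaction amino acid
#' consensus `L/V-X1-5-Y-X1-5-K/R`; CARC is the mirrored pattern
#' `K/R-X1-5-Y/F-X1-5-L/V`. Both are matched strictly N-terminus to
#' C-terminus.
#'
#' @param motif_class `"CARC"` or `"CRAC"`.
#' @param spacer_min,spacer_max Inclusive bounds on the number of residues in
#'   each of the two spacers. Defaults 1 and 5 give the classical `X1-5`
#'   spacers.
#'
#' @return An object of class `motif_pattern`: a list with elements
#'   `motif_class`, `start_set`, `center_set`, `terminal_set`, `spacer_min`
#'   and `spacer_max`.
#'
#' @examples
#' compile_pattern("CRAC")
#' compile_pattern("CARC", spacer_min = 2, spacer_max = 4)
#' @export
compile_pattern <- function(motif_class, spacer_min = 1L, spacer_max = 5L) {
  if (!is.character(motif_class) || length(motif_class) != 1L ||
      !motif_class %in% c("CARC", "CRAC")) {
    carcrac_abort(
      sprintf("unknown motif class %s; expected \"CARC\" or \"CRAC\"",
              deparse(motif_class)),
      "carcrac_invalid_class"
    )
  }
  spacer_min <- as.integer(spacer_min)
  spacer_max <- as.integer(spacer_max)
  if (is.na(spacer_min) || is.na(spacer_max) ||
      spacer_min < 1L || spacer_max < spacer_min) {
    carcrac_abort(
      sprintf("invalid spacer bounds [%s, %s]: need 1 <= spacer_min <= spacer_max",
              spacer_min, spacer_max),
      "carcrac_invalid_spacer"
    )
  }
  sets <- switch(motif_class,
    CRAC = list(start = c("L", "V"), center = "Y",        terminal = c("K", "R")),
    CARC = list(start = c("K", "R"), center = c("Y", "F"), terminal = c("L", "V"))
  )
  structure(
    list(
      motif_class = motif_class,
      start_set = sets$start,
      center_set = sets$center,
      terminal_set = sets$terminal,
      spacer_min = spacer_min,
      spacer_max = spacer_max
    ),
    class = "motif_pattern"
  )
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf(
    "<motif_pattern %s> %s-X%d-%d-%s-X%d-%d-%s\n",
    x$motif_class,
    paste(x$start_set, collapse = "/"),
    x$spacer_min, x$spacer_max,
    paste(x$center_set, collapse = "/"),
    x$spacer_min, x$spacer_max,
    paste(x$terminal_set, collapse = "/")
  ))
  invisible(x)
}

#' Clean and validate a protein sequence for motif scanning
#'
#' Upper-cases the input, truncates at the first stop (`*`, with a warning)
#' and rejects characters outside the 20 standard one-letter residue codes
#' plus the tolerated extras `X U O B Z J` (allowed in spacers, never matched
#' by anchor sets).
#'
#' @param sequence Character scalar of one-letter residue codes.
#' @return A character vector of single upper-case residues.
#' @keywords internal
clean_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  stop_at <- which(chars == "*")
  if (length(stop_at) > 0L) {
    carcrac_warn(
      sprintf("'*' at position %d terminates the sequence; %d trailing characters dropped",
              stop_at[1], length(chars) - stop_at[1]),
      "carcrac_stop_codon"
    )
    chars <- chars[seq_len(stop_at[1] - 1L)]
  }
  bad <- setdiff(unique(chars), c(STANDARD_AA, TOLERATED_AA))
  if (length(bad) > 0L) {
    carcrac_abort(
      sprintf("invalid residue code(s): %s", paste(bad, collapse = ", ")),
      "carcrac_invalid_residue"
    )
  }
  chars
}
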