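## Multiple-sequence-alignment handling: coordinate maps between ungapped
## residue numbering and alignment columns, per-column similarity against a
## reference, and per-isoform motif presence calls.
##
## The alignment is always an input (aligned FASTA or Clustal); this module
## never aligns.

GAP_CHARS <- c("-", ".")

new_aligned_sequence <- function(sequence_id, gapped) {
  chars <- strsplit(gapped, "", fixed = TRUE)[[1]]
  chars[chars %in% GAP_CHARS] <- "-"
  res_idx <- which(chars != "-")
  column_to_residue <- rep(NA_integer_, length(chars))
  column_to_residue[res_idx] <- seq_along(res_idx)
  list(
    sequence_id = sequence_id,
    gapped = paste(chars, collapse = ""),
    ungapped = paste(chars[res_idx], collapse = ""),
    residue_to_column = res_idx,        # strictly increasing by construction
    column_to_residue = column_to_residue
  )
}

#' Read a pre-computed protein multiple sequence alignment
#'
#' Accepts aligned FASTA or Clustal. Gap characters `-` and `.` are both
#' recognized (normalized to `-`). For every member, bidirectional maps
#' between 1-based ungapped residue indices and 1-based alignment columns are
#' built.
#'
#' @param path Alignment file.
#' @param format `"fasta"` (aligned FASTA) or `"clustal"`.
#' @param reference_id Member to treat as the reference (default: first
#'   record).
#' @return An object of class `carcrac_alignment`: list with `members` (named
#'   list, each with `sequence_id`, `gapped`, `ungapped`,
#'   `residue_to_column`, `column_to_residue`), `reference_id`, `width`.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"),
                           reference_id = NULL) {
  format <- match.arg(format)
  msa <- tryCatch(
    Biostrings::readAAMultipleAlignment(path, format = format),
    error = function(e) {
      msg <- conditionMessage(e)
      cls <- if (grepl("equal length|same length|ragged|width", msg,
                       ignore.case = TRUE))
        "carcrac_alignment_shape" else "carcrac_empty_input"
      carcrac_abort(
        sprintf("cannot read alignment '%s' (%s): %s", path, format, msg), cls
      )
    }
  )
  gapped <- as.character(msa)
  if (length(gapped) == 0L) {
    carcrac_abort(sprintf("alignment '%s' contains no sequences", path),
                  "carcrac_empty_input")
  }
  if (length(gapped) < 2L) {
    carcrac_abort(sprintf("alignment '%s' has fewer than 2 sequences", path),
                  "carcrac_empty_input")
  }
  ids <- vapply(strsplit(names(gapped), "\\s+"), `[[`, character(1), 1L)
  as_alignment(stats::setNames(unname(gapped), ids), reference_id)
}

#' Build an alignment object from named gapped strings
#'
#' @param gapped Named character vector of equal-length gapped sequences.
#' @param reference_id Reference member id (default first).
#' @return A `carcrac_alignment`.
#' @export
as_alignment <- function(gapped, reference_id = NULL) {
  stopifnot(is.character(gapped), !is.null(names(gapped)))
  widths <- nchar(gapped)
  if (length(unique(widths)) > 1L) {
    carcrac_abort("ragged alignment: gapped sequences differ in length",
                  "carcrac_alignment_shape")
  }
  if (is.null(reference_id)) reference_id <- names(gapped)[1]
  if (!reference_id %in% names(gapped)) {
    carcrac_abort(
      sprintf("reference id '%s' not among alignment members (%s)",
              reference_id, paste(names(gapped), collapse = ", ")),
      "carcrac_missing_reference"
    )
  }
  members <- lapply(names(gapped), function(id) {
    new_aligned_sequence(id, gapped[[id]])
  })
  names(members) <- names(gapped)
  structure(
    list(members = members, reference_id = reference_id,
         width = unname(widths[1])),
    class = "carcrac_alignment"
  )
}

#' @export
print.carcrac_alignment <- function(x, ...) {
  cat(sprintf("<carcrac_alignment> %d members x %d columns, reference '%s'\n",
              length(x$members), x$width, x$reference_id))
  invisible(x)
}

member_char_at <- function(member, column) {
  substr(member$gapped, column, column)
}

#' Similarity of an alignment column to the reference residue
#'
#' Fraction of non-reference members whose residue at the column scores
#' strictly positive against the reference residue under a substitution
#' matrix (default BLOSUM62). A gap — or a residue the matrix cannot score —
#' counts as dissimilar. This implements the "80% or more sequence
#' similarity" unification rule as a per-column quantity.
#'
#' @param alignment A [read_alignment()] object.
#' @param column 1-based column index.
#' @param reference_id Reference member (default: the alignment's).
#' @param substitution_matrix A square scoring matrix with residue
#'   row/column names; default the BLOSUM62 matrix shipped with Biostrings.
#' @return A fraction in \[0, 1\].
#' @export
column_similarity <- function(alignment, column,
                              reference_id = alignment$reference_id,
                              substitution_matrix = NULL) {
  stopifnot(inherits(alignment, "carcrac_alignment"))
  column <- as.integer(column)
  if (is.na(column) || column < 1L || column > alignment$width) {
    carcrac_abort(sprintf("column %s outside alignment width %d",
                          column, alignment$width), "carcrac_bounds")
  }
  if (is.null(substitution_matrix)) substitution_matrix <- blosum62()
  ref <- alignment$members[[reference_id]]
  if (is.null(ref)) {
    carcrac_abort(sprintf("reference id '%s' not in alignment", reference_id),
                  "carcrac_missing_reference")
  }
  ref_res <- member_char_at(ref, column)
  if (ref_res == "-") {
    carcrac_abort(
      sprintf("reference '%s' has a gap at column %d; similarity undefined",
              reference_id, column),
      "carcrac_undefined_reference"
    )
  }
  others <- alignment$members[setdiff(names(alignment$members), reference_id)]
  similar <- vapply(others, function(m) {
    res <- member_char_at(m, column)
    if (res == "-") return(FALSE)
    if (!ref_res %in% rownames(substitution_matrix) ||
        !res %in% colnames(substitution_matrix)) return(FALSE)
    substitution_matrix[ref_res, res] > 0
  }, logical(1))
  sum(similar) / length(similar)
}

blosum62_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(blosum62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_cache$m <- e$BLOSUM62
  }
  blosum62_cache$m
}

#' Call per-isoform presence of a reference motif
#'
#' A non-reference member carries the motif when its ungapped sequence
#' contains an enumerated match of the same class whose central aromatic maps
#' to an alignment column within `column_tolerance` of the reference match's
#' center column. A gap at the member's aligned center column (with tolerance
#' 0) therefore counts as absent even if the member has a same-class motif
#' elsewhere. The reference member is always present.
#'
#' @param alignment A [read_alignment()] object.
#' @param reference_match One-row motif-match data frame on the reference's
#'   ungapped sequence.
#' @param pattern The [compile_pattern()] object of the match's class.
#' @param column_tolerance Allowed column offset for the member's center
#'   (default 0).
#' @param similarity_threshold Center-column similarity at or above which the
#'   record is flagged `unified` (default 0.80).
#' @param substitution_matrix Passed to [column_similarity()].
#' @return A `conservation_record`: list with `reference_match`,
#'   `per_isoform_presence` (named logical in member order),
#'   `center_column`, `center_column_similarity`, `unified`.
#' @export
motif_presence <- function(alignment, reference_match, pattern,
                           column_tolerance = 0L,
                           similarity_threshold = 0.80,
                           substitution_matrix = NULL) {
  stopifnot(inherits(alignment, "carcrac_alignment"),
            inherits(pattern, "motif_pattern"))
  ref <- alignment$members[[alignment$reference_id]]
  cen <- as.integer(reference_match$center)
  if (is.na(cen) || cen < 1L || cen > length(ref$residue_to_column)) {
    carcrac_abort(
      sprintf("reference match center %s beyond reference length %d",
              cen, length(ref$residue_to_column)),
      "carcrac_bounds"
    )
  }
  center_col <- ref$residue_to_column[cen]
  presence <- vapply(names(alignment$members), function(id) {
    if (id == alignment$reference_id) return(TRUE)
    m <- alignment$members[[id]]
    hits <- enumerate_matches(m$ungapped, pattern, sequence_id = id)
    if (nrow(hits) == 0L) return(FALSE)
    cols <- m$residue_to_column[hits$center]
    any(abs(cols - center_col) <= column_tolerance)
  }, logical(1))
  sim <- column_similarity(alignment, center_col,
                           substitution_matrix = substitution_matrix)
  structure(
    list(
      reference_match = reference_match,
      per_isoform_presence = presence,
      center_column = center_col,
      center_column_similarity = sim,
      unified = sim >= similarity_threshold
    ),
    class = "conservation_record"
  )
}

#' @export
print.conservation_record <- function(x, ...) {
  cat(sprintf(
    "<conservation_record> %s center %d (column %d): %d/%d present, similarity %.3f%s\n",
    x$reference_match$motif_class, x$reference_match$center, x$center_column,
    sum(x$per_isoform_presence), length(x$per_isoform_presence),
    x$center_column_similarity, if (x$unified) " [unified]" else ""
  ))
  invisible(x)
}

#' Conservation summary for a hit set
#'
#' One row per canonical reference match, ordered by start, with a presence
#' string listing the carrying members in alignment order.
#'
#' @param alignment A [read_alignment()] object.
#' @param hits A [motif_hit_set()] computed on the reference member's
#'   ungapped sequence.
#' @param column_tolerance,similarity_threshold,substitution_matrix Passed to
#'   [motif_presence()].
#' @param spacer_min,spacer_max Spacer bounds used when rescanning members.
#' @return A data frame with columns `ref_start`, `motif_class`, `presence`,
#'   `center_similarity`, `unified`; the full `conservation_record` list is
#'   attached as attribute `"records"`.
#' @export
conservation_summary <- function(alignment, hits,
                                 column_tolerance = 0L,
                                 similarity_threshold = 0.80,
                                 substitution_matrix = NULL,
                                 spacer_min = 1L, spacer_max = 5L) {
  stopifnot(inherits(alignment, "carcrac_alignment"),
            inherits(hits, "motif_hit_set"))
  ref <- alignment$members[[alignment$reference_id]]
  if (!identical(hits$sequence_id, alignment$reference_id)) {
    carcrac_abort(
      sprintf("hit set is for '%s' but the alignment reference is '%s'",
              hits$sequence_id, alignment$reference_id),
      "carcrac_inconsistent_input"
    )
  }
  can <- hits$canonical
  if (nrow(can) > 0L) {
    subseq_ok <- vapply(seq_len(nrow(can)), function(i) {
      identical(substr(ref$ungapped, can$start[i], can$end[i]),
                can$subsequence[i])
    }, logical(1))
    if (!all(subseq_ok)) {
      carcrac_abort(
        "hit subsequences do not match the alignment's reference sequence",
        "carcrac_inconsistent_input"
      )
    }
  }
  records <- lapply(seq_len(nrow(can)), function(i) {
    motif_presence(alignment, can[i, , drop = FALSE],
                   compile_pattern(can$motif_class[i], spacer_min, spacer_max),
                   column_tolerance = column_tolerance,
                   similarity_threshold = similarity_threshold,
                   substitution_matrix = substitution_matrix)
  })
  out <- data.frame(
    ref_start = can$start,
    motif_class = can$motif_class,
    presence = vapply(records, function(r) {
      paste(names(r$per_isoform_presence)[r$per_isoform_presence],
            collapse = ", ")
    }, character(1)),
    center_similarity = vapply(records, `[[`, numeric(1),
                               "center_column_similarity"),
    unified = vapply(records, `[[`, logical(1), "unified"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$ref_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "records") <- records
  out
}

#' Write a conservation summary as TSV
#' @param summary Data frame from [conservation_summary()].
#' @param path Output file.
#' @export
write_conservation_tsv <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(summary)
}
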