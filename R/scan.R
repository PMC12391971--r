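## Motif enumeration and hit-set operations.
##
## Matches are plain data frames (one row per motif instance) with columns
## sequence_id, motif_class, start, center, end, subsequence, canonical.
## Coordinates are 1-based, inclusive, in ungapped residue numbering.

#' An empty motif-match table
#' @return A zero-row data frame with the motif-match schema.
#' @export
empty_matches <- function() {
  data.frame(
    sequence_id = character(0),
    motif_class = character(0),
    start = integer(0),
    center = integer(0),
    end = integer(0),
    subsequence = character(0),
    canonical = logical(0),
    stringsAsFactors = FALSE
  )
}

new_match_df <- function(sequence_id, motif_class, start, center, end, chars) {
  n <- length(start)
  if (n == 0L) return(empty_matches())
  data.frame(
    sequence_id = rep_len(sequence_id, n),
    motif_class = rep_len(motif_class, n),
    start = as.integer(start),
    center = as.integer(center),
    end = as.integer(end),
    subsequence = vapply(
      seq_len(n),
      function(i) paste(chars[start[i]:end[i]], collapse = ""),
      character(1)
    ),
    canonical = rep_len(FALSE, n),
    stringsAsFactors = FALSE
  )
}

sort_matches <- function(m) {
  m[order(m$start, m$center, m$end, m$motif_class), , drop = FALSE]
}

#' Enumerate every motif instance on a sequence
#'
#' Returns EVERY (start, center, end) residue-index triple whose anchors and
#' spacer lengths satisfy the pattern — no deduplication, so overlapping
#' spacer combinations at one central aromatic all appear. Use
#' [canonicalize()] to reduce to one representative per site.
#'
#' @param sequence Character scalar of one-letter residue codes
#'   (case-insensitive; `X U O B Z J` tolerated in spacers, `*` truncates
#'   with a warning).
#' @param pattern A [compile_pattern()] object.
#' @param sequence_id Identifier recorded in the output (default `"seq"`).
#'
#' @return A motif-match data frame sorted by (start, center, end), columns
#'   `sequence_id`, `motif_class`, `start`, `center`, `end`, `subsequence`,
#'   `canonical` (all `FALSE` here).
#'
#' @examples
#' enumerate_matches("KILGDCYYCV", compile_pattern("CARC"))
#' enumerate_matches("RKWQFDV", compile_pattern("CARC"))  # two spacer variants
#' @export
enumerate_matches <- function(sequence, pattern, sequence_id = "seq") {
  stopifnot(inherits(pattern, "motif_pattern"))
  chars <- clean_sequence(sequence)
  n <- length(chars)
  smin <- pattern$spacer_min
  smax <- pattern$spacer_max
  centers <- which(chars %in% pattern$center_set)
  out <- vector("list", length(centers))
  for (k in seq_along(centers)) {
    cen <- centers[k]
    # spacer length = center - start - 1 in [smin, smax]
    start_hi <- cen - smin - 1L
    end_lo <- cen + smin + 1L
    if (start_hi < 1L || end_lo > n) next
    starts <- seq.int(max(1L, cen - smax - 1L), start_hi)
    starts <- starts[chars[starts] %in% pattern$start_set]
    ends <- seq.int(end_lo, min(n, cen + smax + 1L))
    ends <- ends[chars[ends] %in% pattern$terminal_set]
    if (length(starts) == 0L || length(ends) == 0L) next
    grid <- expand.grid(start = starts, end = ends, KEEP.OUT.ATTRS = FALSE)
    out[[k]] <- new_match_df(sequence_id, pattern$motif_class,
                             grid$start, rep(cen, nrow(grid)), grid$end, chars)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty_matches())
  sort_matches(do.call(rbind, out))
}

#' Reduce enumerated matches to one canonical instance per site
#'
#' Groups matches by (motif_class, center) and keeps, within each group, the
#' match with the smallest start (leftmost start anchor), breaking remaining
#' ties by the smallest end (nearest terminal anchor). This reproduces
#' conventional reporting where a site with several valid spacer combinations
#' is written once from its leftmost basic/branched anchor.
#'
#' @param matches A motif-match data frame; all rows must share one
#'   `sequence_id`.
#' @return The selected rows, `canonical = TRUE`, sorted by start.
#' @export
canonicalize <- function(matches) {
  if (nrow(matches) == 0L) {
    out <- matches
    out$canonical <- logical(0)
    return(out)
  }
  if (length(unique(matches$sequence_id)) > 1L) {
    carcrac_abort(
      "canonicalize() expects matches from a single sequence_id",
      "carcrac_inconsistent_input"
    )
  }
  key <- paste(matches$motif_class, matches$center, sep = "\r")
  ord <- order(matches$start, matches$end)
  first <- ord[!duplicated(key[ord])]
  out <- matches[sort(first), , drop = FALSE]
  out <- out[order(out$start, out$center, out$end), , drop = FALSE]
  out$canonical <- TRUE
  rownames(out) <- NULL
  out
}

#' Assemble the full hit set for one sequence
#'
#' Runs [enumerate_matches()] for each requested motif class, canonicalizes,
#' and detects cross-class overlaps among canonical matches.
#'
#' @param sequence Residue string.
#' @param sequence_id Identifier for the sequence.
#' @param classes Motif classes to scan (default both).
#' @param spacer_min,spacer_max Spacer bounds passed to [compile_pattern()].
#' @return An object of class `motif_hit_set`: list with `sequence_id`,
#'   `enumerated`, `canonical` (match data frames) and `overlaps` (see
#'   [detect_overlaps()]).
#' @export
motif_hit_set <- function(sequence, sequence_id = "seq",
                          classes = c("CARC", "CRAC"),
                          spacer_min = 1L, spacer_max = 5L) {
  enumerated <- do.call(rbind, lapply(classes, function(cl) {
    enumerate_matches(sequence, compile_pattern(cl, spacer_min, spacer_max),
                      sequence_id = sequence_id)
  }))
  if (is.null(enumerated)) enumerated <- empty_matches()
  enumerated <- sort_matches(enumerated)
  rownames(enumerated) <- NULL
  canonical <- if (nrow(enumerated) > 0L) {
    do.call(rbind, lapply(split(enumerated, enumerated$motif_class), canonicalize))
  } else {
    canonicalize(enumerated)
  }
  canonical <- canonical[order(canonical$start, canonical$center, canonical$end), ,
                         drop = FALSE]
  rownames(canonical) <- NULL
  hits <- structure(
    list(sequence_id = sequence_id, enumerated = enumerated,
         canonical = canonical, overlaps = NULL),
    class = "motif_hit_set"
  )
  hits$overlaps <- detect_overlaps(hits)
  hits
}

#' @export
print.motif_hit_set <- function(x, ...) {
  cat(sprintf("<motif_hit_set %s> %d enumerated, %d canonical, %d cross-class overlap pair(s)\n",
              x$sequence_id, nrow(x$enumerated), nrow(x$canonical),
              nrow(x$overlaps)))
  invisible(x)
}

#' Detect overlapping canonical matches of different motif classes
#'
#' Two canonical matches overlap when their inclusive residue spans
#' \[start, end\] intersect and their motif classes differ (a CARC and a CRAC
#' instance sharing residues — the situation reported for adenylyl-cyclase
#' C2 helix alpha-2).
#'
#' @param hits A `motif_hit_set` (or a canonical match data frame).
#' @return A data frame with one row per unordered pair, columns suffixed
#'   `_a` / `_b` (a = leftmost).
#' @export
detect_overlaps <- function(hits) {
  canonical <- if (inherits(hits, "motif_hit_set")) hits$canonical else hits
  pair_cols <- function(m, suffix) {
    out <- m[, c("motif_class", "start", "center", "end", "subsequence")]
    names(out) <- paste0(names(out), suffix)
    out
  }
  empty <- cbind(pair_cols(empty_matches(), "_a"), pair_cols(empty_matches(), "_b"))
  n <- nrow(canonical)
  if (n < 2L) return(empty)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (canonical$motif_class[i] == canonical$motif_class[j]) next
      if (canonical$start[j] <= canonical$end[i] &&
          canonical$start[i] <= canonical$end[j]) {
        a <- if (canonical$start[i] <= canonical$start[j]) i else j
        b <- if (a == i) j else i
        rows[[length(rows) + 1L]] <-
          cbind(pair_cols(canonical[a, , drop = FALSE], "_a"),
                pair_cols(canonical[b, , drop = FALSE], "_b"))
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Keep matches starting inside a residue region
#'
#' @param matches A motif-match data frame.
#' @param region_start,region_end 1-based inclusive bounds; a match is kept
#'   when its `start` lies inside. Used e.g. to assign motifs to the C1
#'   (197-594) or C2 (815-1080) cytosolic domain of AC7.
#' @return The filtered data frame.
#' @export
filter_by_region <- function(matches, region_start, region_end) {
  region_start <- as.integer(region_start)
  region_end <- as.integer(region_end)
  if (is.na(region_start) || is.na(region_end) || region_start > region_end) {
    carcrac_abort(
      sprintf("invalid region [%s, %s]: need region_start <= region_end",
              region_start, region_end),
      "carcrac_invalid_region"
    )
  }
  out <- matches[matches$start >= region_start & matches$start <= region_end, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Re-validate a motif match against its sequence and pattern
#'
#' Checks anchor membership, spacer bounds and subsequence consistency from
#' first principles; used as a self-consistency guard on everything the
#' enumerator emits.
#'
#' @param sequence Residue string the match was called on.
#' @param match A one-row motif-match data frame (or a list with `start`,
#'   `center`, `end`, optionally `subsequence`).
#' @param pattern The [compile_pattern()] object to validate against.
#' @return `TRUE` or `FALSE`.
#' @export
validate_match <- function(sequence, match, pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  chars <- suppressWarnings(clean_sequence(sequence))
  s <- as.integer(match$start)
  cen <- as.integer(match$center)
  e <- as.integer(match$end)
  if (anyNA(c(s, cen, e)) || s < 1L || e > length(chars)) {
    carcrac_abort(
      sprintf("match indices (%s, %s, %s) out of bounds for sequence of length %d",
              s, cen, e, length(chars)),
      "carcrac_bounds"
    )
  }
  if (!(s < cen && cen < e)) return(FALSE)
  left <- cen - s - 1L
  right <- e - cen - 1L
  ok <- left >= pattern$spacer_min && left <= pattern$spacer_max &&
    right >= pattern$spacer_min && right <= pattern$spacer_max &&
    chars[s] %in% pattern$start_set &&
    chars[cen] %in% pattern$center_set &&
    chars[e] %in% pattern$terminal_set
  if (ok && !is.null(match$subsequence) && !is.na(match$subsequence)) {
    ok <- identical(paste(chars[s:e], collapse = ""),
                    as.character(match$subsequence))
  }
  ok
}
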