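## File interfaces for the scanning stage: FASTA in, TSV/GFF3 out.

#' Scan every record of a protein FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header. Empty
#' records yield a zero-row hit set and a warning.
#'
#' @param path Path to a (multi-record) protein FASTA file.
#' @inheritParams motif_hit_set
#' @return A named list of [motif_hit_set()] objects, one per record.
#' @export
scan_fasta <- function(path, classes = c("CARC", "CRAC"),
                       spacer_min = 1L, spacer_max = 5L) {
  seqs <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) carcrac_abort(
      sprintf("cannot read FASTA '%s': %s", path, conditionMessage(e)),
      "carcrac_unreadable_input"
    )
  )
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  out <- vector("list", length(seqs))
  names(out) <- ids
  for (i in seq_along(seqs)) {
    s <- as.character(seqs[[i]])
    if (nchar(s) == 0L) {
      carcrac_warn(sprintf("record '%s' is empty; 0 motifs", ids[i]),
                   "carcrac_empty_record")
    }
    out[[i]] <- motif_hit_set(s, sequence_id = ids[i], classes = classes,
                              spacer_min = spacer_min, spacer_max = spacer_max)
  }
  out
}

hit_table <- function(hit_sets, which = c("both", "enumerated", "canonical")) {
  which <- match.arg(which)
  if (inherits(hit_sets, "motif_hit_set")) hit_sets <- list(hit_sets)
  rows <- lapply(hit_sets, function(h) {
    switch(which,
      enumerated = h$enumerated,
      canonical = h$canonical,
      both = {
        enum <- h$enumerated
        key <- with(enum, paste(motif_class, start, center, end))
        can <- with(h$canonical, paste(motif_class, start, center, end))
        enum$canonical <- key %in% can
        enum
      }
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_matches()
  rownames(out) <- NULL
  out
}

#' Write motif matches as TSV
#'
#' Columns: `sequence_id  motif_class  start  center  end  subsequence
#' canonical`. Enumerated matches are written with their canonical flag set
#' for the per-site representatives.
#'
#' @param hit_sets A `motif_hit_set` or list of them (from [scan_fasta()]).
#' @param path Output file.
#' @param which Which matches to write: `"both"` (enumerated, flagged),
#'   `"enumerated"` or `"canonical"`.
#' @return The written data frame, invisibly.
#' @export
write_hits_tsv <- function(hit_sets, path, which = "both") {
  tab <- hit_table(hit_sets, which)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Read a motif-match TSV back into a match data frame
#' @param path File written by [write_hits_tsv()].
#' @return A motif-match data frame.
#' @export
read_hits_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c(
                             sequence_id = "character",
                             motif_class = "character",
                             start = "integer", center = "integer",
                             end = "integer",
                             subsequence = "character",
                             canonical = "logical"
                           ),
                           stringsAsFactors = FALSE)
  tab
}

#' Write motif matches as GFF3
#'
#' Emits one `sequence_motif` feature per match (1-based inclusive
#' coordinates on the protein sequence) with attributes `motif_class`,
#' `center` and `subsequence`.
#'
#' @inheritParams write_hits_tsv
#' @export
write_hits_gff3 <- function(hit_sets, path, which = "canonical") {
  tab <- hit_table(hit_sets, which)
  if (nrow(tab) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(tab))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = tab$sequence_id,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end)
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "carcrac",
    type = "sequence_motif",
    motif_class = tab$motif_class,
    center = tab$center,
    subsequence = tab$subsequence
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(tab)
}
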