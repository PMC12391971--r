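## Synthetic stand-ins for the human AC7 (adenylyl cyclase 7) study system.
##
## These are NOT real UniProt sequences. They are anchor-free random
## backgrounds into which the six published AC7 cytosolic CARC/CRAC motif
## subsequences are embedded at their published residue positions, so the
## published motif table can be recomputed offline from first principles.
## Everything outside the embedded motifs is synthetic background drawn from
## BACKGROUND_AA.

#' The published AC7 cytosolic motif table
#'
#' The six CARC/CRAC motif instances reported for the cytosolic catalytic
#' domains of human adenylyl cyclase 7, with their start positions in AC7
#' residue numbering, the isoforms carrying each motif, and the cytosolic
#' region (C1 = residues 197-594, C2 = 815-1080). The central aromatic of the
#' 388 motif is written F here (the published pattern allows F or Y at that
#' position).
#'
#' @return A data frame with columns `motif_class`, `start`, `subsequence`,
#'   `center`, `end`, `presence_published`, `region`.
#' @export
ac7_published_motifs <- function() {
  tab <- data.frame(
    motif_class = c("CARC", "CARC", "CARC", "CARC", "CARC", "CRAC"),
    start = c(324L, 388L, 889L, 921L, 931L, 1044L),
    subsequence = c("KILGDCYYCV", "RKWQFDV", "KVFYTECDV", "KPKFSGV",
                    "KTIGSTYMAAAGL", "LGYSCECR"),
    presence_published = c(
      "AC1, AC2, AC3, AC4, AC5, AC6, AC7, AC8",
      "AC1, AC2, AC3, AC4, AC5, AC6, AC7, AC8, AC9",
      "AC2, AC7",
      "AC2, AC4, AC7",
      "AC1, AC2, AC3, AC4, AC5, AC6, AC7, AC8, AC9",
      "AC2, AC4, AC7"
    ),
    stringsAsFactors = FALSE
  )
  tab$end <- tab$start + nchar(tab$subsequence) - 1L
  # center = position of the leftmost valid central aromatic
  tab$center <- vapply(seq_len(nrow(tab)), function(i) {
    m <- enumerate_matches(tab$subsequence[i],
                           compile_pattern(tab$motif_class[i]))
    tab$start[i] + min(m$center) - 1L
  }, integer(1))
  tab$region <- ifelse(tab$start >= 197L & tab$start <= 594L, "C1",
                       ifelse(tab$start >= 815L & tab$start <= 1080L, "C2", ""))
  tab[, c("motif_class", "start", "center", "end", "subsequence",
          "presence_published", "region")]
}

#' AC7 residue regions for the two cytosolic catalytic domains
#' @return Named list `C1 = c(197, 594)`, `C2 = c(815, 1080)`.
#' @export
ac7_regions <- function() {
  list(C1 = c(197L, 594L), C2 = c(815L, 1080L))
}

embed_motifs <- function(chars, motifs) {
  for (i in seq_len(nrow(motifs))) {
    idx <- seq.int(motifs$start[i], motifs$end[i])
    chars[idx] <- strsplit(motifs$subsequence[i], "", fixed = TRUE)[[1]]
  }
  chars
}

#' Synthetic AC7 stand-in sequence
#'
#' A 1080-residue synthetic sequence: random anchor-free background
#' ([BACKGROUND_AA]) with the six published AC7 motif subsequences embedded
#' at their published start positions. Because the background contains no
#' anchor residues, every motif instance on this sequence lies inside an
#' embedded subsequence. This is a labelled synthetic stand-in for offline
#' analysis, not the real AC7 (UniProtKB P51828) sequence.
#'
#' @param seed Integer seed for the background (default 101).
#' @param sequence_id Record id (default `"AC7"`).
#' @return Named character vector of length 1 (the sequence).
#' @export
synthetic_ac7_sequence <- function(seed = 101L, sequence_id = "AC7") {
  motifs <- ac7_published_motifs()
  chars <- with_seed(seed, sample(BACKGROUND_AA, 1080L, replace = TRUE))
  chars <- embed_motifs(chars, motifs)
  stats::setNames(paste(chars, collapse = ""), sequence_id)
}

#' Synthetic nine-isoform AC family alignment
#'
#' A labelled synthetic stand-in for an alignment of the nine human AC
#' isoforms: every member starts from the [synthetic_ac7_sequence()] core;
#' members that do not carry a motif (per the published presence column) have
#' that motif's central aromatic(s) mutated to `A`; member-specific random
#' background insertions (rate `indel_rate` per position, kept away from
#' motif windows) are encoded as alignment gaps. Member ids are `AC1..AC9`;
#' the reference is `AC7`.
#'
#' @param seed Integer seed (default 101).
#' @param indel_rate Per-position insertion probability outside motif
#'   windows (default 0.01).
#' @return A `carcrac_alignment` with attribute `"presence_truth"`: a named
#'   list mapping each motif start to the planted per-member presence map.
#' @export
synthetic_ac_family_alignment <- function(seed = 101L, indel_rate = 0.01) {
  motifs <- ac7_published_motifs()
  ids <- paste0("AC", 1:9)
  base <- strsplit(unname(synthetic_ac7_sequence(seed)[1]), "", fixed = TRUE)[[1]]
  carriers <- lapply(strsplit(motifs$presence_published, ",\\s*"), identity)
  presence_truth <- lapply(seq_len(nrow(motifs)), function(i) {
    stats::setNames(ids %in% carriers[[i]], ids)
  })
  names(presence_truth) <- as.character(motifs$start)

  # central aromatics per motif site (a site may hold two adjacent centers)
  center_positions <- lapply(seq_len(nrow(motifs)), function(i) {
    m <- enumerate_matches(motifs$subsequence[i],
                           compile_pattern(motifs$motif_class[i]))
    motifs$start[i] + unique(m$center) - 1L
  })

  core <- lapply(ids, function(id) {
    chars <- base
    for (i in seq_len(nrow(motifs))) {
      if (!presence_truth[[i]][[id]]) chars[center_positions[[i]]] <- "A"
    }
    paste(chars, collapse = "")
  })
  names(core) <- ids

  protected <- unlist(lapply(seq_len(nrow(motifs)), function(i) {
    seq.int(max(1L, motifs$start[i] - 3L), min(1080L, motifs$end[i] + 3L))
  }))
  free <- setdiff(seq_len(1079L), protected)
  aln <- with_seed(seed + 1L, {
    # the reference (AC7) stays insertion-free so its ungapped coordinates
    # remain the published motif positions
    insertions <- lapply(ids, function(id) {
      if (id == "AC7") return(integer(0))
      free[stats::runif(length(free)) < indel_rate]
    })
    names(insertions) <- ids
    align_with_insertions(core, insertions, "AC7")
  })
  attr(aln, "presence_truth") <- presence_truth
  aln
}
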