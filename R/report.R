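## Workflow configuration and the Table-style combined report.
##
## run_scan / run_conserve / run_structmap / run_report are the stage
## drivers used by the numbered scripts under analysis/; each is a thin
## orchestration layer over the module functions and writes one TSV.

#' Assemble a workflow configuration
#'
#' Defaults reproduce the published analysis settings: spacers 1-5,
#' similarity threshold 0.80, column tolerance 0, and the AC7 cytosolic
#' regions C1 = 197-594, C2 = 815-1080.
#'
#' @param fasta,msa,pdb,sites Input paths (FASTA, alignment, PDB, YAML site
#'   config); each optional, required only by the stages that use them.
#' @param msa_format `"fasta"` or `"clustal"`.
#' @param reference_id Reference member of the alignment.
#' @param classes Motif classes to scan.
#' @param spacer_min,spacer_max Spacer bounds.
#' @param regions Named list of `c(start, end)` residue regions.
#' @param similarity_threshold Center-column similarity threshold in \[0, 1\].
#' @param column_tolerance Column tolerance for presence calls.
#' @param offset Sequence-to-structure residue numbering offset.
#' @param gff Also write GFF3 from [run_scan()]?
#' @param seed Seed for synthetic stages.
#' @param out_dir Output directory for stage TSVs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(fasta = NULL, msa = NULL, msa_format = "fasta",
                       reference_id = NULL, pdb = NULL, sites = NULL,
                       classes = c("CARC", "CRAC"),
                       spacer_min = 1L, spacer_max = 5L,
                       regions = ac7_regions(),
                       similarity_threshold = 0.80,
                       column_tolerance = 0L,
                       offset = 0L, gff = FALSE, seed = 1L,
                       out_dir = "results") {
  if (similarity_threshold < 0 || similarity_threshold > 1) {
    carcrac_abort("similarity_threshold must lie in [0, 1]",
                  "carcrac_invalid_parameter")
  }
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (length(r) != 2L || r[1] > r[2]) {
      carcrac_abort(sprintf("region '%s' is malformed", nm),
                    "carcrac_invalid_region")
    }
  }
  compile_pattern(classes[1], spacer_min, spacer_max)  # validates bounds
  structure(
    list(fasta = fasta, msa = msa, msa_format = msa_format,
         reference_id = reference_id, pdb = pdb, sites = sites,
         classes = classes, spacer_min = as.integer(spacer_min),
         spacer_max = as.integer(spacer_max), regions = regions,
         similarity_threshold = similarity_threshold,
         column_tolerance = as.integer(column_tolerance),
         offset = as.integer(offset), gff = isTRUE(gff),
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

stage_path <- function(config, name) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(config$out_dir, name)
}

#' Scan stage: FASTA in, hits TSV (and optional GFF3) out
#'
#' @param config A [run_config()] with `fasta` set.
#' @return Invisibly, a list with `hit_sets`, `tsv` and (optionally) `gff`.
#' @export
run_scan <- function(config) {
  if (is.null(config$fasta)) {
    carcrac_abort("run_scan() needs `fasta` in the config",
                  "carcrac_missing_input")
  }
  hit_sets <- scan_fasta(config$fasta, classes = config$classes,
                         spacer_min = config$spacer_min,
                         spacer_max = config$spacer_max)
  n_hits <- sum(vapply(hit_sets, function(h) nrow(h$enumerated), integer(1)))
  message(sprintf("scan: %d record(s), %d enumerated motif(s)",
                  length(hit_sets), n_hits))
  if (n_hits == 0L) message("scan: 0 motifs")
  tsv <- stage_path(config, "hits.tsv")
  write_hits_tsv(hit_sets, tsv, which = "both")
  out <- list(hit_sets = hit_sets, tsv = tsv)
  if (config$gff) {
    gff <- stage_path(config, "hits.gff3")
    write_hits_gff3(hit_sets, gff)
    out$gff <- gff
  }
  invisible(out)
}

#' Conservation stage: alignment + reference hits in, conservation TSV out
#'
#' @param config A [run_config()] with `msa` and `reference_id` set.
#' @param hits Optional precomputed [motif_hit_set()] for the reference; by
#'   default the reference's ungapped sequence is rescanned.
#' @return Invisibly, a list with `summary` and `tsv`.
#' @export
run_conserve <- function(config, hits = NULL) {
  if (is.null(config$msa)) {
    carcrac_abort("run_conserve() needs `msa` in the config",
                  "carcrac_missing_input")
  }
  alignment <- if (inherits(config$msa, "carcrac_alignment")) config$msa
  else read_alignment(config$msa, format = config$msa_format)
  if (!is.null(config$reference_id)) {
    if (!config$reference_id %in% names(alignment$members)) {
      close_ids <- names(alignment$members)[order(utils::adist(
        config$reference_id, names(alignment$members)))]
      carcrac_abort(
        sprintf("reference id '%s' not in alignment; nearest members: %s",
                config$reference_id,
                paste(utils::head(close_ids, 3), collapse = ", ")),
        "carcrac_missing_reference"
      )
    }
    alignment$reference_id <- config$reference_id
  }
  if (is.null(hits)) {
    ref <- alignment$members[[alignment$reference_id]]
    hits <- motif_hit_set(ref$ungapped, sequence_id = alignment$reference_id,
                          classes = config$classes,
                          spacer_min = config$spacer_min,
                          spacer_max = config$spacer_max)
  }
  summary <- conservation_summary(
    alignment, hits,
    column_tolerance = config$column_tolerance,
    similarity_threshold = config$similarity_threshold,
    spacer_min = config$spacer_min, spacer_max = config$spacer_max
  )
  message(sprintf("conserve: %d canonical motif(s) scored across %d members",
                  nrow(summary), length(alignment$members)))
  tsv <- stage_path(config, "conservation.tsv")
  write_conservation_tsv(summary, tsv)
  invisible(list(summary = summary, alignment = alignment, hits = hits,
                 tsv = tsv))
}

#' Structure stage: PDB + hits + sites in, proximity TSV out
#'
#' @param config A [run_config()] with `pdb` and `sites` set.
#' @param hits A [motif_hit_set()] (required).
#' @return Invisibly, a list with `proximity` and `tsv`.
#' @export
run_structmap <- function(config, hits) {
  if (is.null(config$pdb) || is.null(config$sites)) {
    carcrac_abort("run_structmap() needs `pdb` and `sites` in the config",
                  "carcrac_missing_input")
  }
  model <- read_structure(config$pdb)
  sites <- if (is.character(config$sites)) read_sites(config$sites)
  else config$sites
  proximity <- annotate_proximity(model, hits, sites,
                                  sequence_offset = config$offset)
  message(sprintf("structmap: %d (motif x site) distance(s)",
                  nrow(proximity)))
  tsv <- stage_path(config, "proximity.tsv")
  write_proximity_tsv(proximity, tsv)
  invisible(list(proximity = proximity, tsv = tsv))
}

#' Render a match in dashed anchor/spacer notation
#'
#' Dashes separate anchors from spacers:
#' `start - left spacer - center - right spacer - terminal`, e.g.
#' `K-ILGDC-Y-YC-V`.
#'
#' @param match One-row motif-match data frame.
#' @return Character scalar.
#' @export
render_motif_dashes <- function(match) {
  s <- match$subsequence
  n <- nchar(s)
  cen <- match$center - match$start + 1L
  paste(
    substr(s, 1L, 1L),
    substr(s, 2L, cen - 1L),
    substr(s, cen, cen),
    substr(s, cen + 1L, n - 1L),
    substr(s, n, n),
    sep = "-"
  )
}

region_label <- function(start, regions) {
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (start >= r[1] && start <= r[2]) return(nm)
  }
  ""
}

#' Combined Table-style motif report
#'
#' One row per motif *site*: canonical matches sharing an identical
#' \[start, end\] span are merged into a single row; if the merged matches
#' span both classes the row is annotated `"combined CARC/CRAC"`. Each row
#' carries the dashed motif rendering, the raw subsequence (the dashed form
#' alone is ambiguous when a site holds two adjacent centers), the start
#' position, the region label, and — when a conservation summary is given —
#' the presence string.
#'
#' @param config A [run_config()] (supplies region definitions).
#' @param hits A [motif_hit_set()].
#' @param conservation Optional data frame from [conservation_summary()].
#' @param proximity Optional data frame from [annotate_proximity()]; minimum
#'   distances per site are appended as one column per `site_id`.
#' @return Invisibly, a list with `report` (data frame) and `tsv`.
#' @export
run_report <- function(config, hits, conservation = NULL, proximity = NULL) {
  if (missing(hits) || !inherits(hits, "motif_hit_set")) {
    carcrac_abort("run_report() needs the scan stage output (a motif_hit_set)",
                  "carcrac_missing_input")
  }
  can <- hits$canonical
  if (nrow(can) == 0L) {
    report <- data.frame(
      motif = character(0), subsequence = character(0), position = integer(0),
      region = character(0), classes = character(0), presence = character(0),
      note = character(0), stringsAsFactors = FALSE
    )
  } else {
    span <- paste(can$start, can$end, sep = "-")
    groups <- split(seq_len(nrow(can)), span)
    groups <- groups[order(vapply(groups, function(i) can$start[i[1]],
                                  integer(1)))]
    report <- do.call(rbind, lapply(groups, function(idx) {
      g <- can[idx, , drop = FALSE]
      g <- g[order(g$center), , drop = FALSE]
      classes <- sort(unique(g$motif_class))
      combined <- length(classes) > 1L
      note <- if (combined) "combined CARC/CRAC"
      else if (nrow(g) > 1L) "two adjacent centers" else ""
      presence <- ""
      if (!is.null(conservation)) {
        hit_rows <- conservation$ref_start == g$start[1] &
          conservation$motif_class %in% classes
        if (any(hit_rows)) {
          presence <- paste(unique(conservation$presence[hit_rows]),
                            collapse = " | ")
        }
      }
      data.frame(
        motif = render_motif_dashes(g[1, , drop = FALSE]),
        subsequence = g$subsequence[1],
        position = g$start[1],
        region = region_label(g$start[1], config$regions),
        classes = paste(classes, collapse = "/"),
        presence = presence,
        note = note,
        stringsAsFactors = FALSE
      )
    }))
    rownames(report) <- NULL
    if (!is.null(proximity) && nrow(proximity) > 0L) {
      for (sid in unique(proximity$site_id)) {
        col <- paste0("dist_", sid, "_A")
        report[[col]] <- vapply(report$position, function(p) {
          d <- proximity$min_distance_A[proximity$ref_start == p &
                                          proximity$site_id == sid]
          if (length(d) == 0L) NA_real_ else min(d)
        }, numeric(1))
      }
    }
  }
  tsv <- stage_path(config, "report.tsv")
  utils::write.table(report, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message(sprintf("report: %d motif site(s)", nrow(report)))
  invisible(list(report = report, tsv = tsv))
}
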