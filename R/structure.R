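## Structural projection: parse PDB coordinates, resolve named site
## selections, and annotate each canonical motif with its minimum distance
## (in Angstroms) to each site.

#' Read a PDB structure into an atom table
#'
#' Parses ATOM and HETATM records (via bio3d), preserving insertion codes and
#' resolving alternate locations to the highest-occupancy conformer (first on
#' ties).
#'
#' @param path PDB file.
#' @return An object of class `structure_model`: list with `atoms` (data
#'   frame: `chain`, `resno`, `insert`, `resid`, `elety`, `x`, `y`, `z`,
#'   `occ`, `het`) and `path`.
#' @export
read_structure <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) carcrac_abort(
      sprintf("cannot parse PDB '%s': %s", path, conditionMessage(e)),
      "carcrac_parse"
    )
  )
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) {
    carcrac_abort(sprintf("'%s' contains no coordinate records", path),
                  "carcrac_empty_structure")
  }
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = as.integer(a$resno),
    insert = ifelse(is.na(a$insert), "", a$insert),
    resid = a$resid,
    elety = a$elety,
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    het = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    carcrac_abort(sprintf("non-finite coordinates in '%s'", path),
                  "carcrac_parse")
  }
  # altloc resolution: keep the highest-occupancy copy of each atom
  key <- with(atoms, paste(chain, resno, insert, resid, elety, sep = "\r"))
  ord <- order(key, -atoms$occ)
  atoms <- atoms[ord, , drop = FALSE][!duplicated(sort(key)), , drop = FALSE]
  atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, path = path), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, %d residues (%s)\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno, x$atoms$insert))),
              x$path))
  invisible(x)
}

#' Define a named structural site
#'
#' A site is either a residue selection (`chain` + `resno` vector) or a
#' ligand selection by residue name (e.g. `"FSK"` for forskolin).
#'
#' @param site_id Name of the site (e.g. `"atp"`, `"allosteric"`).
#' @param chain Chain id for residue selections (`NULL` = any chain).
#' @param resno Integer vector of residue numbers.
#' @param ligand Ligand residue name (mutually exclusive with `resno`).
#' @return An object of class `site_definition`.
#' @export
site_definition <- function(site_id, chain = NULL, resno = NULL,
                            ligand = NULL) {
  if (is.null(resno) == is.null(ligand)) {
    carcrac_abort(
      sprintf("site '%s': give exactly one of `resno` or `ligand`", site_id),
      "carcrac_invalid_site"
    )
  }
  structure(
    list(site_id = site_id, chain = chain,
         resno = if (!is.null(resno)) as.integer(resno), ligand = ligand),
    class = "site_definition"
  )
}

#' Read site definitions from a YAML config
#'
#' Expected layout:
#' ```yaml
#' sites:
#'   - site_id: atp
#'     chain: A
#'     resno: [396, 397, 398]
#'   - site_id: fsk
#'     ligand: FSK
#' ```
#' @param path YAML file.
#' @return A list of [site_definition()] objects.
#' @export
read_sites <- function(path) {
  cfg <- yaml::read_yaml(path)
  entries <- if (!is.null(cfg$sites)) cfg$sites else cfg
  lapply(entries, function(e) {
    site_definition(e$site_id, chain = e$chain,
                    resno = if (!is.null(e$resno)) unlist(e$resno),
                    ligand = e$ligand)
  })
}

#' Resolve a site definition to concrete atoms
#'
#' @param model A [read_structure()] model.
#' @param site A [site_definition()].
#' @return The atom-table rows selected by the site.
#' @export
resolve_site <- function(model, site) {
  stopifnot(inherits(model, "structure_model"),
            inherits(site, "site_definition"))
  a <- model$atoms
  keep <- if (!is.null(site$ligand)) {
    a$resid == site$ligand
  } else {
    ok <- a$resno %in% site$resno
    if (!is.null(site$chain)) ok <- ok & a$chain == site$chain
    ok
  }
  sel <- a[keep, , drop = FALSE]
  if (nrow(sel) == 0L) {
    carcrac_abort(
      sprintf("site '%s' selects zero atoms in '%s'", site$site_id,
              model$path),
      "carcrac_empty_selection"
    )
  }
  sel
}

atoms_xyz <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

#' Minimum Euclidean distance between two atom sets
#'
#' @param atoms_a,atoms_b Atom tables (rows of a `structure_model`'s `atoms`)
#'   or plain n x 3 coordinate matrices.
#' @return The minimum pairwise distance in Angstroms, with attribute
#'   `nearest_pair` (row indices `i`, `j` into `atoms_a`, `atoms_b`).
#' @export
min_distance <- function(atoms_a, atoms_b) {
  xa <- if (is.matrix(atoms_a)) atoms_a else atoms_xyz(atoms_a)
  xb <- if (is.matrix(atoms_b)) atoms_b else atoms_xyz(atoms_b)
  if (nrow(xa) == 0L || nrow(xb) == 0L) {
    carcrac_abort("min_distance() requires non-empty atom selections",
                  "carcrac_empty_selection")
  }
  # squared distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  ij <- arrayInd(which.min(d2), dim(d2))
  structure(sqrt(d2[ij]), nearest_pair = c(i = ij[1, 1], j = ij[1, 2]))
}

#' Annotate canonical motif matches with distances to named sites
#'
#' For each (canonical match, site) pair, selects all atoms of the motif's
#' residue span (start..end, shifted by `sequence_offset` into the model's
#' numbering) and reports the minimum distance to the site's atoms. This
#' generalizes statements like "the motif lies ~10 A from the allosteric
#' site".
#'
#' @param model A [read_structure()] model.
#' @param hits A [motif_hit_set()] (its canonical matches are annotated) or a
#'   motif-match data frame.
#' @param sites A list of [site_definition()] objects (or a single one).
#' @param sequence_offset Added to motif residue indices to reach the model's
#'   residue numbering (models covering only a domain often renumber);
#'   default 0.
#' @param atom_mode `"all"` (all motif atoms, default), `"calpha"` (CA atoms
#'   only) or `"centroid"` (centroid of the motif atoms vs. site atoms).
#' @param chain Restrict the motif residue selection to one chain (`NULL` =
#'   any).
#' @return A data frame with one row per (match, site): `ref_start`,
#'   `motif_class`, `site_id`, `min_distance_A`, `motif_atom`, `site_atom`.
#' @export
annotate_proximity <- function(model, hits, sites, sequence_offset = 0L,
                               atom_mode = c("all", "calpha", "centroid"),
                               chain = NULL) {
  atom_mode <- match.arg(atom_mode)
  matches <- if (inherits(hits, "motif_hit_set")) hits$canonical else hits
  if (inherits(sites, "site_definition")) sites <- list(sites)
  a <- model$atoms
  rows <- list()
  for (i in seq_len(nrow(matches))) {
    resnos <- seq.int(matches$start[i], matches$end[i]) + sequence_offset
    keep <- a$resno %in% resnos & !a$het
    if (!is.null(chain)) keep <- keep & a$chain == chain
    motif_atoms <- a[keep, , drop = FALSE]
    absent <- setdiff(resnos, motif_atoms$resno)
    if (length(absent) > 0L) {
      carcrac_abort(
        sprintf("motif %s@%d: residue(s) %s absent from the model",
                matches$motif_class[i], matches$start[i],
                paste(absent, collapse = ", ")),
        "carcrac_mapping"
      )
    }
    if (atom_mode == "calpha") {
      motif_atoms <- motif_atoms[motif_atoms$elety == "CA", , drop = FALSE]
      if (nrow(motif_atoms) == 0L) {
        carcrac_abort(
          sprintf("motif %s@%d: no CA atoms in the model",
                  matches$motif_class[i], matches$start[i]),
          "carcrac_mapping"
        )
      }
    }
    motif_xyz <- atoms_xyz(motif_atoms)
    motif_lab <- with(motif_atoms, paste0(chain, resno, "/", elety))
    if (atom_mode == "centroid") {
      motif_xyz <- matrix(colMeans(motif_xyz), nrow = 1)
      motif_lab <- "centroid"
    }
    for (site in sites) {
      site_atoms <- resolve_site(model, site)
      d <- min_distance(motif_xyz, atoms_xyz(site_atoms))
      np <- attr(d, "nearest_pair")
      rows[[length(rows) + 1L]] <- data.frame(
        ref_start = matches$start[i],
        motif_class = matches$motif_class[i],
        site_id = site$site_id,
        min_distance_A = as.numeric(d),
        motif_atom = motif_lab[np["i"]],
        site_atom = with(site_atoms[np["j"], ],
                         paste0(chain, resno, "/", elety)),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else data.frame(
    ref_start = integer(0), motif_class = character(0),
    site_id = character(0), min_distance_A = numeric(0),
    motif_atom = character(0), site_atom = character(0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write a proximity table as TSV
#' @param proximity Data frame from [annotate_proximity()].
#' @param path Output file.
#' @export
write_proximity_tsv <- function(proximity, path) {
  utils::write.table(proximity, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(proximity)
}
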