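## Seeded synthetic-data generators and the brute-force oracle.
##
## Ground truth is exact by construction, not statistical: the background
## alphabet excludes all six anchor residues {K, R, Y, F, L, V}, so the only
## possible motif instances are the planted ones. A cross-implant match is
## impossible when implants are separated by >= 6 background residues: it
## would need a spacer longer than 5, which the pattern forbids.

#' Background alphabet for synthetic sequences (no anchor residues)
#' @export
BACKGROUND_AA <- c("A", "C", "D", "E", "G", "H", "I", "M",
                   "N", "P", "Q", "S", "T", "W")

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Specify one motif implant
#'
#' @param motif_class `"CARC"` or `"CRAC"`.
#' @param position 1-based start index of the implant.
#' @param left_spacer,right_spacer Spacer lengths, each in 1..5.
#' @param start_res,center_res,terminal_res Concrete anchor residues; default
#'   the first element of each anchor set.
#' @return An object of class `implant_spec` with the implant's `start`,
#'   `center`, `end` coordinates precomputed.
#' @export
implant_spec <- function(motif_class, position, left_spacer, right_spacer,
                         start_res = NULL, center_res = NULL,
                         terminal_res = NULL) {
  pat <- compile_pattern(motif_class)
  position <- as.integer(position)
  left_spacer <- as.integer(left_spacer)
  right_spacer <- as.integer(right_spacer)
  if (anyNA(c(position, left_spacer, right_spacer)) || position < 1L ||
      left_spacer < 1L || left_spacer > 5L ||
      right_spacer < 1L || right_spacer > 5L) {
    carcrac_abort("implant position must be >= 1 and spacers in 1..5",
                  "carcrac_invalid_parameter")
  }
  pick <- function(res, set, what) {
    if (is.null(res)) return(set[1])
    if (!res %in% set) {
      carcrac_abort(
        sprintf("%s residue '%s' not in the %s %s set {%s}",
                what, res, motif_class, what, paste(set, collapse = ",")),
        "carcrac_invalid_parameter"
      )
    }
    res
  }
  structure(
    list(
      motif_class = motif_class,
      position = position,
      left_spacer = left_spacer,
      right_spacer = right_spacer,
      start_res = pick(start_res, pat$start_set, "start"),
      center_res = pick(center_res, pat$center_set, "center"),
      terminal_res = pick(terminal_res, pat$terminal_set, "terminal"),
      start = position,
      center = position + 1L + left_spacer,
      end = position + 2L + left_spacer + right_spacer
    ),
    class = "implant_spec"
  )
}

implant_chars <- function(spec, rng_background = TRUE) {
  spacer <- function(k) {
    if (rng_background) sample(BACKGROUND_AA, k, replace = TRUE)
    else rep("A", k)
  }
  c(spec$start_res, spacer(spec$left_spacer), spec$center_res,
    spacer(spec$right_spacer), spec$terminal_res)
}

#' Generate a random sequence with motif implants at known positions
#'
#' Background residues are drawn only from [BACKGROUND_AA] (no anchor
#' residues), so the enumerated matches of the output are exactly the
#' implants.
#'
#' @param length Total sequence length.
#' @param implants List of [implant_spec()] objects (may be empty).
#' @param seed Integer seed; the generator uses a single PRNG stream and
#'   restores the caller's RNG state.
#' @param sequence_id Identifier for the generated sequence.
#' @return An object of class `synthetic_set`: list with `sequences` (named
#'   character), `ground_truth` (motif-match data frame), `seed`.
#' @export
make_sequence_with_implants <- function(length, implants, seed,
                                        sequence_id = "synth1") {
  length <- as.integer(length)
  if (inherits(implants, "implant_spec")) implants <- list(implants)
  if (base::length(implants) > 0L) {
    ord <- order(vapply(implants, `[[`, integer(1), "position"))
    implants <- implants[ord]
    spans <- vapply(implants, function(s) c(s$start, s$end), integer(2))
    if (any(spans[2, ] > length)) {
      carcrac_abort("implant extends beyond the sequence length",
                    "carcrac_implant_conflict")
    }
    if (base::length(implants) > 1L) {
      gaps <- spans[1, -1] - spans[2, -ncol(spans)] - 1L
      if (any(gaps < 6L)) {
        carcrac_abort(
          sprintf("implants must be separated by >= 6 background residues (observed gap %d)",
                  min(gaps)),
          "carcrac_implant_conflict"
        )
      }
    }
  }
  chars <- with_seed(seed, {
    bg <- sample(BACKGROUND_AA, length, replace = TRUE)
    for (s in implants) {
      bg[s$start:s$end] <- implant_chars(s)
    }
    bg
  })
  sequence <- paste(chars, collapse = "")
  truth <- if (base::length(implants) > 0L) {
    do.call(rbind, lapply(implants, function(s) {
      data.frame(
        sequence_id = sequence_id, motif_class = s$motif_class,
        start = s$start, center = s$center, end = s$end,
        subsequence = substr(sequence, s$start, s$end),
        canonical = TRUE, stringsAsFactors = FALSE
      )
    }))
  } else empty_matches()
  structure(
    list(sequences = stats::setNames(sequence, sequence_id),
         ground_truth = truth, alignment = NULL, structure_path = NULL,
         seed = as.integer(seed)),
    class = "synthetic_set"
  )
}

#' @export
print.synthetic_set <- function(x, ...) {
  cat(sprintf("<synthetic_set> %d sequence(s), %d planted match(es)%s%s (seed %d)\n",
              length(x$sequences), nrow(x$ground_truth),
              if (!is.null(x$alignment)) ", alignment" else "",
              if (!is.null(x$structure_path)) ", structure" else "",
              x$seed))
  invisible(x)
}

## Insert member-specific single-residue insertions (encoded as gap columns
## for everyone else) into a set of equal-length core sequences. `insertions`
## is a named list: member id -> integer vector of core positions AFTER which
## one background residue is inserted.
align_with_insertions <- function(core, insertions, reference_id) {
  L <- nchar(core[[1]])
  ids <- names(core)
  ins_count <- matrix(0L, nrow = length(ids), ncol = L + 1L,
                      dimnames = list(ids, NULL))
  for (id in names(insertions)) {
    pos <- insertions[[id]]
    for (p in pos) ins_count[id, p + 1L] <- ins_count[id, p + 1L] + 1L
  }
  slot_width <- apply(ins_count, 2, max)
  gapped <- vapply(ids, function(id) {
    chars <- strsplit(core[[id]], "", fixed = TRUE)[[1]]
    out <- character(0)
    for (slot in seq_len(L + 1L)) {
      w <- slot_width[slot]
      if (w > 0L) {
        k <- ins_count[id, slot]
        ins <- if (k > 0L) sample(BACKGROUND_AA, k, replace = TRUE) else character(0)
        out <- c(out, ins, rep("-", w - k))
      }
      if (slot <= L) out <- c(out, chars[slot])
    }
    paste(out, collapse = "")
  }, character(1))
  as_alignment(gapped, reference_id)
}

#' Generate an alignment with a planted per-member presence map
#'
#' All members share one background core carrying the implant; members marked
#' absent have the implant's central aromatic substituted by `A`. Random
#' background insertions (per member, rate `indel_rate` per core position)
#' are placed away from the implant window and encoded as alignment gaps in
#' the other members, so motif centers of carriers still align to one column.
#' The reference member receives no insertions, keeping the planted implant
#' coordinates valid in its own ungapped numbering.
#'
#' @param n_members Number of members (ids `member1..memberN` unless
#'   `presence` is named).
#' @param presence Logical vector (length `n_members`) of planted presence;
#'   the first member is the reference and must be `TRUE`.
#' @param implant An [implant_spec()].
#' @param indel_rate Per-position insertion probability outside the implant
#'   window (default 0).
#' @param seed Integer seed.
#' @param core_length Ungapped core length (default: implant end + 15).
#' @return A `synthetic_set` whose `alignment` is a `carcrac_alignment` and
#'   whose `ground_truth_presence` is the planted named logical map.
#' @export
make_alignment_with_presence <- function(n_members, presence, implant,
                                         indel_rate = 0, seed,
                                         core_length = NULL) {
  stopifnot(inherits(implant, "implant_spec"))
  if (length(presence) != n_members) {
    carcrac_abort("presence must have one entry per member",
                  "carcrac_invalid_design")
  }
  if (is.null(names(presence))) {
    names(presence) <- paste0("member", seq_len(n_members))
  }
  if (!presence[[1]]) {
    carcrac_abort("the reference (first) member must carry the implant",
                  "carcrac_invalid_design")
  }
  if (is.null(core_length)) core_length <- implant$end + 15L
  reference_id <- names(presence)[1]
  out <- with_seed(seed, {
    base <- make_sequence_with_implants(core_length, list(implant),
                                        seed = sample.int(2^30, 1),
                                        sequence_id = reference_id)
    base_seq <- unname(base$sequences[1])
    core <- lapply(names(presence), function(id) {
      s <- base_seq
      if (!presence[[id]]) {
        substr(s, implant$center, implant$center) <- "A"
      }
      s
    })
    names(core) <- names(presence)
    # insertion slots: outside the implant window plus a 3-residue margin
    window <- seq.int(max(1L, implant$start - 3L),
                      min(core_length, implant$end + 3L))
    free <- setdiff(seq_len(core_length - 1L), window)
    # the reference stays insertion-free so the planted implant coordinates
    # remain valid in its own ungapped numbering
    insertions <- lapply(names(presence), function(id) {
      if (id == reference_id || indel_rate <= 0 || length(free) == 0L) {
        return(integer(0))
      }
      free[stats::runif(length(free)) < indel_rate]
    })
    names(insertions) <- names(presence)
    aln <- align_with_insertions(core, insertions, reference_id)
    list(core = core, alignment = aln)
  })
  structure(
    list(
      sequences = vapply(out$core, identity, character(1)),
      ground_truth = empty_matches(),
      ground_truth_presence = vapply(presence, isTRUE, logical(1)),
      alignment = out$alignment,
      structure_path = NULL,
      implant = implant,
      seed = as.integer(seed)
    ),
    class = "synthetic_set"
  )
}

#' Generate a toy structure with a planted motif-to-site distance
#'
#' Writes a PDB with one C-alpha per motif residue placed 3.8 A apart along a
#' line, plus a single pseudo-site atom (residue name `SIT`, chain `S`)
#' positioned so the minimum motif-to-site distance equals `target_distance`
#' exactly. The whole rigid body is rotated and translated by a seeded random
#' isometry, which leaves all distances unchanged.
#'
#' @param match One-row motif-match data frame (residues `start..end` get a
#'   CA each).
#' @param target_distance Planted minimum distance in Angstroms (>= 0).
#' @param seed Integer seed (drives the random isometry).
#' @param path Output PDB path (default: a tempfile).
#' @return A `synthetic_set` with `structure_path`, the pseudo-`site`
#'   definition and `target_distance` recorded.
#' @export
make_toy_structure <- function(match, target_distance, seed,
                               path = tempfile(fileext = ".pdb")) {
  target_distance <- as.numeric(target_distance)
  if (is.na(target_distance) || target_distance < 0) {
    carcrac_abort("target_distance must be >= 0", "carcrac_invalid_parameter")
  }
  resnos <- seq.int(match$start, match$end)
  n <- length(resnos)
  xyz <- cbind(x = (seq_len(n) - 1) * 3.8, y = 0, z = 0)
  site_xyz <- c(xyz[n, 1] + target_distance, 0, 0)
  coords <- rbind(xyz, site_xyz)
  coords <- with_seed(seed, {
    # seeded rigid-body motion that stays exact under the PDB 3-decimal
    # coordinate fields: a signed axis permutation (det +1) plus a
    # translation on the 0.001-A grid
    rot <- diag(sample(c(-1, 1), 3, replace = TRUE))[, sample(3), drop = FALSE]
    if (det(rot) < 0) rot[, 1] <- -rot[, 1]
    shift <- round(stats::rnorm(3, sd = 20), 3)
    sweep(coords %*% rot, 2, -shift)
  })
  lines <- c(
    vapply(seq_len(n), function(i) {
      sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
              i, resnos[i], coords[i, 1], coords[i, 2], coords[i, 3])
    }, character(1)),
    sprintf("HETATM%5d ZN   SIT S%4d    %8.3f%8.3f%8.3f  1.00  0.00          ZN",
            n + 1L, 999L, coords[n + 1L, 1], coords[n + 1L, 2], coords[n + 1L, 3]),
    "END"
  )
  writeLines(lines, path)
  structure(
    list(
      sequences = character(0), ground_truth = match,
      alignment = NULL, structure_path = path,
      site = site_definition("pseudo_site", ligand = "SIT"),
      target_distance = target_distance,
      seed = as.integer(seed)
    ),
    class = "synthetic_set"
  )
}

#' Brute-force motif enumeration oracle
#'
#' Literal nested loops over every (start, center, end) index triple of the
#' sequence, checking the pattern's conditions for each triple — no windowing
#' or anchor pre-indexing. Serves as the independent ground truth for
#' equivalence tests against [enumerate_matches()].
#'
#' @inheritParams enumerate_matches
#' @return A motif-match data frame sorted by (start, center, end).
#' @export
brute_force_oracle <- function(sequence, pattern, sequence_id = "seq") {
  stopifnot(inherits(pattern, "motif_pattern"))
  chars <- clean_sequence(sequence)
  n <- length(chars)
  starts <- integer(0); centers <- integer(0); ends <- integer(0)
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) {
      if (!chars[i] %in% pattern$start_set) next
      for (cen in seq.int(i + 1L, n - 1L)) {
        if (!chars[cen] %in% pattern$center_set) next
        left <- cen - i - 1L
        if (left < pattern$spacer_min || left > pattern$spacer_max) next
        for (j in seq.int(cen + 1L, n)) {
          if (!chars[j] %in% pattern$terminal_set) next
          right <- j - cen - 1L
          if (right < pattern$spacer_min || right > pattern$spacer_max) next
          starts <- c(starts, i); centers <- c(centers, cen); ends <- c(ends, j)
        }
      }
    }
  }
  sort_matches(new_match_df(sequence_id, pattern$motif_class,
                            starts, centers, ends, chars))
}

#' Write a synthetic set's sequences and ground truth to files
#'
#' @param synth A `synthetic_set`.
#' @param dir Output directory (created if needed).
#' @param stem File stem (default `"synthetic"`).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_set <- function(synth, dir, stem = "synthetic") {
  stopifnot(inherits(synth, "synthetic_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (length(synth$sequences) > 0L) {
    p <- file.path(dir, paste0(stem, ".fasta"))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(synth$sequences), p)
    paths["fasta"] <- p
  }
  if (!is.null(synth$alignment)) {
    p <- file.path(dir, paste0(stem, "_aln.fasta"))
    gapped <- vapply(synth$alignment$members, `[[`, character(1), "gapped")
    Biostrings::writeXStringSet(Biostrings::AAStringSet(gapped), p)
    paths["alignment"] <- p
  }
  if (nrow(synth$ground_truth) > 0L) {
    p <- file.path(dir, paste0(stem, "_truth.tsv"))
    utils::write.table(synth$ground_truth, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["truth"] <- p
  }
  if (!is.null(synth$structure_path)) paths["structure"] <- synth$structure_path
  invisible(paths)
}
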