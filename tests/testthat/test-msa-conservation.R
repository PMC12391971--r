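# Alignment coordinate maps, per-column similarity and presence calls.

write_aln_fasta <- function(gapped, path = tempfile(fileext = ".fasta")) {
  writeLines(c(rbind(paste0(">", names(gapped)), unname(gapped))), path)
  path
}

test_that("read_alignment builds bidirectional coordinate maps", {
  p <- write_aln_fasta(c(s1 = "ACDEFGHIKL", s2 = "ACDEFGHIKL"))
  aln <- read_alignment(p)
  for (m in aln$members) {
    expect_equal(m$residue_to_column, 1:10)
    expect_equal(m$column_to_residue, 1:10)
  }

  p2 <- write_aln_fasta(c(s1 = "A-CD", s2 = "AACD"))
  aln2 <- read_alignment(p2)
  expect_equal(aln2$members$s1$ungapped, "ACD")
  expect_equal(aln2$members$s1$residue_to_column[2], 3L)  # C sits in column 3
  expect_equal(aln2$members$s1$column_to_residue, c(1L, NA, 2L, 3L))

  expect_error(as_alignment(c(a = "ACD-", b = "ACD")),
               class = "carcrac_alignment_shape")
  empty <- tempfile(fileext = ".fasta"); file.create(empty)
  expect_error(read_alignment(empty), class = "carcrac_empty_input")
  expect_error(as_alignment(c(a = "ACD", b = "ACD"), reference_id = "zz"),
               class = "carcrac_missing_reference")
})

test_that("clustal input and '.' gaps are handled", {
  clustal <- tempfile(fileext = ".aln")
  writeLines(c(
    "CLUSTAL W (1.83) multiple sequence alignment",
    "",
    "",
    "s1              KILGDCYYCV",
    "s2              KILGDCYYCV",
    "                **********"
  ), clustal)
  aln <- read_alignment(clustal, format = "clustal")
  expect_equal(length(aln$members), 2L)
  expect_equal(aln$members$s2$ungapped, "KILGDCYYCV")

  aln2 <- as_alignment(c(a = "A.CD", b = "AACD"))
  expect_equal(aln2$members$a$ungapped, "ACD")
})

test_that("column <-> residue maps round-trip on random gapped sequences", {
  set.seed(5)
  for (rep in 1:30) {
    n <- sample(5:40, 1)
    chars <- sample(c(carcrac:::STANDARD_AA, "-", "-"), n, replace = TRUE)
    if (all(chars == "-")) chars[1] <- "A"
    aln <- as_alignment(c(x = paste(chars, collapse = ""),
                          y = paste(rep("A", n), collapse = "")))
    m <- aln$members$x
    for (i in seq_len(nchar(m$ungapped))) {
      expect_identical(m$column_to_residue[m$residue_to_column[i]], i)
    }
    expect_true(all(diff(m$residue_to_column) > 0))
  }
})

test_that("column similarity counts positive substitution scores", {
  ids <- paste0("m", 1:9)
  # all identical at column 1
  aln <- as_alignment(stats::setNames(rep("YAAA", 9), ids))
  expect_equal(column_similarity(aln, 1), 1.0)

  # reference + 7 identical + 1 gapped at the column -> 7/8
  gapped <- c(rep("YAAA", 8), "-AAA")
  aln2 <- as_alignment(stats::setNames(gapped, ids))
  expect_equal(column_similarity(aln2, 1), 7 / 8)

  # all others gapped -> 0
  aln3 <- as_alignment(stats::setNames(c("YAAA", rep("-AAA", 8)), ids))
  expect_equal(column_similarity(aln3, 1), 0.0)

  # conservative substitution (F vs Y scores +3) counts as similar,
  # dissimilar residue (A vs Y) does not
  aln4 <- as_alignment(c(r = "Y", a = "F", b = "A"))
  expect_equal(column_similarity(aln4, 1), 1 / 2)

  expect_error(column_similarity(as_alignment(c(r = "-A", x = "AA")), 1),
               class = "carcrac_undefined_reference")
  expect_error(column_similarity(aln, 99), class = "carcrac_bounds")
})

test_that("presence calls follow the aligned center column", {
  carc <- compile_pattern("CARC")
  s <- "AAKILGDCYYCVAA"
  ref_match <- canonicalize(enumerate_matches(s, carc, sequence_id = "m1"))

  # identical members: all present
  aln <- as_alignment(stats::setNames(rep(s, 3), paste0("m", 1:3)))
  rec <- motif_presence(aln, ref_match, carc)
  expect_true(all(rec$per_isoform_presence))
  expect_equal(rec$center_column_similarity, 1.0)
  expect_true(rec$unified)

  # center aromatic mutated in one member: that member absent
  mut <- sub("YYC", "AYC", s)  # Y at the center -> A
  aln2 <- as_alignment(c(m1 = s, m2 = mut, m3 = s))
  rec2 <- motif_presence(aln2, ref_match, carc)
  expect_equal(unname(rec2$per_isoform_presence), c(TRUE, FALSE, TRUE))

  # upstream insertion, gapped so centers share a column: still present
  ins <- paste0("GGG", s)
  aln3 <- as_alignment(c(m1 = paste0("---", s), m2 = ins))
  rec3 <- motif_presence(aln3, ref_match, carc)
  expect_true(rec3$per_isoform_presence[["m2"]])

  # gap at the member's aligned center column counts as absent even though
  # the member carries the same motif elsewhere
  aln4 <- as_alignment(c(
    m1 = paste0(s, strrep("-", nchar(s))),
    m2 = paste0(strrep("-", nchar(s)), s)
  ))
  rec4 <- motif_presence(aln4, ref_match, carc)
  expect_false(rec4$per_isoform_presence[["m2"]])

  expect_error(motif_presence(aln, one_match(1, 99, 120), carc),
               class = "carcrac_bounds")
})

test_that("increasing column tolerance never turns presence off", {
  set.seed(19)
  for (rep in 1:20) {
    synth <- make_alignment_with_presence(
      5, c(TRUE, sample(c(TRUE, FALSE), 4, replace = TRUE)),
      implant_spec("CARC", position = 10, left_spacer = 3, right_spacer = 2),
      indel_rate = 0.08, seed = 1000 + rep
    )
    ref_match <- one_match(10, 14, 17)
    carc <- compile_pattern("CARC")
    prev <- NULL
    for (tol in 0:3) {
      pres <- motif_presence(synth$alignment, ref_match, carc,
                             column_tolerance = tol)$per_isoform_presence
      if (!is.null(prev)) expect_true(all(pres[prev]))
      prev <- pres
    }
  }
})

test_that("conservation_summary renders presence strings in member order", {
  implant <- implant_spec("CARC", position = 12, left_spacer = 2,
                          right_spacer = 4)
  ids <- paste0("AC", 1:9)
  presence <- stats::setNames(rep(TRUE, 9), ids)
  synth <- make_alignment_with_presence(9, presence, implant, seed = 3)
  ref <- synth$alignment$members$AC1
  hits <- motif_hit_set(ref$ungapped, sequence_id = "AC1")
  cs <- conservation_summary(synth$alignment, hits)
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$presence, paste(ids, collapse = ", "))
  expect_true(cs$unified)

  presence2 <- stats::setNames(c(TRUE, rep(FALSE, 8)), ids)
  presence2[c("AC2", "AC7")] <- TRUE
  synth2 <- make_alignment_with_presence(9, presence2, implant, seed = 4)
  hits2 <- motif_hit_set(synth2$alignment$members$AC1$ungapped,
                         sequence_id = "AC1")
  cs2 <- conservation_summary(synth2$alignment, hits2)
  expect_equal(cs2$presence, "AC1, AC2, AC7")

  # empty canonical set -> empty summary
  no_motif <- as_alignment(c(a = "ACDACDACD", b = "ACDACDACD"))
  empty_hits <- motif_hit_set("ACDACDACD", sequence_id = "a")
  expect_equal(nrow(conservation_summary(no_motif, empty_hits)), 0L)

  # hits for a different sequence are rejected
  wrong <- motif_hit_set(ref$ungapped, sequence_id = "zz")
  expect_error(conservation_summary(synth$alignment, wrong),
               class = "carcrac_inconsistent_input")
})
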