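# Motif pattern compilation, exhaustive enumeration, canonical selection,
# overlap detection and region filtering.

test_that("compile_pattern fixes anchor sets by class and validates spacers", {
  crac <- compile_pattern("CRAC")
  expect_setequal(crac$start_set, c("L", "V"))
  expect_setequal(crac$center_set, "Y")
  expect_setequal(crac$terminal_set, c("K", "R"))
  expect_equal(c(crac$spacer_min, crac$spacer_max), c(1L, 5L))

  carc <- compile_pattern("CARC")
  expect_setequal(carc$start_set, c("K", "R"))
  expect_setequal(carc$center_set, c("Y", "F"))
  expect_setequal(carc$terminal_set, c("L", "V"))

  expect_error(compile_pattern("FOO"), class = "carcrac_invalid_class")
  expect_error(compile_pattern("CARC", spacer_min = 0),
               class = "carcrac_invalid_spacer")
  expect_error(compile_pattern("CARC", spacer_min = 3, spacer_max = 2),
               class = "carcrac_invalid_spacer")
})

test_that("enumeration returns every valid triple and nothing else", {
  carc <- compile_pattern("CARC")
  crac <- compile_pattern("CRAC")

  m <- enumerate_matches("KILGDCYYCV", carc)
  expect_equal(match_triples(m), "CARC:1-7-10")
  expect_equal(m$subsequence, "KILGDCYYCV")

  expect_equal(nrow(enumerate_matches("AAAAA", carc)), 0L)
  expect_equal(match_triples(enumerate_matches("RKWQFDV", carc)),
               c("CARC:1-5-7", "CARC:2-5-7"))
  expect_equal(nrow(enumerate_matches("KILGDCYYCV", crac)), 0L)

  # case-insensitive; tolerated extras allowed in spacers, never as anchors
  expect_equal(match_triples(enumerate_matches("kilgdcyycv", carc)),
               "CARC:1-7-10")
  expect_equal(match_triples(enumerate_matches("KXXXXXYXV", carc)),
               "CARC:1-7-9")  # X's fill spacers but can never be anchors
  expect_equal(match_triples(enumerate_matches("XKXXXXYXVX", carc)),
               "CARC:2-7-9")
  expect_error(enumerate_matches("KIL1DCYYCV", carc),
               class = "carcrac_invalid_residue")
  expect_warning(m2 <- enumerate_matches("RKWQFDV*KILGDCYYCV", carc),
                 class = "carcrac_stop_codon")
  expect_equal(match_triples(m2), c("CARC:1-5-7", "CARC:2-5-7"))
})

test_that("canonical selection keeps the leftmost start then nearest end", {
  carc <- compile_pattern("CARC")
  can <- canonicalize(enumerate_matches("RKWQFDV", carc))
  expect_equal(match_triples(can), "CARC:1-5-7")
  expect_true(all(can$canonical))

  # idempotence and one representative per (class, center)
  expect_equal(canonicalize(can)[, 1:5], can[, 1:5])
  # two terminals for one center: nearest end wins
  m <- enumerate_matches("KAFAVAL", carc)  # center F3, ends V5 and L7
  expect_equal(match_triples(m), c("CARC:1-3-5", "CARC:1-3-7"))
  expect_equal(match_triples(canonicalize(m)), "CARC:1-3-5")

  expect_equal(nrow(canonicalize(empty_matches())), 0L)
  mixed <- rbind(one_match(1, 3, 5), one_match(1, 3, 5, sequence_id = "other"))
  expect_error(canonicalize(mixed), class = "carcrac_inconsistent_input")
})

test_that("canonical output size equals the number of (class, center) groups", {
  set.seed(41)
  for (rep in 1:25) {
    s <- random_sequence(sample(10:60, 1))
    for (cl in c("CARC", "CRAC")) {
      m <- enumerate_matches(s, compile_pattern(cl))
      can <- canonicalize(m)
      expect_equal(nrow(can),
                   length(unique(paste(m$motif_class, m$center))))
    }
  }
})

test_that("cross-class overlapping canonical pairs are detected", {
  hits <- motif_hit_set("VAYAKAYAL")
  expect_equal(nrow(hits$overlaps), 1L)
  expect_equal(hits$overlaps$motif_class_a, "CRAC")
  expect_equal(hits$overlaps$motif_class_b, "CARC")
  expect_equal(hits$overlaps$end_a, 5L)
  expect_equal(hits$overlaps$start_b, 5L)

  # disjoint spans: no pair
  disjoint <- rbind(one_match(1, 3, 5, "CRAC"), one_match(10, 12, 14, "CARC"))
  expect_equal(nrow(detect_overlaps(disjoint)), 0L)
  # same class intersecting: no pair
  same <- rbind(one_match(1, 3, 5, "CARC"), one_match(4, 6, 8, "CARC"))
  expect_equal(nrow(detect_overlaps(same)), 0L)
})

test_that("region filtering is inclusive on start positions", {
  starts <- c(324L, 388L, 889L, 921L, 931L, 1044L)
  m <- do.call(rbind, lapply(starts, function(s) one_match(s, s + 2, s + 4)))
  expect_equal(filter_by_region(m, 197, 594)$start, c(324L, 388L))
  expect_equal(nrow(filter_by_region(m, 815, 1080)), 4L)
  expect_equal(filter_by_region(m, 324, 324)$start, 324L)
  expect_error(filter_by_region(m, 5, 4), class = "carcrac_invalid_region")
  # identity on the whole sequence
  expect_equal(filter_by_region(m, 1, 2000), m)
})

test_that("validate_match re-derives every invariant from the sequence", {
  carc <- compile_pattern("CARC")
  crac <- compile_pattern("CRAC")
  s <- "KILGDCYYCV"
  expect_true(validate_match(s, one_match(1, 7, 10), carc))
  expect_false(validate_match(s, one_match(1, 8, 10), carc))  # left spacer 6
  expect_false(validate_match(s, one_match(1, 7, 10, "CRAC"), crac))
  expect_error(validate_match(s, one_match(1, 7, 11), carc),
               class = "carcrac_bounds")
  # subsequence consistency is enforced when provided
  expect_false(validate_match(s, one_match(1, 7, 10, subsequence = "WRONG"),
                              carc))
})

test_that("every emitted match passes validate_match (self-consistency)", {
  set.seed(7)
  for (rep in 1:50) {
    s <- random_sequence(sample(5:60, 1))
    for (cl in c("CARC", "CRAC")) {
      pat <- compile_pattern(cl)
      m <- enumerate_matches(s, pat)
      for (i in seq_len(nrow(m))) {
        expect_true(validate_match(s, m[i, ], pat))
      }
    }
  }
})

test_that("enumeration agrees with the brute-force oracle on random input", {
  set.seed(11)
  for (rep in 1:100) {
    s <- random_sequence(sample(0:50, 1))
    for (cl in c("CARC", "CRAC")) {
      pat <- compile_pattern(cl)
      expect_identical(match_triples(enumerate_matches(s, pat)),
                       match_triples(brute_force_oracle(s, pat)),
                       info = paste(cl, s))
    }
  }
})

test_that("CARC with Y center mirrors to CRAC on the reversed sequence", {
  rev_seq <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  carc <- compile_pattern("CARC")
  crac <- compile_pattern("CRAC")
  set.seed(23)
  for (rep in 1:60) {
    s <- random_sequence(sample(5:50, 1))
    n <- nchar(s)
    chars <- strsplit(s, "")[[1]]
    carc_y <- enumerate_matches(s, carc)
    carc_y <- carc_y[chars[carc_y$center] == "Y", , drop = FALSE]
    mirrored <- if (nrow(carc_y) == 0L) character(0) else
      sort(sprintf("CRAC:%d-%d-%d", n + 1L - carc_y$end,
                   n + 1L - carc_y$center, n + 1L - carc_y$start))
    expect_identical(match_triples(enumerate_matches(rev_seq(s), crac)),
                     mirrored, info = s)
  }
})
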