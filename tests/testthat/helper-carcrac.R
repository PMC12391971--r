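# Shared helpers: random sequences over the full residue alphabet and a
# quick coordinate-triple formatter for readable failure messages.

random_sequence <- function(n, alphabet = carcrac:::STANDARD_AA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

match_triples <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  sort(sprintf("%s:%d-%d-%d", m$motif_class, m$start, m$center, m$end))
}

one_match <- function(start, center, end, motif_class = "CARC",
                      sequence_id = "seq", subsequence = NA_character_) {
  data.frame(sequence_id = sequence_id, motif_class = motif_class,
             start = as.integer(start), center = as.integer(center),
             end = as.integer(end), subsequence = subsequence,
             canonical = TRUE, stringsAsFactors = FALSE)
}
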