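---
title: "Methods: CARC/CRAC motif scanning, conservation and structural proximity"
author: "carcrac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CARC/CRAC motif scanning, conservation and structural proximity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carcrac)
```

## The problem

Cholesterol and its derivatives interact with membrane proteins through two
short, loosely specified sequence motifs. The CRAC motif (Cholesterol
Recognition/Interaction Amino acid Consensus) reads, from the N- to the
C-terminus,

```
L/V - X(1-5) - Y - X(1-5) - K/R
```

and the CARC motif is its mirrored counterpart, also written N→C:

```
K/R - X(1-5) - Y/F - X(1-5) - L/V
```

Each motif consists of three *anchors* — a branched apolar start (L/V), a
central aromatic (Y, or Y/F for CARC), and a basic terminal (K/R) — separated
by two *spacers* of one to five arbitrary residues. The variable spacers make
the patterns degenerate: a single central aromatic can participate in many
valid (start, center, end) triples, and candidate instances must afterwards
be judged by conservation and by where they sit in the 3D structure.

This package implements that pipeline for protein sequences in general, with
the cytosolic catalytic domains of human transmembrane adenylyl cyclases
(AC1–AC9) as the worked system: their C1 (residues 197–594 in AC7 numbering)
and C2 (815–1080) domains carry several CARC/CRAC instances near the ATP and
forskolin binding sites.

## Motif enumeration and canonical selection

`enumerate_matches()` returns **every** index triple satisfying the pattern —
no deduplication. This exhaustive set is the well-defined mathematical object
(it is what a brute-force scan of all triples produces), so it is what the
test oracle checks and what downstream presence calls rescan.

For reporting, one representative per *site* is selected by
`canonicalize()`: matches are grouped by `(motif_class, center)` — motif
identity is anchored on the central aromatic — and within a group the match
with the **leftmost start** wins, remaining ties broken by the **nearest
terminal**. When two basic residues sit adjacent upstream of a center (as in
`RKWQ-F-DV`, where both R and K are valid starts), this rule reports the
R-anchored instance, matching how such sites are conventionally written.

A site may legitimately hold *two* canonical matches when two adjacent
aromatics are both valid centers (e.g. `KV-FY-TECD-V`, centers F and Y with
the same span). The report layer (`run_report()`) merges span-identical
canonical matches into one row, annotated `"two adjacent centers"`, or
`"combined CARC/CRAC"` when the merged matches come from both classes.
Cross-class overlap on *different* spans is reported separately by
`detect_overlaps()`.

Other scanning conventions, stated once:

* Coordinates are 1-based and inclusive, in ungapped residue numbering.
* Input is upper-cased before scanning. The ambiguity/non-standard codes
  `X U O B Z J` are tolerated in spacer positions but never match an anchor
  set; `*` truncates the sequence with a warning; anything else is an error.
* Scanning is strictly N→C for both classes (CARC is already the mirrored
  pattern written N→C); no reverse-strand logic exists for proteins.
* Output ordering is deterministic — `(start, center, end, class)` — so
  repeated runs diff cleanly.

A useful structural identity: reversing a sequence maps every Y-centered CARC
instance onto a CRAC instance (and vice versa), with coordinates reflected as
`i → n + 1 − i`. The test suite exercises this mirror property on random
sequences, since it catches asymmetric off-by-one errors in either spacer
window.

## Conservation on a multiple sequence alignment

The alignment is always an **input** (aligned FASTA or Clustal; gaps `-` or
`.`): this package never aligns, which keeps results deterministic and keeps
third-party aligner behavior out of the tested surface.

Two quantities are computed per canonical reference motif:

* **Per-isoform presence.** A member carries the motif iff its ungapped
  sequence contains an enumerated match of the same class whose central
  aromatic maps to the same alignment column as the reference center
  (`column_tolerance = 0` by default, configurable). Anchoring presence on
  the aligned center column — rather than, say, on any same-class match in a
  window — is a design choice: the central aromatic is the defining contact
  of both motifs, and the column map makes the criterion exact under
  insertions elsewhere. A gap at the member's aligned center column counts
  as absent even if the member has a same-class motif elsewhere. Increasing
  the tolerance can only add members, never remove them (a tested
  monotonicity property).
* **Center-column similarity.** The fraction of non-reference members whose
  residue at the center column scores strictly positive against the
  reference residue under BLOSUM62 (gaps and unscorable codes count as
  dissimilar). A record is flagged `unified` when this fraction is ≥ 0.80,
  mirroring the common practice of unifying annotations shared by at least
  80% of aligned sequences. Whether such a rule should be applied per
  column, per motif window, or per annotation block is genuinely open; the
  per-center-column reading used here is the most conservative one that is
  still anchored on the motif's defining residue, and both the matrix and
  the threshold are arguments.

## Structural proximity

`read_structure()` parses PDB coordinate records (insertion codes preserved,
alternate locations resolved to the highest-occupancy conformer), and
`annotate_proximity()` reports, for each (canonical match, named site) pair,
the minimum Euclidean distance between the motif's atoms and the site's
atoms.

Statements like "the motif lies ≈10 Å from the allosteric site" never come
with an atom-selection convention, so the default here is the **all-atom
minimum distance** over the full motif span — reproducible and conservative
(it lower-bounds every other convention). `atom_mode = "calpha"` and
`"centroid"` are offered for sensitivity checks, and such published rounded
distances are treated as qualitative anchors only, never as test oracles.
`sequence_offset` maps sequence numbering into model numbering for
structures that cover only a domain. Sites are user-supplied — a residue
selection or a ligand residue name, optionally from a small YAML config —
because pocket *prediction* is outside this package's scope.

## Synthetic data: what it emulates, and what it does not

Every stage is testable offline against exact ground truth because the
generators make false signals impossible *by construction* rather than
improbable:

* **Sequences** (`make_sequence_with_implants()`): background residues are
  drawn only from the 14-letter alphabet that excludes all six anchor
  residues `{K, R, Y, F, L, V}`, so the enumerated matches of a generated
  sequence are exactly the implants. Implants must be separated by ≥ 6
  background residues: a cross-implant match would need a spacer longer
  than 5, which the pattern forbids.
* **Alignments** (`make_alignment_with_presence()`): members share one core;
  absent members have the implant's central aromatic mutated to `A`
  (destroying the match while leaving the other anchors intact — the
  hardest absence to detect correctly); random per-member insertions away
  from the motif window become gap columns for everyone else, so carriers'
  centers still share one column. The reference member receives no
  insertions, keeping planted coordinates valid in its numbering.
* **Structures** (`make_toy_structure()`): one Cα per motif residue along a
  line plus a single pseudo-site atom at exactly the target distance; the
  whole body is then moved by a seeded rigid isometry. Because PDB
  coordinate fields carry three decimals, the isometry is restricted to a
  signed axis permutation plus a 0.001 Å-grid translation, which the file
  format represents exactly — an arbitrary rotation would inject ~10⁻³ Å
  of rounding noise and mask real regressions below that scale. Rigid-body
  invariance under *arbitrary* rotations is tested separately, in memory.

All generators take a mandatory seed, use a single PRNG stream, restore the
caller's RNG state, and regenerate byte-identical files from equal seeds.

What the generators deliberately do **not** emulate: real amino-acid
composition (backgrounds are uniform over a reduced alphabet), real MSA
uncertainty (indels never hit the motif window; real aligners can misplace
motif columns), and real protein geometry (toy structures are collinear Cα
traces). Passing tests therefore demonstrate the *correctness of the
machinery* — enumeration, coordinate maps, presence logic, distance
computation — not the biological sensitivity or specificity of the motif
definitions on real proteomes, which is known to be limited for such
degenerate patterns.

## The adenylyl-cyclase stand-ins

`synthetic_ac7_sequence()` and `synthetic_ac_family_alignment()` are
**labelled synthetic stand-ins**, not database sequences: a 1080-residue
anchor-free random background in which the six published AC7 cytosolic motif
subsequences (`KILGDCYYCV`@324, `RKWQFDV`@388, `KVFYTECDV`@889,
`KPKFSGV`@921, `KTIGSTYMAAAGL`@931, `LGYSCECR`@1044) are embedded at their
published start positions, and a nine-member family built from that core
with each motif's central aromatic knocked out in exactly the isoforms
reported not to carry it. The published table lists the 388-site center as
F/Y; the stand-in uses F, since only the underlying database sequence could
resolve the choice, and either letter satisfies the pattern.

Running the pipeline on the stand-ins therefore recomputes the published
motif positions, the 2 (C1) / 4 (C2) region split, and the per-isoform
presence strings from first principles — it validates the scanner,
coordinate maps and presence logic against the published table, but it does
not re-derive that table from the real isoform sequences, which is what one
would do with database access by pointing `run_scan()`/`run_conserve()` at
the real FASTA and MSA.

## Problem sizes and numerical choices

The verification sweeps use 1,000 random sequences (length ≤ 50, both
classes) for scanner-vs-oracle equivalence, 200 implant-recovery sequences,
500 mirror-property sequences, 100 planted-presence alignments, and 10 toy
structures each for planted-distance recovery (tolerance 10⁻⁶ Å) and
rigid-body invariance; all complete in seconds. Degenerate inputs are
defined, not accidental: empty sequences scan to empty tables; an empty
canonical set yields an empty (header-only) report; zero-length selections
and empty structures are classed errors rather than NA propagation.

## Known limitations

* Presence calls depend on alignment quality; a misaligned center column
  produces a false absence. The `column_tolerance` knob mitigates but cannot
  repair a bad alignment.
* The 80% unification rule is one defensible reading of a convention that is
  usually stated without an operational definition (see above); comparisons
  across tools should fix the matrix, the threshold, and the per-column
  reading explicitly.
* CARC/CRAC patterns are highly degenerate; enumerated counts on real
  proteins are large, and the canonical set is a reporting convention, not a
  claim about binding. Functional relevance requires orthogonal evidence.
* Distance annotation is geometry only: no solvent accessibility, no pocket
  prediction, no docking, no pose scoring.
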