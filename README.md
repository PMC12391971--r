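# carcrac

Scanning, conservation scoring and structural mapping of CARC/CRAC
cholesterol-recognition motifs on protein sequences.

## The problem

Cholesterol and sterol derivatives recognize membrane proteins through two
short consensus motifs, written N- to C-terminus:

```
CRAC:  L/V - X(1-5) - Y   - X(1-5) - K/R
CARC:  K/R - X(1-5) - Y/F - X(1-5) - L/V   (the mirrored pattern)
```

Three anchor residues (branched apolar start, central aromatic, basic
terminal) are separated by two spacers of 1–5 arbitrary residues. The
variable spacers make the patterns degenerate, so finding them is only the
first step: candidate instances must be checked for conservation across
homologs on a multiple sequence alignment and located relative to functional
sites in the 3D structure. This package implements that pipeline for anyone
studying cholesterol-recognition motifs in protein families — the worked
system is the cytosolic catalytic domains (C1: residues 197–594, C2:
815–1080 in AC7 numbering) of the nine human transmembrane adenylyl
cyclases, which carry several such motifs near their ATP and forskolin
binding sites.

The package provides:

* **Motif scanning** — exhaustive enumeration of every valid
  (start, center, end) triple (`enumerate_matches()`), canonical per-site
  selection (`canonicalize()`: leftmost start, then nearest terminal),
  cross-class overlap detection, and region filtering; FASTA in, TSV/GFF3
  out.
* **Conservation** — residue↔column maps on a pre-computed alignment
  (aligned FASTA or Clustal), per-isoform presence calls anchored on the
  aligned central-aromatic column, and BLOSUM62-based center-column
  similarity with an 80% unification flag.
* **Structural proximity** — PDB parsing, named site selections (residue
  sets or ligands, YAML-configurable), and minimum all-atom motif-to-site
  distances in Å.
* **Synthetic data** — seeded generators for motif-implanted sequences,
  alignments with planted presence maps, and toy structures with planted
  distances, plus a brute-force enumeration oracle; ground truth is exact
  by construction (anchor-free background alphabet), so every stage is
  testable offline.

`synthetic_ac7_sequence()` and `synthetic_ac_family_alignment()` are
labelled synthetic stand-ins for the adenylyl-cyclase system: anchor-free
random background with the six published AC7 cytosolic motif subsequences
embedded at their published positions (and, for the family, each motif's
central aromatic knocked out in the isoforms reported not to carry it).
They are not database sequences; with database access you would point the
same functions at the real FASTA/MSA/PDB files.

## Worked example

```r
library(carcrac)

# exhaustive enumeration: both R388- and K389-anchored variants of one site
enumerate_matches("RKWQFDV", compile_pattern("CARC"))
#>   sequence_id motif_class start center end subsequence canonical
#> 1         seq        CARC     1      5   7     RKWQFDV     FALSE
#> 2         seq        CARC     2      5   7      KWQFDV     FALSE

# canonical selection keeps the leftmost start
canonicalize(enumerate_matches("RKWQFDV", compile_pattern("CARC")))
#>   sequence_id motif_class start center end subsequence canonical
#> 1         seq        CARC     1      5   7     RKWQFDV      TRUE

# a CRAC and a CARC instance sharing residue 5 of "VAYAKAYAL"
motif_hit_set("VAYAKAYAL")$overlaps
#>   motif_class_a start_a center_a end_a subsequence_a motif_class_b start_b
#> 1          CRAC       1        3     5         VAYAK          CARC       5
#>   center_b end_b subsequence_b
#> 1        7     9         KAYAL
```

The full workflow on the synthetic adenylyl-cyclase stand-ins lives in the
numbered drivers under `analysis/` (scan → conservation → structure →
report), each writing its table under `results/`:

```sh
Rscript analysis/01_scan_motifs.R
Rscript analysis/02_conservation.R
Rscript analysis/03_structure_proximity.R
Rscript analysis/04_report.R
```

Stage 1 prints the six motif sites (`KILGDCYYCV`@324 … `LGYSCECR`@1044) and
their 2 (C1) / 4 (C2) region split; stage 2 recomputes each site's
per-isoform presence string (e.g. `AC1, …, AC9` for the 388 site,
`AC2, AC7` for the 889 site); stage 4 merges span-identical canonical
matches into single rows rendered in dashed notation (`K-ILGDC-Y-YC-V`).

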