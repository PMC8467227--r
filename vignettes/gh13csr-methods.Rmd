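---
title: "CSR fingerprinting of GH13 alpha-amylases: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CSR fingerprinting of GH13 alpha-amylases: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gh13csr)
```

## The coordinate system

Alpha-amylases of glycoside hydrolase family GH13 share a catalytic
(beta/alpha)8 TIM-barrel whose eight parallel strands carry short conserved
sequence regions (CSRs). Concatenated in their order of appearance along the
sequence — CSR-VIII (beta1), CSR-VI, CSR-I, CSR-V, CSR-II, CSR-III, CSR-IV,
CSR-VII (beta8) — they form a 55-column *fingerprint* that serves as a
family-wide coordinate system:

```{r}
csr_layout()
```

Three landmark sets live on this frame. The catalytic triad sits at columns
28 (Asp, nucleophile, CSR-II), 37 (Glu, proton donor, CSR-III) and 46 (Asp,
transition-state stabilizer, CSR-IV). The chloride-binding triad of animal
and animal-like enzymes sits at 26 (Arg), 44 (Asn) and 50 (Arg or Lys). All
downstream statistics — logo profiles, chloride verdicts, the CSR tree —
are computed on this 55-column frame, so anchoring it correctly on an
alignment is the package's central operation.

One recorded inconsistency: descriptions of the GH13_42 subfamily place a
YYGS motif at "positions 53–56" of a 55-column logo. The layout caps at 55;
the packaged GH13_42 motif carries YYG at 53–55 and the discrepancy is noted
rather than resolved.

## Anchoring: reference-guided by design

Published CSR assignments rest on expert curation of a manually tuned
alignment. The reproducible equivalent used here is a *reference
annotation*: one alignment row whose ungapped CSR start positions and triad
positions are known. `locate_anchors()` maps those positions to alignment
columns by counting non-gap characters along the reference row, verifies
Asp/Glu/Asp at the triad columns (a hard error otherwise), and requires the
reference row to be gap-free inside every CSR, since CSRs are defined as
ungapped blocks. `extract_fingerprints()` then reads the 55 reference
columns for every row; a row gapped at a column carries `-` there, so every
fingerprint is exactly 55 characters.

A conservation-based fallback, `infer_anchors()`, is provided for
alignments with no annotated row. It scans for the Asp/Glu/Asp column triple
maximizing occupancy-weighted conservation under CSR-compatible spacing,
using the family's other near-invariant landmarks (Arg at 26, Asn at 44,
the Asp closing CSR-III at 40) to break ties, and places the remaining CSR
spans at conservation-maximizing windows. It is documented and tested as a
heuristic; a curated reference is always preferable.

## The synthetic families

Because the original 268 GenBank/UniProt sequences are not redistributed,
every stage is exercised on synthetic families with planted truth. A record
is a chain of eight CSR blocks copied from a per-subfamily consensus motif,
joined by linkers whose lengths are drawn uniformly from configurable
ranges and whose content is a per-subfamily consensus prefix,
point-substituted at rate ε (default 0.10, a realistic within-family
divergence; recovery tests use ε = 0.05). Landmark columns — the catalytic
triad, the chloride sites and any planted SBS residues — are never mutated,
so the generated truth table (fingerprints, chloride capability, SBS
letters and positions) is exact by construction.

The default motifs encode the documented landmarks in every subfamily:
D28/E37/D46, the broadly conserved R26, N44, and Arg at 50 only in the
chloride-dependent animal subfamilies (GH13_15, GH13_24). The GH13_42 motif
instead carries the subfamily's distinctive serine at 44 (with Thr11,
Tyr41, an MTA start and the YYG tail), which is why a GH13_42 family is
never chloride-capable. The `chloride_triad` switch plants `RNR`, `RNK`
(the cold-adapted bacterial pattern), a custom triple, or forces a
non-Arg/Lys residue (Gln — the known glutamine exception pattern) at 50.

`generate_truth_msa()` pads each variable-length block to its family-wide
maximum with trailing gaps, yielding an oracle alignment in which CSR
columns line up exactly. What the generator deliberately does **not**
emulate: substitution-model evolution along a tree, indels inside CSRs,
compositional bias, and domain architecture beyond one optional signal
peptide. Green tests on synthetic data therefore certify the machinery
(coordinate bookkeeping, classification rules, tree plumbing), not the
biological accuracy of any particular alignment of real sequences.

## Redundancy reduction

Sets are reduced so that no two retained sequences exceed 90% identity.
Identity is matches over residue–residue alignment columns (gap columns
excluded from the denominator) — the least length-biased common convention,
chosen because the underlying procedure does not pin one down. The greedy
scheme visits records longest-first (ties by accession) and keeps a record
iff its identity to every kept representative is ≤ the threshold; strictly
exceeding it (matching the ">90%" rule) assigns the record to the first
such representative. Longest-first retention is a documented choice:
deterministic, and it preserves the most informative representative.

## The aligner

The progressive aligner exists so the pipeline runs with no external
tools. Pairwise and profile–profile alignment use global (Needleman–Wunsch/
Gotoh) dynamic programming with affine gaps under the convention
`cost(k) = gap_open + (k−1)·gap_extend` (defaults 10/0.5, classic
Clustal-era values; terminal gaps penalized like internal ones), BLOSUM62
by default, and deterministic traceback ties (diagonal, then gap in the
first input, then gap in the second). The guide tree is UPGMA on
pairwise-identity distances; profiles are merged bottom-up with
frequency-weighted column scores (gaps contribute zero). The aim is not to
reproduce any external aligner column-for-column: externally computed MSAs
import first-class via `read_msa()`, and the reference-guided anchoring
absorbs the role that manual alignment curation plays in expert practice.

Correctness is pinned by an enumeration oracle: a memo-free recursion over
all alignments, checked exhaustively for every ordered pair of length ≤ 3
over a 3-letter alphabet and on a seeded sample of 200 pairs of lengths
4–5 (the oracle handles length 5; exhaustive coverage beyond length 3 was
scaled for test-suite size, a package choice).

## Logo statistics

Per fingerprint column the profile counts the 20 standard residues (gaps
and X excluded), and information content is `IC = log2(20) − H` bits with
`H` the Shannon entropy of observed letter frequencies. The small-sample
correction `e_n = 19/(2 ln 2 · n)` is available but **off** by default,
since the rendering service historically used for such logos does not
report its internal settings. Closed forms anchor the tests: an invariant
column is 4.3219 bits, a uniform 20-letter column 0 bits, a 50/50
two-letter column 3.3219 bits. Seven profile sets are produced for a full
input: one pooled and one per subfamily.

## Chloride classification

A fingerprint is chloride-capable iff column 26 is R, 44 is N and 50 is R
or K; K gives the "lys" variant (an equally positive side chain known not
to abolish binding). Gaps and X never satisfy a site. The rule is strictly
boolean and purely local to the three columns — a metamorphic test mutates
any other position and requires an unchanged verdict. Column 44 follows the
logo numbering; prose descriptions sometimes place the asparagine "three
residues before" the stabilizer where the coordinates give two — the
self-consistent coordinates win. Only R/K pass at column 50; whether other
positive residues (e.g. His) could support binding is not addressed and
deliberately not speculated on.

## SBS correspondence mapping

Templates are solved structures with experimentally identified surface
binding sites, stored with both mature (signal peptide removed) and
precursor numbering; which numbering applies to a given row is
caller-declared, mirroring how it must be resolved structure-by-structure
in practice. `map_template_columns()` counts the template residue position
along the template's own alignment row and hard-fails if the row's letter
disagrees — mapping through a wrong numbering mode is caught immediately.
Correspondences read the observed letter of every row at each mapped
column; the aromatic set is {F, W, Y} (His excluded, configurable). The
packaged registry keeps both published readings of the *B.
paralicheniformis* second SBS residue (Y358 canonical, Y368 as
`variant_precursor`) rather than silently resolving them, and registers the
*A. niger* structure under both of its circulating PDB codes. Transcribed
per-subfamily residue grids ship as plain-text fixtures so conservation
summaries are testable with no downloads.

## Trees

Two trees are built per run: one from the beta1–beta8 segment alignment,
one from the 55-column fingerprint alignment. Inference is neighbor-joining
on p-distances (pairwise deletion by default, complete deletion behind a
flag), with negative branch lengths clamped to zero, plus nonparametric
bootstrap (column resampling) supports; the default 500 replicates matches
standard practice for this analysis, while tests and the demonstration
pipeline use 20–100 to keep runs short. NJ stands in for maximum-likelihood
inference deliberately: it is deterministic and desk-scale, the ML settings
behind published trees are unspecified, and alignments are exported in
PHYLIP/FASTA for external ML programs. NJ recovers additive distances
exactly, which the tests verify against randomly generated trees; exact
reproduction of any published topology is not attempted.

## Pipeline and determinism

`run_pipeline()` chains simulate → dedupe → align → anchor/extract → logos
→ chloride → SBS → trees, writes only plain-text artifacts plus a run
manifest (package version, seed, parameter echo — no timestamps), and is
byte-identical across reruns with the same configuration and seed: one
integer seeds the generator, and the bootstrap. The demonstration problem
size (60 records, bootstrap 100) was chosen so a full run completes in
seconds; every stage is also callable standalone on file-level inputs.

## Known limitations

* Anchoring requires the reference row to be gap-free within CSRs; families
  with insertions inside a CSR in the reference row are rejected rather
  than guessed at.
* The greedy dedupe is quadratic in the number of sequences — appropriate
  for hundreds, not tens of thousands (no k-mer prefilter).
* `infer_anchors()` is a heuristic and can be misled by strongly conserved
  Asp/Glu columns outside the CSRs; it is a fallback, not the method.
* Synthetic families validate machinery, not biology; conclusions about
  real sequences require real alignments, supplied via `read_msa()` with a
  curated reference annotation.
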