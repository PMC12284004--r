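---
title: "Methods: scaffold detection, anchored alignment and subfamily classification of CSαβ defensins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scaffold detection, anchored alignment and subfamily classification of CSab defensins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csabtools)
library(dplyr)
```

# The problem

Cysteine-stabilised αβ (CSαβ) defensins are small antimicrobial peptides in
which an α-helix is fastened to a β-sheet by three disulphide bonds between
six conserved cysteines (C1…C6). The family spans fungi, molluscs,
arthropods — and, through defensin-like bacteriocins such as actifensin,
bacteria. Comparative analysis of these peptides separates them into two
structural subfamilies with distinct N-terminal architecture:

* **GXGCP**: a short N-terminal loop ending Gly–aromatic–Gly immediately
  before C1, usually followed by Pro at C1+1. This group spans bacteria and
  "ancient" invertebrate/fungal lineages (trans-kingdom).
* **XTCD**: an extended N-terminal loop with Thr at C1−1 and Asp at C1+1,
  usually followed by a pair of aliphatic residues; found only in
  eukaryotes, concentrated in the recent insect orders.

`csabtools` packages that comparative analysis as a deterministic,
offline-reproducible pipeline: scaffold detection, maturation, a
cysteine-anchored multiple alignment, rule-based subfamily classification,
conservation scoring of the plectasin lipid II binding residues, and
taxonomic spread summaries — together with a seeded synthetic-corpus
generator so every stage is testable without any database download.

# Scaffold detection

`find_scaffold()` searches the cysteines of a sequence for six positions
whose five inter-cysteine loop lengths fall inside configurable spacing
windows. The defaults generalise the plectasin anchor geometry (cysteines
at 4, 15, 19, 30, 37, 39, i.e. loops of 10, 3, 10, 6, 1 residues):

| loop  | window (residues) |
|-------|-------------------|
| C1–C2 | 4–16 |
| C2–C3 | 2–6  |
| C3–C4 | 6–14 |
| C4–C5 | 3–10 |
| C5–C6 | 1–3  |

plus an N-loop cap of 25 residues during search. Among valid six-subsets
the winner maximises the number of loops at their window midpoint, breaking
ties by smallest total deviation from the midpoints, then smallest C1, then
lexicographically smallest positions — a fully deterministic rule. The
implementation is a window-pruned depth-first extension; the test suite
checks it against exhaustive enumeration of all six-cysteine subsets on
hundreds of random sequences.

Two windows deserve comment. The C5–C6 window (1–3) is tight because the
β2–β3 turn is structurally constrained; the C1–C2 window is wide because
the helix-entry loop absorbs most of the family's length variation. All
windows are user-configurable for peptides outside the 34–60 residue range
the defaults target.

**Maturation.** `trim_to_mature()` anchors trimming on the detected
scaffold: `mature_start = max(1, C1 − max_nloop)` (default 12) and
`mature_end = min(length, C6 + max_tail)` (default 6). This is deliberately
*scaffold-anchored*, not leader-model-based: predicted signal/leader
annotations from curated databases are not available offline, and a
scaffold-anchored rule is exactly reproducible. During this search the
N-loop cap is lifted (a precursor's leader sits before C1 and removing it
is the point of trimming). Trimming is idempotent, and sequences without a
valid scaffold are flagged, never dropped silently.

# Cysteine-anchored alignment

The classical workflow for these families — run a general-purpose aligner,
then manually adjust so the six cysteines line up — is not reproducible.
`build_anchored_alignment()` replaces it with a deterministic construction
that *guarantees* the anchors: the seven scaffold segments (N-loop, five
interior loops, C-tail) are aligned as independent blocks and concatenated
around dedicated single-residue anchor columns that are cysteine in every
row.

* The **N-loop block is right-justified** toward C1 and padded on the
  left. This keeps the motif positions C1−1, C1−2, C1−3 column-stable,
  which is what makes the GXGCP/XTCD motifs readable as columns.
* The **C-tail block is left-justified** — ragged tails have no anchor on
  their right, and justification is the only choice that cannot reorder
  homologous residues.
* The five **interior loop blocks** are aligned with the center-star
  method (`align_segment_center_star()`): the star segment maximises the
  summed pairwise global-alignment score; every other segment is aligned
  to the star by affine-gap global alignment (Gotoh); the pairwise
  alignments are merged under "once a gap, always a gap". Star ties break
  on the lexicographically smallest segment, so the block does not depend
  on input order.

Defaults are BLOSUM62 with gap open 10 and extend 1 (a gap of length *L*
costs 10 + *L*); these are conventional values for short peptide loops, and
a `pad` mode (justify-and-pad only) is provided as a trivially verifiable
baseline.

**What center-star does and does not guarantee.** Center-star is the
classical 2-approximation of the sum-of-pairs-optimal multiple alignment.
On exhaustive small instances (up to four segments of up to four residues,
widths up to max length + 2) the package's brute-force oracle shows the
implementation never exceeds the optimum, is exact for two segments, and
attains the optimum on the large majority of random instances — but not
all of them: both the arbitrary choice among co-optimal pairwise
alignments and the star topology itself can cost a few score points (e.g.
segments `{"KQ", "", "W"}` admit no center-star merge that reaches the
optimum). Users needing certified SP-optimality on tiny blocks should use
an exact method; within this pipeline the anchors, not the intra-loop gap
placement, carry the biology.

Coordinate bookkeeping is explicit: `column_for_reference_position()` and
`position_for_column()` are mutually inverse on non-gap cells, and all
surfaced positions and columns are 1-based.

# Subfamily classification

Only part of each subfamily carries its complete motif (in the curated
corpus that motivated the defaults, 52/88 short-loop peptides carry the
full GXG and 23/33 extended-loop peptides the aliphatic pair), so a single
motif test cannot reproduce the subfamily split. `classify_subfamily()`
therefore scores three votes per label:

* `score_GXGCP` = [N-loop ≤ 5] + [G, aromatic, G at C1−3…C1−1] + [P at C1+1]
* `score_XTCD` = [N-loop ≥ 6] + [T at C1−1 and D at C1+1] + [aliphatic pair
  at C1+2…C1+3]

and assigns the unique winner when it reaches 2 votes, otherwise
`UNCLASSIFIED`. Loop length is one vote because it is the one feature that
holds across each whole subfamily; the 5/6 threshold splits the short
(≤ 5, actifensin-like N-loop of 3) and extended (≥ 6) loop regimes and is
configurable. The two motifs are structurally exclusive (G versus T at
C1−1), so no peptide can carry both. The conserved histidine immediately
before C3 is computed (`check_prec3_his()`) and reported — including per
subfamily, since its published denominator is ambiguous — but never votes:
it is conserved across *both* subfamilies and cannot separate them. The
XTCD "X" and the helix double-Ala propensity are likewise descriptive, not
scored: their published frequencies are observations, not rules. The
aliphatic-pair offset (C1+2…C1+3) is configurable because the exact
position of the pair within the loop is not pinned down in the source
material.

# Mechanism-residue conservation

Nine plectasin residues have been tied to lipid II binding: F2, H18, K20,
I22, K23, Y25, K26, Y29, Y40. `score_mechanism_residues()` maps each onto
its alignment column via the plectasin reference row (built in:
`plectasin_record()`, the 40-residue mature peptide) and scores every
peptide as `identical`, `conservative`, `nonconservative` or `gap` at that
column.

"Conservative" is never defined numerically in the comparative literature
this package serves, so the package makes the definition transparent and
auditable: two residues are conservative substitutes when they share at
least one class in

aromatic {F, W, Y, H}, aliphatic {A, V, L, I, M}, positive {K, R, H},
negative {D, E}, small-polar {S, T, N, Q, G, C, P},

with histidine deliberately in two classes. An alternative `blosum` mode
(conservative ⇔ BLOSUM62 score > 0) is provided for sensitivity analysis.
Unknown residues (X) score nonconservative. K23 receives no special
treatment: its expected non-conservation in actifensin-like peptides is a
property of the data, not a rule of the scorer.

# Taxonomic spread

`spread_by_clade()` aggregates subfamily calls up a user-supplied lineage
table (taxon → ordered clade path), flagging each clade GXGCP-only,
XTCD-only or mixed, with parent counts equal to the sum over children at
every node. "Kingdom" is operationalised as depth 1 of the supplied
lineage — the children of the shared root — because the package never
queries a live taxonomy service; `trans_kingdom_flag()` is true when a
label occurs under at least two depth-1 clades. Tree annotation
(`write_tree_annotation()`) emits the input Newick unchanged plus a
leaf/label/colour table under the fixed convention GXGCP = yellow,
XTCD = blue; labels for taxa absent from the tree are reported and
skipped, never fatal.

# The synthetic corpus generator

`generate_corpus()` builds peptides segment-wise on a scaffold sampled
inside the spacing windows, then plants subfamily features at configured
fidelities. The defaults *are* the corpus-level statistics of the curated
family the analysis targets: an 88:35 GXGCP:XTCD mixture (71.5% GXGCP),
lengths 34–60, mean 38 (sampled as 34 + Poisson(4), which also reproduces
the observed concentration of lengths at ≤ 43), and fidelities
p\_gxg = 0.59, p\_pro = 0.91, p\_his = 0.82, p\_xtcd = 1.0,
p\_aliphatic = 0.70. Mechanism residues are planted from a subfamily
template at fidelity 0.9 per position (a package default: the qualitative
published description — "largely conserved or conservatively substituted"
— gives no number), with class-shuffled alternatives on failure; the XTCD
template substitutes Y25→R and Y40→K (the non-conservative substitutions
described for that group) and leaves the F2-homologous position unplanted.
Taxa are sampled from synthetic clades shaped like the family's real
spread: GXGCP from bacterial plus fungal/mollusc/early-insect clades, XTCD
from the recent insect orders only.

What the generator deliberately does **not** emulate: real loop sequence
homology (backgrounds are uniform over the 19 non-Cys residues, so
interior loops align far more raggedly than real family members would),
cysteine-containing leaders (leaders are Cys-free so scaffold-anchored
maturation is well-posed), database artefacts such as ambiguous residues,
and real taxon identifiers. Passing tests therefore demonstrate the
*pipeline's* correctness — anchor guarantees, label recovery, count
conservation, determinism — not that real corpora will show any particular
conservation percentage.

Determinism is strict: a fixed seed yields byte-identical FASTA, truth
table, lineage table and Newick, and the generator restores the caller's
RNG state.

# Numerical and degenerate-input choices

* All probabilities are validated into [0, 1]; infeasible length/window
  combinations fail before any output.
* Empty segments are legal everywhere (an empty N-loop or tail is a
  zero-width block).
* Sequences with fewer than six cysteines, or with no window-satisfying
  subset, return "no scaffold" rather than erroring; downstream stages
  list them in exclusion reports.
* Score ties are always broken deterministically (documented per
  function); no stage depends on hash or input order.
* Report files contain no timestamps, so identical config + seed
  reproduces byte-identical outputs.

# Problem sizes used by the test suite

The bundled tests and the acceptance script run entirely on generated
data: corpora of 123 peptides (the canonical 88:35 mixture) for
pipeline-level checks, 100–250 peptides per subfamily for statistical
fidelity checks, 500 random sequences for the scaffold-search oracle, and
200 random segment sets (≤ 4 segments × ≤ 4 residues) for the exhaustive
alignment oracle. These sizes give the oracles full coverage of the
combinatorics they enumerate while keeping a complete run in tens of
seconds on one CPU.

# Known limitations

* Two-disulphide (2ds-CSαβ) scaffolds are out of scope; the detector
  requires exactly six matched cysteines.
* Center-star intra-loop alignment is a 2-approximation (see above).
* Maturation can retain up to `max_nloop` leader residues when the true
  leader/mature boundary is further from C1 than the configured margin;
  on peptides whose leader contains cysteines the scaffold search may in
  principle select a leader cysteine as C1 if the spacing windows admit
  it.
* The classifier's loop-length thresholds (5/6) are defaults calibrated to
  the family's short/extended loop regimes, not universal constants.

# A worked example

```{r example}
corpus <- generate_corpus(generator_config(n_gxgcp = 20, n_xtcd = 8, seed = 42))
mature <- trim_to_mature(corpus$records)
calls  <- classify_subfamily(mature)
summarize_calls(calls)

aln <- build_anchored_alignment(
  bind_rows(mature, trim_to_mature(plectasin_record()))
)
glance(aln)

report <- score_mechanism_residues(aln, calls = calls)
glance(report)

spread <- spread_by_clade(calls, corpus$lineages)
trans_kingdom_flag(spread, "GXGCP")
trans_kingdom_flag(spread, "XTCD")
```
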