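# csabtools

Comparative sequence analysis of cysteine-stabilised αβ (CSαβ) defensins
and defensin-like bacteriocins, for researchers studying antimicrobial
peptides across kingdoms. The CSαβ fold fastens an α-helix to a β-sheet
with three disulphide bonds between six conserved cysteines (C1…C6); the
family separates into two structural subfamilies by N-terminal
architecture:

* **GXGCP** — short N-terminal loop ending Gly–X(aromatic)–Gly before C1,
  usually Pro at C1+1; a trans-kingdom group spanning bacteria (e.g.
  actifensin-like bacteriocins), fungi and ancient invertebrates.
* **XTCD** — extended N-terminal loop with Thr at C1−1 and Asp at C1+1,
  usually followed by an aliphatic pair; eukaryote-only, concentrated in
  recent insect orders.

The package provides, as composable tibble-in/tibble-out functions:

* `find_scaffold()` / `trim_to_mature()` — detect the six-cysteine
  scaffold by configurable loop-spacing windows and trim precursors to
  mature peptides, scaffold-anchored and fully offline;
* `build_anchored_alignment()` — a deterministic multiple alignment whose
  six anchor columns are guaranteed all-cysteine (center-star alignment of
  the loop blocks, affine-gap Gotoh pairwise core, BLOSUM62 defaults),
  replacing the usual align-then-manually-adjust workflow;
* `classify_subfamily()` / `summarize_calls()` — a 2-of-3 vote over loop
  length, N-terminal motif and accessory residues:

  `score_GXGCP = [N-loop ≤ 5] + [GXG at C1−3…C1−1] + [P at C1+1]`,
  `score_XTCD = [N-loop ≥ 6] + [T at C1−1 ∧ D at C1+1] + [aliphatic pair at C1+2…C1+3]`;

* `score_mechanism_residues()` — conservation of the nine plectasin
  lipid II binding residues (F2, H18, K20, I22, K23, Y25, K26, Y29, Y40)
  under an auditable residue-class scheme (or BLOSUM62 > 0);
* `spread_by_clade()` / `trans_kingdom_flag()` /
  `write_tree_annotation()` — subfamily spread over a supplied taxonomy
  with the fixed colour convention GXGCP = yellow, XTCD = blue;
* `generate_corpus()` — a seeded synthetic corpus generator with planted
  motifs and a truth table (default: the canonical 88:35 mixture, lengths
  34–60 with mean 38), so the whole pipeline is testable offline;
* `run_pipeline()` — end-to-end orchestration with a manifest and
  byte-reproducible reports (plus a thin CLI in
  `inst/scripts/csab-pipeline.R`).

Result objects follow broom conventions (`tidy()`, `glance()`) and have
`autoplot()` methods.

## A worked example

```r
library(csabtools)
library(dplyr)

corpus <- generate_corpus(generator_config(seed = 1))   # 88 GXGCP + 35 XTCD
mature <- trim_to_mature(corpus$records)
calls  <- classify_subfamily(mature)
summarize_calls(calls)
#> <subfamily_summary>
#>         label  n fraction
#>         GXGCP 82    66.7%
#>          XTCD 35    28.5%
#>  UNCLASSIFIED  6     4.9%
#> lengths: 34-44 (mean 38.1, n=123)
```

The generator planted 88 GXGCP peptides but only 59% of them carry the
full GXG motif and 91% the Pro (the family's real motif fidelities), so a
handful land in `UNCLASSIFIED` — the classifier recovers the planted
subfamily for 95–98% of peptides depending on the seed.

```r
aln <- build_anchored_alignment(
  bind_rows(mature, trim_to_mature(plectasin_record()))
)
glance(aln)
#>   n_rows width gap_fraction anchor_purity n_excluded
#> 1    124   142        0.731             1          0
```

`anchor_purity` of 1 means every row has cysteine in all six anchor
columns — the alignment's defining guarantee. The high gap fraction is a
property of the uniform-random synthetic loops; real family loops are far
more alignable.

```r
report <- score_mechanism_residues(aln, calls = calls)
glance(report)
#>   n_peptides n_positions frac_identical frac_conservative frac_nonconservative
#> 1        123           9          0.647             0.117               0.0813

spread <- spread_by_clade(calls, corpus$lineages)
trans_kingdom_flag(spread, "GXGCP")   # TRUE  — bacteria + eukaryotes
trans_kingdom_flag(spread, "XTCD")    # FALSE — eukaryotes only
```

About 76% of mechanism-residue cells are identical or conservatively
substituted (the generator plants the plectasin template at fidelity 0.9
in GXGCP peptides and non-conservative Y25/Y40 substitutions in XTCD
peptides); GXGCP is flagged trans-kingdom because it occurs under two or
more depth-1 clades of the lineage table.

See `vignettes/csab-methods.Rmd` for the full model description,
parameter meanings and limitations.

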