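---
title: "Methods and design notes for rnasa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for rnasa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnasa)
```

# The model

`rnasa` treats per-nucleotide solvent accessibility as a regression
problem: the target is the residue's accessible surface area (ASA, Å²)
divided by 400 Å², and the input is a window of per-position 4-vectors
around the residue. The regressor is an epsilon-SVR with RBF kernel — a
kernel method that tolerates the high feature dimension (4×(2w+1), 324 at
the default w = 40) on training sets of tens of thousands of positions,
and whose epsilon-insensitive loss ignores target noise below the tube
width.

The central assumptions are (i) that local sequence context carries
information about burial — true because paired, stacked and
protein-contacted regions have sequence signatures — and (ii) that
chains, not positions, are the exchangeable units: adjacent positions on
one chain are strongly dependent, so all accuracy estimates here use
chain-level cross-validation in which every position of a chain shares a
fold.

# Ground-truth ASA

Per-atom ASA uses the Shrake–Rupley construction: points quasi-uniformly
distributed on each atom's probe-expanded sphere (van der Waals radius
plus probe radius), with a point counted as accessible when it lies
outside every neighbour's expanded sphere. Design choices:

* **Quadrature points.** A deterministic Fibonacci lattice, default 960
  points per atom, so results are reproducible without a random seed.
  Doubling the point count moves well-exposed atom areas by well under
  1%; almost-fully-buried atoms have tiny areas whose *relative* error is
  intrinsically larger, which is why convergence is best summarised
  relative to the full sphere area.
* **Probe radius.** Default 0.75 Å, reading a probe *diameter* of 1.5 Å
  literally. Because the conventional water probe is instead a 1.4 Å
  *radius*, the knob is exposed (`asa_config(probe_radius = 1.4)`); all
  downstream machinery is agnostic to the choice.
* **Radii.** A Bondi-style element-keyed table (C 1.70, N 1.55, O 1.52,
  P 1.80, S 1.80 Å), overridable via `vdw_radii()`. Hydrogens are ignored:
  crystal structures at the resolutions used for training rarely resolve
  them, and heavy-atom ASA is standard practice.
* **Scope of the sum.** Residue ASA sums over *all* heavy atoms of the
  nucleotide (sugar + phosphate + base). A base-only variant would need
  only a different atom subset upstream of `aggregate_residue_asa()`.
* **Normalization.** Division by 400 Å² — of the order of the largest
  accessible area of any base — gives a target of magnitude ~1 for the
  SVR. Ground-truth values above 400 Å² normalize above 1 and are *not*
  clipped, preserving invertibility; only predictions are clipped (below).

The completeness filter keeps residue *i* only when residues *i−1*, *i*,
*i+1* all carry their full expected heavy-atom inventory; a missing atom
would understate the local area and bias the regression target. At chain
termini, validity requires completeness of the residue and of whichever
neighbour exists — the rule's purpose is an accurate local ASA, which a
terminal residue satisfies with its single neighbour.

# Alignment profiles

In *prof* mode the per-position vector is
$P_{i,j} = -\log\big(N_{i,j} / \sum_j N_{i,j}\big)$ over the per-column
base counts $N_{i,j}$ of a multiple alignment (query row included, so the
query base never has a zero count). Pseudocounts of 9.0 (query base) and
0.3 (others) are added first; they encode a strong prior toward the
observed base while keeping all frequencies nonzero. Numerical choices:

* **Log base.** Natural log. Any base is an affine rescaling that the
  subsequent (−1, 1) normalization absorbs, so the choice is
  observationally neutral downstream.
* **(−1, 1) mapping.** A global min–max affine map whose bounds are taken
  over the training profiles, stored in the model archive, and *clamped*
  at prediction time — out-of-range test values saturate at ±1 rather
  than extrapolating.
* **Gaps and ambiguity codes.** Gap characters contribute to no base;
  IUPAC codes contribute fractional counts split equally among their
  compatible bases; T maps to U on input.
* **Columns where the query has a gap** are dropped, keeping positions in
  query coordinates.

Homology search itself is out of scope: the module consumes an aligned
FASTA or a pre-tabulated counts TSV produced by external search tools.

# Encoding, training and evaluation

The window encoder concatenates per-position vectors over positions
$i-w \dots i+w$, substituting the fixed pad vector (−1,−1,−1,−1) outside
the sequence; bases outside A/C/G/U reuse the same vector, keeping the
feature alphabet closed. The encoder is alphabet-generic, so a 20-letter
alphabet at w = 8 (the typical protein setting, 340 features) is directly
expressible.

SVR defaults: epsilon 0.1; grid search over C ∈ 2^{−3…7}, γ ∈ 2^{−9…1}
(log-2 spaced), selected by pooled cross-validated Pearson r with ties
broken toward smaller C then smaller γ (preferring the less complex
model). Predictions are clipped to [0, 1.25] normalized — 0 to 500 Å² —
allowing modest overshoot past the normalization constant instead of
censoring genuinely large areas. A model archive stores the fitted
regressor, configuration, encoder mode and profile bounds; reloading
reproduces predictions bit-identically because R serialization
round-trips doubles exactly. When every training point falls inside the
epsilon tube the SVR has no support vectors and its decision function is
the constant intercept; prediction handles this degenerate case
explicitly.

The headline metric is the *pooled* Pearson r over all held-out
positions, matching how predicted-vs-actual density plots are read;
per-chain and per-base correlations are also reported (sample SD, n−1,
for per-base summaries).

# Downstream analyses

* **DMS normalization** proceeds strictly in order: per-condition
  division by the per-mRNA maximum read; fragment means over consecutive
  non-overlapping 50-base fragments (a trailing partial fragment is
  dropped, reading "non-overlapping 50-base fragments" strictly);
  fragments with a zero denatured or compared mean removed ("null
  counts" interpreted as an exactly-zero fragment mean); finally the
  compare/denature ratio. The ratio cancels position-dependent bias
  shared across conditions. An input filter keeps mRNAs with at least
  4000 reacted bases (configurable).
* **MAF binning** stably sorts SNVs by predicted ASA and splits them into
  100 near-equal bins, the first `n mod 100` bins taking one extra
  record; the association statistic is the Pearson r between bin-mean
  predicted ASA and bin-mean log10(MAF). Averaging log(MAF) (not logging
  the average) is the implemented reading; base 10 only rescales the
  averaged axis and cannot change r. Strata smaller than the bin count
  are skipped with a warning, never merged.
* **Boundary profiles** average predicted ASA at offsets −50…+49 around
  each region boundary (offset 0 = first base after the boundary line)
  over transcripts whose 5′UTR, CDS, intron and 3′UTR totals all reach
  100 bases.

# What the synthetic fixtures emulate

Every input class has a seeded generator that writes the same shapes the
real adapters read, so tests exercise the true I/O and modelling paths:

* `make_synthetic_chain()` — helical coordinate sets with reduced 8-atom
  residue inventories and a 1.5 Å steric floor; enough to exercise
  quadrature, aggregation and the completeness filter, with no attempt at
  real RNA geometry (no base pairing, no realistic helix parameters).
* `make_asa_regression_set()` — targets are a fixed random linear map of
  the one-hot window of half-width h = 3 plus Gaussian noise (signal SD
  0.18, noise SD 0.08 around 0.5, clipped to [0, 1]), so an encoder
  window covering h can recover the signal. Sixty chains of 50–70 bases
  mimic the scale of a curated training set while keeping a five-fold CV
  run in seconds.
* `make_conservation_set()` — targets combine a base-identity effect with
  a buriedness effect, and homolog alignments mutate only at exposed
  positions; profile encoding can read the conservation signal that
  one-hot encoding cannot, giving the expected prof ≥ seq ordering.
* `make_snv_table()` — MAF = 10^(−3 + 2.5·ASA) times lognormal noise: the
  link is affine on the log10 scale, so with zero noise the bin means
  are exactly collinear (r = 1) — the clean positive control for the
  binning machinery.
* `make_dms_tracks()` — Poisson read counts sharing a positional bias
  across conditions, with a planted exposure term in the in-vivo
  condition only; default length 5000 bases, the scale of an mRNA
  passing the reacted-base filter.

Passing these tests shows the machinery recovers structure it was built
to recover under known generative models. It does **not** show that real
RNA accessibility is predictable to the same degree: real chains have
long-range tertiary contacts, alignment depth varies by orders of
magnitude, DMS reactivity saturates and is base-selective, and variant
frequencies reflect selection and demography far beyond accessibility.
Accuracy on real data must be established on curated structure sets.

# Problem sizes and runtime choices

The shipped tests and the acceptance script run five-fold CV on 60
chains (~3,700 positions, 84 features at w = 10) — a scale chosen so a
full suite executes in well under a minute on one CPU while still
leaving each fold ~48 training chains. The grid-search test uses a
deliberately pathological γ contrast (0.05 vs 50) on 15 chains to verify
that chain-level CV, not training fit, drives selection. The permutation
null for the MAF binning uses 1000 shuffles of 200 SNVs.

# Known limitations

* The quadrature is O(atoms² · points) in pure R; for whole-ribosome
  structures a spatial grid or compiled kernel would be the next step.
* Profile quality is inherited from the upstream alignment; the package
  neither searches nor filters homologs.
* The SVR is retrained from scratch for every grid point; there is no
  warm-starting or caching across the grid.
* mmCIF support relies on the `bio3d` reader and inherits its
  field-mapping quirks for exotic entries.
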