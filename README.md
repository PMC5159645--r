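# rnasa

Sequence-based prediction of RNA solvent accessibility, with the
structure-derived ground truth it is trained on and the genome-scale
analyses it feeds.

## The problem

Most RNAs never get a solved 3D structure, yet the solvent-accessible
surface area (ASA) of each nucleotide — how much of it a solvent probe can
touch — separates exposed, potentially functional sites from buried core
regions. `rnasa` predicts per-nucleotide ASA from sequence alone, or from an
evolutionary profile built from a multiple sequence alignment, using
windowed support-vector regression; it also computes the ground-truth ASA
from RNA 3D coordinates so models can be trained and evaluated end to end.
It is aimed at structural bioinformaticians who want per-base accessibility
estimates for RNAs without structures, and at anyone relating accessibility
to chemical-probing reactivity, variant frequencies, or transcript
architecture.

## The method

**Ground truth.** Per-atom ASA is computed by Shrake–Rupley numerical
quadrature: a deterministic Fibonacci lattice of points is placed on each
atom's probe-expanded sphere (vdW radius + probe radius, default probe
radius 0.75 Å) and points buried inside any neighbour's expanded sphere are
discounted. Residue ASA is the sum over its atoms, normalized by 400 Å² to
a dimensionless target. A completeness filter keeps only residues whose own
atom inventory and those of their two sequence neighbours are complete, so
missing atoms cannot bias the target.

**Features.** Each position is a 4-vector in fixed A,C,G,U order — one-hot
(+1 query base, −1 otherwise) in *seq* mode, or a normalized
−log-frequency alignment profile in *prof* mode:

P<sub>i,j</sub> = −log( N<sub>i,j</sub> / Σ<sub>j</sub> N<sub>i,j</sub> ),

with pseudocounts of 9.0 on the query base and 0.3 on the others, min–max
mapped to (−1, 1) with the training bounds persisted in the model. The
feature row for a position concatenates the 4-vectors across a symmetric
window of half-width *w* (default 40 → 4×(2·40+1) = 324 features), padding
(−1,−1,−1,−1) past the sequence ends.

**Model.** An epsilon-SVR with RBF kernel maps feature rows to normalized
ASA. Hyperparameters (C, γ) are chosen by grid search under chain-level
k-fold cross-validation: all positions of a chain share a fold, so no
within-chain leakage inflates the held-out pooled Pearson r.

**Downstream.** Utilities normalize DMS-seq reactivities against a
denatured control over non-overlapping 50-base fragments, correlate binned
mean predicted ASA with mean log10 minor allele frequency across 100
SNV bins, and average predicted ASA in ±50-base windows around transcript
region boundaries (5′UTR|CDS, CDS|intron, intron|CDS, CDS|3′UTR).

## Worked example

```r
library(rnasa)

# ground truth from coordinates
ch  <- make_synthetic_chain(seed = 1, n_residues = 8)
res <- chain_asa(ch$atoms, expected = ch$inventory)
print(res, n = 4)
#> # A tibble: 8 × 5
#>   residue_index base    asa asa_norm valid
#>           <int> <chr> <dbl>    <dbl> <lgl>
#> 1             0 A      192.    0.481 TRUE
#> 2             1 U      150.    0.376 TRUE
#> 3             2 G      150.    0.375 TRUE
#> 4             3 A      155.    0.388 TRUE

# cross-validated prediction on a fixture with a planted window-local signal
set <- make_asa_regression_set(seed = 7)
rf  <- regression_features(set, w = 10)
cv  <- cross_validate(rf$features, rf$targets, rf$chain,
                      k = 5, seed = 11, cfg = svr_config(C = 4, w = 10))
cv
#> <rnasa_cv> 5-fold chain-level cross-validation (seed 11)
#>   positions: 3678  chains: 60
#>   pooled Pearson r: 0.896
glance(cv)
#> # A tibble: 1 × 5
#>       k n_chains n_positions     r mean_chain_r
#> 1     5       60        3678 0.896        0.902
```

The first block computes each residue's area in Å² (`asa`), its normalized
value (`asa_norm = asa / 400`), and whether it passes the completeness
filter. The second generates 60 synthetic chains whose targets depend on a
local sequence window, encodes them, and shows that a model never trained
on a chain still predicts its positions with pooled r ≈ 0.9 — the
chain-level generalization the method is designed to measure.
`autoplot(cv)` renders the predicted-vs-actual density plot, and
`tidy(cv)` gives per-chain correlations.

A thin command-line front end wrapping the same functions ships at
`inst/cli/rnasa` (subcommands `asa`, `profile`, `encode`, `train`,
`predict`, `eval`, `dms-norm`, `maf-bin`, `boundary-profile`, `fixtures`).

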