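---
title: "Methods: uncertainty-guided discovery of activation domains with adscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uncertainty-guided discovery of activation domains with adscout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(adscout)
```

# Scope and model

Activation domains (ADs) are intrinsically disordered regions of
transcription factors that recruit transcriptional machinery and promote
gene expression. Because ADs are poorly conserved, their discovery relies on
massively parallel reporter assays: proteins are sliced into fixed-length
tiles (53 amino acids, 10-residue stride), each tile is fused to a synthetic
transcription factor, and its activity is read out as a GFP:mCherry
fluorescence ratio via cell sorting and barcode sequencing. adscout
implements the full computational loop around such an assay: a
sequence-to-activity regressor with epistemic uncertainty, an acquisition
function for choosing which tiles to measure next, the sort-seq scoring
computation, and harmonization of activity scales across experiments.

The regressor is a one-dimensional residual convolutional network over
encoded tiles: a convolutional stem (kernel 5, default 64 channels), a stack
of residual blocks (each two convolutions with batch normalization and ReLU
and an identity skip; default 3 blocks, kernel 3), global average pooling
over positions, and one dense output. Activities are z-scored with the
training split's statistics; the network minimizes mean squared error with
Adam (default learning rate 1e-3, batch 64) and stops early when validation
loss fails to improve for 5 epochs, keeping the best-validation weights.
Splits are 80/10/10 after sequence deduplication, stratified on the
activity binarized at its median so each split carries the global
above-median fraction to within one count.

The published topology specifies the layer types but not their sizes; the
defaults above are this package's choices and every size is
config-overridable via `regressor_spec()`. The training engine itself is
authored in vectorized R (im2col gathers plus BLAS matrix products); its
backward pass is verified against numerical differentiation in the test
suite, which is the contract that matters for a hand-built engine.

Epistemic uncertainty comes from a deep ensemble: members share one
train/validation split and differ only in the seed driving initialization
and minibatch shuffling — standard deep-ensemble practice; no bootstrap
resampling is used because the assay-scale reference for this design reports
none. The prediction is the member mean and the uncertainty is the
population (ddof = 0) standard deviation of member predictions, both on the
de-normalized activity scale. Twenty members reproduce the study-scale
configuration; the examples and tests here use 3–5 members, which already
stabilizes the mean and gives usable uncertainty at desk scale.

# Encodings

One-hot over the fixed alphabet `ACDEFGHIKLMNPQRSTVWY` is the default and
the encoding used by every test. Protein-language-model embeddings are
supported through a provider contract — any function
`provider(sequence, layer)` returning a positions-by-D matrix — with a cache
keyed by sequence hash, provider name and layer so provider upgrades cannot
silently mix representations. No language model is bundled: the package
stays desk-scale and the provider is an injection point. Composition
descriptors use net charge `K + R − D − E` (histidine excluded, as its
protonation state is ambiguous at assay pH) and the non-polar set
`A V L I M F W P G`; both sets are arguments, since conventions differ
across the literature.

# Acquisition

`quantile_balanced_sample()` implements quantile-balanced uncertainty
sampling: candidates are assigned to equal-frequency bins of predicted
activity (rank-based, so bins differ in size by at most one; ties broken by
tile id), and each bin contributes its top-uncertainty candidates up to
quota `ceil(batch/bins)`. Overshoot from the ceiling is trimmed by dropping
the globally lowest-uncertainty selections; shortfall from sparse bins is
refilled by global uncertainty rank. Every bin's final selection is a
prefix of its uncertainty ranking, which yields a local-optimality
guarantee: no within-bin swap can increase total selected uncertainty, and
on small instances the selection matches exhaustive search. The default of
10 bins is a package choice (the bin count of the study-scale selection is
not published). The same engine selects harmonization tiles (smallest
|empirical − predicted| per bin of empirical activity) and control tiles
(highest uncertainty per bin of empirical activity).

# Sort-seq scoring

Reads are parsed against the assay cassette's conserved flanks; only reads
whose tile region perfectly matches a library sequence are kept
(rejections are categorized as no-flank, no-match, bad-length or
non-ACGT). Counts per (tile, barcode) across the 8 sorted bins are
normalized by each bin's total reads, renormalized to a relative abundance,
and the activity is the inner product with the bins' median fluorescence
values — a weighted average, hence always inside the bin-median range and
invariant to uniform sequencing-depth changes of any single bin. Rows with
fewer than 50 raw reads are discarded. The published filter names "tiles";
this package applies it per (tile, barcode) row because filtering is part
of the per-barcode scoring flow, and a tile's score is then the unweighted
mean of its surviving barcodes. Barcodes observed for more than one tile
are dropped with a warning, since collisions cannot be attributed. Bin
median fluorescence values are required inputs; they are not published, so
the simulator generates them from its cell population.

# Harmonization

Sorters saturate at both ends of the reporter range, so two experiments are
comparable only inside a linear range. The window is chosen by maximizing
the Pearson correlation of harmonization-tile pairs retained inside
candidate windows, over a 5%-step grid of quantile-probability pairs,
subject to retaining at least half the pairs; control-tile pairs only
validate the chosen window and never drive the argmax. A window's
thresholds are applied on both activity scales at the same probabilities,
and interior thresholds are exclusive: saturated measurements pile up
exactly at the dynamic-range limits, so a boundary value is treated as
outside the range — this is what actually removes pegged points, and on
continuous data the strictness is a measure-zero distinction. Ties in
correlation break toward the window retaining more pairs, then the wider
quantile span. The affine map is ordinary least squares of reference on new
activity; residual noise is modeled as Gaussian (`sigma` = residual
standard deviation) and injected only on request (`inject_noise = TRUE`),
because mapping deterministically and matching distributions by noise
injection are both defensible readings of the procedure; the deterministic
map is the default.

# Active-learning round

`run_round()` predicts the design space, acquires a quantile-balanced
maximum-uncertainty batch, obtains labels (from a labeler function — here
the synthetic oracle; in practice a wet-lab result table), optionally
applies a harmonization map to the new labels, and retrains the ensemble
*from scratch* on the merged dataset (matching the study-scale procedure of
retraining on the harmonized dataset rather than fine-tuning). The
evaluation set is fixed before the round and can never be acquired, which
prevents leakage. Out-of-distribution inference can also be rehearsed with
`spectral_ood_split()`: tiles are mean-pooled, an RBF affinity with
bandwidth equal to the median pairwise distance (unspecified in the source
material; a standard heuristic) feeds normalized-Laplacian spectral
clustering, and one cluster is held out.

# The synthetic oracle and simulator

Every stage is testable without experimental data because the `synthetic`
module provides a known ground truth. The oracle is shaped like the acidic
exposure model of AD function: hydrophobic/aromatic residues (W 2.0, F 1.8,
L 1.2, M 1.2, Y 1.0) contribute only when an acidic residue (D/E) lies
within 3 positions — acidic context keeps them solvent-exposed — basic
residues (K/R) subtract 0.5 each, and the clamped total saturates as
`10·r/(8 + r)`, plus optional Gaussian label noise (sd 0.2). *All of these
constants are simulator inventions chosen to produce a plausible activity
distribution; none are experimental measurements.* The library generator
mixes four composition regimes — uniform background, acidic-AD-like,
non-acidic Leu/Phe-rich activators, and basic inactives — mirroring the
composition contrast between model-yeast datasets and tiles acquired from
non-model genomes; regime labels are kept so out-of-distribution
experiments are well-defined.

The sort-seq simulator draws cell fluorescence as `Normal(activity,
cell_sd)`, sets bin boundaries at the population deciles 10%–90% (8 bins of
10% each; cells outside the central 80% are unsampled, as in the assay
design), takes within-bin population medians as the bin fluorescence
values, draws a Poisson(12) number of barcodes per tile (median 12, the
study-scale barcode multiplicity) and multinomial reads per barcode over
its cells' bin occupancy. Nucleotide-level reads use a fixed
one-codon-per-residue reverse translation and the cassette's conserved
flank sequences, so the perfect-match extraction filter can be tested with
exact expectations. What the simulator does not emulate: PCR amplification
bias, barcode sequencing errors, instrument drift, and aleatoric structure
beyond i.i.d. Gaussian cell noise — so passing tests demonstrate the
correctness of the computations, not robustness to every artifact of real
sequencing data.

# Attribution

`attribute_positions()` estimates additive per-position contributions by
sampled Shapley values: for each evaluated tile, random position
permutations are walked from a background tile to the tile of interest and
the output differences are attributed to the switched position, with
antithetic (reversed) permutations for variance reduction. The binding
contract is completeness — per tile, attributions sum exactly to the
prediction minus the mean background prediction, and for a linear model one
permutation is already exact — rather than any particular explainer
implementation. Attributions are computed per ensemble member with shared
permutations and averaged, then aggregated by (residue, position). On
ensembles trained against the oracle, K/R attributions are negative and
W/F positive, reproducing the acidic-exposure pattern at desk scale.

# Numerical choices and problem sizes

* Greedy identity clustering is a test-scale stand-in for CD-HIT semantics:
  identity is exact matches in a global alignment divided by the shorter
  length, sequences are processed longest-first with lexicographic-id
  tie-breaks, and a sequence joins the first representative at or above the
  threshold. Trailing residues not covered by a full window are dropped and
  proteins shorter than the window yield no tiles (the source material is
  silent on both; no end-anchored tile is added so every tile obeys
  `start % stride == 0`). Non-canonical residues skip the protein by
  default, or are masked to all-zero rows on request.
* Early stopping compares validation MSE with a 1e-12 improvement margin;
  the best checkpoint, not the last, is kept. Batch-norm running statistics
  use momentum 0.1 and epsilon 1e-5.
* The test and acceptance runs use 16–32 channels, 1–2 residual blocks,
  8–30 epochs, and 400–3,000 labeled tiles; the active-learning experiment
  uses a 2,000-tile design pool in which the withheld Leu/Phe regime is a
  7.5% minority (a design space in which the informative class is rare, as
  in a genome-scale tiling space), 5-member ensembles, a 500-tile batch and
  a 300-tile fixed out-of-distribution evaluation set. These sizes are the
  package's desk-scale study conditions.
* Reproducibility: every stochastic step (splits, initialization,
  shuffling, simulators, permutations) is driven by an explicit seed, and
  seeded RNG use is wrapped so library calls never perturb the caller's RNG
  stream.

# Known limitations

The greedy clusterer is quadratic and meant for test-scale inputs, not
millions of proteins. The regressor engine is CPU-bound R; at study scale
(tens of millions of tiles, language-model encodings) one would swap the
provider and a GPU backend behind the same module surfaces. Multi-round
active learning is supported but only benchmarked on synthetic data, since
the reference workflow performs a single acquisition round. Harmonization
fits ordinary least squares, which attributes all noise to the reference
axis; errors-in-variables alternatives are out of scope.
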