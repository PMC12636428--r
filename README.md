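# adscout

Active learning for discovering and quantifying transcriptional activation
domains (ADs).

ADs are intrinsically disordered regions of transcription factors that
recruit transcriptional machinery to drive gene expression. They are poorly
conserved, so comparative genomics fails on them; instead they are mapped
with massively parallel reporter assays in which proteins are sliced into
53-amino-acid tiles (10-residue stride), each tile activates a GFP reporter,
and activity is quantified as a GFP:mCherry ratio by sorting cells into
fluorescence bins and sequencing DNA barcodes. adscout is for computational
biologists running or modeling such screens: it provides the regression
model, the uncertainty-guided experiment-selection loop, and the assay
quantification pipeline, together with a synthetic ground truth so the
whole framework runs and is tested without any experimental data.

## What is in the package

* **Design space** — FASTA loading, exact deduplication, greedy
  90%-identity clustering (CD-HIT-like semantics at test scale), and tiling:
  `read_protein_fasta()`, `deduplicate_and_represent()`, `slice_tiles()`.
* **Regressor** — a residual convolutional network over one-hot (or
  pluggable protein-language-model) encodings, trained on z-scored
  activities with Adam, MSE loss and patience-5 early stopping:
  `fit_regressor()`, `predict_activity()`. For labeled tiles
  \eqn{(x_i, y_i)}, members minimize
  `mean((f(x_i) - z(y_i))^2)` with `z(y) = (y - mean_train) / sd_train`.
* **Deep ensemble** — mean prediction and epistemic uncertainty as the
  population standard deviation across seed-diversified members:
  `fit_ensemble()`, `predict_with_uncertainty()`.
* **Acquisition** — quantile-balanced uncertainty sampling: top-uncertainty
  picks within equal-frequency bins of predicted activity, plus the
  harmonization-tile and control-tile selectors: `quantile_balanced_sample()`,
  `select_harmonization_tiles()`, `select_control_tiles()`.
* **Sort-seq scoring** — perfect-match read extraction against the assay
  cassette flanks, bin normalization, and the inner product of relative
  abundance with bin median fluorescence (rows under 50 reads discarded;
  tile score = mean over barcodes): `extract_tile_barcodes()`,
  `score_barcodes()`, `aggregate_tile_activity()`.
* **Harmonization** — linear-range estimation by Pearson maximization over
  quantile windows (validated on control tiles) and an OLS affine map with
  Gaussian residual model: `estimate_linear_range()`, `fit_affine_map()`,
  `apply_map()`.
* **Active learning** — one full acquire/label/harmonize/retrain round:
  `run_round()`.
* **Synthetic oracle** — a library generator with four composition regimes,
  an acidic-exposure-style activity law, and a sort-seq read-count
  simulator: `sample_library()`, `oracle_activity()`,
  `simulate_sortseq_counts()`.
* **Attribution** — sampled-Shapley per-position contributions with an
  exact completeness guarantee: `attribute_positions()`.

A thin command-line wrapper is installed at `exec/adscout`
(`tile`, `score`, `acquire`, `harmonize`, `harmonize-apply`, `simulate`).

## Worked example

Train a small ensemble on oracle-labeled synthetic tiles, score its
uncertainty on an unseen composition regime, and run one active-learning
round:

```r
library(adscout)

dat <- sample_library(400, mix = c(background = 0.5, acidic = 0.3,
                                   leuphe = 0, basic = 0.2), seed = 901)
dat$activity <- oracle_activity(dat$sequence, noise = TRUE, seed = 911)

ens <- fit_ensemble(dat, n_members = 5,
                    spec = regressor_spec(stem_channels = 16, n_blocks = 1),
                    config = training_config(learning_rate = 2e-3,
                                             max_epochs = 12),
                    base_seed = 930)

pool <- sample_library(2000, mix = c(background = 0.625, acidic = 0.15,
                                     leuphe = 0.075, basic = 0.15),
                       seed = 931, prefix = "pool")
oodtest <- sample_library(300, mix = c(background = 0, acidic = 0,
                                       leuphe = 1, basic = 0),
                          seed = 941, prefix = "ood")
oodtest$activity <- oracle_activity(oodtest$sequence)

labeler <- function(tiles) {
  data.frame(tile_id = tiles$tile_id,
             activity = oracle_activity(tiles$sequence, noise = TRUE,
                                        seed = 951))
}
out <- run_round(ens, pool, labeler, batch_size = 500, eval_set = oodtest)
cat(sprintf("pre : n = %d | RMSE = %.4f | Pearson r = %.4f\n",
            out$report$metrics_pre$n, out$report$metrics_pre$rmse,
            out$report$metrics_pre$pearson_r))
#> pre : n = 300 | RMSE = 1.9577 | Pearson r = 0.4430
cat(sprintf("post: n = %d | RMSE = %.4f | Pearson r = %.4f\n",
            out$report$metrics_post$n, out$report$metrics_post$rmse,
            out$report$metrics_post$pearson_r))
#> post: n = 300 | RMSE = 1.6047 | Pearson r = 0.6374
```

The pre-round model, trained without any Leu/Phe-rich activator (an
out-of-distribution regime under the oracle's acidic-exposure-style law),
mispredicts that regime; after one quantile-balanced maximum-uncertainty
batch of 500 tiles is labeled and the ensemble retrained, out-of-
distribution RMSE drops and the correlation rises. The batch preferentially
captures the rare informative regime: in this run 105 of the pool's 151
Leu/Phe tiles are acquired, versus ~38 expected under random sampling.

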