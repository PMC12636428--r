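test_that("stratified split is disjoint, exhaustive and balanced within one count", {
  dat <- labeled_library(1000, seed = 31)
  sp <- stratified_split(dat, seed = 17)
  idx <- c(sp$train, sp$validation, sp$test)
  expect_equal(sort(idx), seq_len(nrow(sp$data)))
  expect_equal(anyDuplicated(idx), 0L)
  above <- sp$data$activity > median(sp$data$activity)
  for (part in list(sp$train, sp$validation, sp$test)) {
    expect_lte(abs(mean(above[part]) - mean(above)), 1 / length(part))
  }
  expect_equal(length(sp$validation), round(0.1 * nrow(sp$data)), tolerance = 2)
})

test_that("splits are deterministic given the seed and deduplicate sequences", {
  dat <- labeled_library(200, seed = 32)
  expect_identical(stratified_split(dat, seed = 4)[c("train", "validation", "test")],
                   stratified_split(dat, seed = 4)[c("train", "validation", "test")])
  dup <- rbind(dat, dat[1:50, ])
  sp <- stratified_split(dup, seed = 4)
  expect_equal(nrow(sp$data), 200L)
  expect_error(stratified_split(dat[1:5, ], seed = 1), ">= 10")
})

test_that("evaluation metrics match hand computations", {
  m <- evaluate_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$rmse, 0)
  expect_equal(m$pearson_r, 1)
  expect_equal(m$spearman_rho, 1)

  m <- evaluate_metrics(c(-1, 0, 1), c(1, 0, -1))
  expect_equal(m$pearson_r, -1)

  m <- evaluate_metrics(c(1.5, 1.5, 3.5, 3.5), c(1, 2, 3, 4))
  expect_equal(m$rmse, 0.5)
  expect_equal(m$pearson_r, 1 / sqrt(1.25), tolerance = 1e-12)

  m <- evaluate_metrics(c(1, NA, 2, 3), c(1, 1, NA, 3))
  expect_equal(m$n, 2L)
  expect_error(evaluate_metrics(1, 1), "length|pairs")
})

test_that("constant labels raise the zero-variance error", {
  lib <- sample_library(40, seed = 33)
  enc <- encode_tiles(lib)
  expect_error(
    fit_regressor(enc, rep(1, 40), spec = small_spec(),
                  config = small_config()),
    "zero variance")
})

test_that("early stopping halts patience epochs after the best validation loss", {
  dat <- labeled_library(200, seed = 34)
  enc <- encode_tiles(dat)
  cfg <- small_config(seed = 2, max_epochs = 60L)
  fit <- fit_regressor(enc, dat$activity, spec = small_spec(), config = cfg)
  h <- fit$history
  if (nrow(h) < cfg$max_epochs) {
    expect_equal(nrow(h), fit$best_epoch + cfg$patience)
    expect_true(all(h$val_loss[(fit$best_epoch + 1):nrow(h)] >=
                      min(h$val_loss) - 1e-12))
  }
  expect_equal(min(h$val_loss), h$val_loss[fit$best_epoch])
})

test_that("a noise-free linear composition target is recovered (r >= 0.95)", {
  lib <- sample_library(800, seed = 35)
  w <- seq(-1, 1, length.out = 20)
  counts <- t(vapply(lib$sequence, function(s)
    composition_profile(s)$residue_fractions, numeric(20)))
  lib$activity <- as.vector(counts %*% w) * 10
  sp <- stratified_split(lib, seed = 5)
  enc <- encode_tiles(sp$data)
  fit <- fit_regressor(enc, sp$data$activity, split = sp, spec = small_spec(),
                       config = small_config(seed = 6, max_epochs = 25L))
  pred <- predict_activity(fit, enc)
  m <- evaluate_metrics(pred[sp$test], sp$data$activity[sp$test])
  expect_gte(m$pearson_r, 0.95)
  # trained model beats the mean-predictor baseline on validation data
  base_mse <- mean((mean(sp$data$activity[sp$train]) -
                      sp$data$activity[sp$validation])^2)
  expect_lt(min(fit$history$val_loss) * fit$norm$sd^2, base_mse)
})

test_that("training is reproducible for a fixed seed and predictions are deterministic", {
  dat <- labeled_library(150, seed = 36)
  enc <- encode_tiles(dat)
  cfg <- small_config(seed = 9, max_epochs = 4L)
  f1 <- fit_regressor(enc, dat$activity, spec = small_spec(), config = cfg)
  f2 <- fit_regressor(enc, dat$activity, spec = small_spec(), config = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(predict_activity(f1, enc), predict_activity(f2, enc))
})

test_that("z-scoring round-trips through prediction scale", {
  dat <- labeled_library(150, seed = 37)
  enc <- encode_tiles(dat)
  fit <- fit_regressor(enc, dat$activity, spec = small_spec(),
                       config = small_config(seed = 3, max_epochs = 3L))
  z <- (dat$activity - fit$norm$mean) / fit$norm$sd
  expect_equal(fit$norm$mean + fit$norm$sd * z, dat$activity, tolerance = 1e-9)
  expect_error(predict_activity(fit, list(x = array(0, c(1, 53, 5)))),
               "channels")
})

test_that("spectral clustering recovers well-separated composition regimes", {
  lib <- rbind(sample_library(60, mix = c(background = 0, acidic = 1,
                                          leuphe = 0, basic = 0), seed = 38,
                              prefix = "a"),
               sample_library(60, mix = c(background = 0, acidic = 0,
                                          leuphe = 0, basic = 1), seed = 39,
                              prefix = "b"))
  enc <- encode_tiles(lib)
  sp <- spectral_ood_split(enc, n_clusters = 2L)
  ari <- mclust::adjustedRandIndex(sp$assignments[lib$tile_id],
                                   lib$regime)
  expect_gte(ari, 0.9)
  expect_equal(sort(c(sp$train_ids, sp$test_ids)), sort(lib$tile_id))
})

test_that("spectral split handles singletons and is permutation-invariant", {
  lib <- sample_library(12, seed = 40)
  enc <- encode_tiles(lib)
  sp_all <- spectral_ood_split(enc, n_clusters = 12L)
  expect_equal(length(sp_all$test_ids), 1L)

  perm <- sample(nrow(lib))
  enc_p <- encode_tiles(lib[perm, ])
  sp1 <- spectral_ood_split(enc, n_clusters = 3L)
  sp2 <- spectral_ood_split(enc_p, n_clusters = 3L)
  tab <- table(sp1$assignments[lib$tile_id], sp2$assignments[lib$tile_id])
  expect_equal(sum(apply(tab, 1, max)), nrow(lib))  # identical up to relabeling
})

test_that("degenerate similarity matrices are rejected with diagnostics", {
  lib <- sample_library(10, seed = 41)
  lib$sequence <- rep(lib$sequence[1], 10)
  enc <- encode_tiles(lib)
  expect_error(spectral_ood_split(enc, 2L), "degenerate")
})
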