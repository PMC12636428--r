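# regressor: residual convolutional activity regressor.

#' Regressor architecture specification
#'
#' Topology: a convolutional stem, `n_blocks` residual blocks (each two
#' convolutions with batch normalization and ReLU, identity skip), global
#' average pooling over positions, and a single dense output. Block channels
#' equal stem channels so the identity skip needs no projection.
#'
#' @param stem_channels Channels after the stem convolution.
#' @param stem_kernel Stem kernel width (odd).
#' @param n_blocks Number of residual blocks.
#' @param block_kernel Kernel width inside blocks (odd).
#' @return List of class `regressor_spec`.
#' @export
regressor_spec <- function(stem_channels = 64L, stem_kernel = 5L,
                           n_blocks = 3L, block_kernel = 3L) {
  .assert(stem_channels >= 1 && n_blocks >= 0 &&
            stem_kernel %% 2 == 1 && block_kernel %% 2 == 1,
          "layer sizes must be positive; kernels odd")
  structure(list(stem_channels = as.integer(stem_channels),
                 stem_kernel = as.integer(stem_kernel),
                 n_blocks = as.integer(n_blocks),
                 block_kernel = as.integer(block_kernel)),
            class = "regressor_spec")
}

#' Training configuration
#'
#' Mean-squared-error loss on z-scored activities, optimized with Adam;
#' training stops early when validation loss has not improved for `patience`
#' epochs, and the best-validation weights are retained.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience in epochs (>= 1).
#' @param seed Seed controlling initialization and shuffling; recorded in
#'   the fitted model.
#' @return List of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-3, batch_size = 64L,
                            max_epochs = 200L, patience = 5L, seed = 1L) {
  .assert(patience >= 1, "patience must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "training_config")
}

#' Stratified train/validation/test split
#'
#' Removes duplicate sequences, binarizes activity at the median, and
#' allocates each stratum across the three splits so the above-median
#' fraction in every split matches the global fraction to within one count.
#' Deterministic given `seed`.
#'
#' @param tiles Labeled tile `data.frame` with `tile_id`, `sequence`,
#'   `activity` (>= 10 rows after deduplication).
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed Random seed.
#' @return List of class `tile_split` with integer index vectors `train`,
#'   `validation`, `test` into the deduplicated table, plus `data` (the
#'   deduplicated table) and `seed`.
#' @export
stratified_split <- function(tiles, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  .assert(abs(sum(fractions) - 1) < 1e-9 && length(fractions) == 3L,
          "fractions must be length 3 and sum to 1")
  tiles <- tiles[!duplicated(tiles$sequence), , drop = FALSE]
  rownames(tiles) <- NULL
  n <- nrow(tiles)
  .assert(n >= 10L, "need >= 10 labeled tiles to stratify (have %d)", n)
  above <- tiles$activity > stats::median(tiles$activity)
  idx <- .with_seed(seed, {
    parts <- list(train = integer(0), validation = integer(0),
                  test = integer(0))
    for (stratum in unique(above)) {
      rows <- sample(which(above == stratum))
      m <- length(rows)
      n_val <- round(fractions[2] * m)
      n_test <- round(fractions[3] * m)
      parts$validation <- c(parts$validation, rows[seq_len(n_val)])
      parts$test <- c(parts$test, rows[n_val + seq_len(n_test)])
      parts$train <- c(parts$train, rows[-seq_len(n_val + n_test)])
    }
    lapply(parts, sort)
  })
  .assert(all(lengths(idx) > 0), "a split is empty; provide more tiles")
  structure(c(idx, list(data = tiles, seed = as.integer(seed))),
            class = "tile_split")
}

#' Out-of-distribution split by spectral clustering
#'
#' Mean-pools each tile's encoding over positions, builds an RBF affinity
#' (bandwidth = median pairwise distance), and clusters the normalized
#' graph-Laplacian eigenvector embedding with k-means. All members of the
#' held-out cluster form the test set. Tiles are ordered canonically by
#' `tile_id` internally, so the partition is invariant to input permutation
#' (up to cluster relabeling).
#'
#' @param enc An `encoded_tiles` object (see [encode_tiles()]).
#' @param n_clusters Number of clusters (>= 2, <= number of tiles).
#' @param held_out_cluster Which cluster forms the test set (default: the
#'   smallest).
#' @return List with `assignments` (named integer vector by `tile_id`),
#'   `train_ids`, `test_ids`, `sizes`.
#' @export
spectral_ood_split <- function(enc, n_clusters, held_out_cluster = NULL) {
  n <- dim(enc$x)[1]
  .assert(n_clusters >= 2 && n_clusters <= n, "need 2 <= n_clusters <= n tiles")
  feat <- apply(enc$x, c(1, 3), mean)
  ord <- order(enc$tile_id)
  feat <- feat[ord, , drop = FALSE]
  ids <- enc$tile_id[ord]
  d <- as.matrix(stats::dist(feat))
  sigma <- stats::median(d[upper.tri(d)])
  .assert(is.finite(sigma) && sigma > 0,
          "degenerate similarity: median pairwise distance is %s", sigma)
  W <- exp(-d^2 / (2 * sigma^2)); diag(W) <- 0
  deg <- rowSums(W)
  .assert(all(deg > 0), "degenerate similarity: isolated tile(s)")
  Dh <- 1 / sqrt(deg)
  L <- diag(n) - (Dh %o% Dh) * W
  ev <- eigen(L, symmetric = TRUE)
  U <- ev$vectors[, n - seq_len(n_clusters) + 1L, drop = FALSE]
  rn <- sqrt(rowSums(U^2)); rn[rn == 0] <- 1
  U <- U / rn
  cl <- if (n_clusters == n) seq_len(n) else {
    .with_seed(571L, stats::kmeans(U, centers = n_clusters, nstart = 20L,
                                   iter.max = 100L)$cluster)
  }
  sizes <- tabulate(cl, n_clusters)
  if (is.null(held_out_cluster)) held_out_cluster <- which.min(sizes)
  structure(list(assignments = stats::setNames(cl, ids),
                 train_ids = ids[cl != held_out_cluster],
                 test_ids = ids[cl == held_out_cluster],
                 sizes = sizes, held_out_cluster = held_out_cluster),
            class = "ood_split")
}

#' Fit the residual convolutional regressor
#'
#' Activities are z-scored with the training split's mean and standard
#' deviation; the network minimizes MSE on the z scale with Adam, stopping
#' when validation loss fails to improve for `config$patience` epochs and
#' keeping the best-validation checkpoint. Per-epoch train/validation losses
#' are recorded in `history`.
#'
#' @param enc An `encoded_tiles` object covering all labeled tiles.
#' @param activity Numeric activities aligned with `enc$tile_id`.
#' @param split A [stratified_split()]-style list with `train` and
#'   `validation` index vectors into `enc`; if `NULL`, a fresh stratified
#'   split is drawn with `config$seed`.
#' @param spec A [regressor_spec()].
#' @param config A [training_config()].
#' @return Object of class `adscout_regressor` with fields `model` (weights,
#'   architecture, batch-norm state), `norm` (activity mean/sd), `history`,
#'   `spec`, `config`, `best_epoch`.
#' @export
fit_regressor <- function(enc, activity, split = NULL,
                          spec = regressor_spec(), config = training_config()) {
  .assert(length(activity) == dim(enc$x)[1], "activity/encoding length mismatch")
  .assert(all(is.finite(activity)), "labels must be finite")
  if (is.null(split)) {
    split <- .index_split(length(activity), activity, config$seed)
  }
  tr <- split$train; va <- split$validation
  mu <- mean(activity[tr]); sd_ <- stats::sd(activity[tr])
  .assert(is.finite(sd_) && sd_ > 0,
          "zero variance in training labels: z-score undefined")
  yz <- (activity - mu) / sd_

  P <- dim(enc$x)[2]; C <- dim(enc$x)[3]
  arch <- list(in_channels = C, channels = spec$stem_channels,
               stem_kernel = spec$stem_kernel, n_blocks = spec$n_blocks,
               block_kernel = spec$block_kernel)
  init <- .nn_init(arch, config$seed)
  model <- list(params = init$params, bn = init$bn, arch = arch)
  adam <- .adam_init(model$params)

  x_val <- enc$x[va, , , drop = FALSE]
  best <- list(loss = Inf, params = NULL, bn = NULL, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  no_improve <- 0L

  .with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      sh <- sample(tr)
      tl <- 0; nb <- 0L
      for (s in seq(1L, length(sh), by = config$batch_size)) {
        idx <- sh[s:min(length(sh), s + config$batch_size - 1L)]
        B <- length(idx)
        X <- matrix(enc$x[idx, , , drop = FALSE], B * P, C)
        fwd <- .nn_fwd(model, X, B, P, train = TRUE)
        model$bn <- fwd$bn
        loss <- mean((fwd$yhat - yz[idx])^2)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite training loss at epoch %d; try a lower learning rate",
                       epoch), call. = FALSE)
        }
        grads <- .nn_bwd(model, X, B, P, fwd, yz[idx])
        up <- .adam_step(model$params, grads, adam, config$learning_rate)
        model$params <- up$params; adam <- up$state
        tl <- tl + loss * B; nb <- nb + B
      }
      val_pred <- .nn_predict_z(model, x_val)
      val_loss <- mean((val_pred - yz[va])^2)
      if (!is.finite(val_loss)) {
        stop(sprintf("non-finite validation loss at epoch %d", epoch),
             call. = FALSE)
      }
      history[epoch, ] <- c(epoch, tl / nb, val_loss)
      if (val_loss < best$loss - 1e-12) {
        best <- list(loss = val_loss, params = model$params, bn = model$bn,
                     epoch = epoch)
        no_improve <- 0L
      } else {
        no_improve <- no_improve + 1L
        if (no_improve >= config$patience) break
      }
    }
  })
  model$params <- best$params; model$bn <- best$bn
  structure(list(model = model, norm = list(mean = mu, sd = sd_),
                 history = history, spec = spec, config = config,
                 best_epoch = best$epoch, encoding = enc$encoding),
            class = "adscout_regressor")
}

#' @noRd
.index_split <- function(n, activity, seed, fractions = c(0.8, 0.1, 0.1)) {
  fake <- data.frame(tile_id = sprintf("t%06d", seq_len(n)),
                     sequence = sprintf("s%06d", seq_len(n)),
                     activity = activity)
  sp <- stratified_split(fake, fractions, seed)
  sp
}

#' @export
print.adscout_regressor <- function(x, ...) {
  cat(sprintf(
    "adscout_regressor: %d channels, %d residual block(s); best epoch %d (val MSE %.4g)\n",
    x$model$arch$channels, x$model$arch$n_blocks, x$best_epoch,
    min(x$history$val_loss)))
  invisible(x)
}

#' Predict activity on the original scale
#'
#' Runs the network in evaluation mode (batch normalization uses running
#' statistics) and inverts the training z-score, so outputs are on the
#' activity scale of the labels. Deterministic.
#'
#' @param object A fitted `adscout_regressor`.
#' @param enc An `encoded_tiles` object with the training encoding shape.
#' @return Numeric vector of activities, named by `tile_id`.
#' @export
predict_activity <- function(object, enc) {
  .assert(inherits(object, "adscout_regressor"), "not an adscout_regressor")
  .assert(dim(enc$x)[3] == object$model$arch$in_channels,
          "encoding channels (%d) do not match the model (%d)",
          dim(enc$x)[3], object$model$arch$in_channels)
  z <- .nn_predict_z(object$model, enc$x)
  stats::setNames(object$norm$mean + object$norm$sd * z, enc$tile_id)
}

#' @export
predict.adscout_regressor <- function(object, enc, ...) {
  predict_activity(object, enc)
}

#' Regression evaluation metrics
#'
#' Root-mean-squared error plus Pearson and Spearman correlations. Pairs
#' with missing values are dropped and the surviving count reported.
#'
#' @param predictions,labels Numeric vectors of equal length.
#' @return List of class `metrics_report`: `rmse`, `pearson_r`,
#'   `spearman_rho`, `n`.
#' @export
evaluate_metrics <- function(predictions, labels) {
  .assert(length(predictions) == length(labels), "length mismatch")
  ok <- is.finite(predictions) & is.finite(labels)
  predictions <- predictions[ok]; labels <- labels[ok]
  .assert(length(labels) >= 2L, "need >= 2 complete pairs")
  structure(list(
    rmse = sqrt(mean((predictions - labels)^2)),
    pearson_r = stats::cor(predictions, labels),
    spearman_rho = stats::cor(predictions, labels, method = "spearman"),
    n = length(labels)), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d | RMSE = %.4f | Pearson r = %.4f | Spearman rho = %.4f\n",
              x$n, x$rmse, x$pearson_r, x$spearman_rho))
  invisible(x)
}
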