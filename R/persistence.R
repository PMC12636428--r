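# Checkpointing: weights plus a JSON manifest describing how they were made.

#' Save / load a fitted regressor
#'
#' Writes `weights.rds` (parameters, batch-norm state, normalization) and a
#' human-readable `manifest.json` (architecture, training configuration,
#' seed, best epoch, final losses) into `dir`.
#'
#' @param object A fitted `adscout_regressor`.
#' @param dir Checkpoint directory (created if needed).
#' @return `save_regressor()` returns `dir` invisibly; `load_regressor()`
#'   returns the regressor.
#' @export
save_regressor <- function(object, dir) {
  .assert(inherits(object, "adscout_regressor"), "not an adscout_regressor")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(object, file.path(dir, "weights.rds"))
  manifest <- list(
    spec = unclass(object$spec), config = unclass(object$config),
    norm = object$norm, best_epoch = object$best_epoch,
    encoding = object$encoding,
    final_val_loss = min(object$history$val_loss),
    weights_hash = .hash_object(object$model$params))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_regressor
#' @export
load_regressor <- function(dir) {
  readRDS(file.path(dir, "weights.rds"))
}

#' Save / load an ensemble
#'
#' Members are checkpointed in `member_<i>/` subdirectories; the ensemble
#' manifest lists member seeds, the training-data hash, and member
#' directories.
#'
#' @param ensemble A fitted `adscout_ensemble`.
#' @param dir Checkpoint directory.
#' @return `save_ensemble()` returns `dir` invisibly; `load_ensemble()`
#'   returns the ensemble.
#' @export
save_ensemble <- function(ensemble, dir) {
  .assert(inherits(ensemble, "adscout_ensemble"), "not an adscout_ensemble")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ensemble$members)) {
    save_regressor(ensemble$members[[i]],
                   file.path(dir, sprintf("member_%02d", i)))
  }
  saveRDS(ensemble[c("data", "split", "spec", "config", "base_seed",
                     "member_seeds", "data_hash")],
          file.path(dir, "ensemble.rds"))
  manifest <- list(
    n_members = length(ensemble$members),
    member_seeds = ensemble$member_seeds,
    member_dirs = sprintf("member_%02d", seq_along(ensemble$members)),
    data_hash = ensemble$data_hash,
    spec = unclass(ensemble$spec), config = unclass(ensemble$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  meta <- readRDS(file.path(dir, "ensemble.rds"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  members <- lapply(manifest$member_dirs, function(d)
    load_regressor(file.path(dir, d)))
  structure(c(list(members = members, encoder = encode_tiles), meta),
            class = "adscout_ensemble")
}
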