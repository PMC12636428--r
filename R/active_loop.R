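# active_loop: one full acquire -> label -> (harmonize) -> retrain round.

#' Run one active-learning round
#'
#' Predicts activity and uncertainty for every design-space tile, acquires a
#' quantile-balanced maximum-uncertainty batch, obtains labels from the
#' labeler, optionally harmonizes the new labels onto the training scale,
#' retrains the ensemble from scratch on the merged dataset, and reports
#' pre/post metrics on a fixed evaluation set plus pre/post median
#' design-space uncertainty.
#'
#' @param ensemble A trained [fit_ensemble()] object (carries its training
#'   data).
#' @param design Unlabeled design-space tile `data.frame` (`tile_id`,
#'   `sequence`); must be disjoint from the training data.
#' @param labeler Either a function `(tile data.frame) -> data.frame
#'   (tile_id, activity)` (e.g. the synthetic oracle, or a wet-lab stub) or
#'   a pre-computed label `data.frame`.
#' @param batch_size Number of tiles to acquire.
#' @param n_bins Acquisition quantile bins.
#' @param eval_set Optional fixed labeled `data.frame` (`tile_id`,
#'   `sequence`, `activity`) for pre/post metrics; fixed before round 1 and
#'   never acquired.
#' @param harmonization_map Optional [fit_affine_map()] result applied to
#'   the new labels before merging (labels arriving on a different scale).
#' @param round_index Round number recorded in the report.
#' @param retrain_seed Base seed for the retrained ensemble (default: the
#'   ensemble's base seed).
#' @param out_dir Optional directory; when given, `acquired.tsv`,
#'   `labels.tsv` and `report.json` are written there.
#' @return List with `ensemble` (retrained) and `report` (a round report:
#'   metrics, uncertainties, seeds, config/data hashes).
#' @export
run_round <- function(ensemble, design, labeler, batch_size, n_bins = 10L,
                      eval_set = NULL, harmonization_map = NULL,
                      round_index = 1L, retrain_seed = NULL,
                      out_dir = NULL) {
  .assert(inherits(ensemble, "adscout_ensemble"), "ensemble required")
  overlap <- intersect(design$tile_id, ensemble$data$tile_id)
  if (length(overlap)) {
    stop("design space overlaps training data: ",
         paste(utils::head(overlap, 5L), collapse = ", "), call. = FALSE)
  }
  if (!is.null(eval_set)) {
    .assert(!any(eval_set$tile_id %in% design$tile_id),
            "evaluation set must not be acquirable")
  }

  preds <- predict_with_uncertainty(ensemble, design)
  unc_pre <- stats::median(preds$uncertainty)
  metrics_pre <- if (!is.null(eval_set)) {
    p <- predict_with_uncertainty(ensemble, eval_set)
    evaluate_metrics(p$mean_activity, eval_set$activity)
  }

  acquired <- quantile_balanced_sample(preds, batch_size, n_bins)

  labels <- if (is.function(labeler)) {
    labeler(design[design$tile_id %in% acquired, , drop = FALSE])
  } else labeler
  labels <- labels[labels$tile_id %in% acquired, , drop = FALSE]
  missing <- setdiff(acquired, labels$tile_id)
  if (length(missing)) {
    stop("labeler returned no labels for: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) sprintf(" (+%d more)", length(missing) - 5L),
         call. = FALSE)
  }
  if (!is.null(harmonization_map)) {
    labels$activity <- as.vector(apply_map(labels$activity, harmonization_map))
  }

  new_rows <- merge(design[design$tile_id %in% acquired,
                           c("tile_id", "sequence")],
                    labels[, c("tile_id", "activity")], by = "tile_id")
  merged <- rbind(ensemble$data[, c("tile_id", "sequence", "activity")],
                  new_rows)
  .assert(!anyDuplicated(merged$tile_id), "a tile would be labeled twice")

  if (is.null(retrain_seed)) retrain_seed <- ensemble$base_seed
  new_ens <- fit_ensemble(merged, n_members = length(ensemble$members),
                          spec = ensemble$spec, config = ensemble$config,
                          base_seed = retrain_seed,
                          encoder = ensemble$encoder)

  remaining <- design[!design$tile_id %in% acquired, , drop = FALSE]
  unc_post <- if (nrow(remaining)) {
    stats::median(predict_with_uncertainty(new_ens, remaining)$uncertainty)
  } else NA_real_
  metrics_post <- if (!is.null(eval_set)) {
    p <- predict_with_uncertainty(new_ens, eval_set)
    evaluate_metrics(p$mean_activity, eval_set$activity)
  }

  report <- list(
    round = round_index,
    n_acquired = length(acquired),
    acquired = acquired,
    metrics_pre = if (!is.null(metrics_pre)) unclass(metrics_pre),
    metrics_post = if (!is.null(metrics_post)) unclass(metrics_post),
    median_uncertainty_pre = unc_pre,
    median_uncertainty_post = unc_post,
    member_seeds_pre = ensemble$member_seeds,
    member_seeds_post = new_ens$member_seeds,
    config_hash = .hash_object(ensemble$config),
    data_hash_pre = ensemble$data_hash,
    data_hash_post = new_ens$data_hash)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(preds[preds$tile_id %in% acquired, ],
               file.path(out_dir, "acquired.tsv"))
    .write_tsv(labels, file.path(out_dir, "labels.tsv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(ensemble = new_ens, report = report)
}
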