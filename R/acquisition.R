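# acquisition: batch selection for labeling.

# Shared engine. Candidates are split into equal-frequency bins of `bin_by`
# (rank-based, sizes differ by at most one; ties broken by id); within each
# bin the best-ranked candidates (by `rank_by`) are taken up to quota
# ceil(n / n_bins). If the per-bin quotas overshoot n, the globally
# worst-ranked selected candidates are dropped; shortfall from sparse bins
# is refilled from the globally best-ranked unselected candidates. Each
# bin's final selection is therefore always a prefix of its ranking, which
# yields the local-optimality guarantee (no within-bin swap can improve the
# selection). Ties in rank are broken lexicographically by id.
#' @noRd
.balanced_select <- function(ids, bin_by, rank_by, n, n_bins,
                             decreasing = TRUE) {
  m <- length(ids)
  .assert(!anyDuplicated(ids), "duplicated tile ids")
  .assert(n >= 1 && n_bins >= 1, "n and n_bins must be >= 1")
  .assert(n <= m, "requested %d tiles but only %d candidates", n, m)
  key <- if (decreasing) -rank_by else rank_by
  bin <- .equal_freq_bins(bin_by, ids, n_bins)
  quota <- ceiling(n / n_bins)
  selected <- logical(m)
  for (b in seq_len(n_bins)) {
    members <- which(bin == b)
    if (!length(members)) next
    ord <- members[order(key[members], ids[members])]
    selected[utils::head(ord, quota)] <- TRUE
  }
  while (sum(selected) > n) {
    sel <- which(selected)
    worst <- max(key[sel])
    cand <- sel[key[sel] == worst]
    drop <- cand[order(ids[cand], decreasing = TRUE)][1L]
    selected[drop] <- FALSE
  }
  if (sum(selected) < n) {
    uns <- which(!selected)
    ord <- uns[order(key[uns], ids[uns])]
    selected[utils::head(ord, n - sum(selected))] <- TRUE
  }
  sort(ids[selected])
}

#' Quantile-balanced uncertainty sampling
#'
#' The acquisition function: candidates are binned into `n_bins`
#' equal-frequency bins of predicted activity and the highest-uncertainty
#' candidates are taken per bin (quota `ceil(batch_size / n_bins)`, sparse
#' bins redistributed by global uncertainty rank), so the batch spans the
#' predicted-activity range while maximizing uncertainty. With `n_bins = 1`
#' this reduces to plain top-k uncertainty sampling. Deterministic; ties
#' broken lexicographically by `tile_id`.
#'
#' @param candidates `data.frame` with `tile_id`, `mean_activity`,
#'   `uncertainty` (e.g. from [predict_with_uncertainty()]).
#' @param batch_size Number of tiles to select.
#' @param n_bins Number of equal-frequency activity bins (default 10).
#' @return Character vector of selected `tile_id`s (sorted), of length
#'   exactly `batch_size`.
#' @export
quantile_balanced_sample <- function(candidates, batch_size, n_bins = 10L) {
  .assert(all(c("tile_id", "mean_activity", "uncertainty") %in% names(candidates)),
          "candidates need tile_id, mean_activity and uncertainty columns")
  .assert(all(candidates$uncertainty >= 0), "uncertainty must be >= 0")
  .balanced_select(candidates$tile_id, candidates$mean_activity,
                   candidates$uncertainty, batch_size, n_bins,
                   decreasing = TRUE)
}

#' Select harmonization tiles
#'
#' From tiles carrying both empirical and predicted activity, picks per
#' equal-frequency bin of empirical activity the tiles with the smallest
#' absolute prediction error, up to quota; exactly `n` are returned. These
#' anchor the affine map between two activity scales (see
#' [fit_affine_map()]).
#'
#' @param tiles `data.frame` with `tile_id`, `activity` (empirical), and
#'   `predicted`.
#' @param n Number of tiles to select.
#' @param n_bins Number of equal-frequency empirical-activity bins.
#' @return Character vector of selected `tile_id`s (sorted).
#' @export
select_harmonization_tiles <- function(tiles, n, n_bins = 10L) {
  .assert(all(c("tile_id", "activity", "predicted") %in% names(tiles)),
          "tiles need tile_id, activity and predicted columns")
  .balanced_select(tiles$tile_id, tiles$activity,
                   abs(tiles$activity - tiles$predicted), n, n_bins,
                   decreasing = FALSE)
}

#' Select control tiles
#'
#' Same mechanics as [quantile_balanced_sample()] but binned on empirical
#' activity: the highest-uncertainty externally labeled tiles spanning the
#' empirical activity range.
#'
#' @param tiles `data.frame` with `tile_id`, `activity` (empirical), and
#'   `uncertainty`.
#' @inheritParams select_harmonization_tiles
#' @return Character vector of selected `tile_id`s (sorted).
#' @export
select_control_tiles <- function(tiles, n, n_bins = 10L) {
  .assert(all(c("tile_id", "activity", "uncertainty") %in% names(tiles)),
          "tiles need tile_id, activity and uncertainty columns")
  .assert(all(tiles$uncertainty >= 0), "uncertainty must be >= 0")
  .balanced_select(tiles$tile_id, tiles$activity, tiles$uncertainty, n,
                   n_bins, decreasing = TRUE)
}
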