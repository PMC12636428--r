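# harmonize: linear-range estimation and affine mapping between activity
# scales.

#' Pairs inside a linear-range window
#'
#' A pair is in-window when its reference activity lies inside the window's
#' reference-scale thresholds and its new activity inside the new-scale
#' thresholds. Interior thresholds (quantile probability strictly between 0
#' and 1) are exclusive: saturated measurements pile up exactly at the
#' dynamic-range limits, and treating the boundary as outside the linear
#' range is what removes them.
#'
#' @param pairs `data.frame` with `ref_activity`, `new_activity`.
#' @param window A `linear_range` object.
#' @return Logical vector.
#' @export
in_linear_range <- function(pairs, window) {
  cmp <- function(x, lo, hi, p_lo, p_hi) {
    a <- if (p_lo > 0) x > lo else x >= lo
    b <- if (p_hi < 1) x < hi else x <= hi
    a & b
  }
  cmp(pairs$ref_activity, window$lower, window$upper,
      window$p_lower, window$p_upper) &
    cmp(pairs$new_activity, window$new_lower, window$new_upper,
        window$p_lower, window$p_upper)
}

#' Estimate the assay's linear range
#'
#' The sorter saturates at high and low reporter signal, so only a central
#' window of the activity scale is linearly comparable across datasets.
#' Candidate windows are quantile-probability pairs on a `grid_step` grid,
#' applied to both activity scales (see [in_linear_range()]); the chosen
#' window maximizes the Pearson correlation between reference and new
#' activities over the retained harmonization pairs, subject to retaining at
#' least `min_fraction` of them. Ties (within 1e-12 in correlation) are
#' broken toward the window retaining more pairs, then toward the wider
#' quantile span. Control pairs never influence the argmax; they only
#' provide an independent validation correlation inside the chosen window.
#'
#' @param pairs `data.frame` with `ref_activity` and `new_activity` for the
#'   harmonization tiles (>= 20 rows).
#' @param control_pairs Optional `data.frame` with the same columns for
#'   control tiles; used only for validation.
#' @param grid_step Quantile grid step (default 0.05).
#' @param min_fraction Minimum fraction of pairs a window must retain.
#' @return Object of class `linear_range`: `lower`/`upper` (reference-scale
#'   thresholds), `new_lower`/`new_upper` (new-scale thresholds),
#'   `p_lower`/`p_upper` (the quantile probabilities), `r_fit`,
#'   `r_validation` (NA without controls), `n_retained`,
#'   `fraction_retained`.
#' @export
estimate_linear_range <- function(pairs, control_pairs = NULL,
                                  grid_step = 0.05, min_fraction = 0.5) {
  .assert(nrow(pairs) >= 20L, "need >= 20 harmonization pairs (have %d)",
          nrow(pairs))
  ref <- pairs$ref_activity; new <- pairs$new_activity
  probs <- seq(0, 1, by = grid_step)
  q_ref <- stats::quantile(ref, probs = probs, names = FALSE)
  q_new <- stats::quantile(new, probs = probs, names = FALSE)
  window_at <- function(i, j) {
    structure(list(lower = q_ref[i], upper = q_ref[j],
                   new_lower = q_new[i], new_upper = q_new[j],
                   p_lower = probs[i], p_upper = probs[j]),
              class = "linear_range")
  }
  best <- NULL
  cand_summary <- list()
  for (i in seq_along(probs)) {
    for (j in seq_along(probs)) {
      if (j <= i) next
      w <- window_at(i, j)
      inw <- in_linear_range(pairs, w)
      n_in <- sum(inw)
      if (n_in < 3L) next
      if (stats::sd(ref[inw]) == 0 || stats::sd(new[inw]) == 0) next
      r <- stats::cor(ref[inw], new[inw])
      cand <- c(w, list(r_fit = r, n_retained = n_in,
                        span = probs[j] - probs[i]))
      cand_summary[[length(cand_summary) + 1L]] <- cand
      if (n_in < min_fraction * length(ref)) next
      if (is.null(best) ||
          r > best$r_fit + 1e-12 ||
          (abs(r - best$r_fit) <= 1e-12 &&
             (n_in > best$n_retained ||
                (n_in == best$n_retained && cand$span > best$span)))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    o <- order(-vapply(cand_summary, `[[`, numeric(1), "r_fit"))
    stop("no window satisfies the retention constraint (min_fraction = ",
         min_fraction, "); best candidates: ",
         paste(utils::head(vapply(cand_summary[o], function(c)
           sprintf("[%.3g, %.3g] r=%.3f n=%d", c$lower, c$upper, c$r_fit,
                   c$n_retained), character(1)), 3L), collapse = "; "),
         call. = FALSE)
  }
  r_val <- NA_real_
  if (!is.null(control_pairs)) {
    cin <- in_linear_range(control_pairs, best)
    if (sum(cin) >= 3L) {
      r_val <- stats::cor(control_pairs$ref_activity[cin],
                          control_pairs$new_activity[cin])
    }
  }
  structure(list(lower = best$lower, upper = best$upper,
                 new_lower = best$new_lower, new_upper = best$new_upper,
                 p_lower = best$p_lower, p_upper = best$p_upper,
                 r_fit = best$r_fit, r_validation = r_val,
                 n_retained = best$n_retained,
                 fraction_retained = best$n_retained / length(ref)),
            class = "linear_range")
}

#' @export
print.linear_range <- function(x, ...) {
  cat(sprintf(
    "linear range [%.4g, %.4g]: fit r = %.4f (n = %d, %.0f%% retained), validation r = %s\n",
    x$lower, x$upper, x$r_fit, x$n_retained, 100 * x$fraction_retained,
    ifelse(is.na(x$r_validation), "NA", sprintf("%.4f", x$r_validation))))
  invisible(x)
}

#' Fit the affine harmonization map
#'
#' Ordinary least squares of reference on new activity
#' (`ref = slope * new + intercept`) over the pairs inside the linear-range
#' window; `sigma` is the residual standard deviation.
#'
#' @param pairs `data.frame` with `ref_activity`, `new_activity`.
#' @param window Optional [estimate_linear_range()] result restricting the
#'   fit to in-window pairs (by reference activity).
#' @return Object of class `harmonization_map`: `slope`, `intercept`,
#'   `sigma`, `window`, `n_pairs`.
#' @export
fit_affine_map <- function(pairs, window = NULL) {
  if (!is.null(window)) {
    pairs <- pairs[in_linear_range(pairs, window), , drop = FALSE]
  }
  .assert(nrow(pairs) >= 3L, "need >= 3 in-window pairs (have %d)", nrow(pairs))
  .assert(stats::sd(pairs$new_activity) > 0,
          "zero variance in new-scale activities")
  fit <- stats::lm(ref_activity ~ new_activity, data = pairs)
  # residual sd computed directly; summary.lm warns on perfect fits
  sigma <- sqrt(sum(stats::residuals(fit)^2) / (nrow(pairs) - 2L))
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 sigma = sigma,
                 window = window, n_pairs = nrow(pairs)),
            class = "harmonization_map")
}

#' @export
print.harmonization_map <- function(x, ...) {
  cat(sprintf(
    "harmonization map: ref = %.4f * new + %.4f (sigma = %.4f, n = %d)\n",
    x$slope, x$intercept, x$sigma, x$n_pairs))
  invisible(x)
}

#' Apply a harmonization map to activities
#'
#' By default the deterministic affine transform `slope * x + intercept`;
#' with `inject_noise = TRUE`, adds `N(0, sigma)` residual noise
#' (distribution-matching mode) under a fixed seed. When the map carries a
#' linear-range window, mapped values falling outside it are flagged via the
#' `"out_of_window"` attribute.
#'
#' @param activities Numeric vector on the new scale.
#' @param map A [fit_affine_map()] result.
#' @param inject_noise Add residual Gaussian noise.
#' @param seed Seed used when injecting noise.
#' @return Numeric vector on the reference scale; attribute
#'   `"out_of_window"` is a logical vector when the map has a window.
#' @export
apply_map <- function(activities, map, inject_noise = FALSE, seed = 1L) {
  .assert(inherits(map, "harmonization_map"), "map must be a harmonization_map")
  y <- map$slope * activities + map$intercept
  if (inject_noise) {
    y <- y + .with_seed(seed, stats::rnorm(length(y), 0, map$sigma))
  }
  if (!is.null(map$window)) {
    attr(y, "out_of_window") <- y < map$window$lower | y > map$window$upper
  }
  y
}

#' Persist / load a harmonization map as JSON
#'
#' @param map A `harmonization_map`.
#' @param path JSON file path.
#' @return `write_harmonization_map()` returns `path` invisibly;
#'   `read_harmonization_map()` returns the map.
#' @export
write_harmonization_map <- function(map, path) {
  obj <- unclass(map)
  if (!is.null(obj$window)) obj$window <- unclass(obj$window)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_harmonization_map
#' @export
read_harmonization_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$window)) {
    obj$window <- structure(obj$window, class = "linear_range")
  }
  structure(obj, class = "harmonization_map")
}
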