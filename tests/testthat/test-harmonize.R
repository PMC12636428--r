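# Generator for harmonization pairs: a linear relationship whose new-scale
# measurement saturates (hard-clips) outside its central 80%, mimicking the
# sorter's dynamic-range limits.
clipped_pairs <- function(n = 400, slope = 0.8, intercept = 0.3,
                          noise_sd = 0.1, seed = 91) {
  set.seed(seed)
  y_new_true <- runif(n, 0, 10)
  y_ref <- slope * y_new_true + intercept + rnorm(n, 0, noise_sd)
  lo <- quantile(y_new_true, 0.1)
  hi <- quantile(y_new_true, 0.9)
  data.frame(tile_id = sprintf("p%04d", seq_len(n)),
             ref_activity = y_ref,
             new_activity = pmin(pmax(y_new_true, lo), hi),
             clipped = y_new_true < lo | y_new_true > hi)
}

test_that("perfectly linear pairs select the widest window", {
  pairs <- data.frame(ref_activity = seq(0, 10, length.out = 50))
  pairs$new_activity <- 2 * pairs$ref_activity + 1
  w <- estimate_linear_range(pairs)
  expect_equal(w$lower, min(pairs$ref_activity))
  expect_equal(w$upper, max(pairs$ref_activity))
  expect_equal(w$fraction_retained, 1)
  expect_equal(w$r_fit, 1, tolerance = 1e-12)
})

test_that("the selected window excludes saturated tails and recovers the fit", {
  pairs <- clipped_pairs()
  w <- estimate_linear_range(pairs)
  inw <- in_linear_range(pairs, w)
  expect_gte(mean(!inw[pairs$clipped]), 0.9)  # >= 90% of clipped excluded
  map <- fit_affine_map(pairs, window = w)
  expect_lt(abs(map$slope - 0.8), 0.05)
  expect_lt(abs(map$intercept - 0.3), 0.05)
})

test_that("control pairs validate but never drive the window choice", {
  pairs <- clipped_pairs(seed = 92)
  controls <- clipped_pairs(n = 100, seed = 93)
  w1 <- estimate_linear_range(pairs, control_pairs = controls)
  # different controls, same argmax
  controls2 <- clipped_pairs(n = 100, noise_sd = 1.5, seed = 94)
  w2 <- estimate_linear_range(pairs, control_pairs = controls2)
  expect_equal(w1[c("lower", "upper", "r_fit")], w2[c("lower", "upper", "r_fit")])
  expect_false(isTRUE(all.equal(w1$r_validation, w2$r_validation)))
  w0 <- estimate_linear_range(pairs)
  expect_true(is.na(w0$r_validation))
})

test_that("an unsatisfiable retention constraint raises a diagnostic error", {
  pairs <- clipped_pairs(n = 40, seed = 95)
  expect_error(estimate_linear_range(pairs, min_fraction = 1.5),
               "retention constraint")
  expect_error(estimate_linear_range(pairs[1:10, ]), ">= 20")
})

test_that("noiseless affine pairs are recovered exactly and applied exactly", {
  pairs <- data.frame(new_activity = seq(-2, 6, length.out = 30))
  pairs$ref_activity <- 2 * pairs$new_activity + 1
  map <- fit_affine_map(pairs)
  expect_equal(map$slope, 2, tolerance = 1e-9)
  expect_equal(map$intercept, 1, tolerance = 1e-9)
  expect_equal(map$sigma, 0, tolerance = 1e-9)
  expect_equal(as.vector(apply_map(1.5, map)), 4.0)
  expect_equal(as.vector(apply_map(pairs$new_activity, map)),
               pairs$ref_activity, tolerance = 1e-9)

  ident <- structure(list(slope = 1, intercept = 0, sigma = 0, window = NULL,
                          n_pairs = 3L), class = "harmonization_map")
  x <- c(0.2, 5, -3)
  expect_identical(as.vector(apply_map(x, ident)), x)
})

test_that("OLS asymmetry: swapping axes recovers the reciprocal slope only when exact", {
  pairs <- clipped_pairs(noise_sd = 0, seed = 96)
  pairs <- pairs[!pairs$clipped, ]
  fwd <- fit_affine_map(pairs)
  rev <- fit_affine_map(data.frame(ref_activity = pairs$new_activity,
                                   new_activity = pairs$ref_activity))
  expect_equal(rev$slope, 1 / fwd$slope, tolerance = 1e-9)
  noisy <- clipped_pairs(noise_sd = 0.5, seed = 97)
  noisy <- noisy[!noisy$clipped, ]
  fwd_n <- fit_affine_map(noisy)
  rev_n <- fit_affine_map(data.frame(ref_activity = noisy$new_activity,
                                     new_activity = noisy$ref_activity))
  expect_gt(abs(rev_n$slope - 1 / fwd_n$slope), 1e-3)
})

test_that("injected noise reproduces the residual scale", {
  map <- structure(list(slope = 1, intercept = 0, sigma = 0.4, window = NULL,
                        n_pairs = 10L), class = "harmonization_map")
  y <- apply_map(rep(2, 10000), map, inject_noise = TRUE, seed = 5)
  expect_equal(sd(y), 0.4, tolerance = 0.02)
  expect_equal(mean(y), 2, tolerance = 0.02)
})

test_that("self-harmonization is the identity map within noise", {
  set.seed(98)
  x <- runif(100, 0, 5)
  pairs <- data.frame(ref_activity = x, new_activity = x + rnorm(100, 0, 0.01))
  map <- fit_affine_map(pairs)
  expect_equal(map$slope, 1, tolerance = 0.02)
  expect_equal(map$intercept, 0, tolerance = 0.02)
})

test_that("maps survive a JSON round-trip and flag out-of-window values", {
  pairs <- clipped_pairs(seed = 99)
  w <- estimate_linear_range(pairs)
  map <- fit_affine_map(pairs, window = w)
  f <- withr::local_tempfile(fileext = ".json")
  write_harmonization_map(map, f)
  back <- read_harmonization_map(f)
  expect_equal(back$slope, map$slope)
  expect_equal(back$window$lower, map$window$lower)
  y <- apply_map(c(-100, 3, 100), back)
  expect_equal(attr(y, "out_of_window"), c(TRUE, FALSE, TRUE))
})

test_that("zero variance on the new scale is rejected", {
  pairs <- data.frame(ref_activity = 1:5, new_activity = rep(2, 5))
  expect_error(fit_affine_map(pairs), "zero variance")
})
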