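# Fixtures are generated in code; nothing is read from disk. Expensive
# trained objects are memoized so several test files can share them.

.fixture_cache <- new.env(parent = emptyenv())

#' Memoize an expensive fixture by name.
memo_fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

#' Small architecture / training configuration used throughout the suite.
#' Model and problem sizes are desk-scale: large enough for the synthetic
#' oracle's structure to be learnable, small enough for fast runs.
small_spec <- function() regressor_spec(stem_channels = 16L, n_blocks = 1L)
small_config <- function(seed = 1L, max_epochs = 12L) {
  training_config(learning_rate = 2e-3, batch_size = 64L,
                  max_epochs = max_epochs, patience = 5L, seed = seed)
}

#' Labeled synthetic dataset (regimes + noisy oracle labels).
labeled_library <- function(n, seed, mix = c(background = 0.4, acidic = 0.3,
                                             leuphe = 0.15, basic = 0.15),
                            noise = TRUE, prefix = "syn") {
  lib <- sample_library(n, mix = mix, seed = seed, prefix = prefix)
  lib$activity <- oracle_activity(lib$sequence, noise = noise,
                                  seed = seed + 1L)
  lib
}

#' In-distribution mix: the Leu/Phe-rich non-acidic regime withheld, so it
#' can serve as the out-of-distribution probe.
id_mix <- function() c(background = 0.5, acidic = 0.3, leuphe = 0, basic = 0.2)

#' A 3-member ensemble trained on oracle-labeled tiles, shared across tests.
oracle_ensemble <- function() {
  memo_fixture("oracle_ensemble", function() {
    dat <- labeled_library(600, seed = 301)
    fit_ensemble(dat, n_members = 3L, spec = small_spec(),
                 config = small_config(max_epochs = 15L), base_seed = 310L)
  })
}

#' Brute-force equal-frequency bin assignment (independent re-statement of
#' the binning contract used by the acquisition oracles).
bf_bins <- function(values, ids, n_bins) {
  o <- order(values, ids)
  bin <- integer(length(values))
  bin[o] <- ceiling(seq_along(o) * n_bins / length(o))
  bin
}

#' Exhaustive search over quota-respecting selections optimizing total
#' `objective` (maximize when decreasing, minimize otherwise).
bf_balanced_select <- function(ids, bins, objective, n, quota,
                               decreasing = TRUE) {
  combos <- utils::combn(seq_along(ids), n, simplify = FALSE)
  ok <- Filter(function(s) all(table(bins[s]) <= quota), combos)
  tot <- vapply(ok, function(s) sum(objective[s]), numeric(1))
  best <- if (decreasing) max(tot) else min(tot)
  list(value = best,
       sets = lapply(ok[abs(tot - best) < 1e-12], function(s) sort(ids[s])))
}
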