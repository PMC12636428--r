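# synthetic: sequence libraries with a known activity law and a sort-seq
# simulator, so every downstream stage is testable without experimental data.

#' Synthetic activity oracle specification
#'
#' The oracle is a simulator invention shaped like the acidic exposure model
#' of AD function: hydrophobic/aromatic residues contribute only when an
#' acidic residue (D/E) lies within `radius` positions (acidic context keeps
#' them solvent-exposed), basic residues (K/R) are penalized, and the total
#' saturates. None of the constants are experimental measurements.
#'
#' @param hydro Named weights for contributing residues.
#' @param radius Acidic-context radius in residues.
#' @param basic_penalty Penalty per K/R residue.
#' @param l_max,k_half Saturation parameters: `activity =
#'   l_max * r / (k_half + r)` for clamped raw score `r = max(raw, 0)`.
#' @param noise_sd Label noise standard deviation when noise is requested.
#' @return List of class `oracle_spec`.
#' @export
oracle_spec <- function(hydro = c(W = 2.0, F = 1.8, L = 1.2, M = 1.2, Y = 1.0),
                        radius = 3L, basic_penalty = 0.5,
                        l_max = 10, k_half = 8, noise_sd = 0.2) {
  .assert(all(is.finite(hydro)) && l_max > 0 && k_half > 0,
          "invalid oracle parameters")
  structure(list(hydro = hydro, radius = as.integer(radius),
                 basic_penalty = basic_penalty, l_max = l_max,
                 k_half = k_half, noise_sd = noise_sd),
            class = "oracle_spec")
}

#' Ground-truth activity of a sequence under the synthetic oracle
#'
#' `raw = sum_i h(s_i) * [D or E within +/- radius of i] -
#' basic_penalty * count(K, R)`; activity saturates as
#' `l_max * max(raw, 0) / (k_half + max(raw, 0))`, optionally plus Gaussian
#' label noise. Deterministic with `noise = FALSE`; bounded in `[0, l_max]`
#' (noise off).
#'
#' @param sequences Character vector of canonical sequences.
#' @param spec An [oracle_spec()].
#' @param noise Add `N(0, noise_sd)` label noise.
#' @param seed Seed used when `noise = TRUE`.
#' @return Numeric vector of activities.
#' @export
oracle_activity <- function(sequences, spec = oracle_spec(), noise = FALSE,
                            seed = 1L) {
  raw <- vapply(sequences, function(s) {
    ch <- strsplit(s, "")[[1]]
    h <- spec$hydro[ch]
    h[is.na(h)] <- 0
    acidic <- which(ch %in% c("D", "E"))
    ctx <- logical(length(ch))
    for (a in acidic) {
      lo <- max(1L, a - spec$radius); hi <- min(length(ch), a + spec$radius)
      ctx[lo:hi] <- TRUE
    }
    sum(h * ctx) - spec$basic_penalty * sum(ch %in% c("K", "R"))
  }, numeric(1), USE.NAMES = FALSE)
  r <- pmax(raw, 0)
  act <- spec$l_max * r / (spec$k_half + r)
  if (noise) act <- act + .with_seed(seed, stats::rnorm(length(act), 0, spec$noise_sd))
  act
}

# Regime-specific residue sampling probabilities. Background is uniform; the
# activator regimes mirror the composition contrast seen between model-yeast
# tile datasets and acquired non-model tiles: an acidic regime (D/E plus
# exposed W/F/L/M), a non-acidic Leu/Phe-rich regime, and a basic inactive
# regime.
.regime_probs <- function() {
  base <- stats::setNames(rep(1, 20), AA_ALPHABET)
  acidic <- base
  acidic[c("D", "E")] <- 5.5
  acidic[c("W", "F", "L", "M")] <- 2.5
  leuphe <- base
  leuphe[c("L", "F")] <- 7
  leuphe[c("D", "E")] <- 0.9
  basic <- base
  basic[c("K", "R")] <- 6
  basic[c("D", "E")] <- 0.25
  lapply(list(background = base, acidic = acidic, leuphe = leuphe,
              basic = basic), function(p) p / sum(p))
}

#' Sample a synthetic tile library
#'
#' Draws fixed-length sequences from a mixture of composition regimes:
#' `background` (uniform residue usage), `acidic` (acidic-AD-like, D/E plus
#' W/F/L/M enriched), `leuphe` (non-acidic leucine/phenylalanine-rich
#' activators), and `basic` (K/R-rich inactives). The regime label is kept
#' for out-of-distribution experiments.
#'
#' @param n Number of tiles.
#' @param length Tile length (default 53).
#' @param mix Named fractions over the four regimes; must sum to 1.
#' @param seed Random seed; the library is deterministic given the seed.
#' @param prefix Tile id prefix.
#' @return `data.frame` with `tile_id`, `sequence`, `regime`.
#' @export
sample_library <- function(n, length = 53L,
                           mix = c(background = 0.4, acidic = 0.3,
                                   leuphe = 0.15, basic = 0.15),
                           seed = 1L, prefix = "syn") {
  probs <- .regime_probs()
  .assert(all(names(mix) %in% names(probs)), "unknown regime in mix")
  .assert(abs(sum(mix) - 1) < 1e-9 && all(mix >= 0), "mix fractions must sum to 1")
  .with_seed(seed, {
    regime <- sample(names(mix), n, replace = TRUE, prob = mix)
    seqs <- vapply(regime, function(r) {
      paste(sample(AA_ALPHABET, length, replace = TRUE, prob = probs[[r]]),
            collapse = "")
    }, character(1), USE.NAMES = FALSE)
    data.frame(tile_id = sprintf("%s_%05d", prefix, seq_len(n)),
               sequence = seqs, regime = regime, stringsAsFactors = FALSE)
  })
}

#' Sort-seq simulator specification
#'
#' Emulates the assay design: cells carrying a tile fluoresce around the
#' tile's true activity, 8 sorting bins each capture 10% of the population
#' (the central 80%; cells outside the decile-10/90 window are unsampled),
#' and each tile carries a Poisson number of barcodes with median 12.
#'
#' @param cell_sd Cell-level fluorescence standard deviation (activity
#'   units).
#' @param cells_per_barcode Simulated cells per barcode.
#' @param reads_per_barcode Sequencing reads drawn per barcode
#'   (multinomially over its bin occupancy).
#' @param barcode_lambda Poisson mean of barcodes per tile (truncated at 1).
#' @param seed Random seed.
#' @return List of class `sortseq_sim_spec`.
#' @export
sortseq_sim_spec <- function(cell_sd = 1.0, cells_per_barcode = 50L,
                             reads_per_barcode = 200L, barcode_lambda = 12,
                             seed = 1L) {
  .assert(reads_per_barcode > 0, "reads_per_barcode must be positive")
  structure(list(cell_sd = cell_sd, cells_per_barcode = cells_per_barcode,
                 reads_per_barcode = reads_per_barcode,
                 barcode_lambda = barcode_lambda, seed = seed),
            class = "sortseq_sim_spec")
}

#' @noRd
.random_barcodes <- function(n) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 14L, replace = TRUE), collapse = ""),
    character(1))
}

#' Simulate sorted-bin barcode read counts
#'
#' For every barcode of every tile, cell fluorescences are drawn as
#' `Normal(activity, cell_sd)`; bin boundaries are the population deciles
#' 10%..90% (8 bins over the central 80%); bin medians are within-bin
#' population medians; each barcode's reads are multinomial over its cells'
#' bin occupancy. Deterministic given the spec seed.
#'
#' @param truth `data.frame` with `tile_id` and true `activity`.
#' @param sim A [sortseq_sim_spec()].
#' @return List with `counts` (a bin-count table: `tile_id`, `barcode`,
#'   `bin_1`..`bin_8`) and `bins` (`bin`, `total_reads`,
#'   `median_fluorescence`); bin boundaries attached as attribute
#'   `boundaries`.
#' @export
simulate_sortseq_counts <- function(truth, sim = sortseq_sim_spec()) {
  .assert(all(is.finite(truth$activity)), "activities must be finite")
  .with_seed(sim$seed, {
    n_bc <- pmax(1L, stats::rpois(nrow(truth), sim$barcode_lambda))
    tile_of_bc <- rep(truth$tile_id, n_bc)
    act_of_bc <- rep(truth$activity, n_bc)
    nb <- length(tile_of_bc)
    barcodes <- .random_barcodes(nb)
    while (anyDuplicated(barcodes)) {
      d <- which(duplicated(barcodes))
      barcodes[d] <- .random_barcodes(length(d))
    }
    nc <- sim$cells_per_barcode
    fluor <- stats::rnorm(nb * nc, mean = rep(act_of_bc, each = nc),
                          sd = sim$cell_sd)
    bounds <- stats::quantile(fluor, probs = seq(0.1, 0.9, by = 0.1),
                              names = FALSE)
    # bin index 1..8 for cells inside [q10, q90); others unsampled
    bin_of_cell <- findInterval(fluor, bounds, rightmost.closed = FALSE)
    inside <- bin_of_cell >= 1L & bin_of_cell <= 8L
    medians <- vapply(1:8, function(b)
      stats::median(fluor[inside & bin_of_cell == b]), numeric(1))
    cnt <- matrix(0L, nb, 8L,
                  dimnames = list(NULL, paste0("bin_", 1:8)))
    bc_of_cell <- rep(seq_len(nb), each = nc)
    occ <- table(factor(bc_of_cell[inside], levels = seq_len(nb)),
                 factor(bin_of_cell[inside], levels = 1:8))
    occ <- matrix(as.numeric(occ), nb, 8L)
    for (i in seq_len(nb)) {
      if (sum(occ[i, ]) > 0) {
        cnt[i, ] <- as.integer(stats::rmultinom(1L, sim$reads_per_barcode,
                                                occ[i, ]))
      }
    }
    counts <- cbind(data.frame(tile_id = tile_of_bc, barcode = barcodes,
                               stringsAsFactors = FALSE),
                    as.data.frame(cnt))
    bins <- data.frame(bin = 1:8, total_reads = colSums(cnt),
                       median_fluorescence = medians)
    structure(list(counts = counts, bins = bins), boundaries = bounds)
  })
}

# Fixed reverse-translation table (one codon per residue) used only by the
# nucleotide-level read simulator.
.CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
            H = "CAT", I = "ATT", K = "AAA", L = "TTG", M = "ATG", N = "AAT",
            P = "CCA", Q = "CAA", R = "AGA", S = "TCT", T = "ACT", V = "GTT",
            W = "TGG", Y = "TAT")

#' Conserved flanks of the tile cassette
#'
#' The upstream/downstream sequences flanking every tile in the assay
#' construct; reads are parsed against them by [extract_tile_barcodes()].
#' @return Named character vector with `up` and `down`.
#' @export
tile_flanks <- function() {
  c(up = "GCGGGCTCTACTTCATCGGCTAGC", down = "TGATAACTAGCTGAGGGCCCG")
}

#' Reverse-translate amino-acid tiles to nucleotide sequences
#'
#' Uses a fixed one-codon-per-residue table, so the mapping is deterministic
#' and invertible.
#'
#' @param sequences Amino-acid strings.
#' @return Nucleotide strings.
#' @export
reverse_translate <- function(sequences) {
  vapply(sequences, function(s)
    paste(.CODON[strsplit(s, "")[[1]]], collapse = ""),
    character(1), USE.NAMES = FALSE)
}

#' Simulate merged sequencing reads of the tile cassette
#'
#' Each read is `upstream flank + tile nucleotides + downstream flank +
#' 14 nt barcode`. Exactly `round(corruption_rate * n_reads)` reads (chosen
#' at random) receive one substitution inside the tile region, guaranteed to
#' produce a sequence absent from the library, so the perfect-match filter
#' must reject precisely those reads.
#'
#' @param tiles Tile `data.frame` (`tile_id`, `sequence`).
#' @param n_reads Number of reads.
#' @param corruption_rate Fraction of reads to corrupt.
#' @param seed Random seed.
#' @return `data.frame` with `read`, `true_tile_id`, `barcode`, `corrupted`.
#' @export
simulate_reads <- function(tiles, n_reads, corruption_rate = 0, seed = 1L) {
  fl <- tile_flanks()
  nt <- reverse_translate(tiles$sequence)
  .with_seed(seed, {
    pick <- sample(nrow(tiles), n_reads, replace = TRUE)
    barcodes <- .random_barcodes(n_reads)
    tile_nt <- nt[pick]
    n_bad <- round(corruption_rate * n_reads)
    corrupted <- logical(n_reads)
    if (n_bad > 0) {
      bad <- sample(n_reads, n_bad)
      corrupted[bad] <- TRUE
      for (i in bad) {
        repeat {
          pos <- sample(nchar(tile_nt[i]), 1L)
          old <- substr(tile_nt[i], pos, pos)
          new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
          cand <- tile_nt[i]
          substr(cand, pos, pos) <- new
          if (!cand %in% nt) { tile_nt[i] <- cand; break }
        }
      }
    }
    data.frame(read = paste0(fl["up"], tile_nt, fl["down"], barcodes),
               true_tile_id = tiles$tile_id[pick], barcode = barcodes,
               corrupted = corrupted, stringsAsFactors = FALSE)
  })
}
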