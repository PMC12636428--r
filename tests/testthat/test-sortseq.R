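toy_library <- function(n = 6, seed = 81) {
  lib <- sample_library(n, length = 20L, seed = seed, prefix = "lib")
  data.frame(tile_id = lib$tile_id, sequence = lib$sequence,
             nt_sequence = reverse_translate(lib$sequence),
             stringsAsFactors = FALSE)
}

test_that("reads with exact flanks and library tiles are extracted", {
  lib <- toy_library()
  fl <- tile_flanks()
  bc <- paste0(strrep("ACGT", 3), "GG")  # 14 nt
  read <- paste0("TT", fl["up"], lib$nt_sequence[2], fl["down"], bc, "AAAA")
  res <- extract_tile_barcodes(read, lib)
  expect_equal(res$status, "ok")
  expect_equal(res$tile_id, lib$tile_id[2])
  expect_equal(res$barcode, bc)
})

test_that("rejections are categorized: substitution, flank, length, alphabet", {
  lib <- toy_library()
  fl <- tile_flanks()
  bc <- strrep("AC", 7)
  nt <- lib$nt_sequence[1]
  substr(nt, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                              substr(nt, 5, 5))[1]
  reads <- c(
    paste0(fl["up"], nt, fl["down"], bc),                 # single substitution
    paste0(lib$nt_sequence[1], fl["down"], bc),           # no upstream flank
    paste0(fl["up"], lib$nt_sequence[1], fl["down"], "ACGT"),  # short barcode
    paste0(fl["up"], "NNNN", fl["down"], bc))             # malformed
  res <- extract_tile_barcodes(reads, lib)
  expect_equal(res$status, c("no_match", "no_flank", "bad_length", "non_acgt"))
  expect_true(all(is.na(res$tile_id)))
})

test_that("exactly the corrupted fraction of simulated reads is rejected", {
  lib <- toy_library(10, seed = 82)
  sim <- simulate_reads(lib, n_reads = 1000L, corruption_rate = 0.05,
                        seed = 83)
  res <- extract_tile_barcodes(sim$read, lib)
  expect_equal(sum(res$status == "ok"), 950L)
  expect_equal(res$status == "ok", !sim$corrupted)
  ok <- res$status == "ok"
  expect_equal(res$tile_id[ok], sim$true_tile_id[ok])
  expect_equal(res$barcode[ok], sim$barcode[ok])
})

hand_bins <- function(totals = rep(1000, 8)) {
  data.frame(bin = 1:8, total_reads = totals, median_fluorescence = 1:8)
}

hand_counts <- function() {
  cnt <- rbind(
    c(0, 0, 100, 0, 0, 0, 0, 0),   # delta in bin 3
    rep(8, 8),                     # uniform across bins
    c(49, 0, 0, 0, 0, 0, 0, 0))    # below the read filter
  out <- data.frame(tile_id = c("t1", "t2", "t3"),
                    barcode = c("b1", "b2", "b3"),
                    stringsAsFactors = FALSE)
  colnames(cnt) <- paste0("bin_", 1:8)
  cbind(out, as.data.frame(cnt))
}

test_that("hand-built count table scores exactly", {
  expect_message(sc <- score_barcodes(hand_counts(), hand_bins()), "discarded")
  expect_equal(sc$tile_id, c("t1", "t2"))
  expect_equal(sc$activity, c(3, 4.5))
  expect_equal(attr(sc, "n_dropped"), 1L)
  # a 50-read row survives the default filter
  h <- hand_counts()
  h[3, "bin_1"] <- 50
  sc2 <- score_barcodes(h, hand_bins())
  expect_equal(nrow(sc2), 3L)
  expect_equal(sc2$activity[3], 1)
})

test_that("scores are invariant to uniform depth rescaling of one bin", {
  set.seed(84)
  cnt <- matrix(rpois(40, 30), 5, 8, dimnames = list(NULL, paste0("bin_", 1:8)))
  tab <- cbind(data.frame(tile_id = paste0("t", 1:5), barcode = paste0("b", 1:5)),
               as.data.frame(cnt))
  bins <- hand_bins(totals = colSums(cnt))
  s1 <- score_barcodes(tab, bins, min_reads = 1)
  tab2 <- tab
  tab2$bin_5 <- tab$bin_5 * 10L
  bins2 <- bins
  bins2$total_reads[5] <- bins$total_reads[5] * 10L
  s2 <- score_barcodes(tab2, bins2, min_reads = 1)
  expect_equal(s2$activity, s1$activity, tolerance = 1e-12)
  # convexity: always within the bin-median range
  expect_true(all(s1$activity >= 1 & s1$activity <= 8))
})

test_that("zero-read bins are excluded only when empty everywhere", {
  tab <- hand_counts()[1:2, ]
  bins <- hand_bins()
  bins$total_reads[8] <- 0
  expect_error(score_barcodes(tab, bins), "zero total reads")
  tab$bin_8 <- 0L
  expect_warning(sc <- score_barcodes(tab, bins), "empty bin")
  expect_equal(sc$activity[1], 3)
  bad <- hand_bins()
  bad$median_fluorescence <- rep(1, 8)
  expect_error(score_barcodes(tab, bad), "increasing")
})

test_that("barcode collisions across tiles are dropped with a warning", {
  tab <- rbind(hand_counts()[1:2, ], hand_counts()[1, ])
  tab$barcode <- c("b1", "b1", "b9")
  expect_warning(sc <- score_barcodes(tab, hand_bins()), "multiple tiles")
  expect_equal(sc$barcode, "b9")
  expect_equal(sc$activity, 3)
})

test_that("tile aggregation is the unweighted barcode mean", {
  sc <- data.frame(tile_id = c("t1", "t1", "t2"),
                   barcode = c("b1", "b2", "b3"),
                   activity = c(2, 4, 5), total_reads = c(100, 300, 80))
  agg <- aggregate_tile_activity(sc, expected_tiles = c("t1", "t2", "t3"))
  expect_equal(agg$activity, c(3, 5))
  expect_equal(agg$n_barcodes, c(2L, 1L))
  expect_equal(attr(agg, "missing"), "t3")
  expect_equal(attr(agg, "recovery_rate"), 2 / 3)
})

test_that("extraction + tabulation + scoring recover simulated bin structure", {
  lib <- toy_library(4, seed = 85)
  truth <- data.frame(tile_id = lib$tile_id,
                      activity = c(1, 3, 5, 7))
  sim <- simulate_sortseq_counts(
    truth, sortseq_sim_spec(cell_sd = 0.8, reads_per_barcode = 200L,
                            seed = 86))
  sc <- suppressMessages(score_barcodes(sim$counts, sim$bins))
  agg <- aggregate_tile_activity(sc)
  m <- merge(agg, truth, by = "tile_id")
  expect_equal(cor(m$activity.x, m$activity.y, method = "spearman"), 1)
})
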