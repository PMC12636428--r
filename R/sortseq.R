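# sortseq: activity quantification from sorted-bin barcode sequencing.

#' Extract tile and barcode from merged reads
#'
#' A valid read is `<anything> upstream-flank <tile nt> downstream-flank
#' <14 nt barcode> <anything>`. Both flanks must match exactly and the tile
#' nucleotide sequence must be a perfect match to the supplied library; all
#' other reads are rejected with a categorized reason: `non_acgt`
#' (malformed characters), `no_flank` (flanks absent or out of order),
#' `bad_length` (fewer than 14 nt after the downstream flank), `no_match`
#' (tile not in the library).
#'
#' @param reads Character vector of merged read sequences.
#' @param library `data.frame` with `tile_id` and `nt_sequence` (the exact
#'   expected tile nucleotide sequences).
#' @param flanks Named vector with `up` and `down` flank sequences (default
#'   [tile_flanks()]).
#' @return `data.frame` with one row per read: `status` (`"ok"` or a
#'   rejection reason), `tile_id`, `barcode` (NA unless `"ok"`). A table of
#'   rejection reasons is attached as attribute `"rejections"`.
#' @export
extract_tile_barcodes <- function(reads, library, flanks = tile_flanks()) {
  .assert(!anyDuplicated(library$nt_sequence), "duplicated library sequences")
  lut <- stats::setNames(library$tile_id, library$nt_sequence)
  up <- flanks[["up"]]; down <- flanks[["down"]]
  n <- length(reads)
  status <- rep("ok", n)
  tile_id <- rep(NA_character_, n)
  barcode <- rep(NA_character_, n)

  bad_chars <- grepl("[^ACGT]", reads)
  status[bad_chars] <- "non_acgt"
  todo <- which(!bad_chars)

  up_pos <- regexpr(up, reads[todo], fixed = TRUE)
  has_up <- up_pos > 0
  status[todo[!has_up]] <- "no_flank"
  todo2 <- todo[has_up]
  rest <- substring(reads[todo2], up_pos[has_up] + nchar(up))
  down_pos <- regexpr(down, rest, fixed = TRUE)
  has_down <- down_pos > 0
  status[todo2[!has_down]] <- "no_flank"
  todo3 <- todo2[has_down]
  rest <- rest[has_down]; down_pos <- down_pos[has_down]

  tile_nt <- substring(rest, 1L, down_pos - 1L)
  after <- substring(rest, down_pos + nchar(down))
  short <- nchar(after) < 14L
  status[todo3[short]] <- "bad_length"
  todo4 <- todo3[!short]
  tile_nt <- tile_nt[!short]
  bc <- substring(after[!short], 1L, 14L)

  hit <- lut[tile_nt]
  miss <- is.na(hit)
  status[todo4[miss]] <- "no_match"
  ok <- todo4[!miss]
  tile_id[ok] <- hit[!miss]
  barcode[ok] <- bc[!miss]

  out <- data.frame(status = status, tile_id = tile_id, barcode = barcode,
                    stringsAsFactors = FALSE)
  attr(out, "rejections") <- table(status[status != "ok"])
  out
}

#' Tabulate extracted reads into a bin-count table
#'
#' @param extracted List of extraction results (one per bin, in bin order),
#'   each as returned by [extract_tile_barcodes()].
#' @return Bin-count `data.frame`: `tile_id`, `barcode`, `bin_1`..`bin_8`.
#' @export
tabulate_bin_counts <- function(extracted) {
  .assert(length(extracted) == 8L, "expected 8 per-bin extraction results")
  keys <- unique(do.call(rbind, lapply(extracted, function(e)
    e[e$status == "ok", c("tile_id", "barcode")])))
  cnt <- matrix(0L, nrow(keys), 8L, dimnames = list(NULL, paste0("bin_", 1:8)))
  key_of <- paste(keys$tile_id, keys$barcode)
  for (b in 1:8) {
    e <- extracted[[b]]
    ok <- e[e$status == "ok", ]
    tab <- table(paste(ok$tile_id, ok$barcode))
    cnt[match(names(tab), key_of), b] <- as.integer(tab)
  }
  cbind(keys, as.data.frame(cnt))
}

#' Per-barcode activity scores from a bin-count table
#'
#' Implements the assay's quantification: counts are normalized by the total
#' reads of each bin, renormalized across the 8 bins to a relative
#' abundance, and the activity is the inner product of relative abundance
#' with the bins' median fluorescence values (a weighted average, hence
#' always within the range of the bin medians). Rows whose raw read total is
#' below `min_reads` are discarded and reported.
#'
#' Barcodes observed for more than one tile are dropped with a warning
#' (collisions cannot be attributed).
#'
#' @param counts Bin-count `data.frame` (`tile_id`, `barcode`,
#'   `bin_1`..`bin_8`).
#' @param bins `data.frame` with `bin` (1..8), `total_reads`,
#'   `median_fluorescence` (strictly increasing with bin).
#' @param min_reads Minimum raw reads per (tile, barcode) row (default 50,
#'   i.e. rows with fewer than 50 reads are discarded).
#' @return `data.frame` with `tile_id`, `barcode`, `activity`,
#'   `total_reads`; dropped row count attached as attribute `"n_dropped"`.
#' @export
score_barcodes <- function(counts, bins, min_reads = 50L) {
  .assert(nrow(bins) == 8L, "expected 8 bins")
  bins <- bins[order(bins$bin), , drop = FALSE]
  .assert(all(diff(bins$median_fluorescence) > 0),
          "bin median fluorescence must be strictly increasing")
  cols <- paste0("bin_", 1:8)
  .assert(all(cols %in% names(counts)), "counts must have bin_1..bin_8")
  cnt <- as.matrix(counts[, cols])
  .assert(all(cnt >= 0), "negative counts")

  collided <- counts$barcode[counts$barcode %in%
                               counts$barcode[duplicated(counts$barcode)]]
  if (length(collided)) {
    warning(length(unique(collided)),
            " barcode(s) observed for multiple tiles dropped")
    keep <- !(counts$barcode %in% collided)
    counts <- counts[keep, , drop = FALSE]
    cnt <- cnt[keep, , drop = FALSE]
  }

  totals <- bins$total_reads
  zero <- totals == 0
  use <- rep(TRUE, 8L)
  if (any(zero)) {
    if (all(cnt[, zero] == 0)) {
      warning(sum(zero), " empty bin(s) excluded from scoring")
      use <- !zero
    } else {
      stop("bin(s) with zero total reads but nonzero counts: ",
           paste(which(zero), collapse = ", "), call. = FALSE)
    }
  }

  raw_total <- rowSums(cnt)
  keep <- raw_total >= min_reads
  n_dropped <- sum(!keep)
  if (n_dropped) message(n_dropped, " row(s) with < ", min_reads,
                         " reads discarded")
  cnt <- cnt[keep, , drop = FALSE]
  norm <- sweep(cnt[, use, drop = FALSE], 2L, totals[use], "/")
  rel <- norm / rowSums(norm)
  activity <- as.vector(rel %*% bins$median_fluorescence[use])
  out <- data.frame(tile_id = counts$tile_id[keep],
                    barcode = counts$barcode[keep],
                    activity = activity,
                    total_reads = raw_total[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Aggregate barcode scores to tile activity
#'
#' The tile activity score is the unweighted mean over its surviving
#' barcodes. When `expected_tiles` is supplied, tiles with zero surviving
#' barcodes are reported as missing (recovery rate attached).
#'
#' @param barcode_scores Output of [score_barcodes()].
#' @param expected_tiles Optional character vector of tiles that were in the
#'   library.
#' @return `data.frame` with `tile_id`, `activity`, `n_barcodes`,
#'   `total_reads`; attributes `"missing"` (character vector) and
#'   `"recovery_rate"` when `expected_tiles` is given.
#' @export
aggregate_tile_activity <- function(barcode_scores, expected_tiles = NULL) {
  .assert(nrow(barcode_scores) >= 1L, "no surviving barcodes")
  f <- factor(barcode_scores$tile_id)
  agg <- data.frame(
    tile_id = levels(f),
    activity = as.vector(tapply(barcode_scores$activity, f, mean)),
    n_barcodes = as.integer(tabulate(f)),
    total_reads = as.vector(tapply(barcode_scores$total_reads, f, sum)),
    stringsAsFactors = FALSE)
  if (!is.null(expected_tiles)) {
    missing <- setdiff(expected_tiles, agg$tile_id)
    if (length(missing)) message(length(missing), " tile(s) not recovered")
    attr(agg, "missing") <- missing
    attr(agg, "recovery_rate") <-
      1 - length(missing) / length(expected_tiles)
  }
  agg
}

#' Read / write sort-seq tables
#'
#' TSV helpers for the bin-count table (`tile_id`, `barcode`,
#' `bin_1`..`bin_8`), the bin statistics table (`bin`, `total_reads`,
#' `median_fluorescence`) and activity tables.
#'
#' @param path File path.
#' @return The corresponding `data.frame`.
#' @export
read_bin_counts <- function(path) .read_tsv(path)

#' @rdname read_bin_counts
#' @export
read_bin_stats <- function(path) .read_tsv(path)

#' @rdname read_bin_counts
#' @param x Table to write.
#' @export
write_activity_table <- function(x, path) {
  .write_tsv(x, path)
  invisible(path)
}

#' @rdname read_bin_counts
#' @export
read_activity_table <- function(path) .read_tsv(path)
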