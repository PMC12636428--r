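# Internal helpers shared across modules.

#' @noRd
.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' Equal-frequency bin assignment.
#'
#' Ranks `values` (ties broken by `ids`) and assigns `n_bins` bins of equal
#' frequency (sizes differ by at most one). Deterministic.
#' @noRd
.equal_freq_bins <- function(values, ids, n_bins) {
  n <- length(values)
  o <- order(values, ids)
  bin <- integer(n)
  bin[o] <- ceiling(seq_len(n) * n_bins / n)
  bin
}

#' Content hash of an arbitrary R object (provenance pinning).
#' @noRd
.hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

#' @noRd
.read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' @noRd
.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run code with a private RNG stream, restoring the caller's stream after.
#' @noRd
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Population standard deviation (ddof = 0).
#' @noRd
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
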