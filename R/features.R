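# features: numeric encodings of tiles and composition descriptors.

#' One-hot encode a tile sequence
#'
#' Returns a `positions x 20` binary matrix over the fixed canonical alphabet
#' [AA_ALPHABET] (columns in that order); each row carries exactly one 1.
#' With `mask_noncanonical = TRUE`, residues outside the alphabet (e.g. `X`)
#' produce an all-zero row instead of an error.
#'
#' @param sequence Amino-acid string.
#' @param mask_noncanonical Encode non-canonical residues as all-zero rows.
#' @return Numeric matrix `nchar(sequence) x 20` with column names
#'   [AA_ALPHABET].
#' @export
one_hot_encode <- function(sequence, mask_noncanonical = FALSE) {
  chars <- strsplit(sequence, "")[[1]]
  idx <- match(chars, AA_ALPHABET)
  if (anyNA(idx) && !mask_noncanonical) {
    stop("non-canonical residue(s): ",
         paste(unique(chars[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  m <- matrix(0, length(chars), 20L, dimnames = list(NULL, AA_ALPHABET))
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

#' Decode a one-hot matrix back to a sequence
#'
#' @param m One-hot matrix as produced by [one_hot_encode()].
#' @return Amino-acid string (`X` for all-zero rows).
#' @export
one_hot_decode <- function(m) {
  idx <- apply(m, 1L, function(r) {
    w <- which(r == 1)
    if (length(w) == 1L) w else NA_integer_
  })
  paste(ifelse(is.na(idx), "X", AA_ALPHABET[idx]), collapse = "")
}

#' Encode a tile table into a numeric array
#'
#' Produces the container consumed by the regressor: an array of dimension
#' `n_tiles x positions x channels`. The default encoding is one-hot over
#' [AA_ALPHABET]. A provider (e.g. a protein language model behind a function
#' contract) may be supplied instead; see [embed_with_provider()].
#'
#' @param tiles Tile `data.frame` with `tile_id` and `sequence` (all sequences
#'   the same length).
#' @param encoding `"onehot"` or `"provider"`.
#' @param provider,layer,cache Passed to [embed_with_provider()] when
#'   `encoding = "provider"`.
#' @param mask_noncanonical See [one_hot_encode()].
#' @return An object of class `encoded_tiles`: list with `tile_id`, `x`
#'   (array `n x P x C`), `encoding`, `alphabet`.
#' @export
encode_tiles <- function(tiles, encoding = c("onehot", "provider"),
                         provider = NULL, layer = c("last", "first"),
                         cache = NULL, mask_noncanonical = FALSE) {
  encoding <- match.arg(encoding)
  lens <- unique(nchar(tiles$sequence))
  .assert(length(lens) == 1L, "tiles must share one length (found: %s)",
          paste(lens, collapse = ", "))
  if (encoding == "onehot") {
    mats <- lapply(tiles$sequence, one_hot_encode,
                   mask_noncanonical = mask_noncanonical)
    name <- "onehot"
  } else {
    mats <- embed_with_provider(tiles, provider, layer = layer, cache = cache)
    name <- paste0("provider:", attr(mats, "provider_name") %||% "anonymous")
  }
  P <- nrow(mats[[1L]]); C <- ncol(mats[[1L]])
  x <- array(0, dim = c(length(mats), P, C))
  for (i in seq_along(mats)) x[i, , ] <- mats[[i]]
  structure(list(tile_id = tiles$tile_id, x = x, encoding = name,
                 alphabet = colnames(mats[[1L]]) %||% AA_ALPHABET),
            class = "encoded_tiles")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.encoded_tiles <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("encoded_tiles: %d tiles x %d positions x %d channels (%s)\n",
              d[1], d[2], d[3], x$encoding))
  invisible(x)
}

#' Embed tiles with a pluggable provider
#'
#' The provider contract is a function `provider(sequence, layer)` returning a
#' `positions x D` numeric matrix; the package never bundles a language
#' model. Results are cached in `cache` (an environment) keyed by the
#' sequence content hash, provider name, and layer, so a cache hit bypasses
#' recomputation and provider upgrades never silently mix representations.
#'
#' @param tiles Tile `data.frame`.
#' @param provider Function `(sequence, layer) -> matrix`, optionally carrying
#'   a `name` attribute.
#' @param layer `"last"` or `"first"` -- which representation layer to request.
#' @param cache Optional environment used as the embedding cache.
#' @return List of `positions x D` matrices, one per tile, with a
#'   `provider_name` attribute.
#' @export
embed_with_provider <- function(tiles, provider, layer = c("last", "first"),
                                cache = NULL) {
  layer <- match.arg(layer)
  .assert(is.function(provider), "provider must be a function(sequence, layer)")
  pname <- attr(provider, "name") %||% "anonymous"
  mats <- vector("list", nrow(tiles))
  D <- NULL
  for (i in seq_len(nrow(tiles))) {
    s <- tiles$sequence[i]
    key <- paste(.hash_object(s), pname, layer, sep = ":")
    m <- if (!is.null(cache) && !is.null(cache[[key]])) {
      cache[[key]]
    } else {
      m0 <- tryCatch(provider(s, layer), error = function(e) {
        stop(sprintf("provider failed on tile '%s': %s",
                     tiles$tile_id[i], conditionMessage(e)), call. = FALSE)
      })
      if (!is.null(cache)) cache[[key]] <- m0
      m0
    }
    .assert(is.matrix(m) && nrow(m) == nchar(s),
            "provider returned wrong shape for tile '%s'", tiles$tile_id[i])
    if (is.null(D)) D <- ncol(m)
    .assert(ncol(m) == D, "embedding dimension mismatch at tile '%s'",
            tiles$tile_id[i])
    mats[[i]] <- m
  }
  attr(mats, "provider_name") <- pname
  mats
}

#' Composition profile of a sequence
#'
#' Descriptors used to characterize tile datasets: net charge
#' (`count(K) + count(R) - count(D) - count(E)`, histidine excluded), the
#' fraction of non-polar residues, and per-residue fractions. The charge and
#' non-polar sets are conventions, overridable via arguments.
#'
#' @param sequence Amino-acid string (canonical, non-empty).
#' @param positive,negative Residues counted as +1 / -1 charge.
#' @param nonpolar The non-polar residue set (default A, V, L, I, M, F, W, P,
#'   G).
#' @return List of class `composition_profile` with `net_charge` (integer),
#'   `nonpolar_fraction`, `residue_fractions` (named 20-vector summing to 1),
#'   and `length`.
#' @export
composition_profile <- function(sequence,
                                positive = c("K", "R"),
                                negative = c("D", "E"),
                                nonpolar = c("A", "V", "L", "I", "M", "F", "W", "P", "G")) {
  .assert(nzchar(sequence), "empty sequence")
  chars <- strsplit(sequence, "")[[1]]
  .assert(all(chars %in% AA_ALPHABET), "non-canonical residues in sequence")
  counts <- table(factor(chars, levels = AA_ALPHABET))
  counts <- stats::setNames(as.integer(counts), AA_ALPHABET)
  structure(list(
    net_charge = sum(counts[positive]) - sum(counts[negative]),
    nonpolar_fraction = sum(counts[nonpolar]) / length(chars),
    residue_fractions = counts / length(chars),
    length = length(chars)), class = "composition_profile")
}

#' Composition table for many tiles
#'
#' @param tiles Tile `data.frame` with `tile_id`, `sequence`.
#' @inheritParams composition_profile
#' @return `data.frame` with `tile_id`, `net_charge`, `nonpolar_fraction`,
#'   and one `frac_<residue>` column per canonical residue.
#' @export
composition_table <- function(tiles, ...) {
  rows <- lapply(seq_len(nrow(tiles)), function(i) {
    p <- composition_profile(tiles$sequence[i], ...)
    c(net_charge = p$net_charge, nonpolar_fraction = p$nonpolar_fraction,
      stats::setNames(p$residue_fractions, paste0("frac_", AA_ALPHABET)))
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(tile_id = tiles$tile_id, stringsAsFactors = FALSE), out)
}
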