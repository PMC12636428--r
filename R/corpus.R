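# corpus: load, deduplicate, cluster and tile protein sequences.

#' Read protein sequences from FASTA
#'
#' Loads a FASTA file into a protein record table. Headers follow the
#' `>protein_id genome_id=...` convention; the `genome_id=` token is optional
#' and wrapped sequence lines are tolerated. Sequences are uppercased and
#' checked against the canonical 20-letter alphabet.
#'
#' @param path Path to a FASTA file.
#' @param on_noncanonical What to do with sequences containing residues
#'   outside [AA_ALPHABET]: `"skip"` drops the record (with a message),
#'   `"mask"` replaces offending residues with `"X"` (encoded downstream as an
#'   all-zero row), `"error"` aborts.
#' @return A `data.frame` with columns `protein_id`, `genome_id`, `sequence`.
#' @seealso [write_protein_fasta()], [slice_tiles()]
#' @export
read_protein_fasta <- function(path, on_noncanonical = c("skip", "mask", "error")) {
  on_noncanonical <- match.arg(on_noncanonical)
  set <- Biostrings::readAAStringSet(path)
  .assert(length(set) > 0L, "no sequences in '%s'", path)
  headers <- names(set)
  protein_id <- sub("\\s.*$", "", headers)
  genome_id <- ifelse(grepl("genome_id=", headers),
                      sub(".*genome_id=(\\S+).*", "\\1", headers), "")
  seqs <- toupper(as.character(set))
  records <- data.frame(protein_id = protein_id, genome_id = genome_id,
                        sequence = seqs, stringsAsFactors = FALSE)
  sanitize_protein_records(records, on_noncanonical)
}

#' @noRd
sanitize_protein_records <- function(records, on_noncanonical = "skip") {
  pat <- sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = ""))
  ok <- nzchar(records$sequence) & grepl(pat, records$sequence)
  if (any(!ok)) {
    bad <- records$protein_id[!ok]
    if (on_noncanonical == "error") {
      stop("non-canonical residues in: ", paste(bad, collapse = ", "),
           call. = FALSE)
    } else if (on_noncanonical == "mask") {
      pat_bad <- sprintf("[^%s]", paste(AA_ALPHABET, collapse = ""))
      records$sequence[!ok] <- gsub(pat_bad, "X", records$sequence[!ok])
      records <- records[nzchar(records$sequence), , drop = FALSE]
    } else {
      message(length(bad), " record(s) with non-canonical residues skipped")
      records <- records[ok, , drop = FALSE]
    }
  }
  .assert(nrow(records) > 0L, "no canonical protein records remain")
  rownames(records) <- NULL
  records
}

#' Write protein records to FASTA
#'
#' @param records A protein record `data.frame` (`protein_id`, `genome_id`,
#'   `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- ifelse(nzchar(records$genome_id),
                       paste0(records$protein_id, " genome_id=", records$genome_id),
                       records$protein_id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Pairwise sequence identity (CD-HIT-like)
#'
#' Identity is the number of exactly matching aligned positions in a global
#' pairwise alignment divided by the length of the shorter sequence. The
#' alignment maximizes matches under a simple scheme (match 2, mismatch -1,
#' gap opening 10, gap extension 0.5), so equal-length sequences differing
#' only by substitutions align without gaps.
#'
#' @param a,b Amino-acid strings.
#' @return Identity fraction in \[0, 1\].
#' @export
sequence_identity <- function(a, b) {
  .assert(nzchar(a) && nzchar(b), "empty sequence")
  mat <- matrix(-1, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  diag(mat) <- 2
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 10, gapExtension = 0.5)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Deduplicate and cluster proteins, keeping one representative per cluster
#'
#' Collapses exact duplicate sequences (first occurrence kept, multiplicity
#' recorded), then clusters the unique sequences greedily, longest first
#' (ties broken by lexicographic `protein_id`): a sequence joins the first
#' existing cluster whose representative it matches at identity >=
#' `identity_threshold`, otherwise it founds a new cluster. This mirrors
#' CD-HIT's greedy longest-first semantics at test scale; see
#' [sequence_identity()] for the identity definition.
#'
#' @param records Protein record `data.frame` with `protein_id`, `sequence`.
#' @param identity_threshold Fraction in (0, 1]; default 0.9.
#' @return A list with `representatives` (subset of `records`) and
#'   `assignment` (`data.frame` mapping every input `protein_id` to its
#'   `representative_id`, with `multiplicity` counting exact duplicates of
#'   each kept sequence).
#' @export
deduplicate_and_represent <- function(records, identity_threshold = 0.9) {
  .assert(is.data.frame(records) && nrow(records) > 0L, "records must be non-empty")
  .assert(is.numeric(identity_threshold) && length(identity_threshold) == 1L &&
            identity_threshold > 0 && identity_threshold <= 1,
          "identity_threshold must be in (0, 1]")
  .assert(!anyDuplicated(records$protein_id), "duplicated protein_id values")

  # exact dedup: first occurrence kept
  first <- !duplicated(records$sequence)
  kept <- records[first, , drop = FALSE]
  kept_id_of_seq <- stats::setNames(kept$protein_id, kept$sequence)
  dup_parent <- kept_id_of_seq[records$sequence]
  multiplicity <- table(dup_parent)

  # greedy longest-first clustering of unique sequences
  o <- order(-nchar(kept$sequence), kept$protein_id)
  kept <- kept[o, , drop = FALSE]
  rep_idx <- integer(0)
  cluster_of <- character(nrow(kept))
  for (i in seq_len(nrow(kept))) {
    assigned <- FALSE
    for (j in rep_idx) {
      if (sequence_identity(kept$sequence[i], kept$sequence[j]) >= identity_threshold) {
        cluster_of[i] <- kept$protein_id[j]
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      rep_idx <- c(rep_idx, i)
      cluster_of[i] <- kept$protein_id[i]
    }
  }
  representatives <- kept[rep_idx, , drop = FALSE]
  rownames(representatives) <- NULL

  cluster_of_kept <- stats::setNames(cluster_of, kept$protein_id)
  assignment <- data.frame(
    protein_id = records$protein_id,
    representative_id = unname(cluster_of_kept[dup_parent]),
    multiplicity = as.integer(multiplicity[dup_parent]),
    stringsAsFactors = FALSE)
  list(representatives = representatives, assignment = assignment)
}

#' Slice a protein into fixed-length tiles
#'
#' Emits windows of `window` residues at starts 0, `stride`, 2 `stride`, ...
#' while the window fits entirely inside the protein (0-based, half-open
#' coordinates). Proteins shorter than the window yield no tiles; trailing
#' residues not covered by a full window are dropped.
#'
#' @param sequence Amino-acid string (or a single-row protein record
#'   `data.frame`).
#' @param window Tile length in residues (default 53).
#' @param stride Offset between consecutive tile starts (default 10).
#' @param parent_id Identifier recorded as the tile's parent (default
#'   `"protein"`, or the record's `protein_id`).
#' @return A `data.frame` with `tile_id`, `parent_id`, `start`, `sequence`,
#'   ordered by `start`. Zero rows for short proteins.
#' @export
slice_tiles <- function(sequence, window = 53L, stride = 10L,
                        parent_id = "protein") {
  if (is.data.frame(sequence)) {
    parent_id <- sequence$protein_id[1L]
    sequence <- sequence$sequence[1L]
  }
  .assert(window >= 1L && stride >= 1L, "window and stride must be >= 1")
  L <- nchar(sequence)
  if (L < window) {
    return(data.frame(tile_id = character(0), parent_id = character(0),
                      start = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  starts <- seq.int(0L, L - window, by = stride)
  data.frame(
    tile_id = sprintf("%s_%d", parent_id, starts),
    parent_id = parent_id,
    start = as.integer(starts),
    sequence = substring(sequence, starts + 1L, starts + window),
    stringsAsFactors = FALSE)
}

#' Tile a set of protein records
#'
#' Applies [slice_tiles()] to every record and binds the results. Proteins
#' shorter than the window are reported via a message and contribute no rows.
#'
#' @inheritParams slice_tiles
#' @param records Protein record `data.frame`.
#' @return Combined tile `data.frame`.
#' @export
tile_proteins <- function(records, window = 53L, stride = 10L) {
  short <- nchar(records$sequence) < window
  if (any(short)) {
    message(sum(short), " protein(s) shorter than the window yield no tiles")
  }
  out <- lapply(seq_len(nrow(records)), function(i) {
    slice_tiles(records$sequence[i], window, stride,
                parent_id = records$protein_id[i])
  })
  do.call(rbind, out)
}

#' Read / write tile tables
#'
#' Tab-separated tile tables with columns `tile_id`, `parent_id`, `start`,
#' `sequence`.
#'
#' @param path File path.
#' @return `read_tile_table()` returns a tile `data.frame`.
#' @export
read_tile_table <- function(path) .read_tsv(path)

#' @rdname read_tile_table
#' @param tiles Tile `data.frame`.
#' @export
write_tile_table <- function(tiles, path) {
  .write_tsv(tiles, path)
  invisible(path)
}
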