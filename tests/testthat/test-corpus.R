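test_that("tile slicing matches brute-force window enumeration for all lengths", {
  set.seed(101)
  for (L in c(1, 52, 53, 54, 62, 63, 73, 100, 499, 500)) {
    seqc <- paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
    tiles <- slice_tiles(seqc, window = 53, stride = 10, parent_id = "p")
    starts_bf <- Filter(function(s) s %% 10 == 0 && s + 53 <= L, 0:max(0, L - 1))
    expect_equal(tiles$start, as.integer(starts_bf))
    expect_equal(nrow(tiles), max(0, floor((L - 53) / 10) + 1))
    expect_true(all(nchar(tiles$sequence) == 53))
    if (nrow(tiles) > 0) {
      expect_equal(tiles$sequence,
                   substring(seqc, tiles$start + 1, tiles$start + 53))
    }
  }
  # closed-form count over the full length range
  for (L in 1:500) {
    n_bf <- sum(vapply(0:max(0, L - 1),
                       function(s) s %% 10 == 0 && s + 53 <= L, logical(1)))
    expect_identical(n_bf, max(0L, as.integer((L - 53) %/% 10) + 1L))
  }
})

test_that("tile slicing handles windows, strides and short proteins", {
  s <- paste(rep("A", 53), collapse = "")
  expect_equal(nrow(slice_tiles(s)), 1L)
  expect_equal(slice_tiles(s)$start, 0L)
  expect_equal(nrow(slice_tiles(substr(s, 1, 52))), 0L)
  t73 <- slice_tiles(paste(rep("AD", 40), collapse = ""), window = 53)
  expect_equal(t73$start, c(0L, 10L, 20L))
  expect_error(slice_tiles("ADA", window = 0), "window")
})

test_that("tiling a record set drops short proteins with a message", {
  recs <- data.frame(protein_id = c("a", "b"), genome_id = "",
                     sequence = c(strrep("A", 80), strrep("C", 20)))
  expect_message(tiles <- tile_proteins(recs), "shorter")
  expect_true(all(tiles$parent_id == "a"))
})

test_that("exact duplicates collapse to the first occurrence with multiplicity", {
  recs <- data.frame(protein_id = c("p1", "p2"), sequence = rep(strrep("ACDEF", 12), 2))
  res <- deduplicate_and_represent(recs, 0.9)
  expect_equal(nrow(res$representatives), 1L)
  expect_equal(res$representatives$protein_id, "p1")
  expect_equal(res$assignment$multiplicity, c(2L, 2L))
  expect_equal(unique(res$assignment$representative_id), "p1")
})

test_that("threshold 1.0 keeps pairwise-distinct sequences apart", {
  set.seed(7)
  recs <- data.frame(protein_id = c("a", "b", "c"),
                     sequence = vapply(1:3, function(i)
                       paste(sample(AA_ALPHABET, 40, TRUE), collapse = ""),
                       character(1)))
  res <- deduplicate_and_represent(recs, 1.0)
  expect_equal(nrow(res$representatives), 3L)
})

test_that("greedy clustering matches all-pairs brute force on a toy set", {
  set.seed(11)
  base <- paste(sample(AA_ALPHABET, 60, TRUE), collapse = "")
  mutate <- function(s, k) {
    pos <- sample(60, k)
    ch <- strsplit(s, "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(AA_ALPHABET, ch[p]), 1)
    paste(ch, collapse = "")
  }
  seqs <- c(base, mutate(base, 3), mutate(base, 5), mutate(base, 30),
            paste(sample(AA_ALPHABET, 60, TRUE), collapse = ""),
            paste(sample(AA_ALPHABET, 60, TRUE), collapse = ""))
  recs <- data.frame(protein_id = paste0("s", 1:6), sequence = seqs)

  # independent oracle: Hamming identity (equal lengths, substitutions only),
  # same greedy longest-first/lexicographic rule
  ident <- function(a, b) {
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  ord <- order(-nchar(seqs), recs$protein_id)
  reps_bf <- integer(0)
  assign_bf <- character(6)
  for (i in ord) {
    hit <- FALSE
    for (j in reps_bf) {
      if (ident(seqs[i], seqs[j]) >= 0.9) { assign_bf[i] <- recs$protein_id[j]; hit <- TRUE; break }
    }
    if (!hit) { reps_bf <- c(reps_bf, i); assign_bf[i] <- recs$protein_id[i] }
  }

  res <- deduplicate_and_represent(recs, 0.9)
  expect_equal(sort(res$representatives$protein_id),
               sort(recs$protein_id[reps_bf]))
  expect_equal(res$assignment$representative_id, assign_bf)
  expect_equal(nrow(res$representatives), 4L)
})

test_that("clustering representatives again is idempotent", {
  set.seed(13)
  recs <- data.frame(protein_id = paste0("p", 1:8),
                     sequence = vapply(1:8, function(i)
                       paste(sample(AA_ALPHABET, 50, TRUE), collapse = ""),
                       character(1)))
  res1 <- deduplicate_and_represent(recs, 0.9)
  res2 <- deduplicate_and_represent(res1$representatives, 0.9)
  expect_equal(res2$representatives$sequence, res1$representatives$sequence)
  expect_equal(res2$assignment$representative_id,
               res2$assignment$protein_id)
})

test_that("clustering validates its inputs", {
  recs <- data.frame(protein_id = "a", sequence = "ACDEF")
  expect_error(deduplicate_and_represent(recs[0, ]), "non-empty")
  expect_error(deduplicate_and_represent(recs, 0), "identity_threshold")
  expect_error(deduplicate_and_represent(recs, 1.2), "identity_threshold")
})

test_that("FASTA round-trip preserves ids, genomes and sequences", {
  recs <- data.frame(protein_id = c("prot1", "prot2"),
                     genome_id = c("gen1", ""),
                     sequence = c(strrep("ACDEFGHIKL", 8), strrep("MNPQRSTVWY", 6)))
  f <- withr::local_tempfile(fileext = ".fa")
  write_protein_fasta(recs, f)
  back <- read_protein_fasta(f)
  expect_equal(back, recs)
})

test_that("non-canonical residues are skipped or masked per configuration", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">good", strrep("ACDEF", 4), ">bad", "ACDXF"), f)
  expect_message(recs <- read_protein_fasta(f), "skipped")
  expect_equal(recs$protein_id, "good")
  masked <- read_protein_fasta(f, on_noncanonical = "mask")
  expect_equal(masked$sequence[masked$protein_id == "bad"], "ACDXF")
  expect_error(read_protein_fasta(f, on_noncanonical = "error"), "non-canonical")
})
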