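sw_scoring <- list(match = 2, mismatch = -4, gap_open = -4, gap_extend = -2)

biostrings_local <- function(a, b) {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = m, gapOpening = 4, gapExtension = 2,
    type = "local"))
}

test_that("smith_waterman matches hand-computed local alignments", {
  expect_equal(smith_waterman("ACGTACGTAC", "ACGTACGTAC")$as_score, 20)
  # best local alignment of ACGT vs AGGT is the GT/GT suffix
  expect_equal(smith_waterman("ACGT", "AGGT")$as_score, 4)
  r <- smith_waterman("AAAACGTAAA", "CGT")
  expect_equal(r$as_score, 6)
  expect_equal(r$query_start, 4)
  expect_equal(r$query_end, 7)
  expect_equal(r$n_match, 3)
  expect_equal(r$block_length, 3)
})

test_that("smith_waterman agrees with an independent local aligner", {
  set.seed(11)
  for (i in 1:30) {
    a <- longamp:::random_dna(sample(5:20, 1))
    b <- longamp:::random_dna(sample(5:20, 1))
    expect_equal(smith_waterman(a, b)$as_score, biostrings_local(a, b),
                 info = paste(a, b))
  }
  for (i in 1:8) {
    a <- longamp:::random_dna(sample(100:300, 1))
    b <- longamp:::random_dna(sample(100:300, 1))
    expect_equal(smith_waterman(a, b)$as_score, biostrings_local(a, b))
  }
  # score is never negative, N never counts as a match
  expect_gte(smith_waterman("AAAA", "TTTT")$as_score, 0)
  expect_equal(smith_waterman("NNNN", "NNNN")$as_score, 0)
})

test_that("minimizer selection matches an R window-minimum oracle", {
  set.seed(4)
  for (L in c(300, 1200)) {
    s <- longamp:::random_dna(L)
    k <- 15; w <- 10
    got <- longamp:::sketch_cpp(s, k, w)
    kh <- longamp:::kmer_hashes_cpp(s, k)
    # oracle: windowed minima over valid k-mer hashes, deduplicated
    m <- nrow(kh)
    sel <- integer(0)
    for (start in seq_len(m - w + 1)) {
      win <- start:(start + w - 1)
      win <- win[kh$valid[win] == 1]
      if (!length(win)) next
      sel <- c(sel, win[which.min(kh$hash[win])])
    }
    sel <- sort(unique(sel))
    expect_equal(got$pos, kh$pos[sel])
    # density is about 2L/(w+1)
    expect_lt(abs(nrow(got) - 2 * L / (w + 1)) / (2 * L / (w + 1)), 0.35)
  }
})

test_that("index build is deterministic and degenerate inputs warn", {
  db <- tiny_refs()
  p <- align_params(band = 100)
  i1 <- build_index(db, p); i2 <- build_index(db, p)
  expect_identical(i1$n_minimizers, i2$n_minimizers)
  # identical duplicate records index identical minimizer sets
  recs <- rbind(reference_record("a", "SpA", "GA", db$records$sequence[1]),
                reference_record("b", "SpA", "GA", db$records$sequence[1]))
  ii <- build_index(reference_db(recs, "16S"), p)
  expect_equal(ii$n_minimizers[1], ii$n_minimizers[2])
  shortrec <- reference_record("s", "SpS", "GS", "ACGTACGT")
  expect_warning(build_index(reference_db(shortrec, "16S"), p), "shorter")
  expect_error(build_index(reference_db(db$records[0, ], "16S"), p), "empty")
})

test_that("reads map to their source reference, matching the exhaustive oracle", {
  db <- tiny_refs()
  p <- align_params(band = 100, min_as = 30)
  idx <- build_index(db, p)
  set.seed(23)
  ok <- 0
  for (i in 1:20) {
    src <- sample(n_records(db), 1)
    read <- noisy_substring(db$records$sequence[src], 1, 400,
                            error_model(0.95))
    hits <- map_read(idx, read, p)
    oracle <- exhaustive_best_ref(read, db)
    expect_gt(nrow(hits), 0)
    if (hits$ref_id[1] %in% oracle$ref_ids &&
        hits$ref_id[1] == db$records$ref_id[src]) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("a read without shared k-mers yields no hits", {
  db <- tiny_refs()
  p <- align_params(band = 100)
  idx <- build_index(db, p)
  expect_equal(nrow(map_read(idx, strrep("AT", 200), p)), 0)
})

test_that("mapping is strand symmetric with forward-read coordinates", {
  db <- tiny_refs()
  p <- align_params(band = 100, min_as = 30)
  idx <- build_index(db, p)
  set.seed(31)
  read <- noisy_substring(db$records$sequence[2], 30, 300, error_model(0.93))
  h1 <- map_read(idx, read, p)
  h2 <- map_read(idx, revcomp(read), p)
  expect_equal(sort(h1$as_score), sort(h2$as_score))
  o1 <- h1[order(h1$ref_id, h1$as_score), ]
  o2 <- h2[order(h2$ref_id, h2$as_score), ]
  expect_equal(o1$ref_id, o2$ref_id)
  expect_true(all(o1$strand != o2$strand))
  # coordinates are reported on the forward read in both cases
  expect_equal(nchar(read) - o1$read_end, o2$read_start)
})

test_that("median top AS never increases with simulated error rate", {
  db <- db_16s_small()
  p <- default_align_params("16S")
  idx <- build_index(db, p)
  for (seed in c(3, 4)) {
    meds <- vapply(c(1, 0.95, 0.89, 0.80), function(acc) {
      sim <- simulate_reads(db, even_design(db_species(db), 30, "16S"),
                            error = error_model(acc), chimera_rate = 0,
                            short_fragment_rate = 0, seed = seed)
      tr <- trim_fixed_ends(sim$reads, 45)$reads
      hits <- best_hits(map_reads(idx, tr, p))
      median(hits$as_score)
    }, numeric(1))
    expect_true(all(diff(meds) <= 0))
  }
})
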