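test_that("synthesized reference sets have marker-scale lengths and are deterministic", {
  db <- db_rrn_small()
  expect_equal(n_records(db), 8)
  expect_true(all(abs(db$records$length - 4300) < 150))
  db16 <- db_16s_small()
  expect_true(all(abs(db16$records$length - 1500) < 100))
  again <- synthesize_reference_set(8, "rrn", seed = 42)
  expect_identical(again$records$sequence, db$records$sequence)
})

test_that("the designated close pair sits at the requested global identity", {
  db <- db_16s_small()
  pa <- Biostrings::pairwiseAlignment(db$records$sequence[1],
                                      db$records$sequence[2], type = "global")
  expect_lt(abs(Biostrings::pid(pa) / 100 - 0.97), 0.005)
  # close pair shares a genus; unrelated species are far more diverged
  expect_equal(db$records$genus[1], db$records$genus[2])
  pa_bg <- Biostrings::pairwiseAlignment(db$records$sequence[3],
                                         db$records$sequence[5], type = "global")
  expect_lt(Biostrings::pid(pa_bg) / 100, 0.9)
})

test_that("infeasible divergence specs are rejected", {
  expect_error(synthesize_reference_set(4, "16S", close_pair_identity = 1.2),
               "infeasible")
  expect_error(synthesize_reference_set(4, "16S", close_pair_identity = 0.5),
               "infeasible")
})

test_that("same seed reproduces FASTQ and truth byte for byte", {
  db <- db_16s_small()
  des <- even_design(db_species(db), 60, "16S")
  s1 <- simulate_reads(db, des, seed = 77)
  s2 <- simulate_reads(db, des, seed = 77)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(s1$reads, f1); write_fastq(s2$reads, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_reads(db, des, seed = 78)
  expect_false(identical(s1$reads$sequence, s3$reads$sequence))
})

test_that("noiseless reads are exact tagged amplicons or their reverse complements", {
  db <- db_16s_small()
  des <- even_design(db_species(db), 40, "16S")
  sim <- simulate_reads(db, des, error = error_model(sub = 0, ins = 0, del = 0),
                        length_jitter = list(sd_frac = 0),
                        chimera_rate = 0, short_fragment_rate = 0, seed = 5)
  seqs <- longamp:::ref_lookup(db, "sequence")
  for (i in seq_len(40)) {
    expected <- paste0(longamp:::TAG5, seqs[[sim$truth$truth_ref_id[i]]],
                       longamp:::TAG3)
    got <- sim$reads$sequence[i]
    if (sim$truth$strand[i] == "-") got <- revcomp(got)
    expect_identical(got, expected)
  }
})

test_that("realized error-event identity matches the analytic expectation", {
  db <- db_16s_small()
  des <- even_design(db_species(db), 150, "16S")
  m <- error_model(0.89)
  expect_equal(m$sub, 0.055)
  expect_equal(m$ins, 0.0275)
  expect_equal(m$del, 0.0275)
  sim <- simulate_reads(db, des, error = m, chimera_rate = 0,
                        short_fragment_rate = 0, seed = 8)
  expect_lt(abs(realized_identity(sim) - expected_identity(m)), 0.005)
})

test_that("chimera counts follow the requested rate", {
  db <- db_16s_small()
  des <- even_design(db_species(db), 2000, "16S")
  sim <- simulate_reads(db, des, chimera_rate = 0.05, seed = 13)
  n_chim <- sum(sim$truth$is_chimera)
  se <- sqrt(2000 * 0.05 * 0.95)
  expect_lt(abs(n_chim - 100), 3 * se)
  # chimeric truth rows carry two reference ids, others one
  expect_true(all(nzchar(sim$truth$truth_ref_id2[sim$truth$is_chimera])))
  expect_true(all(!nzchar(sim$truth$truth_ref_id2[!sim$truth$is_chimera])))
})

test_that("per-species read shares converge to even design weights", {
  db <- db_16s_small()
  des <- even_design(db_species(db), 10000, "16S")
  sim <- simulate_reads(db, des, chimera_rate = 0, short_fragment_rate = 0,
                        seed = 21)
  counts <- table(factor(sim$truth$truth_species, levels = db_species(db)))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("designs validate their members", {
  db <- db_16s_small()
  expect_error(community_design(data.frame(species = character(0),
                                           weight = numeric(0)),
                                "proportion", "16S", 10), "empty")
  expect_error(community_design(data.frame(species = "a", weight = 0.5),
                                "proportion", "16S", 10), "sum to 1")
  bad <- even_design(c(db_species(db)[1], "Species_999"), 10, "16S")
  expect_error(simulate_reads(db, bad, seed = 1), "Species_999")
})

test_that("staggered designs put five species on each copy level", {
  db <- synthesize_reference_set(20, "16S", seed = 5)
  des <- staggered_design(db_species(db), 1000, "16S")
  expect_equal(as.vector(table(des$members$weight)), rep(5L, 4))
  expect_equal(des$weight_kind, "operon_copies")
})

test_that("carryover injection hits the requested fraction and keeps labels", {
  db <- db_16s_small()
  sp <- db_species(db)
  primary <- simulate_reads(db, even_design(sp[1:4], 9400, "16S"), seed = 31,
                            chimera_rate = 0, short_fragment_rate = 0)
  contam <- simulate_reads(db, even_design(sp[5:8], 1000, "16S"), seed = 32,
                           chimera_rate = 0, short_fragment_rate = 0)
  mix <- inject_carryover(primary, contam, 0.06, seed = 33)
  expect_equal(nrow(mix$reads), 10000)
  expect_equal(sum(mix$truth$is_carryover), 600)
  # labels preserved bit-exact through injection
  co <- mix$truth[mix$truth$is_carryover, ]
  orig <- contam$truth[match(sub("^carry_", "", co$read_id),
                             contam$truth$read_id), ]
  expect_equal(co$truth_species, orig$truth_species)
  expect_equal(co$truth_ref_id, orig$truth_ref_id)
  expect_identical(inject_carryover(primary, contam, 0), primary)
  expect_error(inject_carryover(primary, contam, 1), "fraction")
  expect_error(inject_carryover(primary, contam, 0.9), "too small")
})
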