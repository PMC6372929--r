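mk_table <- function(counts) {
  tab <- data.frame(taxon = names(counts), read_count = as.integer(counts),
                    relative_abundance = as.numeric(counts) / sum(counts),
                    stringsAsFactors = FALSE)
  attr(tab, "rank") <- "species"
  attr(tab, "total_classified") <- sum(tab$read_count)
  tab
}

test_that("detection reports split truth into detected, missed and off-target", {
  truth <- mock_truth(data.frame(species = c("A", "B", "C"),
                                 expected_value = c(1e3, 1e4, 1e5)))
  rep1 <- detection_report(mk_table(c(A = 5, B = 1, D = 2)), truth)
  expect_setequal(rep1$detected, c("A", "B"))
  expect_equal(rep1$missed, "C")
  expect_equal(rep1$false_positives, "D")
  # min_reads raises the bar
  rep2 <- detection_report(mk_table(c(A = 5, B = 1)), truth, min_reads = 2)
  expect_equal(rep2$detected, "A")
  # empty table: everything missed
  rep3 <- detection_report(mk_table(c(A = 1))[0, ], truth)
  expect_setequal(rep3$missed, c("A", "B", "C"))
})

test_that("log-log regression recovers exact proportionality and flat profiles", {
  truth <- mock_truth(data.frame(species = letters[1:5],
                                 expected_value = 10^(1:5)))
  prop <- mk_table(stats::setNames(10^(1:5), letters[1:5]))
  r <- abundance_regression(prop, truth)
  expect_equal(r$slope, 1, tolerance = 1e-9)
  expect_equal(r$r_squared, 1, tolerance = 1e-9)
  flat <- mk_table(stats::setNames(rep(100, 5), letters[1:5]))
  expect_equal(abundance_regression(flat, truth)$slope, 0, tolerance = 1e-9)
  # zero-count species are excluded and too few points are an error
  some <- mk_table(stats::setNames(c(10, 100), letters[1:2]))
  expect_error(abundance_regression(some, truth), ">= 3")
})

test_that("read accuracy distinguishes unconditional from conditional", {
  truth <- data.frame(read_id = sprintf("r%d", 1:10),
                      truth_species = "SpeciesX", truth_ref_id = "refA",
                      is_chimera = FALSE, is_carryover = FALSE,
                      stringsAsFactors = FALSE)
  a <- data.frame(read_id = sprintf("r%d", 1:10),
                  status = rep(c("assigned", "ambiguous"), each = 5),
                  species = c(rep("SpeciesX", 5), rep("", 5)),
                  genus = "GenusX", as_score = 1L, n_best_ties = 1L,
                  stringsAsFactors = FALSE)
  acc <- read_accuracy(a, truth)
  expect_equal(acc$species_unconditional, 0.5)
  expect_equal(acc$species_conditional, 1.0)
  # chimeric/carryover truth reads are excluded from the denominator
  truth2 <- truth; truth2$is_chimera[6:10] <- TRUE
  acc2 <- read_accuracy(a, truth2)
  expect_equal(acc2$species_unconditional, 1.0)
  expect_error(read_accuracy(rbind(a, a[1, ]) -> aa, truth[1:3, ]), "missing")
})

test_that("carryover estimation sums contaminant-only taxa", {
  tab <- mk_table(c(A = 470, B = 470, C = 30, D = 30))
  expect_equal(carryover_estimate(tab, c("C", "D")), 0.06, ignore_attr = TRUE)
  expect_equal(carryover_estimate(tab, c("E", "F")), 0, ignore_attr = TRUE)
  expect_warning(est <- carryover_estimate(tab, c("C", "A"),
                                           sample_taxa = c("A", "B")),
                 "excluded: A")
  expect_equal(est, 0.03, ignore_attr = TRUE)
  expect_warning(est2 <- carryover_estimate(tab, c("A", "B"),
                                            sample_taxa = c("A", "B")))
  expect_equal(est2, 0, ignore_attr = TRUE)
})

test_that("assignment accuracy is antitone in the simulated error rate", {
  db <- db_16s_small()
  accs <- vapply(c(1, 0.95, 0.89, 0.80), function(target) {
    sim <- simulate_reads(db, even_design(db_species(db), 120, "16S"),
                          error = error_model(target), chimera_rate = 0,
                          short_fragment_rate = 0, seed = 61)
    res <- profile_reads(sim$reads, db, run_config("16S"))
    read_accuracy(res$assignments, sim$truth, db)$species_unconditional
  }, numeric(1))
  expect_true(all(diff(accs) <= 1e-9))
})
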