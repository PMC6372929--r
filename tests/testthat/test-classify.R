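two_species_db <- function() {
  recs <- rbind(
    reference_record("refA", "SpeciesX", "GenusX", strrep("ACGT", 400)),
    reference_record("refA2", "SpeciesX", "GenusX", strrep("ACGT", 400)),
    reference_record("refB", "SpeciesY", "GenusX", strrep("TGCA", 400)),
    reference_record("refC", "SpeciesZ", "GenusZ", strrep("GGCA", 400)))
  reference_db(recs, "16S")
}

test_that("block-length filtering is inclusive at the marker threshold", {
  h <- rbind(make_hit("r1", "refA", 100, block_length = 999),
             make_hit("r2", "refA", 100, block_length = 1000))
  expect_equal(filter_hits(h, "16S")$read_id, "r2")
  h2 <- rbind(make_hit("r1", "refA", 100, block_length = 2999),
              make_hit("r2", "refA", 100, block_length = 3000),
              make_hit("r3", "refA", 100, block_length = 4100))
  expect_equal(filter_hits(h2, "rrn")$read_id, c("r2", "r3"))
  expect_equal(nrow(filter_hits(h[0, ], "16S")), 0)
  expect_error(filter_hits(h, "ITS"), "ITS")
})

test_that("the best-AS rule assigns the top-scoring species", {
  db <- two_species_db()
  h <- rbind(make_hit("r1", "refA", 500), make_hit("r1", "refB", 400))
  a <- assign_read(h, db)
  expect_equal(a$status, "assigned")
  expect_equal(a$species, "SpeciesX")
  expect_equal(a$as_score, 500)
  expect_equal(a$n_best_ties, 1)
})

test_that("ties within one species assign it; cross-species ties follow policy", {
  db <- two_species_db()
  same <- rbind(make_hit("r1", "refA", 500), make_hit("r1", "refA2", 500))
  a <- assign_read(same, db)
  expect_equal(a$status, "assigned")
  expect_equal(a$species, "SpeciesX")
  expect_equal(a$n_best_ties, 2)
  # same genus: LCA resolves to genus, status stays ambiguous
  lca <- rbind(make_hit("r1", "refA", 500), make_hit("r1", "refB", 500))
  a2 <- assign_read(lca, db)
  expect_equal(a2$status, "ambiguous")
  expect_equal(a2$species, "")
  expect_equal(a2$genus, "GenusX")
  # different genera: no LCA at genus
  cross <- rbind(make_hit("r1", "refA", 500), make_hit("r1", "refC", 500))
  a3 <- assign_read(cross, db)
  expect_equal(a3$status, "ambiguous")
  expect_equal(a3$genus, "")
  # drop_ambiguous never resolves
  a4 <- assign_read(lca, db, classify_params(tie_policy = "drop_ambiguous"))
  expect_equal(a4$genus, "")
  # no hits at all
  a5 <- assign_read(lca[0, ], db, read_id = "r9")
  expect_equal(a5$status, "unassigned")
})

test_that("assign_reads partitions every read into exactly one status", {
  db <- two_species_db()
  raw <- rbind(make_hit("r1", "refA", 500),
               make_hit("r2", "refA", 90, block_length = 500),
               make_hit("r4", "refA", 200), make_hit("r4", "refB", 200))
  flags <- data.frame(read_id = c("r1", "r2", "r3", "r4", "r5"),
                      status = c("clean", "clean", "uncovered", "clean", "chimeric"),
                      stringsAsFactors = FALSE)
  filt <- filter_hits(raw, "16S")
  a <- assign_reads(filt, db, read_ids = sprintf("r%d", 1:5),
                    raw_hits = raw, chimera_flags = flags)
  expect_equal(nrow(a), 5)
  expect_equal(a$status[a$read_id == "r1"], "assigned")
  expect_equal(a$status[a$read_id == "r2"], "filtered_block")
  expect_equal(a$status[a$read_id == "r3"], "uncovered")
  expect_equal(a$status[a$read_id == "r4"], "ambiguous")
  expect_equal(a$status[a$read_id == "r5"], "chimeric")
  expect_equal(sum(table(a$status)), 5)
})

test_that("abundance tables normalize over classified reads", {
  a <- data.frame(read_id = sprintf("r%d", 1:100),
                  status = "assigned",
                  species = rep(c("X", "Y"), each = 50),
                  genus = rep(c("GX", "GY"), each = 50),
                  as_score = 100L, n_best_ties = 1L, stringsAsFactors = FALSE)
  tab <- abundance_table(a, "species")
  expect_equal(sort(tab$relative_abundance), c(0.5, 0.5))
  expect_equal(attr(tab, "total_classified"), 100L)
  expect_equal(sum(tab$relative_abundance), 1)
  # genus rank counts LCA-resolved ambiguous reads too
  a$status[1:10] <- "ambiguous"; a$species[1:10] <- ""
  tabs <- abundance_table(a, "species")
  expect_equal(attr(tabs, "total_classified"), 90L)
  tabg <- abundance_table(a, "genus")
  expect_equal(attr(tabg, "total_classified"), 100L)
  # zero assigned reads: empty table, not an error
  empty <- abundance_table(a[a$status == "none", ], "species")
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "total_classified"), 0L)
})

test_that("rarefaction curves behave at the boundaries and are monotone", {
  a <- data.frame(read_id = sprintf("r%d", 1:200), status = "assigned",
                  species = sample(c("A", "B", "C", "D"), 200, replace = TRUE),
                  genus = "G", as_score = 1L, n_best_ties = 1L,
                  stringsAsFactors = FALSE)
  rc <- rarefaction_curve(a, c(10, 50, 200), replicates = 20, seed = 3)
  expect_equal(rc$mean_taxa[rc$depth == 200], length(unique(a$species)))
  expect_true(all(diff(rc$mean_taxa) >= 0))
  one <- a; one$species <- "A"
  rc1 <- rarefaction_curve(one, c(5, 50), seed = 3)
  expect_true(all(rc1$mean_taxa == 1))
  expect_warning(rarefaction_curve(a, c(10, 500), seed = 3), "exceeding")
  # determinism
  expect_identical(rarefaction_curve(a, c(10, 50), seed = 9),
                   rarefaction_curve(a, c(10, 50), seed = 9))
})
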