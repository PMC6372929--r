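test_that("FASTA load/write round trip preserves records and lineages", {
  db <- synthesize_reference_set(4, "16S", seed = 3)
  path <- tempfile(fileext = ".fasta")
  write_reference_fasta(db, path)
  db2 <- load_reference_fasta(path, "16S")
  expect_equal(n_records(db2), 4)
  expect_equal(db2$records$ref_id, db$records$ref_id)
  expect_equal(db2$records$sequence, db$records$sequence)
  expect_equal(db2$records$lineage, db$records$lineage)
  expect_equal(length(db_species(db2)), 4)
  # taxon_index covers every species
  expect_setequal(names(db2$taxon_index$species), db$records$species)
})

test_that("duplicate ref_id and missing taxonomy are rejected", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">dup1|genus=G;species=G s1", "ACGTACGTACGT",
               ">dup1|genus=G;species=G s2", "ACGTACGTACGT"), path)
  expect_error(load_reference_fasta(path, "16S"), "dup1")
  path2 <- tempfile(fileext = ".fasta")
  writeLines(c(">r1|genus=G", "ACGT"), path2)
  expect_error(load_reference_fasta(path2, "16S"), "species")
})

test_that("excluding a taxon removes exactly its records", {
  db <- db_rrn_small()
  tax <- export_taxonomy(db)
  # class 2 groups three one-species genera
  in_class <- tax$ref_id[tax$class == "Class_02"]
  expect_length(in_class, 3)
  sub <- subset_excluding_taxon(db, "class", "Class_02")
  expect_equal(n_records(sub), n_records(db) - length(in_class))
  expect_false(any(in_class %in% sub$records$ref_id))
  # partition invariant
  expect_equal(n_records(sub) + length(in_class), n_records(db))
  # original db unchanged
  expect_equal(n_records(db), 8)
  # zero records remain at the excluded taxon
  expect_null(sub$taxon_index$class[["Class_02"]])
})

test_that("excluding an absent taxon is a no-op with a notice", {
  db <- db_16s_small()
  expect_message(sub <- subset_excluding_taxon(db, "class", "NoSuchClass"),
                 "unchanged")
  expect_identical(sub$records, db$records)
  expect_error(subset_excluding_taxon(db, "superkingdom", "Bacteria"),
               "not present")
})

test_that("excluding the class of all records empties the db with a warning", {
  db <- db_16s_small()
  tax <- export_taxonomy(db)
  only <- reference_db(db$records[tax$class == "Class_02", ], "16S")
  expect_warning(sub <- subset_excluding_taxon(only, "class", "Class_02"),
                 "every record")
  expect_equal(n_records(sub), 0)
})

test_that("add_reference appends records and composes with subsetting", {
  db <- db_16s_small()
  n0 <- n_records(db)
  sp0 <- length(db_species(db))
  rec <- reference_record("newref", "Species_new", "Genus_new",
                          longamp:::random_dna(1500),
                          lineage = c(domain = "Bacteria", class = "Class_99",
                                      genus = "Genus_new",
                                      species = "Species_new"))
  db2 <- add_reference(db, rec)
  expect_equal(n_records(db2), n0 + 1)
  expect_equal(length(db_species(db2)), sp0 + 1)
  # second operon of an existing species: record +1, species unchanged
  rec2 <- reference_record("op2", db$records$species[1], db$records$genus[1],
                           db$records$sequence[1],
                           lineage = db$records$lineage[[1]])
  db3 <- add_reference(db2, rec2)
  expect_equal(n_records(db3), n0 + 2)
  expect_equal(length(db_species(db3)), sp0 + 1)
  # duplicate id rejected
  expect_error(add_reference(db2, rec), "newref")
  # add then exclude its class removes it again
  db4 <- subset_excluding_taxon(db2, "class", "Class_99")
  expect_false("newref" %in% db4$records$ref_id)
})

test_that("records validate sequence alphabet and taxonomy fields", {
  expect_error(reference_record("x", "s", "g", "ACGTX"), "outside")
  expect_error(reference_record("x", "", "g", "ACGT"), "non-empty")
  expect_silent(reference_record("x", "s", "g", "ACGTN"))
})
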