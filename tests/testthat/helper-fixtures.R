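# Shared fixtures, memoised so expensive simulations are built once per
# test run. Everything is generated in code from fixed seeds.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

db_16s_small <- function() fixture("db_16s_small",
  synthesize_reference_set(8, "16S", seed = 42))

db_16s_pair <- function() fixture("db_16s_pair",
  synthesize_reference_set(10, "16S", seed = 101))

db_rrn_small <- function() fixture("db_rrn_small",
  synthesize_reference_set(8, "rrn", seed = 42))

# random references without marker structure, for aligner micro-tests
tiny_refs <- function(n = 6, len = 400, seed = 9) {
  fixture(sprintf("tiny_refs_%d_%d_%d", n, len, seed), {
    set.seed(seed)
    recs <- do.call(rbind, lapply(seq_len(n), function(i)
      reference_record(sprintf("tiny%02d", i), sprintf("TinySp_%02d", i),
                       sprintf("TinyGen_%02d", i), longamp:::random_dna(len))))
    reference_db(recs, "16S")
  })
}

# a read drawn from one reference with a given error level
noisy_substring <- function(refseq, start, len, model) {
  as.character(mutate_sequence(substr(refseq, start, start + len - 1), model))
}

# exhaustive Smith-Waterman over every reference and both strands
exhaustive_best_ref <- function(read, db,
                                scoring = list(match = 2, mismatch = -4,
                                               gap_open = -4, gap_extend = -2)) {
  scores <- vapply(seq_len(n_records(db)), function(i) {
    s <- db$records$sequence[i]
    max(smith_waterman(read, s, scoring)$as_score,
        smith_waterman(revcomp(read), s, scoring)$as_score)
  }, numeric(1))
  list(ref_ids = db$records$ref_id[scores == max(scores)], score = max(scores))
}

# minimal hit-table row constructor for classification tests
make_hit <- function(read_id, ref_id, as_score, block_length = 1500,
                     read_start = 0, read_end = 1400, strand = "+") {
  data.frame(read_id = read_id, ref_id = ref_id, strand = strand,
             read_start = read_start, read_end = read_end,
             ref_start = 0L, ref_end = read_end - read_start,
             block_length = block_length,
             n_match = round(block_length * 0.9), as_score = as_score,
             identity = 0.9, stringsAsFactors = FALSE)
}
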