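# longamp

Mapping-based taxonomic profiling of noisy long amplicon reads of two
ribosomal markers: the full-length 16S rRNA gene (~1.5 kb) and the
16S-ITS-23S region of the rrn operon (~4.3 kb). It is aimed at
microbiome researchers who want species-level community profiles from
nanopore-class reads (~89% accuracy) by mapping against a taxonomically
labelled reference set, and at method developers who need a controlled,
fully simulated test bed for that kind of pipeline.

## The method

For each read the pipeline:

1. trims 45 bp from each end (universal tags + custom primers);
2. keeps reads of 1,200–1,800 bp (16S) or 3,500–5,000 bp (rrn), inclusive;
3. maps the read against the reference database with a minimizer
   seed–chain–extend aligner (k = 15, w = 10; match +2 / mismatch −4 /
   gap open −4 / gap extend −2; z-drop 70) producing local alignments
   with Smith–Waterman-style AS scores;
4. flags chimeras as reads whose coverage profile has an internal
   uncovered gap between two covered intervals, and drops them;
5. keeps hits with alignment block ≥ 1,000 bp (16S) or ≥ 3,000 bp (rrn);
6. assigns the read to the species of the hit with the highest AS score;
   cross-species ties resolve to a genus-level LCA or are dropped;
7. reports species/genus abundance tables, rarefaction curves,
   database-completeness diagnostics (block/AS histograms, bimodality
   flags, paired full-vs-subset database comparisons) and
   mock-community evaluation metrics (detection, log–log abundance
   regression, per-read accuracy, carryover estimation).

A first-class simulator generates taxonomically labelled synthetic
reference sets (conserved/variable marker mosaics with one designated
~97%-identity close-relative pair), nanopore-like reads with truth
labels (substitution/insertion/deletion errors, chimeras, short
fragments, strand flips), and carryover contamination — so the entire
pipeline is testable without any real sequencing data.

## Worked example

```r
library(longamp)

db     <- synthesize_reference_set(10, "16S", seed = 1)   # 10 species, one ~97% pair
design <- even_design(db_species(db)[c(1, 3, 5, 7)], 400, "16S")
sim    <- simulate_reads(db, design, seed = 2)            # reads + truth labels
res    <- profile_reads(sim$reads, db, run_config("16S"))

res$stats$classification
#>       assigned      ambiguous     unassigned filtered_block       chimeric
#>            369              0              0              0              8
#>      uncovered
#>              0

res$abundance_species
#>         taxon read_count relative_abundance
#> 1 Species_007        105          0.2845528
#> 2 Species_003         94          0.2547425
#> 3 Species_005         91          0.2466125
#> 4 Species_001         79          0.2140921

read_accuracy(res$assignments, sim$truth, db)$species_conditional
#> [1] 1
```

Of 400 simulated reads, 377 pass trimming and length selection (the
rest are simulated short fragments), the coverage-gap detector removes
the 8 simulated chimeras, and all 369 assigned reads hit their true
species — including
reads from `Species_001`, whose ~97%-identical relative sits in the
database as a decoy — and the four community members come out near the
even 25% design proportions.

A thin command-line wrapper over the same functions ships in
`inst/scripts/longamp.R` with `simulate`, `makedb`, `classify`,
`diagnose` and `evaluate` subcommands.

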