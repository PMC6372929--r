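# Pipeline orchestration: trim -> length filter -> map -> chimera filter
# -> block filter -> assign -> community tables, with per-stage counts
# and deterministic, serializable configuration.

#' Pipeline run configuration
#'
#' @param marker `"16S"` or `"rrn"`
#' @param reads_path input FASTQ path (may be `NULL` when reads are passed
#'   in memory)
#' @param db_path reference FASTA path (may be `NULL` when the database is
#'   passed in memory)
#' @param outdir output directory
#' @param preprocess a [preprocess_params()]
#' @param align an [align_params()]
#' @param chimera list(min_cov, min_internal_gap, min_covered_fraction)
#' @param classify a [classify_params()]
#' @param diagnose list(bins, prominence)
#' @param seed integer seed recorded in the manifest
#' @return a `run_config`
#' @export
run_config <- function(marker = c("rrn", "16S"), reads_path = NULL,
                       db_path = NULL, outdir = tempfile("longamp_run_"),
                       preprocess = preprocess_params(),
                       align = default_align_params(marker),
                       chimera = list(min_cov = 1, min_internal_gap = 50,
                                      min_covered_fraction = 0.8),
                       classify = classify_params(),
                       diagnose = list(bins = 50, prominence = 0.05),
                       seed = 1) {
  marker <- match.arg(marker)
  structure(list(marker = marker, reads_path = reads_path, db_path = db_path,
                 outdir = outdir, preprocess = preprocess, align = align,
                 chimera = chimera, classify = classify, diagnose = diagnose,
                 seed = seed,
                 version = as.character(utils::packageVersion("longamp"))),
            class = "run_config")
}

#' Run the profiling stages in memory
#'
#' Executes trim, length selection, mapping, chimera flagging, block
#' filtering and assignment on a read table, returning every intermediate
#' product plus stage-level counts. Read counts are conserved at every
#' stage: input = kept + each discard category.
#'
#' @param reads data.frame with read_id, sequence (and optionally quality)
#' @param db a `reference_db`
#' @param config a [run_config()]
#' @return list with trimmed reads, hits, filtered hits, chimera flags,
#'   assignments, abundance tables and a `stats` list
#' @export
profile_reads <- function(reads, db, config = run_config(db$marker)) {
  if (!nrow(reads)) stopf("preprocess stage: no input reads")
  marker <- config$marker
  tr <- trim_fixed_ends(reads, config$preprocess$end_trim_bp)
  lf <- filter_by_length(tr$reads, marker, config$preprocess)
  kept <- lf$reads
  stats <- list(
    input = nrow(reads),
    trim = c(input = nrow(reads), kept = nrow(tr$reads),
             rejected = nrow(tr$rejected)),
    length_filter = lf$stats)
  if (!nrow(kept)) stopf("length-filter stage: no reads left")
  idx <- build_index(db, config$align)
  hits <- map_reads(idx, kept, config$align)
  read_lengths <- stats::setNames(nchar(kept$sequence), kept$read_id)
  profiles <- coverage_profiles(hits, read_lengths, config$chimera$min_cov)
  flags <- detect_chimeras(profiles, config$chimera$min_internal_gap,
                           config$chimera$min_covered_fraction)
  stats$chimera <- c(table(factor(flags$status,
                                  levels = c("clean", "chimeric", "uncovered"))))
  clean_ids <- flags$read_id[flags$status == "clean"]
  clean_hits <- hits[hits$read_id %in% clean_ids, , drop = FALSE]
  fhits <- filter_hits(clean_hits, marker, config$classify)
  assignments <- assign_reads(fhits, db, config$classify,
                              read_ids = kept$read_id, raw_hits = hits,
                              chimera_flags = flags)
  stats$classification <- c(table(factor(
    assignments$status,
    levels = c("assigned", "ambiguous", "unassigned", "filtered_block",
               "chimeric", "uncovered"))))
  list(reads = kept, hits = hits, filtered_hits = fhits, flags = flags,
       assignments = assignments,
       abundance_species = abundance_table(assignments, "species"),
       abundance_genus = abundance_table(assignments, "genus"),
       index = idx, stats = stats)
}

serialize_config <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip)
    else if (!is.null(names(x))) as.list(x)  # keep names through JSON
    else x
  }
  strip(config)
}

#' Run the full pipeline and write its artifacts
#'
#' Reads and references are loaded from the configured paths unless given
#' in memory. Every stage writes its artifact (TSV) into `config$outdir`
#' together with a machine-readable run manifest (JSON) holding stage
#' counts, the serialized configuration, the package version and the
#' seed. Rerunning with the same config and inputs is byte-identical.
#'
#' @param config a [run_config()]
#' @param reads optional in-memory read data.frame (else `reads_path`)
#' @param db optional in-memory `reference_db` (else `db_path`)
#' @return the [profile_reads()] result, invisibly, with `outdir` attached
#' @export
run_pipeline <- function(config, reads = NULL, db = NULL) {
  if (is.null(reads)) {
    if (is.null(config$reads_path)) stopf("preprocess stage: no reads given")
    reads <- read_fastq(config$reads_path)
  }
  if (is.null(db)) {
    if (is.null(config$db_path)) stopf("makedb stage: no database given")
    db <- load_reference_fasta(config$db_path, config$marker)
  }
  res <- profile_reads(reads, db, config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  write_tsv(res$hits, out("hits.tsv"))
  write_tsv(res$flags, out("chimera_flags.tsv"))
  write_tsv(res$assignments, out("assignments.tsv"))
  write_tsv(res$abundance_species, out("abundance_species.tsv"))
  write_tsv(res$abundance_genus, out("abundance_genus.tsv"))
  stage_counts <- data.frame(
    stage = c("input", "trimmed", "length_kept", "clean", "assigned"),
    reads = c(res$stats$input, unname(res$stats$trim["kept"]),
              unname(res$stats$length_filter["kept"]),
              unname(res$stats$chimera["clean"]),
              unname(res$stats$classification["assigned"])))
  write_tsv(stage_counts, out("stage_counts.tsv"))
  manifest <- list(config = serialize_config(config),
                   stats = res$stats, seed = config$seed,
                   version = config$version)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  attr(res, "outdir") <- config$outdir
  invisible(res)
}
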