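# Scoring pipeline output against mock-community truth: detection,
# abundance-vs-expectation regression, per-read accuracy, carryover
# quantification.

#' Mock community truth table
#'
#' @param members data.frame with `species` and `expected_value`
#' @param value_kind `"operon_copies"` or `"proportion_16S_content"`
#' @return a `mock_truth`
#' @export
mock_truth <- function(members,
                       value_kind = c("operon_copies", "proportion_16S_content")) {
  value_kind <- match.arg(value_kind)
  if (any(members$expected_value <= 0)) stopf("expected values must be > 0")
  if (anyDuplicated(members$species)) stopf("duplicate species in truth")
  structure(list(members = members, value_kind = value_kind),
            class = "mock_truth")
}

#' Truth from a community design
#' @param design a [community_design()]
#' @return a `mock_truth` with the design weights as expected values
#' @export
design_truth <- function(design) {
  mock_truth(data.frame(species = design$members$species,
                        expected_value = design$members$weight,
                        stringsAsFactors = FALSE),
             value_kind = if (design$weight_kind == "operon_copies")
               "operon_copies" else "proportion_16S_content")
}

#' Detection report against a truth table
#'
#' A species counts as detected when its read count reaches `min_reads`;
#' observed taxa absent from the truth are reported as false positives.
#'
#' @param table an [abundance_table()] at species rank
#' @param truth a [mock_truth()]
#' @param min_reads detection threshold in reads
#' @return list(detected, missed, false_positives)
#' @export
detection_report <- function(table, truth, min_reads = 1) {
  counts <- stats::setNames(table$read_count, table$taxon)
  expected <- truth$members$species
  obs <- counts[expected]
  obs[is.na(obs)] <- 0
  detected <- expected[obs >= min_reads]
  list(detected = detected,
       missed = setdiff(expected, detected),
       false_positives = setdiff(table$taxon[table$read_count >= min_reads],
                                 expected))
}

#' Log-log regression of observed proportions on expected values
#'
#' Ordinary least squares of `log10(observed proportion)` on
#' `log10(expected value)`; species with zero observed reads are excluded
#' (not pseudo-counted) and reported. With observed proportions exactly
#' proportional to expected copies the slope is 1 and R-squared 1.
#'
#' @param table an [abundance_table()] at species rank
#' @param truth a [mock_truth()]
#' @return list(slope, intercept, r_squared, n_points, excluded)
#' @export
abundance_regression <- function(table, truth) {
  counts <- stats::setNames(table$relative_abundance, table$taxon)
  obs <- counts[truth$members$species]
  use <- !is.na(obs) & obs > 0
  excluded <- truth$members$species[!use]
  if (sum(use) < 3)
    stopf("need >= 3 species with nonzero observed proportion (have %d)",
          sum(use))
  x <- log10(truth$members$expected_value[use])
  y <- log10(obs[use])
  fit <- stats::lm(y ~ x)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n_points = sum(use), excluded = excluded)
}

#' Per-read assignment accuracy against simulator truth
#'
#' Computed over truth reads that are neither chimeric nor carryover.
#' The unconditional denominator counts reads that reached classification
#' (statuses assigned, ambiguous, unassigned and filtered_block); the
#' conditional accuracy divides by assigned reads only and is the figure
#' comparable to published assignment percentages, which are computed
#' over classified reads.
#'
#' @param assignments data.frame from [assign_reads()]
#' @param truth truth data.frame from [simulate_reads()]
#' @param db `reference_db` used to map species to genus
#' @return list with species/genus accuracies, unconditional and
#'   conditional, plus denominators
#' @export
read_accuracy <- function(assignments, truth, db = NULL) {
  missing <- setdiff(assignments$read_id, truth$read_id)
  if (length(missing))
    stopf("reads missing from truth: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  m <- match(assignments$read_id, truth$read_id)
  tr <- truth[m, , drop = FALSE]
  eval_mask <- !tr$is_chimera & !tr$is_carryover
  a <- assignments[eval_mask, , drop = FALSE]
  tr <- tr[eval_mask, , drop = FALSE]
  denom_mask <- a$status %in% c("assigned", "ambiguous", "unassigned",
                                "filtered_block")
  assigned <- a$status == "assigned"
  correct_sp <- assigned & a$species == tr$truth_species
  genus_of <- if (!is.null(db)) {
    g <- db$records$genus[match(db$records$species, db$records$species)]
    stats::setNames(db$records$genus, db$records$species)
  } else NULL
  res <- list(
    species_unconditional = if (sum(denom_mask)) sum(correct_sp) / sum(denom_mask) else NA_real_,
    species_conditional = if (sum(assigned)) sum(correct_sp) / sum(assigned) else NA_real_,
    n_evaluated = sum(denom_mask), n_assigned = sum(assigned))
  if (!is.null(genus_of)) {
    truth_gen <- unname(genus_of[tr$truth_species])
    has_gen <- a$status %in% c("assigned", "ambiguous") & nzchar(a$genus)
    correct_gen <- has_gen & a$genus == truth_gen
    res$genus_unconditional <- if (sum(denom_mask)) sum(correct_gen) / sum(denom_mask) else NA_real_
    res$genus_conditional <- if (sum(has_gen)) sum(correct_gen) / sum(has_gen) else NA_real_
  }
  res
}

#' Estimate carryover contamination from a community profile
#'
#' Sums the relative abundance of taxa attributable only to the previous
#' run. Contaminant taxa that also belong to the expected sample are
#' flagged, excluded, and reported (their reads cannot be attributed).
#'
#' @param table an [abundance_table()] at species rank
#' @param contaminant_taxa taxa of the contaminating (previous) run
#' @param sample_taxa expected taxa of the current sample (used to detect
#'   overlap; optional)
#' @return the estimated contaminant fraction, with attribute
#'   `excluded_overlap`
#' @export
carryover_estimate <- function(table, contaminant_taxa, sample_taxa = NULL) {
  overlap <- if (is.null(sample_taxa)) character(0)
             else intersect(contaminant_taxa, sample_taxa)
  if (length(overlap))
    warnf("contaminant taxa also expected in the sample, excluded: %s",
          paste(overlap, collapse = ", "))
  use <- setdiff(contaminant_taxa, overlap)
  est <- sum(table$relative_abundance[table$taxon %in% use])
  attr(est, "excluded_overlap") <- overlap
  est
}
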