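# Database-completeness diagnostics. When reads lack a reference, their
# best alignments shrink (shorter blocks, lower AS); histograms of the
# winning hit's block length or AS then shift from a single full-length
# peak to a bimodal shape, and paired full-vs-subset comparisons show the
# per-read score drop directly.

#' Best hit per read
#'
#' @param hits hit data.frame
#' @return one row per read: the hit with maximal AS (ties broken by
#'   ref_id, then leftmost ref_start)
#' @export
best_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  ord <- order(hits$read_id, -hits$as_score, hits$ref_id, hits$ref_start)
  h <- hits[ord, , drop = FALSE]
  out <- h[!duplicated(h$read_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Histogram of a per-read alignment metric
#'
#' @param hits best-per-read hits (a multi-hit table is reduced with
#'   [best_hits()] first)
#' @param metric `"block_length"` or `"as_score"`
#' @param bins number of equal-width bins over `[0, max]`, or a numeric
#'   vector of bin edges
#' @return a `score_histogram`: list(metric, bin_edges, counts, n_reads)
#' @export
score_distributions <- function(hits, metric = c("block_length", "as_score"),
                                bins = 50) {
  metric <- match.arg(metric)
  if (!nrow(hits)) stopf("no hits to diagnose")
  hits <- best_hits(hits)
  x <- hits[[metric]]
  edges <- if (length(bins) > 1) bins else seq(0, max(x) * 1.001,
                                               length.out = bins + 1)
  counts <- as.integer(table(cut(x, edges, include.lowest = TRUE, right = FALSE)))
  structure(list(metric = metric, bin_edges = edges, counts = counts,
                 n_reads = nrow(hits)), class = "score_histogram")
}

#' @export
print.score_histogram <- function(x, ...) {
  cat(sprintf("score_histogram of %s: %d reads in %d bins\n",
              x$metric, x$n_reads, length(x$counts)))
  invisible(x)
}

#' Export a histogram as TSV (bin_start, bin_end, count)
#' @param hist a `score_histogram`
#' @param path output path
#' @return the data.frame, invisibly
#' @export
write_histogram <- function(hist, path = NULL) {
  df <- data.frame(bin_start = hist$bin_edges[-length(hist$bin_edges)],
                   bin_end = hist$bin_edges[-1], count = hist$counts)
  if (!is.null(path)) write_tsv(df, path)
  invisible(df)
}

moving_average <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - k %/% 2); hi <- min(n, i + k %/% 2)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Flag database incompleteness from a score histogram
#'
#' Modes are located on a smoothed histogram (moving average over
#' `smooth` bins). The distribution is called bimodal when at least two
#' modes each hold `prominence` of the total mass and are separated by a
#' valley no higher than half the smaller peak; a complete database gives
#' a single (typically left-skewed) full-length peak, while missing
#' references add a second peak at low values.
#'
#' @param hist a `score_histogram`
#' @param block_threshold metric threshold below which reads are counted
#'   in `low_mode_mass_below_threshold`
#' @param prominence minimal mass fraction per mode
#' @param smooth moving-average window in bins
#' @return a `completeness_report`: list(metric, modes (location, mass),
#'   is_bimodal, low_mode_mass_below_threshold)
#' @export
completeness_flag <- function(hist, block_threshold, prominence = 0.05,
                              smooth = 5) {
  s <- moving_average(hist$counts, smooth)
  n <- length(s)
  if (n < 3 || sum(hist$counts) == 0) stopf("degenerate histogram")
  peaks <- which(vapply(seq_len(n), function(i) {
    left <- if (i == 1) -Inf else s[i - 1]
    right <- if (i == n) -Inf else s[i + 1]
    s[i] > left && s[i] >= right && s[i] > 0
  }, logical(1)))
  mids <- (hist$bin_edges[-length(hist$bin_edges)] + hist$bin_edges[-1]) / 2
  total <- sum(hist$counts)
  if (!length(peaks)) peaks <- which.max(s)
  # basin boundaries at the minimum between consecutive peaks
  bounds <- c(0)
  if (length(peaks) > 1) {
    for (i in seq_len(length(peaks) - 1)) {
      rng <- peaks[i]:peaks[i + 1]
      bounds <- c(bounds, rng[which.min(s[rng])])
    }
  }
  bounds <- c(bounds, n)
  mass <- vapply(seq_along(peaks), function(i)
    sum(hist$counts[(bounds[i] + 1):bounds[i + 1]]) / total, numeric(1))
  modes <- data.frame(location = mids[peaks], mass = mass,
                      height = s[peaks])
  qual <- which(modes$mass >= prominence)
  is_bimodal <- FALSE
  if (length(qual) >= 2) {
    for (a in qual) for (b in qual) {
      if (a >= b) next
      valley <- min(s[peaks[a]:peaks[b]])
      if (valley <= 0.5 * min(modes$height[a], modes$height[b])) {
        is_bimodal <- TRUE
      }
    }
  }
  low <- sum(hist$counts[hist$bin_edges[-1] <= block_threshold])
  # include partial bin containing the threshold proportionally? keep simple:
  # count reads strictly below threshold from the raw metric if available
  structure(list(metric = hist$metric,
                 modes = modes[, c("location", "mass")],
                 is_bimodal = is_bimodal,
                 low_mode_mass_below_threshold = low / total),
            class = "completeness_report")
}

#' @export
print.completeness_report <- function(x, ...) {
  cat(sprintf("completeness_report (%s): %d mode(s), bimodal: %s, mass below threshold: %.3f\n",
              x$metric, nrow(x$modes), x$is_bimodal,
              x$low_mode_mass_below_threshold))
  invisible(x)
}

#' Paired per-read comparison of hits against two databases
#'
#' Joins each read's best hit against a full database with its best hit
#' against a subset (or otherwise modified) database. Removing references
#' can only lower a read's best AS, so `delta_as = as_full - as_subset`
#' is non-negative up to alignment ties; a large positive median signals
#' that the subset lacks references the reads need.
#'
#' @param hits_full best-per-read hits against database 1
#' @param hits_subset best-per-read hits against database 2
#' @param db_full,db_subset optional `reference_db`s used to translate
#'   ref ids to species (ids are compared directly when omitted)
#' @return data.frame (read_id, as_full, as_subset, species_full,
#'   species_subset, same_species, delta_as, missing_in) with attributes
#'   `median_delta_as` and `concordance`
#' @export
compare_dbs <- function(hits_full, hits_subset, db_full = NULL, db_subset = NULL) {
  bf <- best_hits(hits_full); bs <- best_hits(hits_subset)
  ids <- union(bf$read_id, bs$read_id)
  if (!length(intersect(bf$read_id, bs$read_id)))
    stopf("the two hit sets share no reads")
  sp_f <- if (is.null(db_full)) stats::setNames(bf$ref_id, bf$ref_id)
          else ref_lookup(db_full, "species")
  sp_s <- if (is.null(db_subset)) stats::setNames(bs$ref_id, bs$ref_id)
          else ref_lookup(db_subset, "species")
  mf <- match(ids, bf$read_id); ms <- match(ids, bs$read_id)
  out <- data.frame(
    read_id = ids,
    as_full = ifelse(is.na(mf), NA_integer_, bf$as_score[mf]),
    as_subset = ifelse(is.na(ms), NA_integer_, bs$as_score[ms]),
    species_full = ifelse(is.na(mf), NA_character_,
                          unname(sp_f[bf$ref_id[mf]])),
    species_subset = ifelse(is.na(ms), NA_character_,
                            unname(sp_s[bs$ref_id[ms]])),
    stringsAsFactors = FALSE)
  out$same_species <- out$species_full == out$species_subset
  out$delta_as <- out$as_full - out$as_subset
  out$missing_in <- ifelse(is.na(mf), "full", ifelse(is.na(ms), "subset", ""))
  both <- !is.na(out$as_full) & !is.na(out$as_subset)
  attr(out, "median_delta_as") <- stats::median(out$delta_as[both])
  attr(out, "concordance") <- mean(out$same_species[both])
  out
}
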