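# Coverage-gap chimera detection. A read's alignments to the
# classification database define which parts of the read are explained by
# some reference; an internal unexplained stretch between two explained
# stretches is the signature of a chimeric junction (read-through
# junctions additionally retain ~90 bp of tag/primer sequence that maps
# nowhere). End gaps are permitted.

#' Coverage profile of one read from its alignment hits
#'
#' @param hits hit data.frame rows belonging to a single read
#' @param read_length read length in bp
#' @param min_cov minimum hit multiplicity for a position to count as
#'   covered
#' @return a `coverage_profile`: list(read_id, read_length,
#'   intervals) where intervals is a data.frame of sorted disjoint
#'   half-open `[start, end)` rows
#' @export
compute_coverage <- function(hits, read_length, min_cov = 1) {
  rid <- if (nrow(hits)) hits$read_id[1] else NA_character_
  if (nrow(hits) && length(unique(hits$read_id)) > 1)
    stopf("compute_coverage expects hits of a single read")
  iv <- coverage_intervals(hits$read_start, hits$read_end, read_length, min_cov)
  structure(list(read_id = rid, read_length = read_length, intervals = iv),
            class = "coverage_profile")
}

coverage_intervals <- function(starts, ends, read_length, min_cov) {
  empty <- data.frame(start = integer(0), end = integer(0))
  if (!length(starts)) return(empty)
  ev <- rbind(data.frame(pos = pmax(0L, starts), d = 1L),
              data.frame(pos = pmin(as.integer(read_length), ends), d = -1L))
  ev <- ev[order(ev$pos, -ev$d), , drop = FALSE]
  depth <- cumsum(ev$d)
  open <- depth >= min_cov
  out_s <- integer(0); out_e <- integer(0)
  in_iv <- FALSE; cur <- 0L
  for (i in seq_len(nrow(ev))) {
    if (!in_iv && open[i]) { cur <- ev$pos[i]; in_iv <- TRUE }
    else if (in_iv && !open[i]) {
      out_s <- c(out_s, cur); out_e <- c(out_e, ev$pos[i]); in_iv <- FALSE
    }
  }
  if (!length(out_s)) return(empty)
  # merge abutting intervals
  keep_s <- out_s[1]; res_s <- integer(0); res_e <- integer(0); cur_e <- out_e[1]
  if (length(out_s) > 1) {
    for (i in 2:length(out_s)) {
      if (out_s[i] <= cur_e) cur_e <- max(cur_e, out_e[i])
      else { res_s <- c(res_s, keep_s); res_e <- c(res_e, cur_e)
             keep_s <- out_s[i]; cur_e <- out_e[i] }
    }
  }
  res_s <- c(res_s, keep_s); res_e <- c(res_e, cur_e)
  data.frame(start = res_s, end = res_e)
}

#' Coverage profiles for a whole hit table
#'
#' Reads present in `read_lengths` but absent from `hits` get an empty
#' profile (no coverage).
#'
#' @param hits hit data.frame from [map_reads()]
#' @param read_lengths named vector: read_id -> read length
#' @param min_cov minimum hit multiplicity
#' @return named list of `coverage_profile`s
#' @export
coverage_profiles <- function(hits, read_lengths, min_cov = 1) {
  split_hits <- split(hits, hits$read_id)
  out <- lapply(names(read_lengths), function(rid) {
    h <- split_hits[[rid]]
    iv <- if (is.null(h)) data.frame(start = integer(0), end = integer(0))
          else coverage_intervals(h$read_start, h$read_end,
                                  read_lengths[[rid]], min_cov)
    structure(list(read_id = rid, read_length = read_lengths[[rid]],
                   intervals = iv), class = "coverage_profile")
  })
  stats::setNames(out, names(read_lengths))
}

#' Flag chimeric and uncovered reads from coverage profiles
#'
#' A read is `chimeric` if an internal uncovered run of at least
#' `min_internal_gap` bp lies strictly between two covered intervals;
#' `uncovered` if its covered fraction is below `min_covered_fraction`
#' (including reads with no hits at all); otherwise `clean`. Flagged
#' reads are excluded from classification. End gaps never trigger the
#' chimera rule.
#'
#' The default `min_internal_gap = 50` sits well above alignment-end
#' straggle (a few bp) but below the ~90 bp of residual tag/primer
#' sequence at a read-through junction, and still catches junctions that
#' retain a single 45 bp tag.
#'
#' @param profiles list of `coverage_profile`s (see [coverage_profiles()])
#' @param min_internal_gap minimum internal gap in bp
#' @param min_covered_fraction minimum covered fraction for a clean read
#' @return data.frame: read_id, status, covered_fraction,
#'   largest_internal_gap
#' @export
detect_chimeras <- function(profiles, min_internal_gap = 50,
                            min_covered_fraction = 0.8) {
  rows <- lapply(profiles, function(p) {
    iv <- p$intervals
    covered <- if (nrow(iv)) sum(iv$end - iv$start) else 0L
    frac <- covered / p$read_length
    gap <- 0L
    if (nrow(iv) >= 2) gap <- max(iv$start[-1] - iv$end[-nrow(iv)])
    status <- if (nrow(iv) >= 2 && gap >= min_internal_gap) "chimeric"
              else if (frac < min_covered_fraction) "uncovered"
              else "clean"
    data.frame(read_id = p$read_id, status = status,
               covered_fraction = frac, largest_internal_gap = gap,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
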