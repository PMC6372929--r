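# Post-demultiplexing QC: fixed-end trimming of tag/primer bases and
# marker-specific read length selection.

#' Preprocessing parameters
#'
#' Defaults: 45 bp trimmed from each end (the universal tags and custom
#' primers flanking the amplicon) and inclusive length windows of
#' 1,200-1,800 bp for the full-length 16S gene and 3,500-5,000 bp for the
#' 16S-ITS-23S amplicon, applied to the trimmed read length.
#'
#' @param end_trim_bp bases removed from each read end
#' @param windows named list of `c(min, max)` per marker
#' @return a `preprocess_params` list
#' @export
preprocess_params <- function(end_trim_bp = 45,
                              windows = list(`16S` = c(1200, 1800),
                                             rrn = c(3500, 5000))) {
  if (end_trim_bp < 0) stopf("end_trim_bp must be >= 0")
  for (w in windows) if (w[1] >= w[2]) stopf("length window min must be < max")
  structure(list(end_trim_bp = as.integer(end_trim_bp), windows = windows),
            class = "preprocess_params")
}

#' Trim a fixed number of bases from both read ends
#'
#' Reads with length `<= 2 * n` would be empty after trimming and are
#' rejected (a status, not an error).
#'
#' @param reads data.frame with `read_id`, `sequence`, and optionally
#'   `quality`
#' @param n bases to remove from each end
#' @return list with `reads` (trimmed survivors) and `rejected`
#' @export
trim_fixed_ends <- function(reads, n = 45) {
  if (n < 0) stopf("n must be >= 0")
  len <- nchar(reads$sequence)
  keep <- len > 2 * n
  kept <- reads[keep, , drop = FALSE]
  if (n > 0 && nrow(kept)) {
    l2 <- nchar(kept$sequence)
    kept$sequence <- substr(kept$sequence, n + 1, l2 - n)
    if (!is.null(kept$quality)) kept$quality <- substr(kept$quality, n + 1, l2 - n)
  }
  rownames(kept) <- NULL
  list(reads = kept, rejected = reads[!keep, , drop = FALSE])
}

#' Select reads by marker-specific length window
#'
#' @param reads data.frame with a `sequence` column
#' @param marker `"16S"` or `"rrn"`
#' @param params a [preprocess_params()]
#' @return list with `reads` (kept) and `stats` (input, kept,
#'   discarded_short, discarded_long)
#' @export
filter_by_length <- function(reads, marker, params = preprocess_params()) {
  w <- params$windows[[marker]]
  if (is.null(w)) stopf("no length window configured for marker '%s'", marker)
  len <- nchar(reads$sequence)
  short <- len < w[1]
  long <- len > w[2]
  kept <- reads[!short & !long, , drop = FALSE]
  rownames(kept) <- NULL
  list(reads = kept,
       stats = c(input = nrow(reads), kept = nrow(kept),
                 discarded_short = sum(short), discarded_long = sum(long)))
}
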