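# Minimizer seed -> chain -> banded-extension read mapping with
# Smith-Waterman-style AS scores, plus an exact Smith-Waterman reference
# implementation used as a test oracle and for small inputs.

#' Alignment parameters
#'
#' Scoring defaults (match +2, mismatch -4, gap open -4, gap extend -2;
#' a gap of length g costs 4 + 2g) mirror the defaults under which the
#' block-length and AS thresholds used downstream were established.
#' `z_drop` terminates extension once the running score falls that far
#' below its maximum, which both saves work and stops extension across
#' chimeric junctions. `band` bounds the diagonal drift of the extension
#' (about twice the expected indel count of a full-length read).
#'
#' @param k minimizer k-mer length (>= 8)
#' @param w minimizer window size
#' @param match,mismatch,gap_open,gap_extend scoring (penalties negative)
#' @param z_drop score-drop extension cutoff (> 0)
#' @param band extension band half-width in bp
#' @param max_secondary secondary hits reported per read (total hits
#'   `max_secondary + 1`)
#' @param min_chain_anchors minimum minimizer anchors to extend a chain
#' @param min_as minimum AS score to report a hit
#' @param chain_frac extend only chains with at least this fraction of the
#'   best chain's anchor count
#' @param diag_gap single-linkage diagonal gap when clustering anchors
#' @param flank bases of read context added around a chain before
#'   extension (defaults to `band`)
#' @param max_extend cap on extensions attempted per read
#' @return an `align_params` list
#' @export
align_params <- function(k = 15, w = 10, match = 2, mismatch = -4,
                         gap_open = -4, gap_extend = -2, z_drop = 70,
                         band = 500, max_secondary = 5,
                         min_chain_anchors = 2, min_as = 50,
                         chain_frac = 0.5, diag_gap = 50,
                         flank = NULL, max_extend = NULL) {
  if (k < 8) stopf("k must be >= 8")
  if (match <= 0) stopf("match score must be > 0")
  if (mismatch >= 0 || gap_open >= 0 || gap_extend >= 0)
    stopf("mismatch and gap penalties must be negative")
  if (z_drop <= 0) stopf("z_drop must be > 0")
  structure(list(k = as.integer(k), w = as.integer(w),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 z_drop = as.integer(z_drop), band = as.integer(band),
                 max_secondary = as.integer(max_secondary),
                 min_chain_anchors = as.integer(min_chain_anchors),
                 min_as = as.integer(min_as), chain_frac = chain_frac,
                 diag_gap = as.integer(diag_gap),
                 flank = as.integer(flank %||% band),
                 max_extend = as.integer(max_extend %||% max(8, max_secondary + 1))),
            class = "align_params")
}

#' Marker-tuned alignment parameter defaults
#'
#' The extension band scales with the expected number of indel errors in a
#' full-length read: 500 bp for the ~4.3 kb rrn amplicon, 200 bp for the
#' ~1.5 kb 16S gene.
#'
#' @param marker `"16S"` or `"rrn"`
#' @param ... overrides passed to [align_params()]
#' @return an `align_params` list
#' @export
default_align_params <- function(marker = c("rrn", "16S"), ...) {
  marker <- match.arg(marker)
  args <- list(...)
  if (is.null(args$band)) args$band <- if (marker == "rrn") 500L else 200L
  do.call(align_params, args)
}

#' Build a minimizer index over a reference database
#'
#' Indexes canonical (strand-independent) minimizers of every reference;
#' rebuilding from the same inputs is deterministic.
#'
#' @param db a non-empty `reference_db`
#' @param params an [align_params()]
#' @return a `minimizer_index`
#' @export
build_index <- function(db, params = align_params()) {
  if (!n_records(db)) stopf("cannot index an empty reference database")
  ptr <- build_index_cpp(db$records$sequence, db$records$ref_id,
                         params$k, params$w)
  nm <- index_n_minimizers_cpp(ptr)
  if (any(nm == 0))
    warnf("no minimizers for reference(s): %s (shorter than k?)",
          paste(db$records$ref_id[nm == 0], collapse = ", "))
  structure(list(ptr = ptr, ref_ids = db$records$ref_id,
                 ref_lengths = db$records$length,
                 n_minimizers = nm, k = params$k, w = params$w),
            class = "minimizer_index")
}

#' @export
print.minimizer_index <- function(x, ...) {
  cat(sprintf("minimizer_index: %d references, k=%d w=%d, %d minimizers\n",
              length(x$ref_ids), x$k, x$w, sum(x$n_minimizers)))
  invisible(x)
}

#' Map reads against an indexed reference set
#'
#' Candidate references are found from shared minimizers, co-linear anchor
#' chains are clustered per reference and strand, and the best chains are
#' extended with banded affine-gap local alignment under z-drop
#' termination. Hits are reported sorted by AS score (ties broken by
#' reference id, then leftmost reference start), up to
#' `max_secondary + 1` per read; both strands are searched and read
#' coordinates always refer to the forward read. Chimeric reads can yield
#' hits on disjoint read intervals.
#'
#' @param index a [build_index()] result
#' @param reads data.frame with `read_id` and `sequence` (or a named
#'   character vector of sequences)
#' @param params the [align_params()] used to build the index
#' @return data.frame of hits: read_id, ref_id, strand, read_start,
#'   read_end, ref_start, ref_end (0-based half-open), block_length
#'   (alignment columns including gaps), n_match, as_score, identity
#' @export
map_reads <- function(index, reads, params = align_params()) {
  if (is.character(reads))
    reads <- data.frame(read_id = names(reads) %||% as.character(seq_along(reads)),
                        sequence = unname(reads), stringsAsFactors = FALSE)
  hits <- map_reads_cpp(index$ptr, reads$read_id, reads$sequence, unclass(params))
  hits$identity <- ifelse(hits$block_length > 0,
                          hits$n_match / hits$block_length, 0)
  hits
}

#' Map a single read
#'
#' @param index a [build_index()] result
#' @param read a DNA string, or a one-row read data.frame
#' @param params an [align_params()]
#' @param read_id id used in the output when `read` is a bare string
#' @return hit data.frame as in [map_reads()]
#' @export
map_read <- function(index, read, params = align_params(), read_id = "read1") {
  if (is.data.frame(read))
    return(map_reads(index, read, params))
  map_reads(index, stats::setNames(read, read_id), params)
}

#' Exact Smith-Waterman local alignment (reference implementation)
#'
#' Full O(|query| x |target|) affine-gap dynamic programming; used as the
#' oracle for the AS-score contract of the banded mapper and for measuring
#' read identity against a known source. A gap of length g costs
#' `gap_open + g * gap_extend` (penalties negative). N bases are never
#' counted as matches.
#'
#' @param query,target non-empty DNA strings
#' @param scoring list with match, mismatch, gap_open, gap_extend
#' @return list with as_score, query_start/end and target_start/end
#'   (0-based half-open), n_match, block_length, identity
#' @export
smith_waterman <- function(query, target,
                           scoring = list(match = 2, mismatch = -4,
                                          gap_open = -4, gap_extend = -2)) {
  if (!nzchar(query) || !nzchar(target)) stopf("sequences must be non-empty")
  r <- sw_align_cpp(query, target, scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_extend)
  r$identity <- if (r$block_length > 0) r$n_match / r$block_length else 0
  r
}

#' Write a hit table with PAF-compatible core columns
#'
#' Columns: read name, read length, read start, read end, strand, ref
#' name, ref length, ref start, ref end, n_match, block_length, a mapq
#' placeholder (255), and an `AS:i:` tag column.
#'
#' @param hits hit data.frame from [map_reads()]
#' @param index the `minimizer_index` used (for reference lengths)
#' @param read_lengths named integer vector of read lengths
#' @param path output TSV path
#' @return the exported data.frame, invisibly
#' @export
write_hits_paf <- function(hits, index, read_lengths, path = NULL) {
  rl <- stats::setNames(index$ref_lengths, index$ref_ids)
  paf <- data.frame(
    read_id = hits$read_id,
    read_length = as.integer(read_lengths[hits$read_id]),
    read_start = hits$read_start, read_end = hits$read_end,
    strand = hits$strand,
    ref_id = hits$ref_id,
    ref_length = as.integer(rl[hits$ref_id]),
    ref_start = hits$ref_start, ref_end = hits$ref_end,
    n_match = hits$n_match, block_length = hits$block_length,
    mapq = 255L,
    AS = sprintf("AS:i:%d", hits$as_score),
    stringsAsFactors = FALSE)
  if (!is.null(path)) write_tsv(paf, path)
  invisible(paf)
}
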