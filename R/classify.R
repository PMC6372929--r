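# Species assignment from filtered hits: block-length filter, best-AS
# rule, optional genus-level LCA for cross-species ties, and community
# profiles.

#' Classification parameters
#'
#' `min_block` holds the marker-specific alignment block thresholds
#' (inclusive): 1,000 bp for the full-length 16S gene and 3,000 bp for the
#' 16S-ITS-23S amplicon. With the default `tie_policy`
#' `"ambiguous_to_lca"`, reads whose best-AS hits span several species are
#' resolved to genus when the genera agree (reported with status
#' `ambiguous` and a non-empty genus); `"drop_ambiguous"` leaves them
#' unresolved.
#'
#' @param min_block named numeric vector of per-marker block thresholds
#' @param tie_policy `"ambiguous_to_lca"` or `"drop_ambiguous"`
#' @return a `classify_params` list
#' @export
classify_params <- function(min_block = c(`16S` = 1000, rrn = 3000),
                            tie_policy = c("ambiguous_to_lca", "drop_ambiguous")) {
  if (any(min_block <= 0)) stopf("min_block must be > 0")
  structure(list(min_block = min_block, tie_policy = match.arg(tie_policy)),
            class = "classify_params")
}

#' Keep only hits with a sufficient alignment block
#'
#' @param hits hit data.frame
#' @param marker `"16S"` or `"rrn"`
#' @param params a [classify_params()]
#' @return the hits with `block_length >= min_block[marker]`
#' @export
filter_hits <- function(hits, marker, params = classify_params()) {
  mb <- unname(params$min_block[marker])
  if (length(mb) != 1 || is.na(mb))
    stopf("no block threshold for marker '%s'", marker)
  out <- hits[hits$block_length >= mb, , drop = FALSE]
  rownames(out) <- NULL
  out
}

assign_one <- function(h, species_of, genus_of, tie_policy) {
  best <- max(h$as_score)
  top <- h[h$as_score == best, , drop = FALSE]
  sp <- unique(species_of[top$ref_id])
  if (length(sp) == 1) {
    return(list(status = "assigned", species = sp,
                genus = unname(genus_of[top$ref_id[1]]),
                as_score = best, n_best_ties = nrow(top)))
  }
  gn <- unique(genus_of[top$ref_id])
  genus <- if (tie_policy == "ambiguous_to_lca" && length(gn) == 1) gn else ""
  list(status = "ambiguous", species = "", genus = genus,
       as_score = best, n_best_ties = nrow(top))
}

#' Assign one read from its block-filtered hits
#'
#' Hits with the maximal AS score are selected; if they all belong to one
#' species the read is `assigned`; cross-species ties are handled per the
#' tie policy; no hits means `unassigned`.
#'
#' @param hits block-filtered hit data.frame for a single read
#' @param db the `reference_db` the hits were produced against
#' @param params a [classify_params()]
#' @param read_id id to report when `hits` is empty
#' @return one-row data.frame: read_id, status, species, genus, as_score,
#'   n_best_ties
#' @export
assign_read <- function(hits, db, params = classify_params(), read_id = NULL) {
  if (!nrow(hits)) {
    return(data.frame(read_id = read_id %||% NA_character_,
                      status = "unassigned", species = "", genus = "",
                      as_score = NA_integer_, n_best_ties = 0L,
                      stringsAsFactors = FALSE))
  }
  a <- assign_one(hits, ref_lookup(db, "species"), ref_lookup(db, "genus"),
                  params$tie_policy)
  data.frame(read_id = hits$read_id[1], status = a$status, species = a$species,
             genus = a$genus, as_score = a$as_score,
             n_best_ties = a$n_best_ties, stringsAsFactors = FALSE)
}

#' Assign every read, folding in upstream filtering statuses
#'
#' Produces exactly one status per read over `read_ids`: reads flagged by
#' the chimera detector keep that flag (`chimeric` / `uncovered`); clean
#' reads with no raw hits are `unassigned`; clean reads whose hits all
#' fail the block filter are `filtered_block`; the rest are assigned by
#' the best-AS rule.
#'
#' @param filtered_hits block-filtered hits (see [filter_hits()])
#' @param db the `reference_db`
#' @param params a [classify_params()]
#' @param read_ids all read ids entering classification
#' @param raw_hits unfiltered hits (to distinguish `filtered_block` from
#'   `unassigned`); defaults to `filtered_hits`
#' @param chimera_flags data.frame from [detect_chimeras()]
#' @return data.frame with one row per read
#' @export
assign_reads <- function(filtered_hits, db, params = classify_params(),
                         read_ids = NULL, raw_hits = NULL,
                         chimera_flags = NULL) {
  raw_hits <- raw_hits %||% filtered_hits
  read_ids <- read_ids %||% unique(raw_hits$read_id)
  species_of <- ref_lookup(db, "species")
  genus_of <- ref_lookup(db, "genus")
  flag <- stats::setNames(rep("clean", length(read_ids)), read_ids)
  if (!is.null(chimera_flags)) {
    m <- match(read_ids, chimera_flags$read_id)
    flag[!is.na(m)] <- chimera_flags$status[m[!is.na(m)]]
  }
  has_raw <- read_ids %in% raw_hits$read_id
  byread <- split(filtered_hits, filtered_hits$read_id)
  rows <- vector("list", length(read_ids))
  for (i in seq_along(read_ids)) {
    rid <- read_ids[i]
    if (flag[[rid]] %in% c("chimeric", "uncovered")) {
      rows[[i]] <- list(status = flag[[rid]], species = "", genus = "",
                        as_score = NA_integer_, n_best_ties = 0L)
    } else if (is.null(byread[[rid]])) {
      rows[[i]] <- list(status = if (has_raw[i]) "filtered_block" else "unassigned",
                        species = "", genus = "",
                        as_score = NA_integer_, n_best_ties = 0L)
    } else {
      rows[[i]] <- assign_one(byread[[rid]], species_of, genus_of,
                              params$tie_policy)
    }
  }
  data.frame(read_id = read_ids,
             status = vapply(rows, `[[`, character(1), "status"),
             species = vapply(rows, `[[`, character(1), "species"),
             genus = vapply(rows, `[[`, character(1), "genus"),
             as_score = vapply(rows, function(r) as.integer(r$as_score),
                               integer(1)),
             n_best_ties = vapply(rows, function(r) as.integer(r$n_best_ties),
                                  integer(1)),
             stringsAsFactors = FALSE)
}

#' Community profile from per-read assignments
#'
#' At species rank only `assigned` reads count; at genus rank, reads with
#' a genus-level LCA resolution (status `ambiguous`, non-empty genus)
#' count too. Relative abundance is computed over classified reads.
#'
#' @param assignments data.frame from [assign_reads()]
#' @param rank `"species"` or `"genus"`
#' @return data.frame (taxon, read_count, relative_abundance) with
#'   attributes `rank` and `total_classified`
#' @export
abundance_table <- function(assignments, rank = c("species", "genus")) {
  rank <- match.arg(rank)
  taxa <- if (rank == "species") {
    assignments$species[assignments$status == "assigned"]
  } else {
    g <- assignments$genus[assignments$status %in% c("assigned", "ambiguous")]
    g[nzchar(g)]
  }
  taxa <- taxa[nzchar(taxa)]
  if (!length(taxa)) {
    out <- data.frame(taxon = character(0), read_count = integer(0),
                      relative_abundance = numeric(0))
    attr(out, "rank") <- rank
    attr(out, "total_classified") <- 0L
    return(out)
  }
  tab <- sort(table(taxa), decreasing = TRUE)
  out <- data.frame(taxon = names(tab), read_count = as.integer(tab),
                    relative_abundance = as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  attr(out, "rank") <- rank
  attr(out, "total_classified") <- sum(out$read_count)
  out
}

#' Rarefaction curve of observed taxa
#'
#' For each depth, reads are subsampled without replacement `replicates`
#' times and the number of distinct assigned taxa recorded.
#'
#' @param assignments data.frame from [assign_reads()]
#' @param depths subsampling depths (those exceeding the number of
#'   assigned reads are skipped with a warning)
#' @param replicates subsamples per depth
#' @param seed integer seed
#' @param rank `"species"` or `"genus"`
#' @return data.frame: depth, mean_taxa, sd_taxa
#' @export
rarefaction_curve <- function(assignments, depths, replicates = 10, seed = 1,
                              rank = "species") {
  taxa <- assignments[[rank]][assignments$status == "assigned"]
  taxa <- taxa[nzchar(taxa)]
  n <- length(taxa)
  ok <- depths <= n
  if (any(!ok))
    warnf("skipping depths exceeding %d assigned reads: %s", n,
          paste(depths[!ok], collapse = ", "))
  depths <- depths[ok]
  set.seed(seed)
  rows <- lapply(depths, function(d) {
    obs <- vapply(seq_len(replicates), function(r)
      length(unique(sample(taxa, d))), numeric(1))
    data.frame(depth = d, mean_taxa = mean(obs), sd_taxa = stats::sd(obs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
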