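# Reference marker database: taxonomically labelled 16S / rrn operon
# sequences with per-rank indices. Species is the classification unit;
# a species may contribute several operon copies (records).

RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Create a single reference record
#'
#' @param ref_id unique record identifier
#' @param species species name (classification unit)
#' @param genus genus name
#' @param sequence uppercase DNA string over `{A,C,G,T,N}`
#' @param lineage named character vector of `rank = name` pairs ordered from
#'   domain to species; defaults to a minimal genus/species lineage
#' @return a one-row `data.frame` with a `lineage` list column
#' @export
reference_record <- function(ref_id, species, genus, sequence, lineage = NULL) {
  sequence <- toupper(sequence)
  check_dna(sequence, sprintf("sequence of '%s'", ref_id))
  if (!nzchar(species) || !nzchar(genus))
    stopf("record '%s': species and genus must be non-empty", ref_id)
  if (is.null(lineage)) lineage <- c(genus = genus, species = species)
  lineage[["genus"]] <- genus
  lineage[["species"]] <- species
  lineage <- lineage[intersect(RANKS, names(lineage))]
  df <- data.frame(ref_id = ref_id, species = species, genus = genus,
                   sequence = sequence, length = nchar(sequence),
                   stringsAsFactors = FALSE)
  df$lineage <- list(lineage)
  df
}

build_taxon_index <- function(records) {
  idx <- list()
  for (i in seq_len(nrow(records))) {
    lin <- records$lineage[[i]]
    for (rank in names(lin)) {
      nm <- lin[[rank]]
      if (is.null(idx[[rank]])) idx[[rank]] <- list()
      idx[[rank]][[nm]] <- c(idx[[rank]][[nm]], records$ref_id[i])
    }
  }
  idx
}

#' Construct a reference database
#'
#' @param records data.frame of reference records (see [reference_record()])
#' @param marker `"16S"` or `"rrn"`
#' @return an object of class `reference_db`
#' @export
reference_db <- function(records, marker = c("rrn", "16S")) {
  marker <- match.arg(marker)
  if (!nrow(records)) {
    db <- list(records = records, marker = marker, taxon_index = list())
    class(db) <- "reference_db"
    return(db)
  }
  dup <- records$ref_id[duplicated(records$ref_id)]
  if (length(dup))
    stopf("duplicate ref_id in reference set: %s", paste(unique(dup), collapse = ", "))
  check_dna(records$sequence, "reference sequence")
  records$length <- nchar(records$sequence)
  db <- list(records = records, marker = marker,
             taxon_index = build_taxon_index(records))
  class(db) <- "reference_db"
  db
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("reference_db: %d records, %d species, marker %s\n",
              nrow(x$records), length(unique(x$records$species)), x$marker))
  invisible(x)
}

#' Number of records in a reference database
#' @param db a `reference_db`
#' @return integer record count
#' @export
n_records <- function(db) nrow(db$records)

#' Species present in a reference database
#' @param db a `reference_db`
#' @return character vector of distinct species
#' @export
db_species <- function(db) unique(db$records$species)

ref_lookup <- function(db, field) {
  stats::setNames(db$records[[field]], db$records$ref_id)
}

#' Default FASTA header scheme
#'
#' Headers follow `refid|rank1=name1;rank2=name2;...;species=Genus species`.
#' The delimiters are configurable; the scheme is a repository convention.
#'
#' @param field_sep separator between the id and the taxonomy string
#' @param tax_sep separator between `rank=name` pairs
#' @param kv_sep separator between a rank and its name
#' @return a `header_scheme` list
#' @export
header_scheme <- function(field_sep = "|", tax_sep = ";", kv_sep = "=") {
  structure(list(field_sep = field_sep, tax_sep = tax_sep, kv_sep = kv_sep),
            class = "header_scheme")
}

parse_header <- function(h, scheme) {
  parts <- strsplit(h, scheme$field_sep, fixed = TRUE)[[1]]
  ref_id <- trimws(parts[1])
  lin <- c()
  if (length(parts) >= 2) {
    kvs <- strsplit(parts[2], scheme$tax_sep, fixed = TRUE)[[1]]
    for (kv in kvs) {
      p <- strsplit(kv, scheme$kv_sep, fixed = TRUE)[[1]]
      if (length(p) == 2) lin[trimws(p[1])] <- trimws(p[2])
    }
  }
  list(ref_id = ref_id, lineage = lin)
}

format_header <- function(ref_id, lineage, scheme = header_scheme()) {
  tax <- paste(names(lineage), unlist(lineage), sep = scheme$kv_sep,
               collapse = scheme$tax_sep)
  paste0(ref_id, scheme$field_sep, tax)
}

#' Load a reference database from FASTA
#'
#' One record per FASTA entry; taxonomy is parsed from the header according
#' to `scheme`. Headers must provide at least `species` and `genus`;
#' duplicate ids are rejected.
#'
#' @param path FASTA file path
#' @param marker `"16S"` or `"rrn"`
#' @param scheme a [header_scheme()]
#' @return a `reference_db`
#' @export
load_reference_fasta <- function(path, marker = c("rrn", "16S"),
                                 scheme = header_scheme()) {
  marker <- match.arg(marker)
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stopf("no FASTA records in '%s'", path)
  headers <- names(seqs)
  parsed <- lapply(headers, parse_header, scheme = scheme)
  missing <- vapply(parsed, function(p)
    !all(c("species", "genus") %in% names(p$lineage)), logical(1))
  if (any(missing))
    stopf("headers lacking species/genus annotation: %s",
          paste(utils::head(headers[missing], 5), collapse = " ; "))
  recs <- do.call(rbind, lapply(seq_along(parsed), function(i) {
    p <- parsed[[i]]
    reference_record(p$ref_id, p$lineage[["species"]], p$lineage[["genus"]],
                     as.character(seqs[[i]]), lineage = p$lineage)
  }))
  reference_db(recs, marker)
}

#' Write a reference database to FASTA
#'
#' Headers are rebuilt from each record's lineage with the default scheme;
#' sequences are wrapped at 80 columns, so a load/write/load round trip
#' preserves records and lineages exactly.
#'
#' @param db a `reference_db`
#' @param path output path
#' @param scheme a [header_scheme()]
#' @return `path`, invisibly
#' @export
write_reference_fasta <- function(db, path, scheme = header_scheme()) {
  x <- Biostrings::DNAStringSet(db$records$sequence)
  names(x) <- vapply(seq_len(nrow(db$records)), function(i)
    format_header(db$records$ref_id[i], db$records$lineage[[i]], scheme),
    character(1))
  Biostrings::writeXStringSet(x, path, width = 80)
  invisible(path)
}

#' Export the taxonomy table of a database as TSV
#'
#' @param db a `reference_db`
#' @param path output TSV path (columns: ref_id, then one column per rank)
#' @return the exported data.frame, invisibly
#' @export
export_taxonomy <- function(db, path = NULL) {
  ranks <- unique(unlist(lapply(db$records$lineage, names)))
  ranks <- intersect(RANKS, ranks)
  tab <- data.frame(ref_id = db$records$ref_id, stringsAsFactors = FALSE)
  for (r in ranks)
    tab[[r]] <- vapply(db$records$lineage, function(l) l[r] %||% NA_character_,
                       character(1))
  if (!is.null(path)) write_tsv(tab, path)
  invisible(tab)
}

#' Subset a database by excluding one taxon
#'
#' Removes every record whose lineage contains `(rank, name)`, emulating the
#' removal of a whole class (e.g. Gammaproteobacteria) from a reference set
#' to probe database incompleteness. The input database is unchanged.
#'
#' @param db a `reference_db`
#' @param rank rank to match (e.g. `"class"`)
#' @param name taxon name to exclude
#' @return a new `reference_db` without the matching records
#' @export
subset_excluding_taxon <- function(db, rank, name) {
  known_ranks <- unique(unlist(lapply(db$records$lineage, names)))
  if (!rank %in% known_ranks)
    stopf("rank '%s' not present in this database's lineage scheme", rank)
  hit <- vapply(db$records$lineage, function(l)
    !is.na(l[rank]) && identical(unname(l[rank]), name), logical(1))
  if (!any(hit)) {
    message(sprintf("no records with %s == '%s'; database unchanged", rank, name))
    return(db)
  }
  kept <- db$records[!hit, , drop = FALSE]
  if (!nrow(kept))
    warnf("excluding %s '%s' removed every record", rank, name)
  reference_db(kept, db$marker)
}

#' Add a record to a reference database
#'
#' Appends one reference (for instance a manually curated operon sequence
#' of a species missing from the database) and refreshes the taxon index.
#'
#' @param db a `reference_db`
#' @param record a one-row record from [reference_record()]
#' @return a new `reference_db` including the record
#' @export
add_reference <- function(db, record) {
  if (record$ref_id %in% db$records$ref_id)
    stopf("ref_id '%s' already present", record$ref_id)
  reference_db(rbind(db$records, record), db$marker)
}
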