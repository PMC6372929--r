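# Synthetic reference sets and nanopore-like amplicon reads with truth
# labels. The generator emulates the experimental designs used to validate
# the pipeline: a pure isolate, an even mock, a staggered mock spanning
# 1e3-1e6 operon copies, and cross-run barcode carryover.

MARKER_LENGTH <- c("16S" = 1500L, "rrn" = 4300L)

# Constant 45-bp universal tag + primer stubs flanking every amplicon.
# End trimming removes them; read-through chimeras retain them internally,
# which is what makes chimeric junctions visible as coverage gaps.
TAG5 <- "ATCGTTACGGCATTCGAAGTCCTGAACGTGATTCACGGTAGCTAA"
TAG3 <- "TTGACCGATAGGCTTCAAGGTCGATACGTTCAGGCTATGACTGCA"

#' Conserved/variable block structure of a marker template
#'
#' Ribosomal markers alternate conserved stretches (which seed alignments
#' in any bacterium) with variable regions (which carry the taxonomic
#' signal). The synthetic templates reproduce that mosaic: nine variable
#' regions in the 16S gene, a hypervariable ITS, and interspersed variable
#' regions in the 23S gene.
#'
#' @param marker `"16S"` or `"rrn"`
#' @return data.frame with columns start, end (1-based inclusive), type
#' @export
marker_regions <- function(marker = c("rrn", "16S")) {
  marker <- match.arg(marker)
  seg_16s <- function(offset = 0L) {
    # 10 conserved blocks of 87 bp interleaved with 9 variable blocks of 70 bp
    starts <- integer(0); ends <- integer(0); types <- character(0)
    pos <- 1L
    for (i in 1:19) {
      len <- if (i %% 2 == 1) 87L else 70L
      typ <- if (i %% 2 == 1) "conserved" else "variable"
      starts <- c(starts, pos); ends <- c(ends, pos + len - 1L)
      types <- c(types, typ)
      pos <- pos + len
    }
    ends[19] <- 1500L  # absorb rounding in the final conserved block
    data.frame(start = starts + offset, end = ends + offset, type = types,
               stringsAsFactors = FALSE)
  }
  if (marker == "16S") return(seg_16s())
  r16 <- seg_16s()
  its <- data.frame(start = 1501L, end = 1900L, type = "its",
                    stringsAsFactors = FALSE)
  # 23S: 7 conserved blocks (~266 bp) interleaved with 6 variable (90 bp)
  starts <- integer(0); ends <- integer(0); types <- character(0)
  pos <- 1901L
  for (i in 1:13) {
    len <- if (i %% 2 == 1) 266L else 90L
    typ <- if (i %% 2 == 1) "conserved" else "variable"
    starts <- c(starts, pos); ends <- c(ends, pos + len - 1L)
    types <- c(types, typ)
    pos <- pos + len
  }
  ends[13] <- 4300L
  rbind(r16, its, data.frame(start = starts, end = ends, type = types,
                             stringsAsFactors = FALSE))
}

region_mask <- function(marker) {
  reg <- marker_regions(marker)
  mask <- character(max(reg$end))
  for (i in seq_len(nrow(reg))) mask[reg$start[i]:reg$end[i]] <- reg$type[i]
  mask
}

substitute_positions <- function(seq_chars, pos) {
  if (!length(pos)) return(seq_chars)
  bases <- c("A", "C", "G", "T")
  cur <- seq_chars[pos]
  shift <- sample.int(3, length(pos), replace = TRUE)
  idx <- (match(cur, bases) - 1L + shift) %% 4L + 1L
  seq_chars[pos] <- bases[idx]
  seq_chars
}

pairwise_identity_after <- function(d) (1 - d)^2 + d^2 / 3

#' Synthesize a taxonomically labelled reference set
#'
#' Generates `n_species` marker sequences from a common template, with
#' low divergence in conserved blocks and high divergence (plus small
#' indels) in variable blocks, so that cross-species alignments seed in
#' conserved regions but break in variable ones. Species 1 and 2 form a
#' designated close-relative pair: species 2 is derived from species 1 by
#' exactly `round((1 - close_pair_identity) * length)` substitutions, so
#' their global identity equals `close_pair_identity` (emulating
#' congeneric species whose 16S genes are ~97% identical).
#'
#' Lineages are synthetic: the close pair shares a genus, every other
#' species has its own genus, and genera are grouped into classes of
#' three (class 1 holds the close pair's genus plus two more).
#'
#' @param n_species number of species (>= 1); one operon record each
#' @param marker `"16S"` or `"rrn"`
#' @param divergence list with per-site substitution divergence from the
#'   template in `conserved` and `variable` blocks (the ITS uses
#'   `variable`)
#' @param close_pair_identity global identity of the designated close pair
#' @param indel_rate per-site indel probability within variable blocks
#' @param seed integer seed; the same seed reproduces the set byte for byte
#' @return a `reference_db`
#' @export
synthesize_reference_set <- function(n_species, marker = c("rrn", "16S"),
                                     divergence = list(conserved = 0.02,
                                                       variable = 0.30),
                                     close_pair_identity = 0.97,
                                     indel_rate = 0.004,
                                     seed = 1) {
  marker <- match.arg(marker)
  if (n_species < 1) stopf("n_species must be >= 1")
  mask <- region_mask(marker)
  L <- length(mask)
  f_var <- mean(mask != "conserved")
  bg <- (1 - f_var) * pairwise_identity_after(divergence$conserved) +
    f_var * pairwise_identity_after(divergence$variable)
  if (close_pair_identity >= 1 || close_pair_identity <= bg)
    stopf("infeasible divergence spec: close_pair_identity %.3f must lie in (%.3f, 1)",
          close_pair_identity, bg)
  set.seed(seed)
  root <- strsplit(random_dna(L), "")[[1]]
  p_site <- ifelse(mask == "conserved", divergence$conserved, divergence$variable)
  var_pos <- which(mask != "conserved")
  recs <- NULL
  seq1_chars <- NULL
  for (i in seq_len(n_species)) {
    if (i == 2 && n_species >= 2) {
      nmut <- round((1 - close_pair_identity) * length(seq1_chars))
      pos <- sample(seq_along(seq1_chars), nmut)
      chars <- substitute_positions(seq1_chars, pos)
    } else {
      pos <- which(stats::runif(L) < p_site)
      chars <- substitute_positions(root, pos)
      n_ind <- stats::rpois(1, length(var_pos) * indel_rate)
      if (n_ind > 0) {
        at <- sort(sample(var_pos, min(n_ind, length(var_pos))), decreasing = TRUE)
        for (p in at) {
          len <- sample.int(3, 1)
          if (stats::runif(1) < 0.5) {
            chars <- chars[-(p:min(p + len - 1L, length(chars)))]
          } else {
            ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
            chars <- append(chars, ins, after = p)
          }
        }
      }
      if (i == 1) seq1_chars <- chars
    }
    g <- if (i <= 2) 1L else i - 1L
    cl <- ceiling(g / 3)
    lin <- c(domain = "Bacteria",
             phylum = sprintf("Phylum_%02d", ceiling(cl / 2)),
             class = sprintf("Class_%02d", cl),
             order = sprintf("Order_%02d", cl),
             family = sprintf("Family_%02d", g),
             genus = sprintf("Genus_%02d", g),
             species = sprintf("Species_%03d", i))
    recs <- rbind(recs, reference_record(
      sprintf("ref%03d", i), lin[["species"]], lin[["genus"]],
      paste(chars, collapse = ""), lineage = lin))
  }
  reference_db(recs, marker)
}

#' Define a community design
#'
#' @param members data.frame with columns `species` and `weight`
#' @param weight_kind `"operon_copies"` or `"proportion"`
#' @param marker `"16S"` or `"rrn"`
#' @param n_reads number of reads to simulate
#' @return a `community_design`
#' @export
community_design <- function(members, weight_kind = c("proportion", "operon_copies"),
                             marker = c("rrn", "16S"), n_reads) {
  weight_kind <- match.arg(weight_kind)
  marker <- match.arg(marker)
  if (!nrow(members)) stopf("empty community design")
  if (any(members$weight <= 0)) stopf("design weights must be > 0")
  if (weight_kind == "proportion" && abs(sum(members$weight) - 1) > 1e-9)
    stopf("proportions must sum to 1")
  structure(list(members = members, weight_kind = weight_kind,
                 marker = marker, n_reads = as.integer(n_reads)),
            class = "community_design")
}

#' Even community design over a species set
#' @param species character vector of species
#' @param n_reads number of reads
#' @param marker marker gene
#' @return a `community_design` with equal proportions
#' @export
even_design <- function(species, n_reads, marker = c("rrn", "16S")) {
  community_design(
    data.frame(species = species, weight = rep(1 / length(species), length(species)),
               stringsAsFactors = FALSE),
    weight_kind = "proportion", marker = match.arg(marker), n_reads = n_reads)
}

#' Staggered community design on a log-spaced operon-copy grid
#'
#' Assigns species to copy numbers on the grid `levels` (by default
#' `1e3, 1e4, 1e5, 1e6`, cycling so that 20 species get 5 per level),
#' emulating a staggered mock community whose member abundances span
#' three orders of magnitude.
#'
#' @param species character vector of species
#' @param n_reads number of reads
#' @param marker marker gene
#' @param levels operon-copy levels
#' @return a `community_design` with `weight_kind = "operon_copies"`
#' @export
staggered_design <- function(species, n_reads, marker = c("rrn", "16S"),
                             levels = c(1e3, 1e4, 1e5, 1e6)) {
  copies <- rep(levels, length.out = length(species))
  community_design(
    data.frame(species = species, weight = copies, stringsAsFactors = FALSE),
    weight_kind = "operon_copies", marker = match.arg(marker), n_reads = n_reads)
}

#' Per-base error model for simulated reads
#'
#' Defaults split the total error of `1 - target_accuracy` as one half
#' substitutions and one quarter each insertions and deletions, which at
#' the default target accuracy of 0.89 gives per-base rates 0.055 /
#' 0.0275 / 0.0275 and an expected alignment identity of ~0.893.
#'
#' @param target_accuracy expected alignment accuracy of reads
#' @param sub,ins,del per-base event probabilities; derived from
#'   `target_accuracy` when `NULL`
#' @return an `error_model`
#' @export
error_model <- function(target_accuracy = 0.89, sub = NULL, ins = NULL, del = NULL) {
  tot <- 1 - target_accuracy
  sub <- sub %||% (tot / 2)
  ins <- ins %||% (tot / 4)
  del <- del %||% (tot / 4)
  if (any(c(sub, ins, del) < 0) || sub + ins + del >= 1)
    stopf("error rates must be >= 0 and sum to < 1")
  structure(list(sub = sub, ins = ins, del = del,
                 target_accuracy = target_accuracy), class = "error_model")
}

#' Expected alignment identity under an error model
#'
#' Matches are template bases that are neither deleted nor substituted;
#' alignment columns are template bases plus inserted bases, so the
#' expected identity is `(1 - del) * (1 - sub) / (1 + ins)`.
#'
#' @param model an [error_model()]
#' @return expected identity (fraction)
#' @export
expected_identity <- function(model) {
  (1 - model$del) * (1 - model$sub) / (1 + model$ins)
}

#' Apply the per-base error process to a sequence
#'
#' @param seq DNA string
#' @param model an [error_model()]
#' @return mutated DNA string (uses R's RNG; seed with `set.seed`)
#' @export
mutate_sequence <- function(seq, model = error_model()) {
  mutate_seq_cpp(seq, model$sub, model$ins, model$del)
}

ref_of_species <- function(db, species) {
  ids <- db$records$ref_id[db$records$species == species]
  if (length(ids) == 1) ids else sample(ids, 1)
}

#' Simulate nanopore-like amplicon reads with truth labels
#'
#' Each read is drawn from a tagged amplicon `TAG5 + reference + TAG3`
#' of a species sampled by design weight. Chimeric reads emulate pore
#' read-through: a 3' portion of one tagged molecule concatenated with the
#' 5' portion of a second molecule from a different species, leaving both
#' molecules' 45-bp tags (90 bp of non-biological sequence) at the
#' junction. Short fragments are truncated amplicons below the marker's
#' length window. Per-base substitution/insertion/deletion errors are then
#' applied, and each read is reverse-complemented with probability 0.5.
#'
#' @param db a `reference_db` containing every design species
#' @param design a [community_design()]
#' @param error an [error_model()]
#' @param length_jitter list with `sd_frac`: Gaussian read-length jitter
#'   (fraction of molecule length), applied as truncation from a random end
#' @param chimera_rate fraction of reads that are chimeric
#' @param short_fragment_rate fraction of reads that are truncated
#'   amplicons (uniform in 0.3-0.8 of the marker length)
#' @param seed integer seed; the same seed gives byte-identical output
#' @return list with `reads` (read_id, sequence, quality, strand) and
#'   `truth` (read_id, truth_species, truth_ref_id, truth_ref_id2,
#'   is_chimera, is_carryover, strand)
#' @export
simulate_reads <- function(db, design, error = error_model(),
                           length_jitter = list(sd_frac = 0.03),
                           chimera_rate = 0.02, short_fragment_rate = 0.05,
                           seed = 1) {
  if (!inherits(design, "community_design")) stopf("design must be a community_design")
  missing_sp <- setdiff(design$members$species, db_species(db))
  if (length(missing_sp))
    stopf("design species missing from database: %s",
          paste(missing_sp, collapse = ", "))
  if (chimera_rate < 0 || chimera_rate >= 1 || short_fragment_rate < 0 ||
      short_fragment_rate >= 1)
    stopf("rates must lie in [0, 1)")
  set.seed(seed)
  n <- design$n_reads
  prob <- design$members$weight / sum(design$members$weight)
  sp_pool <- design$members$species
  seqs <- ref_lookup(db, "sequence")
  qchar <- rawToChar(as.raw(33L + 12L))  # constant Q12 placeholder
  out_seq <- character(n); out_strand <- character(n)
  t_species <- character(n); t_ref <- character(n); t_ref2 <- character(n)
  t_chim <- logical(n)
  ev <- c(n_sub = 0, n_ins = 0, n_del = 0, template_bases = 0)
  for (i in seq_len(n)) {
    chim <- stats::runif(1) < chimera_rate
    if (chim && length(sp_pool) >= 2) {
      pair <- sample(seq_along(sp_pool), 2, prob = prob)
      refA <- ref_of_species(db, sp_pool[pair[1]])
      refB <- ref_of_species(db, sp_pool[pair[2]])
      sA <- seqs[[refA]]; sB <- seqs[[refB]]
      u <- round(stats::runif(1, 0.35, 0.65) * nchar(sA))
      v <- round(stats::runif(1, 0.35, 0.65) * nchar(sB))
      template <- paste0(substr(sA, nchar(sA) - u + 1, nchar(sA)), TAG3,
                         TAG5, substr(sB, 1, v))
      if (u >= v) { t_ref[i] <- refA; t_ref2[i] <- refB }
      else        { t_ref[i] <- refB; t_ref2[i] <- refA }
      t_species[i] <- db$records$species[db$records$ref_id == t_ref[i]]
      t_chim[i] <- TRUE
    } else {
      sp <- sp_pool[sample.int(length(sp_pool), 1, prob = prob)]
      ref <- ref_of_species(db, sp)
      s <- seqs[[ref]]
      if (stats::runif(1) < short_fragment_rate) {
        frag <- round(stats::runif(1, 0.3, 0.8) * MARKER_LENGTH[[design$marker]])
        template <- paste0(TAG5, substr(s, 1, min(frag, nchar(s))))
      } else {
        template <- paste0(TAG5, s, TAG3)
        f <- stats::rnorm(1, 1, length_jitter$sd_frac %||% 0)
        if (f < 1) {
          cut <- round((1 - max(f, 0)) * nchar(template))
          if (cut > 0) {
            template <- if (stats::runif(1) < 0.5)
              substr(template, cut + 1, nchar(template))
            else substr(template, 1, nchar(template) - cut)
          }
        }
      }
      t_ref[i] <- ref; t_ref2[i] <- ""
      t_species[i] <- sp
    }
    mres <- mutate_seq_cpp(template, error$sub, error$ins, error$del)
    rd <- as.character(mres)
    ev <- ev + c(attr(mres, "n_sub"), attr(mres, "n_ins"),
                 attr(mres, "n_del"), attr(mres, "template_bases"))
    if (stats::runif(1) < 0.5) { rd <- revcomp_cpp(rd); out_strand[i] <- "-" }
    else out_strand[i] <- "+"
    out_seq[i] <- rd
  }
  ids <- sprintf("read%06d", seq_len(n))
  reads <- data.frame(read_id = ids, sequence = out_seq,
                      quality = strrep(qchar, nchar(out_seq)),
                      strand = out_strand, stringsAsFactors = FALSE)
  truth <- data.frame(read_id = ids, truth_species = t_species,
                      truth_ref_id = t_ref, truth_ref_id2 = t_ref2,
                      is_chimera = t_chim, is_carryover = FALSE,
                      strand = out_strand, stringsAsFactors = FALSE)
  list(reads = reads, truth = truth, seed = seed, error_events = ev)
}

#' Realized identity from simulator error-event counts
#'
#' The per-run analog of [expected_identity()]: alignment matches are
#' template bases neither deleted nor substituted; columns are all
#' template bases (a deletion leaves a gap column) plus inserted bases.
#'
#' @param sim a [simulate_reads()] result
#' @return realized mean identity (fraction)
#' @export
realized_identity <- function(sim) {
  ev <- sim$error_events
  unname((ev["template_bases"] - ev["n_del"] - ev["n_sub"]) /
           (ev["template_bases"] + ev["n_ins"]))
}

#' Inject carryover contamination from a previous run
#'
#' Adds reads from a contaminant pool so that they make up `fraction` of
#' the combined output, flagging them `is_carryover = TRUE`. All truth
#' labels pass through unchanged. With `fraction = 0` the primary sample
#' is returned as is.
#'
#' @param primary a `simulate_reads()` result (the current sample)
#' @param contaminant a `simulate_reads()` result (the previous run)
#' @param fraction desired contaminant share of the combined reads, in `[0, 1)`
#' @param seed integer seed for sampling and interleaving
#' @return list with `reads` and `truth` as in [simulate_reads()]
#' @export
inject_carryover <- function(primary, contaminant, fraction, seed = 1) {
  if (fraction < 0 || fraction >= 1) stopf("fraction must lie in [0, 1)")
  n_p <- nrow(primary$reads)
  n_c <- round(fraction / (1 - fraction) * n_p)
  if (n_c == 0) return(primary)
  if (n_c > nrow(contaminant$reads))
    stopf("contaminant pool too small: need %d reads, have %d",
          n_c, nrow(contaminant$reads))
  set.seed(seed)
  pick <- sample(nrow(contaminant$reads), n_c)
  c_reads <- contaminant$reads[pick, , drop = FALSE]
  c_truth <- contaminant$truth[pick, , drop = FALSE]
  c_reads$read_id <- paste0("carry_", c_reads$read_id)
  c_truth$read_id <- paste0("carry_", c_truth$read_id)
  c_truth$is_carryover <- TRUE
  ord <- sample(n_p + n_c)
  reads <- rbind(primary$reads, c_reads)[ord, , drop = FALSE]
  truth <- rbind(primary$truth, c_truth)[ord, , drop = FALSE]
  rownames(reads) <- rownames(truth) <- NULL
  list(reads = reads, truth = truth, seed = seed)
}

#' Write reads as FASTQ (4-line records)
#' @param reads data.frame with read_id, sequence, quality
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  q <- Biostrings::BStringSet(reads$quality)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into the read data.frame used by the pipeline
#' @param path FASTQ path
#' @return data.frame with read_id, sequence, quality
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(read_id = names(x), sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}
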