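`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random DNA sequence
#' @param n length in bases
#' @return a single uppercase DNA string
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement of a DNA string
#' @param x character vector of DNA strings
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  vapply(x, revcomp_cpp, character(1), USE.NAMES = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stopf("%s contains characters outside {A,C,G,T,N}: %s", what,
          paste(utils::head(which(bad), 5), collapse = ", "))
  if (any(!nzchar(x))) stopf("%s must be non-empty", what)
  invisible(TRUE)
}
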