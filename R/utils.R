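#' @useDynLib duplexrepair, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character strings (A/C/G/T only).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- character(length(x))
  nz <- nzchar(x)
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

is_dna <- function(x) {
  grepl("^[ACGT]*$", x)
}

#' @keywords internal
rand_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_ALPHABET, n * len, replace = TRUE), nrow = len)
  apply(m, 2, paste0, collapse = "")
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
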