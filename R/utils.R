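# Shared constants and small sequence helpers.

# The 20 standard one-letter amino-acid codes.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x a single DNA string over A/C/G/T.
#' @return the reverse complement, as a character scalar.
#' @keywords internal
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a coding sequence codon by codon
#'
#' Translation starts at the first base and proceeds until the first stop
#' codon or until fewer than three bases remain (a trailing partial codon is
#' dropped). Uses the standard genetic code.
#'
#' @param cds a DNA string.
#' @return list with `peptide` (amino-acid string up to, excluding, any stop)
#'   and `stop_at` (1-based codon index of the first stop, or `NA` if none was
#'   reached).
#' @keywords internal
translate_cds <- function(cds) {
  n_codon <- nchar(cds) %/% 3L
  if (n_codon == 0L) {
    return(list(peptide = "", stop_at = NA_integer_))
  }
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) {
    stop("non-ACGT codon in coding sequence: ",
         paste(codons[is.na(aa)], collapse = ", "))
  }
  stop_at <- which(aa == "*")[1L]
  if (is.na(stop_at)) {
    list(peptide = paste(aa, collapse = ""), stop_at = NA_integer_)
  } else {
    list(peptide = paste(aa[seq_len(stop_at - 1L)], collapse = ""),
         stop_at = stop_at)
  }
}

# split a sequence string into a character vector of residues
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

`%||%` <- function(a, b) if (is.null(a)) b else a
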