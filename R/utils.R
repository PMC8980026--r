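#' Round half away from zero
#'
#' Decimal rounding in which ties go away from zero (`0.0375 -> 0.038`),
#' the convention used for the published per-region tables. Base R's
#' [round()] rounds half to even, which disagrees on exact ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Reverse complement of a nucleotide string
#'
#' @param seq single nucleotide string (A/C/G/T/N, case-insensitive).
#' @return reverse complement, uppercase.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

## single uppercase nucleotide string or fail
check_nucleotide <- function(seq, allow_n = TRUE, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  seq <- toupper(seq)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  if (grepl(sprintf("[^%s]", alphabet), seq)) {
    bad <- unique(strsplit(gsub(sprintf("[%s]", alphabet), "", seq), "")[[1]])
    stop(what, " contains non-nucleotide characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  seq
}
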