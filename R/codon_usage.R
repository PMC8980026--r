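#' The vertebrate mitochondrial genetic code
#'
#' Named character vector mapping the 64 DNA codons to one-letter amino
#' acids, with `"*"` for stops. Differs from the standard code at ATA
#' (Met, not Ile), TGA (Trp, not stop) and AGA/AGG (stop, not Arg); Leu
#' is consequently a six-codon family (TTA/TTG/CTN).
#'
#' @return named character vector of length 64.
#' @export
vertebrate_mito_code <- function() {
  Biostrings::getGeneticCode("2")
}

#' Count in-frame codons over protein-coding genes
#'
#' Reads each sequence in frame from position 1, drops any trailing
#' partial codon (the incomplete-stop remnant), and tallies all in-frame
#' codons including stops. Codons containing N are skipped and counted
#' separately.
#'
#' @param pcg_seqs character vector (or list) of coding-strand nucleotide
#'   sequences, each of length >= 3.
#' @return object of class `"codon_usage"`: `counts` (named integer, 64
#'   codons), `n_codons`, `n_skipped`, `aa` (codon -> amino acid),
#'   `aa_freq` (percentage of total codons per amino acid, stops included
#'   under `"*"`), and an `rscu` slot filled by [rscu()].
#' @export
count_codons <- function(pcg_seqs) {
  pcg_seqs <- vapply(unlist(pcg_seqs, use.names = FALSE), check_nucleotide,
                     character(1), USE.NAMES = FALSE)
  if (any(nchar(pcg_seqs) < 3L)) {
    stop("each sequence must be at least one codon long", call. = FALSE)
  }
  code <- vertebrate_mito_code()
  counts <- stats::setNames(integer(length(code)), names(code))
  n_skipped <- 0L
  for (s in pcg_seqs) {
    n_full <- nchar(s) %/% 3L
    cods <- substring(s, 3L * seq_len(n_full) - 2L, 3L * seq_len(n_full))
    has_n <- grepl("N", cods, fixed = TRUE)
    n_skipped <- n_skipped + sum(has_n)
    tab <- table(cods[!has_n])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  n_codons <- sum(counts)
  aa_freq <- 100 * tapply(counts, code[names(counts)], sum) / n_codons
  structure(list(
    counts = counts, n_codons = n_codons, n_skipped = n_skipped,
    aa = code, aa_freq = aa_freq, rscu = NULL
  ), class = "codon_usage")
}

#' Relative synonymous codon usage (RSCU)
#'
#' For codon j in a synonymous family of size n with counts X:
#' `RSCU_j = X_j * n / sum(X)` — the observed count divided by the count
#' expected if all synonyms were used equally. RSCU is 1 for unbiased
#' usage, > 1 for preferred codons, 0 for an unused codon of an observed
#' family, and `NA` (missing) throughout a family with zero observations.
#' Families follow the vertebrate mitochondrial code; stop codons form
#' their own family and are excluded by default.
#'
#' @param table a [count_codons()] result.
#' @param include_stops also compute RSCU over the stop-codon family.
#' @return the same object with its `rscu` slot filled (named numeric per
#'   codon).
#' @export
rscu <- function(table, include_stops = FALSE) {
  stopifnot(inherits(table, "codon_usage"))
  counts <- table$counts
  aa <- table$aa[names(counts)]
  vals <- stats::setNames(rep(NA_real_, length(counts)), names(counts))
  for (a in unique(aa)) {
    if (a == "*" && !include_stops) next
    fam <- names(counts)[aa == a]
    tot <- sum(counts[fam])
    if (tot == 0) next  # unobserved family: RSCU undefined, stays NA
    vals[fam] <- counts[fam] * length(fam) / tot
  }
  table$rscu <- vals
  table
}

#' Codon usage as a data frame
#'
#' @param x a `codon_usage` object.
#' @param ... unused.
#' @return `data.frame` with columns `codon`, `aa`, `count`, `rscu`.
#' @method as.data.frame codon_usage
#' @export
as.data.frame.codon_usage <- function(x, ...) {
  data.frame(
    codon = names(x$counts),
    aa = unname(x$aa[names(x$counts)]),
    count = unname(x$counts),
    rscu = if (is.null(x$rscu)) NA_real_ else unname(x$rscu),
    stringsAsFactors = FALSE
  )
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("<codon_usage> %d codons counted (%d skipped for N)\n",
              x$n_codons, x$n_skipped))
  top <- sort(x$aa_freq, decreasing = TRUE)
  cat("  most frequent residues:",
      paste(sprintf("%s %.2f%%", names(top)[1:3], top[1:3]), collapse = ", "),
      "\n")
  invisible(x)
}
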