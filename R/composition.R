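#' Base composition of a nucleotide sequence
#'
#' Percentages of A/T/G/C over the unambiguous (non-N) length, retained at
#' full precision; display rounding is applied only in report tables.
#'
#' @param seq nucleotide string (A/C/G/T/N, case-insensitive).
#' @return object of class `"base_composition"`: counts, percentages
#'   (`a_pct`, `t_pct`, `g_pct`, `c_pct`), `at_pct`, `gc_pct`, `n_count`.
#' @export
base_composition <- function(seq) {
  seq <- check_nucleotide(seq)
  if (!nzchar(seq)) stop("empty sequence: composition undefined", call. = FALSE)
  cnt <- Biostrings::alphabetFrequency(Biostrings::DNAString(seq))
  counts <- cnt[c("A", "T", "G", "C")]
  n_count <- unname(cnt["N"])
  denom <- sum(counts)
  if (denom == 0) stop("all-N sequence: composition undefined", call. = FALSE)
  if (n_count / (denom + n_count) > 0.10) {
    warning(sprintf("%.1f%% ambiguous bases excluded from composition",
                    100 * n_count / (denom + n_count)), call. = FALSE)
  }
  pct <- 100 * counts / denom
  structure(list(
    counts = counts,
    a_pct = unname(pct["A"]), t_pct = unname(pct["T"]),
    g_pct = unname(pct["G"]), c_pct = unname(pct["C"]),
    at_pct = unname(pct["A"] + pct["T"]),
    gc_pct = unname(pct["G"] + pct["C"]),
    n_count = n_count
  ), class = "base_composition")
}

#' @export
print.base_composition <- function(x, ...) {
  cat(sprintf("A %.1f%%  T %.1f%%  G %.1f%%  C %.1f%%  (A+T %.1f, G+C %.1f)\n",
              round_half_up(x$a_pct, 1), round_half_up(x$t_pct, 1),
              round_half_up(x$g_pct, 1), round_half_up(x$c_pct, 1),
              round_half_up(x$at_pct, 1), round_half_up(x$gc_pct, 1)))
  invisible(x)
}

#' AT and GC strand skews
#'
#' AT skew = (A - T)/(A + T); GC skew = (G - C)/(G + C). Both are
#' dimensionless in [-1, 1] and measure strand compositional asymmetry;
#' they are 0 on a base-balanced sequence. Computed at full precision;
#' a skew with zero denominator is reported as `NA` (missing), never 0.
#'
#' @param comp a [base_composition()] object, or anything with fields
#'   `a_pct`, `t_pct`, `g_pct`, `c_pct` (e.g. printed table percentages
#'   via [skew_pair()]).
#' @return list with `at_skew` and `gc_skew`.
#' @export
skews <- function(comp) {
  skew_pair(comp$a_pct, comp$t_pct, comp$g_pct, comp$c_pct)
}

#' @rdname skews
#' @param a,t,g,c base percentages (or counts; only ratios matter).
#' @export
skew_pair <- function(a, t, g, c) {
  at <- a + t
  gc <- g + c
  list(
    at_skew = ifelse(at > 0, (a - t) / at, NA_real_),
    gc_skew = ifelse(gc > 0, (g - c) / gc, NA_real_)
  )
}

.mito_stops <- c("TAA", "TAG", "AGA", "AGG")

#' Classify start and stop codons of a mitochondrial gene
#'
#' The start codon is the first three bases. The stop is classified from
#' the gene length modulo 3: complete (length divisible by 3; last codon
#' checked against the vertebrate mitochondrial stops TAA/TAG/AGA/AGG),
#' `TA_incomplete` (remainder 2, displayed `"TA-"`) or `T_incomplete`
#' (remainder 1, displayed `"T--"`). Incomplete stops are completed to TAA
#' by polyadenylation of the mRNA and are common at mitochondrial gene
#' ends abutting a downstream tRNA.
#'
#' @param gene_seq coding-strand nucleotide string, length >= 6.
#' @return list with `start_codon`, `stop_kind`
#'   (`"complete"`/`"TA_incomplete"`/`"T_incomplete"`) and `stop_text`.
#' @export
classify_codons <- function(gene_seq) {
  gene_seq <- check_nucleotide(gene_seq)
  n <- nchar(gene_seq)
  if (n < 6L) stop("gene sequence shorter than 6 bp", call. = FALSE)
  start_codon <- substr(gene_seq, 1L, 3L)
  rem <- n %% 3L
  if (rem == 0L) {
    stop_text <- substr(gene_seq, n - 2L, n)
    if (!stop_text %in% .mito_stops) {
      warning("final codon ", stop_text,
              " is not a vertebrate mitochondrial stop", call. = FALSE)
    }
    stop_kind <- "complete"
  } else if (rem == 2L) {
    tail2 <- substr(gene_seq, n - 1L, n)
    if (tail2 != "TA") {
      warning("trailing bases '", tail2, "' of TA-incomplete stop are not TA",
              call. = FALSE)
    }
    stop_kind <- "TA_incomplete"
    stop_text <- "TA-"
  } else {
    tail1 <- substr(gene_seq, n, n)
    if (tail1 != "T") {
      warning("trailing base '", tail1, "' of T-incomplete stop is not T",
              call. = FALSE)
    }
    stop_kind <- "T_incomplete"
    stop_text <- "T--"
  }
  list(start_codon = start_codon, stop_kind = stop_kind, stop_text = stop_text)
}

#' Per-region statistics table
#'
#' One row per annotated feature in genome order — size, base composition,
#' A+T / G+C content, AT/GC skews, start/stop codons (PCGs only) and the
#' intergenic distance to the next feature (negative = overlap) — plus a
#' final whole-genome row computed on the H strand. Per-feature statistics
#' are computed on the coding-strand sequence, so L-strand regions show
#' their own strand's composition.
#'
#' @param record a `mitogenome` record. Without a sequence, only size and
#'   intergenic columns are filled.
#' @param rounding `"paper"` (percentages to 1 decimal, skews to 3, half-up,
#'   the published display convention) or `"full"` (6 decimals).
#' @return `data.frame` with one row per feature plus a `"genome"` row.
#' @export
region_stats_table <- function(record, rounding = c("paper", "full")) {
  rounding <- match.arg(rounding)
  feats <- record$features
  n <- nrow(feats)
  if (!n) stop("record has no features", call. = FALSE)
  out <- feats[, c("locus", "strand", "start", "end", "size", "category",
                   "anticodon")]
  num_cols <- c("a_pct", "t_pct", "g_pct", "c_pct", "at_pct", "gc_pct",
                "at_skew", "gc_skew")
  for (col in num_cols) out[[col]] <- NA_real_
  out$start_codon <- NA_character_
  out$stop_codon <- NA_character_

  if (!is.null(record$sequence)) {
    for (i in seq_len(n)) {
      s <- extract_gene_sequence(record, feats[i, ])
      comp <- base_composition(s)
      sk <- skews(comp)
      out$a_pct[i] <- comp$a_pct; out$t_pct[i] <- comp$t_pct
      out$g_pct[i] <- comp$g_pct; out$c_pct[i] <- comp$c_pct
      out$at_pct[i] <- comp$at_pct; out$gc_pct[i] <- comp$gc_pct
      out$at_skew[i] <- sk$at_skew; out$gc_skew[i] <- sk$gc_skew
      if (feats$category[i] == "PCG" && feats$size[i] >= 6L) {
        cc <- suppressWarnings(classify_codons(s))
        out$start_codon[i] <- cc$start_codon
        out$stop_codon[i] <- cc$stop_text
      }
    }
  }

  gaps <- if (n >= 2L) {
    so <- spacers_and_overlaps(record)
    ifelse(so$kind == "overlap", -so$length, so$length)
  } else integer(0)
  out$intergenic <- c(gaps, NA_integer_)

  genome <- out[1, ]
  genome[1, ] <- NA
  genome$locus <- "genome"; genome$strand <- "H"
  genome$start <- 1L; genome$end <- record$length
  genome$size <- record$length; genome$category <- NA_character_
  if (!is.null(record$sequence)) {
    comp <- base_composition(record$sequence)
    sk <- skews(comp)
    genome$a_pct <- comp$a_pct; genome$t_pct <- comp$t_pct
    genome$g_pct <- comp$g_pct; genome$c_pct <- comp$c_pct
    genome$at_pct <- comp$at_pct; genome$gc_pct <- comp$gc_pct
    genome$at_skew <- sk$at_skew; genome$gc_skew <- sk$gc_skew
  }
  out <- rbind(out, genome)
  rownames(out) <- NULL

  if (rounding == "paper") {
    pct_cols <- c("a_pct", "t_pct", "g_pct", "c_pct", "at_pct", "gc_pct")
    out[pct_cols] <- lapply(out[pct_cols], round_half_up, digits = 1)
    out[c("at_skew", "gc_skew")] <-
      lapply(out[c("at_skew", "gc_skew")], round_half_up, digits = 3)
  } else {
    out[num_cols] <- lapply(out[num_cols], round_half_up, digits = 6)
  }
  out
}
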