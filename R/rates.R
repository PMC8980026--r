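#' Pairwise p-distances over an aligned gene set
#'
#' Proportion of differing sites between each pair of aligned sequences,
#' with pairwise deletion: for each pair, alignment columns where either
#' sequence has a gap (`-`) or `N` are dropped before counting. The
#' partition restricts the comparison to codon positions — `"all"` (every
#' site), `"pos12"` (first and second positions, where changes are mostly
#' nonsynonymous) or `"pos3"` (third/wobble positions, where most
#' mitochondrial divergence accumulates).
#'
#' @param aln named character vector of aligned sequences (equal lengths),
#'   or a `Biostrings::DNAStringSet`.
#' @param partition `"all"`, `"pos12"` or `"pos3"`; codon frame starts at
#'   alignment column 1.
#' @return list of class `"p_distance"`: `partition`, `matrix` (symmetric,
#'   zero diagonal; `NA` where a pair had no comparable sites) and
#'   `mean_p` (mean over all unordered pairs with defined distance).
#' @export
p_distance <- function(aln, partition = c("all", "pos12", "pos3")) {
  partition <- match.arg(partition)
  aln <- as_aligned_matrix(aln)
  ntax <- nrow(aln)
  if (ntax < 2L) stop("need at least 2 taxa", call. = FALSE)
  pos <- seq_len(ncol(aln))
  keep_pos <- switch(partition,
    all = pos,
    pos12 = pos[(pos - 1L) %% 3L < 2L],
    pos3 = pos[(pos - 1L) %% 3L == 2L]
  )
  m <- matrix(0, ntax, ntax, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(ntax - 1L)) {
    for (j in seq(i + 1L, ntax)) {
      a <- aln[i, keep_pos]
      b <- aln[j, keep_pos]
      ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
      if (!any(ok)) {
        warning("no comparable sites for pair ", rownames(aln)[i], " / ",
                rownames(aln)[j], call. = FALSE)
        m[i, j] <- m[j, i] <- NA_real_
      } else {
        m[i, j] <- m[j, i] <- mean(a[ok] != b[ok])
      }
    }
  }
  structure(list(partition = partition, matrix = m,
                 mean_p = mean(m[upper.tri(m)], na.rm = TRUE)),
            class = "p_distance")
}

as_aligned_matrix <- function(aln) {
  if (inherits(aln, "DNAStringSet") || inherits(aln, "XStringSet")) {
    aln <- stats::setNames(as.character(aln), names(aln))
  }
  if (is.null(names(aln))) names(aln) <- paste0("taxon", seq_along(aln))
  if (length(unique(nchar(aln))) != 1L) {
    stop("aligned sequences must all have the same length", call. = FALSE)
  }
  do.call(rbind, lapply(aln, function(s) strsplit(toupper(s), "")[[1]]))
}

## ---- Nei-Gojobori (1986) ---------------------------------------------------

.bases <- c("A", "C", "G", "T")

## per-codon count of synonymous sites: at each position, the fraction of
## the 3 possible single-base changes that preserve the amino acid.
## Changes to stop codons count as nonsynonymous (classic NG86).
ng_syn_sites <- function(codon, code) {
  s <- 0
  for (pos in 1:3) {
    orig <- substr(codon, pos, pos)
    for (b in setdiff(.bases, orig)) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (code[[mut]] == code[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .permutations(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

## average synonymous/nonsynonymous difference counts between two codons,
## over all minimal mutational pathways with equal weights
ng_diff_counts <- function(c1, c2, code) {
  diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(diffpos)) return(c(sd = 0, nd = 0))
  sd_tot <- 0; nd_tot <- 0
  paths <- .permutations(diffpos)
  for (path in paths) {
    cur <- c1
    for (pos in path) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (code[[nxt]] == code[[cur]]) sd_tot <- sd_tot + 1
      else nd_tot <- nd_tot + 1
      cur <- nxt
    }
  }
  c(sd = sd_tot / length(paths), nd = nd_tot / length(paths))
}

split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Nei-Gojobori Ka/Ks for one aligned coding pair
#'
#' Classic Nei-Gojobori (1986) counting under the vertebrate mitochondrial
#' code: per-codon synonymous site fractions; differences at multi-hit
#' codons averaged over all minimal mutational pathways with equal
#' weights; proportions pS = Sd/S and pN = Nd/N corrected for multiple
#' substitutions with the Jukes-Cantor formula d = -(3/4) ln(1 - 4p/3).
#' Changes to (and pathway steps through) stop codons are counted as
#' nonsynonymous.
#'
#' Codons containing a gap or N in either sequence are removed pairwise
#' before counting; a trailing stop codon shared by both sequences is
#' trimmed; an internal stop raises an error (alignment frame problem).
#'
#' @param seq1,seq2 aligned coding-strand sequences, equal length
#'   divisible by 3.
#' @return list of class `"kaks"`: `Ka`, `Ks`, `ratio` (NA when Ks = 0 or
#'   a correction is undefined), uncorrected `pN`, `pS`, site counts `N`,
#'   `S`, difference counts `Nd`, `Sd`, `n_codons` used, and `reason` when
#'   a value is missing.
#' @export
kaks_pair <- function(seq1, seq2) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2)) {
    stop("sequences must be aligned to equal length", call. = FALSE)
  }
  if (nchar(seq1) %% 3L != 0L) {
    stop("alignment length must be divisible by 3", call. = FALSE)
  }
  code <- vertebrate_mito_code()
  cod1 <- split_codons(seq1)
  cod2 <- split_codons(seq2)
  clean <- !grepl("[-N]", cod1) & !grepl("[-N]", cod2)
  cod1 <- cod1[clean]; cod2 <- cod2[clean]
  nc <- length(cod1)
  if (!nc) stop("no gap-free codons to compare", call. = FALSE)
  ## trailing stop shared by both -> trim; internal stop -> frame error
  if (code[[cod1[nc]]] == "*" || code[[cod2[nc]]] == "*") {
    cod1 <- cod1[-nc]; cod2 <- cod2[-nc]; nc <- nc - 1L
  }
  if (any(code[cod1] == "*") || any(code[cod2] == "*")) {
    stop("internal stop codon: check alignment frame", call. = FALSE)
  }

  s1 <- sum(vapply(cod1, ng_syn_sites, numeric(1), code = code))
  s2 <- sum(vapply(cod2, ng_syn_sites, numeric(1), code = code))
  S <- (s1 + s2) / 2
  N <- 3 * nc - S
  d <- vapply(seq_len(nc),
              function(i) ng_diff_counts(cod1[i], cod2[i], code),
              numeric(2))
  Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_

  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p == 0) return(0)
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  Ks <- jc(pS); Ka <- jc(pN)
  reason <- NULL
  if (is.na(Ks) && !is.na(pS)) reason <- "pS >= 3/4: Jukes-Cantor correction undefined"
  if (is.na(Ka) && !is.na(pN)) reason <- "pN >= 3/4: Jukes-Cantor correction undefined"
  ratio <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  if (is.na(ratio) && is.null(reason)) reason <- "Ks = 0: ratio undefined"
  structure(list(Ka = Ka, Ks = Ks, ratio = ratio, pN = pN, pS = pS,
                 N = N, S = S, Nd = Nd, Sd = Sd, n_codons = nc,
                 reason = reason),
            class = "kaks")
}

#' @export
print.kaks <- function(x, ...) {
  cat(sprintf("Ka = %.4f, Ks = %.4f, Ka/Ks = %s (%d codons)\n",
              x$Ka, x$Ks,
              if (is.na(x$ratio)) paste0("NA [", x$reason, "]")
              else sprintf("%.4f", x$ratio),
              x$n_codons))
  invisible(x)
}

#' Gene-averaged Ka/Ks over all sequence pairs
#'
#' Runs [kaks_pair()] on every unordered pair of an aligned gene set and
#' averages the defined pairwise values; pairs with an undefined ratio
#' (Ks = 0 or saturated) are excluded from the ratio mean and counted.
#'
#' @param aln named character vector (or `DNAStringSet`) of aligned coding
#'   sequences; >= 2 taxa.
#' @return list: `mean_ka`, `mean_ks`, `mean_kaks`, `n_pairs`,
#'   `n_undefined`, and the per-pair data.frame `pairs`.
#' @export
gene_average_kaks <- function(aln) {
  m <- as_aligned_matrix(aln)
  seqs <- apply(m, 1L, paste, collapse = "")
  ntax <- length(seqs)
  if (ntax < 2L) stop("need at least 2 taxa", call. = FALSE)
  rows <- list()
  for (i in seq_len(ntax - 1L)) {
    for (j in seq(i + 1L, ntax)) {
      k <- kaks_pair(seqs[i], seqs[j])
      rows[[length(rows) + 1L]] <- data.frame(
        taxon1 = names(seqs)[i], taxon2 = names(seqs)[j],
        Ka = k$Ka, Ks = k$Ks, ratio = k$ratio, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  defined <- !is.na(pairs$ratio)
  list(
    mean_ka = mean(pairs$Ka, na.rm = TRUE),
    mean_ks = mean(pairs$Ks, na.rm = TRUE),
    mean_kaks = if (any(defined)) mean(pairs$ratio[defined]) else NA_real_,
    n_pairs = nrow(pairs),
    n_undefined = sum(!defined),
    pairs = pairs
  )
}
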