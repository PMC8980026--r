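# Independent oracles, deliberately coded apart from the package internals.

# Vertebrate mitochondrial translation table, hard-coded from the standard
# NCBI table-2 string (codon order: pos1, pos2, pos3 each cycling T,C,A,G).
oracle_code <- local({
  aas <- strsplit(
    "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSS**VVVVAAAADDEEGGGG",
    "")[[1]]
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0)))
  stats::setNames(aas, codons)
})

oracle_translate <- function(codon) oracle_code[[codon]]

# Per-codon synonymous site count: fraction of the 9 single-base mutations
# that preserve the amino acid (stop products = nonsynonymous), summed by
# position as thirds.
oracle_syn_sites <- function(codon) {
  total <- 0
  for (pos in 1:3) {
    syn <- 0
    for (b in c("T", "C", "A", "G")) {
      if (b == substr(codon, pos, pos)) next
      mut <- paste0(substr(codon, 1, pos - 1), b, substr(codon, pos + 1, 3))
      if (oracle_translate(mut) == oracle_translate(codon)) syn <- syn + 1
    }
    total <- total + syn / 3
  }
  total
}

# All orderings of a short vector, by explicit recursion.
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  res <- list()
  for (i in seq_along(v)) {
    for (tail in oracle_perms(v[-i])) res[[length(res) + 1]] <- c(v[i], tail)
  }
  res
}

# Pathway-averaged synonymous/nonsynonymous differences between two codons.
oracle_codon_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  sd_sum <- 0; nd_sum <- 0
  paths <- oracle_perms(pos)
  for (pth in paths) {
    cur <- c1
    for (p in pth) {
      nxt <- paste0(substr(cur, 1, p - 1), substr(c2, p, p),
                    substr(cur, p + 1, 3))
      if (oracle_translate(nxt) == oracle_translate(cur)) {
        sd_sum <- sd_sum + 1
      } else {
        nd_sum <- nd_sum + 1
      }
      cur <- nxt
    }
  }
  c(sd_sum / length(paths), nd_sum / length(paths))
}

# Full Nei-Gojobori on two gap-free, stop-free coding strings.
oracle_kaks <- function(s1, s2) {
  n <- nchar(s1) / 3
  c1 <- substring(s1, 3 * (1:n) - 2, 3 * (1:n))
  c2 <- substring(s2, 3 * (1:n) - 2, 3 * (1:n))
  S <- (sum(sapply(c1, oracle_syn_sites)) +
        sum(sapply(c2, oracle_syn_sites))) / 2
  N <- 3 * n - S
  diffs <- sapply(seq_len(n), function(i) oracle_codon_diffs(c1[i], c2[i]))
  Sd <- sum(diffs[1, ]); Nd <- sum(diffs[2, ])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p == 0) 0 else if (p >= 0.75) NA else -0.75 * log(1 - 4 * p / 3)
  list(Ka = jc(pN), Ks = jc(pS), pN = pN, pS = pS, S = S, N = N,
       Sd = Sd, Nd = Nd)
}

# Mann-Whitney U by direct pair counting (ties contribute 1/2).
oracle_rank_sum_U <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# Naive exact substring search: leftmost 1-based start or NA.
oracle_substring_search <- function(region, motif) {
  n <- nchar(region); m <- nchar(motif)
  if (m > n) return(NA_integer_)
  for (i in 1:(n - m + 1)) {
    if (substr(region, i, i + m - 1) == motif) return(i)
  }
  NA_integer_
}

# Random stop-free coding sequence for oracle cross-checks.
random_coding <- function(n_codons) {
  stops <- c("TAA", "TAG", "AGA", "AGG")
  pool <- setdiff(names(oracle_code), stops)
  paste(sample(pool, n_codons, replace = TRUE), collapse = "")
}

# Mutate k random positions of a coding string, rejecting stop codons.
mutate_coding <- function(seq, k) {
  b <- strsplit(seq, "")[[1]]
  stops <- c("TAA", "TAG", "AGA", "AGG")
  done <- 0; guard <- 0
  while (done < k && guard < 100 * k) {
    guard <- guard + 1
    i <- sample(length(b), 1)
    old <- b[i]
    cand <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    b[i] <- cand
    ci <- (i - 1) %/% 3
    codon <- paste(b[(3 * ci + 1):(3 * ci + 3)], collapse = "")
    if (codon %in% stops) { b[i] <- old; next }
    done <- done + 1
  }
  paste(b, collapse = "")
}
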