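#' Specification for the synthetic-mitogenome generator
#'
#' Collects every knob of the generator with defaults emulating the
#' Decapterus russelli worked example: the 38-feature annotation layout
#' with its printed coordinates; whole-genome H-strand base probabilities
#' A 0.275, C 0.302, T 0.254, G 0.169 (the A/C-rich heavy strand); an
#' AT-rich control region (A 0.330, T 0.306, G 0.163, C 0.201); the
#' shipped CSB motif library; and tRNA groups of 14 heavy-strand and 8
#' light-strand genes with per-pair G-U wobble probabilities 0.03 (H) and
#' 0.13 (L), the strand contrast reported across carangids. The seed
#' fully determines all output.
#'
#' @param seed integer seed.
#' @param base_probs named probabilities for A/C/G/T on the H strand.
#' @param cr_base_probs control-region background probabilities.
#' @param layout feature table (with `start_codon`/`stop_codon` columns
#'   for PCGs); defaults to the shipped D. russelli annotation.
#' @param codon_weights optional named sampling weights over the 64
#'   codons for PCG interiors; default proportional to the product of
#'   `base_probs`, stop codons excluded.
#' @param motif_lib control-region motif library data.frame.
#' @param motif_edits named list `list(name = c(sub, indel))` of edit
#'   counts to plant per motif; default 0 edits for all.
#' @param n_palindromes copies of TACAT/ATGTA planted near the 5' end.
#' @param t_run_len length of the T homopolymer planted between CSB-D
#'   and CSB-1 (5-12 in carangids).
#' @param cr_length control-region length when generated stand-alone.
#' @param trna_n named count of tRNAs per strand group.
#' @param wobble_p named per-pair wobble probability per strand group.
#' @param n_species replicate structure sets (species) for tRNA tallies.
#' @return list of class `"generator_spec"`.
#' @export
generator_spec <- function(seed = 1L,
                           base_probs = c(A = 0.275, C = 0.302,
                                          T = 0.254, G = 0.169),
                           cr_base_probs = c(A = 0.330, T = 0.306,
                                             G = 0.163, C = 0.201),
                           layout = NULL,
                           codon_weights = NULL,
                           motif_lib = NULL,
                           motif_edits = NULL,
                           n_palindromes = 3L,
                           t_run_len = 8L,
                           cr_length = 840L,
                           trna_n = c(H = 14L, L = 8L),
                           wobble_p = c(H = 0.03, L = 0.13),
                           n_species = 1L) {
  stopifnot(abs(sum(base_probs) - 1) < 1e-6,
            abs(sum(cr_base_probs) - 1) < 1e-6,
            all(wobble_p >= 0 & wobble_p <= 1))
  if (is.null(layout)) {
    rec <- decapterus_annotation()
    layout <- rec$features
  }
  if (is.null(motif_lib)) motif_lib <- default_motif_library()
  if (is.null(codon_weights)) {
    code <- vertebrate_mito_code()
    codons <- names(code)
    w <- vapply(codons, function(cd) {
      prod(base_probs[strsplit(cd, "")[[1]]])
    }, numeric(1))
    w[code == "*"] <- 0
    codon_weights <- w / sum(w)
  }
  structure(list(
    seed = as.integer(seed), base_probs = base_probs,
    cr_base_probs = cr_base_probs, layout = layout,
    codon_weights = codon_weights, motif_lib = motif_lib,
    motif_edits = motif_edits, n_palindromes = as.integer(n_palindromes),
    t_run_len = as.integer(t_run_len), cr_length = as.integer(cr_length),
    trna_n = trna_n, wobble_p = wobble_p, n_species = as.integer(n_species)
  ), class = "generator_spec")
}

sample_bases <- function(n, probs) {
  if (n <= 0L) return(character(0))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

## in-frame coding sequence for one PCG of the layout
build_pcg_seq <- function(size, start_codon, stop_codon, codon_weights) {
  rem <- size %% 3L
  codons <- names(codon_weights)
  draw <- function(k) {
    if (k <= 0L) return(character(0))
    sample(codons, k, replace = TRUE, prob = codon_weights)
  }
  if (is.na(stop_codon)) stop_codon <- "TAA"
  if (stop_codon %in% c("TAA", "TAG", "AGA", "AGG")) {
    if (rem != 0L) stop("size ", size, " incompatible with complete stop",
                        call. = FALSE)
    body <- draw(size %/% 3L - 2L)
    paste0(start_codon, paste(body, collapse = ""), stop_codon)
  } else if (stop_codon == "TA-") {
    if (rem != 2L) stop("size ", size, " incompatible with TA- stop", call. = FALSE)
    body <- draw(size %/% 3L - 1L)
    paste0(start_codon, paste(body, collapse = ""), "TA")
  } else if (stop_codon == "T--") {
    if (rem != 1L) stop("size ", size, " incompatible with T-- stop", call. = FALSE)
    body <- draw(size %/% 3L - 1L)
    paste0(start_codon, paste(body, collapse = ""), "T")
  } else {
    stop("unknown stop codon pattern: ", stop_codon, call. = FALSE)
  }
}

#' Generate a synthetic annotated mitogenome
#'
#' Builds a full-length H-strand sequence from the spec's base
#' probabilities, then writes every protein-coding gene in frame at its
#' layout coordinates (chosen start codon, complete or incomplete stop
#' per the layout's stop pattern; L-strand genes written as reverse
#' complements), plants the mTERF tridecamer inside tRNA-Leu(TAA), and
#' replaces the control-region span with a [generate_control_region()]
#' product. Where the layout makes genes overlap, the later feature's
#' bases win, as they must on a single molecule; ground truth records the
#' planted (pre-overwrite) coding sequences.
#'
#' @param spec a [generator_spec()].
#' @return list: `record` (a [mitogenome_record()] with sequence) and
#'   `truth` (planted PCG sequences, start/stop codons, mTERF position,
#'   control-region ground truth, base probabilities, seed).
#' @export
generate_mitogenome <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  layout <- spec$layout
  glen <- max(layout$end)
  genome <- sample_bases(glen, spec$base_probs)

  truth <- list(seed = spec$seed, base_probs = spec$base_probs,
                pcg_seqs = list(), start_codons = character(),
                stop_codons = character())

  pcgs <- layout[layout$category == "PCG", , drop = FALSE]
  if (nrow(pcgs) &&
      (!"start_codon" %in% names(pcgs) || anyNA(pcgs$start_codon))) {
    stop("layout PCGs need start_codon/stop_codon columns", call. = FALSE)
  }
  for (i in seq_len(nrow(pcgs))) {
    f <- pcgs[i, ]
    cseq <- build_pcg_seq(f$size, f$start_codon, f$stop_codon,
                          spec$codon_weights)
    placed <- if (f$strand == "L") revcomp(cseq) else cseq
    genome[f$start:f$end] <- strsplit(placed, "")[[1]]
    truth$pcg_seqs[[f$locus]] <- cseq
    truth$start_codons[f$locus] <- f$start_codon
    truth$stop_codons[f$locus] <- f$stop_codon
  }

  ## mTERF tridecamer inside tRNA-Leu(TAA), offset into its DHU-arm region
  leu <- layout[layout$locus == "tRNA-Leu(TAA)", ]
  if (nrow(leu) == 1L) {
    lib <- spec$motif_lib
    mterf <- lib$sequence[lib$name == "mTERF"]
    if (length(mterf) == 1L) {
      at <- leu$start + 9L
      genome[at:(at + nchar(mterf) - 1L)] <- strsplit(mterf, "")[[1]]
      truth$mterf <- list(start = at, offset_in_gene = at - leu$start + 1L)
    }
  }

  cr <- layout[layout$category == "control_region", ]
  if (nrow(cr) == 1L) {
    sub <- spec
    sub$cr_length <- cr$size
    crg <- generate_control_region(sub, .reseed = FALSE)
    genome[cr$start:cr$end] <- strsplit(crg$region, "")[[1]]
    crg$truth$offset <- cr$start - 1L
    truth$control_region <- crg$truth
  }

  record <- mitogenome_record(
    id = sprintf("synthetic_seed%d", spec$seed),
    length = glen, features = layout,
    sequence = paste(genome, collapse = "")
  )
  ## keep codon annotation for reporting
  for (col in c("start_codon", "stop_codon")) {
    if (col %in% names(layout)) record$features[[col]] <- layout[[col]]
  }
  list(record = record, truth = truth)
}

## apply exactly n_sub/n_ins/n_del random edits to a motif, interior
## positions only so the planted boundaries stay unambiguous
plant_edits <- function(motif, n_sub = 0L, n_ind = 0L) {
  b <- strsplit(motif, "")[[1]]
  n <- length(b)
  interior <- seq(3L, n - 2L)
  if (n_sub + n_ind > length(interior)) {
    stop("edit budget exceeds motif interior", call. = FALSE)
  }
  pos <- sample(interior, n_sub + n_ind)
  sub_pos <- pos[seq_len(n_sub)]
  for (p in sub_pos) b[p] <- sample(setdiff(.bases, b[p]), 1L)
  n_ins <- 0L; n_del <- 0L
  if (n_ind > 0L) {
    ind_pos <- pos[seq(n_sub + 1L, n_sub + n_ind)]
    kinds <- sample(c("ins", "del"), n_ind, replace = TRUE)
    ## apply right-to-left so earlier positions stay valid
    ord <- order(ind_pos, decreasing = TRUE)
    for (k in ord) {
      p <- ind_pos[k]
      if (kinds[k] == "del") {
        b <- b[-p]; n_del <- n_del + 1L
      } else {
        b <- append(b, sample(.bases, 1L), after = p)
        n_ins <- n_ins + 1L
      }
    }
  }
  list(text = paste(b, collapse = ""), n_sub = n_sub,
       n_ins = n_ins, n_del = n_del)
}

#' Generate a synthetic control region with planted motifs
#'
#' Lays the six conserved sequence blocks and the 3'-terminal sequence
#' down in canonical order on an AT-rich random background, each mutated
#' by exactly the requested number of substitutions and indels at
#' recorded positions; plants TACAT/ATGTA palindrome copies near the 5'
#' end and a T homopolymer between CSB-D and CSB-1. The background is
#' resampled (deterministically, under the spec seed) until every planted
#' motif is recovered by [scan_motif()] at its recorded position and edit
#' counts, so the ground truth is exact.
#'
#' @param spec a [generator_spec()]; `motif_edits`, `n_palindromes`,
#'   `t_run_len` and `cr_length` are the relevant fields.
#' @param .reseed set the RNG from `spec$seed` (disabled when called from
#'   [generate_mitogenome()], which owns the RNG stream).
#' @return list: `region` (nucleotide string) and `truth` (per-motif
#'   planted start/end/edit counts, palindrome positions, T-run position
#'   and length).
#' @export
generate_control_region <- function(spec = generator_spec(), .reseed = TRUE) {
  stopifnot(inherits(spec, "generator_spec"))
  if (.reseed) set.seed(spec$seed)
  lib <- spec$motif_lib
  wanted <- c(.csb_order, "terminal-3prime")
  edits <- spec$motif_edits
  get_edits <- function(nm) {
    e <- if (!is.null(edits) && nm %in% names(edits)) edits[[nm]] else c(0L, 0L)
    c(sub = as.integer(e[1]), ind = as.integer(e[2]))
  }

  for (attempt in 1:25) {
    region <- sample_bases(spec$cr_length, spec$cr_base_probs)
    truth <- list(motifs = list(), palindromes = NULL, t_run = NULL)

    ## palindromes near the 5' end
    pal_pos <- integer(0)
    cursor <- 5L
    for (k in seq_len(spec$n_palindromes)) {
      p <- if (k %% 2L == 1L) "TACAT" else "ATGTA"
      region[cursor:(cursor + 4L)] <- strsplit(p, "")[[1]]
      pal_pos <- c(pal_pos, cursor)
      cursor <- cursor + 5L + sample(5:12, 1L)
    }
    truth$palindromes <- data.frame(
      motif = rep(c("TACAT", "ATGTA"),
                  length.out = spec$n_palindromes),
      start = pal_pos, stringsAsFactors = FALSE)

    ## motifs in canonical order with random spacers
    cursor <- cursor + sample(15:30, 1L)
    ok_layout <- TRUE
    for (nm in wanted) {
      mseq <- lib$sequence[lib$name == nm]
      e <- get_edits(nm)
      planted <- plant_edits(mseq, e[["sub"]], e[["ind"]])
      len <- nchar(planted$text)
      if (cursor + len - 1L > spec$cr_length - 5L) { ok_layout <- FALSE; break }
      region[cursor:(cursor + len - 1L)] <- strsplit(planted$text, "")[[1]]
      truth$motifs[[nm]] <- list(start = cursor, end = cursor + len - 1L,
                                 n_sub = planted$n_sub,
                                 n_ins = planted$n_ins,
                                 n_del = planted$n_del)
      cursor <- cursor + len + sample(12:30, 1L)
      if (nm == "CSB-D") {
        ## T homopolymer between CSB-D and CSB-1
        region[cursor:(cursor + spec$t_run_len - 1L)] <- "T"
        ## break any accidental extension of the run
        region[cursor - 1L] <- sample(c("A", "C", "G"), 1L)
        region[cursor + spec$t_run_len] <- sample(c("A", "C", "G"), 1L)
        truth$t_run <- list(start = cursor, length = spec$t_run_len)
        cursor <- cursor + spec$t_run_len + sample(8:15, 1L)
      }
    }
    if (!ok_layout) stop("motif layout overflows control-region length",
                         call. = FALSE)

    region_txt <- paste(region, collapse = "")

    ## accept only if every planted motif is the recovered best hit
    recovered <- TRUE
    for (nm in wanted) {
      row <- lib[lib$name == nm, ]
      hit <- scan_motif(region_txt, row$sequence[1],
                        max_sub = row$max_sub[1], max_indel = row$max_indel[1])
      tr <- truth$motifs[[nm]]
      if (is.null(hit) || hit$start != tr$start ||
          hit$n_substitutions != tr$n_sub ||
          hit$n_insertions != tr$n_ins || hit$n_deletions != tr$n_del) {
        recovered <- FALSE; break
      }
    }
    if (recovered) {
      return(list(region = region_txt, truth = truth))
    }
  }
  stop("could not build a control region whose planted motifs are uniquely ",
       "recoverable; lower the edit budgets", call. = FALSE)
}

.h_trna_names <- c("tRNA-Phe", "tRNA-Val", "tRNA-Leu(TAA)", "tRNA-Ile",
                   "tRNA-Met", "tRNA-Trp", "tRNA-Asp", "tRNA-Lys",
                   "tRNA-Gly", "tRNA-Arg", "tRNA-His", "tRNA-Ser(GCT)",
                   "tRNA-Leu(TAG)", "tRNA-Thr")
.l_trna_names <- c("tRNA-Gln", "tRNA-Ala", "tRNA-Asn", "tRNA-Cys",
                   "tRNA-Tyr", "tRNA-Ser(TGA)", "tRNA-Glu", "tRNA-Pro")

## build one cloverleaf with known pair classes; returns struct + counts
build_cloverleaf <- function(name, strand, wobble_p, dhu_present = TRUE) {
  stem_len <- c(AA = 7L, DHU = if (dhu_present) 4L else 0L,
                AC = 5L, TPsiU = 5L)
  loop_len <- c(DHU = if (dhu_present) sample(4:8, 1L) else 5L,
                AC = 7L, variable = 4L, TPsiU = 7L)

  draw_pair <- function() {
    if (stats::runif(1) < wobble_p) {
      if (stats::runif(1) < 0.5) c("G", "T") else c("T", "G")
    } else {
      wc <- list(c("A", "T"), c("T", "A"), c("G", "C"), c("C", "G"))
      wc[[sample(4L, 1L)]]
    }
  }
  stem_pairs <- lapply(stem_len, function(k) {
    if (k == 0L) NULL else lapply(seq_len(k), function(i) draw_pair())
  })
  rand <- function(n) sample(.bases, n, replace = TRUE)

  seqc <- character(0); db <- character(0)
  add <- function(bases, marks) {
    seqc <<- c(seqc, bases); db <<- c(db, marks)
  }
  open5 <- function(st) vapply(stem_pairs[[st]], `[`, character(1), 1L)
  close3 <- function(st) rev(vapply(stem_pairs[[st]], `[`, character(1), 2L))

  add(open5("AA"), rep("(", stem_len["AA"]))
  add(rand(2L), rep(".", 2L))
  if (dhu_present) {
    add(open5("DHU"), rep("(", stem_len["DHU"]))
    add(rand(loop_len["DHU"]), rep(".", loop_len["DHU"]))
    add(close3("DHU"), rep(")", stem_len["DHU"]))
    add(rand(1L), ".")
  } else {
    add(rand(loop_len["DHU"]), rep(".", loop_len["DHU"]))
  }
  add(open5("AC"), rep("(", stem_len["AC"]))
  add(rand(loop_len["AC"]), rep(".", loop_len["AC"]))
  add(close3("AC"), rep(")", stem_len["AC"]))
  add(rand(loop_len["variable"]), rep(".", loop_len["variable"]))
  add(open5("TPsiU"), rep("(", stem_len["TPsiU"]))
  add(rand(loop_len["TPsiU"]), rep(".", loop_len["TPsiU"]))
  add(close3("TPsiU"), rep(")", stem_len["TPsiU"]))
  add(close3("AA"), rep(")", stem_len["AA"]))
  add(rand(1L), ".")

  wobble_counts <- vapply(names(stem_len), function(st) {
    if (is.null(stem_pairs[[st]])) return(0L)
    sum(vapply(stem_pairs[[st]], function(p) {
      classify_pair(p[1], p[2])$category == "wobble_GU"
    }, logical(1)))
  }, integer(1))

  struct <- partition_cloverleaf(paste(seqc, collapse = ""),
                                 paste(db, collapse = ""),
                                 name = name, strand = strand)
  list(struct = struct, wobble = wobble_counts,
       pairs = sum(stem_len))
}

#' Generate a ground-truthed synthetic tRNA structure set
#'
#' Emulates the strand contrast of carangid mitochondrial tRNAs: for each
#' of `n_species` replicate species, one cloverleaf per tRNA of each
#' strand group, every stem pair drawn Watson-Crick or G-U wobble with
#' the group's wobble probability (tRNA-Ser(GCT) built without a DHU
#' stem). Planted wobble counts are recorded per structure, so downstream
#' tallies have an exact bookkeeping oracle.
#'
#' @param spec a [generator_spec()]; `trna_n`, `wobble_p` and `n_species`
#'   are the relevant fields.
#' @return list: `structs` (list of cloverleafs), `truth` (data.frame
#'   with one row per structure: species, tRNA, strand, per-stem planted
#'   wobble counts, total pairs).
#' @export
generate_trna_set <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  structs <- list()
  rows <- list()
  for (sp in seq_len(spec$n_species)) {
    for (strand in c("H", "L")) {
      pool <- if (strand == "H") .h_trna_names else .l_trna_names
      nms <- pool[seq_len(min(spec$trna_n[[strand]], length(pool)))]
      if (spec$trna_n[[strand]] > length(pool)) {
        nms <- c(nms, sprintf("tRNA-%s%02d", strand,
                              seq_len(spec$trna_n[[strand]] - length(pool))))
      }
      for (nm in nms) {
        b <- build_cloverleaf(nm, strand, spec$wobble_p[[strand]],
                              dhu_present = nm != "tRNA-Ser(GCT)")
        structs[[length(structs) + 1L]] <- b$struct
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, trna = nm, strand = strand,
          wobble_AA = b$wobble[["AA"]], wobble_DHU = b$wobble[["DHU"]],
          wobble_AC = b$wobble[["AC"]], wobble_TPsiU = b$wobble[["TPsiU"]],
          total_pairs = b$pairs, stringsAsFactors = FALSE)
      }
    }
  }
  list(structs = structs, truth = do.call(rbind, rows))
}

#' Simulate an aligned gene family under constrained substitution
#'
#' Small parametric simulator for exercising the p-distance and Ka/Ks
#' machinery with a known generating process: an ancestral in-frame
#' coding sequence is drawn from the codon weights, and each taxon is an
#' independent copy with point substitutions restricted to a site class —
#' `"synonymous"` (only changes preserving the amino acid under the
#' vertebrate mitochondrial code), `"nonsynonymous"` (only changes that
#' alter it, avoiding stops) or `"any"`.
#'
#' @param n_taxa number of taxa.
#' @param n_codons ancestral length in codons (a shared TAA stop is
#'   appended).
#' @param n_subs substitutions attempted per taxon.
#' @param mode `"synonymous"`, `"nonsynonymous"` or `"any"`.
#' @param spec a [generator_spec()] providing seed and codon weights.
#' @return named character vector of aligned sequences (first taxon is
#'   the unmutated ancestor).
#' @export
simulate_gene_family <- function(n_taxa = 4L, n_codons = 100L, n_subs = 10L,
                                 mode = c("synonymous", "nonsynonymous", "any"),
                                 spec = generator_spec()) {
  mode <- match.arg(mode)
  set.seed(spec$seed)
  code <- vertebrate_mito_code()
  anc <- sample(names(spec$codon_weights), n_codons, replace = TRUE,
                prob = spec$codon_weights)
  out <- stats::setNames(character(n_taxa), paste0("taxon", seq_len(n_taxa)))
  out[1] <- paste0(paste(anc, collapse = ""), "TAA")
  for (t in seq(2L, length.out = n_taxa - 1L)) {
    cods <- anc
    done <- 0L; guard <- 0L
    while (done < n_subs && guard < 50L * n_subs) {
      guard <- guard + 1L
      ci <- sample(n_codons, 1L)
      pos <- sample(3L, 1L)
      cod <- cods[ci]
      b <- substr(cod, pos, pos)
      mut <- cod
      substr(mut, pos, pos) <- sample(setdiff(.bases, b), 1L)
      if (code[[mut]] == "*") next
      syn <- code[[mut]] == code[[cod]]
      keep <- switch(mode,
        synonymous = syn,
        nonsynonymous = !syn,
        any = TRUE)
      if (!keep) next
      cods[ci] <- mut
      done <- done + 1L
    }
    out[t] <- paste0(paste(cods, collapse = ""), "TAA")
  }
  out
}
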