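#' Cloverleaf partitioning of a tRNA secondary structure
#'
#' Parses a dot-bracket string into the canonical cloverleaf: the
#' outermost helix is the amino-acid acceptor (AA) stem, and the internal
#' helices in 5' to 3' order are the DHU, anticodon (AC) and T-psi-U
#' stems. A 3-helix structure (the tRNA-Ser(GCT) case, which lacks a
#' recognizable DHU stem) assigns the first internal helix to AC. Loops
#' are the unpaired gaps: DHU loop, AC loop (carrying the anticodon at
#' its centre), variable loop (between AC and T-psi-U stems) and T-psi-U
#' loop.
#'
#' @param seq nucleotide string (T or U accepted).
#' @param structure dot-bracket string of the same length, characters
#'   `().` only; pseudoknot brackets raise a structure error.
#' @param anticodon_pos optional 1-based index of the first anticodon
#'   base; validated against the centre of the AC loop when given.
#' @param name,strand optional tRNA label and encoding strand (`"H"`/`"L"`)
#'   carried through to downstream tallies.
#' @return object of class `"cloverleaf"`: `stems` (named list of 2-column
#'   index matrices, outermost pair first), `loops` (named list of index
#'   vectors), `pairs` (data.frame of stem, indices, bases, pair category),
#'   `dhu_present`, `seq`, `name`, `strand`.
#' @export
partition_cloverleaf <- function(seq, structure, anticodon_pos = NULL,
                                 name = NA_character_, strand = NA_character_) {
  seq <- toupper(chartr("U", "T", seq))
  seq <- check_nucleotide(seq)
  if (nchar(seq) != nchar(structure)) {
    stop("sequence and structure lengths differ", call. = FALSE)
  }
  chars <- strsplit(structure, "")[[1]]
  if (any(!chars %in% c("(", ")", "."))) {
    stop("structure error: only '(', ')', '.' allowed (no pseudoknots)",
         call. = FALSE)
  }
  ## pair map via stack
  stack <- integer(0)
  open <- integer(0); close <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      if (!length(stack)) stop("structure error: unbalanced brackets", call. = FALSE)
      open <- c(open, stack[length(stack)])
      close <- c(close, i)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("structure error: unbalanced brackets", call. = FALSE)
  ord <- order(open)
  open <- open[ord]; close <- close[ord]

  ## split stacked pairs into helices (strictly stacked: i+1 pairs j-1)
  helix_id <- cumsum(c(TRUE, !(diff(open) == 1L & diff(close) == -1L)))
  helices <- lapply(split(seq_along(open), helix_id), function(k) {
    cbind(open = open[k], close = close[k])
  })
  nh <- length(helices)
  if (nh < 3L || nh > 4L) {
    stop("structure error: ", nh, " helix/helices, not a cloverleaf (3-4)",
         call. = FALSE)
  }
  ## outermost helix (contains all others) is the acceptor stem
  spans <- vapply(helices, function(h) max(h[, 2]) - min(h[, 1]), numeric(1))
  aa_i <- which.max(spans)
  aa <- helices[[aa_i]]
  inner <- helices[-aa_i]
  if (!all(vapply(inner, function(h) min(h[, 1]) > max(aa[, 1]) &&
                    max(h[, 2]) < min(aa[, 2]), logical(1)))) {
    stop("structure error: internal helices not nested inside acceptor stem",
         call. = FALSE)
  }
  inner <- inner[order(vapply(inner, function(h) min(h[, 1]), numeric(1)))]
  dhu_present <- nh == 4L
  stems <- if (dhu_present) {
    list(AA = aa, DHU = inner[[1]], AC = inner[[2]], TPsiU = inner[[3]])
  } else {
    list(AA = aa, DHU = NULL, AC = inner[[1]], TPsiU = inner[[2]])
  }

  loop_between <- function(from, to) if (to - from > 1L) seq(from + 1L, to - 1L) else integer(0)
  in_loop <- function(h) loop_between(max(h[, 1]), min(h[, 2]))
  loops <- list(
    DHU = if (dhu_present) in_loop(stems$DHU) else integer(0),
    AC = in_loop(stems$AC),
    variable = loop_between(max(stems$AC[, 2]), min(stems$TPsiU[, 1])),
    TPsiU = in_loop(stems$TPsiU)
  )

  if (!is.null(anticodon_pos)) {
    if (!anticodon_pos %in% loops$AC) {
      warning("anticodon position ", anticodon_pos,
              " not inside the anticodon loop", call. = FALSE)
    }
  }

  bases <- strsplit(seq, "")[[1]]
  pair_rows <- do.call(rbind, lapply(names(stems), function(st) {
    h <- stems[[st]]
    if (is.null(h)) return(NULL)
    cls <- vapply(seq_len(nrow(h)), function(r) {
      classify_pair(bases[h[r, 1]], bases[h[r, 2]])$category
    }, character(1))
    data.frame(stem = st, pos5 = h[, 1], pos3 = h[, 2],
               base5 = bases[h[, 1]], base3 = bases[h[, 2]],
               category = cls, stringsAsFactors = FALSE)
  }))

  structure(list(seq = seq, name = name, strand = strand,
                 stems = stems, loops = loops, pairs = pair_rows,
                 dhu_present = dhu_present),
            class = "cloverleaf")
}

#' @export
print.cloverleaf <- function(x, ...) {
  sizes <- vapply(x$stems, function(h) if (is.null(h)) 0L else nrow(h), integer(1))
  cat(sprintf("<cloverleaf> %s (%s strand), %d nt; stems AA %d / DHU %d / AC %d / TPsiU %d bp%s\n",
              x$name, x$strand, nchar(x$seq),
              sizes["AA"], sizes["DHU"], sizes["AC"], sizes["TPsiU"],
              if (!x$dhu_present) " [no DHU stem]" else ""))
  invisible(x)
}

#' Classify an RNA base pair
#'
#' Watson-Crick (A-T/A-U or G-C), G-U wobble (the non-canonical pair
#' tolerated in RNA helices), or a named mismatch. T and U are
#' equivalent; the mismatch label is the alphabetically ordered pair
#' (e.g. `"A-C"`). Symmetric in its arguments.
#'
#' @param b1,b2 single bases in `A C G T U` (case-insensitive).
#' @return list with `category` (`"watson_crick"`/`"wobble_GU"`/
#'   `"mismatch"`) and `mismatch_label` (`NA` unless a mismatch).
#' @export
classify_pair <- function(b1, b2) {
  b <- toupper(chartr("U", "T", c(b1, b2)))
  if (any(!b %in% .bases)) {
    stop("bases must be one of A, C, G, T, U", call. = FALSE)
  }
  key <- paste(sort(b), collapse = "-")
  if (key %in% c("A-T", "C-G")) {
    list(category = "watson_crick", mismatch_label = NA_character_)
  } else if (key == "G-T") {
    list(category = "wobble_GU", mismatch_label = NA_character_)
  } else {
    list(category = "mismatch", mismatch_label = key)
  }
}

#' Canonical 25-site map of the cloverleaf stems
#'
#' Pair labels in a fixed 1-88 numbering: 8 acceptor-stem sites
#' (`1-87` ... `8-80`), 5 DHU sites (`11-33` ... `15-29`), 6 anticodon
#' sites (`35-53` ... `40-48`) and 6 T-psi-U sites (`60-78` ... `65-73`),
#' each listed outermost pair first. Structures with shorter stems map
#' onto a subset: the acceptor stem is anchored at its outermost pair
#' (`1-87`), the three arms at their innermost pair (the loop-closing
#' pair keeps its label as the stem shortens).
#'
#' @return named list of character vectors, one per stem.
#' @export
canonical_site_map <- function() {
  list(
    AA = paste0(1:8, "-", 88 - (1:8)),
    DHU = paste0(11:15, "-", 33 - 0:4),
    AC = paste0(35:40, "-", 53 - 0:5),
    TPsiU = paste0(60:65, "-", 78 - 0:5)
  )
}

## assign canonical labels to a structure's stem pairs (outermost first)
assign_site_labels <- function(struct, site_map = canonical_site_map()) {
  out <- list()
  for (st in names(site_map)) {
    h <- struct$stems[[st]]
    if (is.null(h) || !nrow(h)) next
    labels <- site_map[[st]]
    np <- nrow(h)
    if (np > length(labels)) {
      stop(st, " stem has ", np, " pairs, more than the ", length(labels),
           "-site canonical map", call. = FALSE)
    }
    lab <- if (st == "AA") labels[seq_len(np)]         # outermost-anchored
           else labels[seq(length(labels) - np + 1L, length(labels))]  # innermost-anchored
    out[[st]] <- lab
  }
  out
}

#' Per-site pairing frequencies across structures
#'
#' Tallies Watson-Crick, G-U wobble and mismatch percentages at each
#' canonical stem site over a collection of cloverleaf structures.
#' Structures lacking a site (short stems, absent DHU arm) are excluded
#' from that site's denominator, so the three percentages always sum to
#' 100 of the structures carrying the site. "Bonded" = Watson-Crick +
#' wobble (hydrogen-bonded).
#'
#' @param structs list of [partition_cloverleaf()] objects.
#' @param site_map canonical labels per stem; see [canonical_site_map()].
#' @return `data.frame` with columns `site`, `stem`, `n`, `pct_wc`,
#'   `pct_wobble`, `pct_mismatch`, `pct_bonded`, in canonical order, with
#'   an attribute `"fully_bonded"` naming the sites at 100% bonding.
#' @export
site_frequencies <- function(structs, site_map = canonical_site_map()) {
  stopifnot(length(structs) >= 1L)
  all_sites <- unlist(site_map, use.names = FALSE)
  stem_of <- rep(names(site_map), lengths(site_map))
  tall <- data.frame(site = character(), category = character(),
                     stringsAsFactors = FALSE)
  for (s in structs) {
    labs <- assign_site_labels(s, site_map)
    for (st in names(labs)) {
      h <- s$stems[[st]]
      cats <- s$pairs$category[s$pairs$stem == st]
      tall <- rbind(tall, data.frame(site = labs[[st]], category = cats,
                                     stringsAsFactors = FALSE))
    }
  }
  out <- do.call(rbind, lapply(seq_along(all_sites), function(i) {
    cats <- tall$category[tall$site == all_sites[i]]
    n <- length(cats)
    if (!n) {
      return(data.frame(site = all_sites[i], stem = stem_of[i], n = 0L,
                        pct_wc = NA_real_, pct_wobble = NA_real_,
                        pct_mismatch = NA_real_, pct_bonded = NA_real_,
                        stringsAsFactors = FALSE))
    }
    wc <- 100 * mean(cats == "watson_crick")
    wo <- 100 * mean(cats == "wobble_GU")
    mm <- 100 * mean(cats == "mismatch")
    data.frame(site = all_sites[i], stem = stem_of[i], n = n,
               pct_wc = wc, pct_wobble = wo, pct_mismatch = mm,
               ## computed from the bonded fraction directly, not wc + wo,
               ## so an all-bonded site is exactly 100
               pct_bonded = 100 * mean(cats != "mismatch"),
               stringsAsFactors = FALSE)
  }))
  attr(out, "fully_bonded") <- out$site[!is.na(out$pct_bonded) &
                                          out$pct_bonded == 100 & out$n > 0]
  out
}

#' Wobble-pair occurrence table by tRNA and stem
#'
#' Counts G-U wobble pairs per tRNA (summed over structures sharing a
#' tRNA label, i.e. across species) in each of the four stems, with
#' totals, per-tRNA percentages (denominator = pairs actually present),
#' per-strand mean percentages and the grand average.
#'
#' @param structs list of cloverleaf structures with `name` and `strand`
#'   set.
#' @return list of class `"wobble_summary"`: `table` (one row per tRNA),
#'   `strand_means` (named numeric, mean per-tRNA wobble percentage by
#'   strand), `grand_pct` (overall wobble percentage over all pairs).
#' @export
wobble_table <- function(structs) {
  stopifnot(length(structs) >= 1L)
  key <- vapply(structs, function(s) paste(s$name, s$strand, sep = "\r"),
                character(1))
  rows <- lapply(split(structs, key), function(grp) {
    counts <- c(AA = 0L, DHU = 0L, AC = 0L, TPsiU = 0L)
    pairs <- counts
    for (s in grp) {
      tb <- table(factor(s$pairs$stem, levels = names(counts)))
      pairs <- pairs + as.integer(tb)
      wb <- s$pairs$stem[s$pairs$category == "wobble_GU"]
      tbw <- table(factor(wb, levels = names(counts)))
      counts <- counts + as.integer(tbw)
    }
    data.frame(trna = grp[[1]]$name, strand = grp[[1]]$strand,
               wobble_AA = counts[["AA"]], wobble_DHU = counts[["DHU"]],
               wobble_AC = counts[["AC"]], wobble_TPsiU = counts[["TPsiU"]],
               total_wobble = sum(counts), total_pairs = sum(pairs),
               pct = 100 * sum(counts) / sum(pairs),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- tab[order(tab$strand, tab$trna), , drop = FALSE]
  strand_means <- tapply(tab$pct, tab$strand, mean)
  structure(list(
    table = tab,
    strand_means = strand_means,
    grand_pct = 100 * sum(tab$total_wobble) / sum(tab$total_pairs)
  ), class = "wobble_summary")
}

#' @export
print.wobble_summary <- function(x, ...) {
  cat(sprintf("<wobble_summary> %d tRNAs, grand wobble %.2f%%\n",
              nrow(x$table), x$grand_pct))
  for (s in names(x$strand_means)) {
    cat(sprintf("  %s strand mean: %.2f%%\n", s, x$strand_means[[s]]))
  }
  invisible(x)
}

#' Compare wobble frequencies between H- and L-strand tRNAs
#'
#' Two-sided Mann-Whitney U test on the per-tRNA wobble percentages of
#' heavy- versus light-strand encoded tRNAs (exact p-value for small
#' samples without ties; normal approximation with tie correction
#' otherwise, as provided by [stats::wilcox.test()]).
#'
#' @param summary a [wobble_table()] result (or its `table` data.frame).
#' @return list: `U` statistic, `p_value`, `group_means`, `n` per group.
#' @export
strand_comparison <- function(summary) {
  tab <- if (inherits(summary, "wobble_summary")) summary$table else summary
  groups <- split(tab$pct, tab$strand)
  if (!all(c("H", "L") %in% names(groups))) {
    stop("need both H and L strand groups", call. = FALSE)
  }
  if (any(lengths(groups[c("H", "L")]) < 3L)) {
    stop("need at least 3 tRNAs per strand group", call. = FALSE)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(groups$H, groups$L, alternative = "two.sided")
  )
  list(U = unname(wt$statistic), p_value = wt$p.value,
       group_means = vapply(groups, mean, numeric(1)),
       n = lengths(groups))
}

#' Locate the mTERF tridecamer binding site
#'
#' Scans a tRNA-Leu(TAA) gene region for the 13-mer mitochondrial
#' transcription termination factor binding site (`TGGCAGAGCCCGG` in
#' humans, conserved across teleosts), allowing up to `max_mismatch`
#' substitutions; reports the best (fewest-mismatch, leftmost) window.
#'
#' @param trna_leu_seq nucleotide string.
#' @param motif the binding-site 13-mer.
#' @param max_mismatch maximum substitutions tolerated (default 0).
#' @return list: `hit` (logical), `start`, `end`, `n_mismatches`,
#'   `mismatch_positions` (1-based within the motif).
#' @export
mterf_site_check <- function(trna_leu_seq, motif = "TGGCAGAGCCCGG",
                             max_mismatch = 0L) {
  seq <- check_nucleotide(trna_leu_seq)
  m <- nchar(motif)
  n <- nchar(seq)
  if (n < m) return(list(hit = FALSE, start = NA_integer_, end = NA_integer_,
                         n_mismatches = NA_integer_,
                         mismatch_positions = integer(0)))
  mb <- strsplit(motif, "")[[1]]
  best <- list(start = NA_integer_, mm = m + 1L, pos = integer(0))
  for (i in seq_len(n - m + 1L)) {
    wb <- strsplit(substr(seq, i, i + m - 1L), "")[[1]]
    diffs <- which(wb != mb)
    if (length(diffs) < best$mm) {
      best <- list(start = i, mm = length(diffs), pos = diffs)
    }
  }
  if (best$mm <= max_mismatch) {
    list(hit = TRUE, start = best$start, end = best$start + m - 1L,
         n_mismatches = best$mm, mismatch_positions = best$pos)
  } else {
    list(hit = FALSE, start = NA_integer_, end = NA_integer_,
         n_mismatches = NA_integer_, mismatch_positions = integer(0))
  }
}

#' Read a tRNA structure table
#'
#' TSV with header `trna_name  strand  sequence  dot_bracket`; each row is
#' parsed with [partition_cloverleaf()].
#'
#' @param path path to the TSV file.
#' @return list of cloverleaf structures.
#' @export
read_trna_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("trna_name", "strand", "sequence", "dot_bracket")
  if (!all(need %in% names(df))) {
    stop("tRNA table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    partition_cloverleaf(df$sequence[i], df$dot_bracket[i],
                         name = df$trna_name[i], strand = df$strand[i])
  })
}
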