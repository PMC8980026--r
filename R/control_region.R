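#' The shipped control-region motif library
#'
#' Reference motifs of the teleost mitochondrial control region: the three
#' central conserved blocks (CSB-F, CSB-E with its GTGGG box, CSB-D), the
#' three conserved sequence blocks (CSB-1/2/3) near the 3' end, the
#' characteristic 3'-terminal sequence, and the mTERF tridecamer, each
#' with its default substitution and indel budget. The F/E/D and 1/2/3
#' boundaries within the concatenated published reference are a recorded,
#' editable convention of this library.
#'
#' @param path optional path to an alternative library TSV with header
#'   `name  sequence  max_sub  max_indel`.
#' @return `data.frame` with those four columns.
#' @export
default_motif_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "csb_motif_library.tsv",
                        package = "mitocomp", mustWork = TRUE)
  }
  lib <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "sequence", "max_sub", "max_indel") %in% names(lib)))
  lib$sequence <- toupper(lib$sequence)
  if (any(!nzchar(lib$sequence)) || any(grepl("[^ACGT]", lib$sequence))) {
    stop("motif library sequences must be non-empty ACGT text", call. = FALSE)
  }
  lib
}

.edit_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1,
                                           baseOnly = TRUE)
}

## serialize a pairwiseAlignment (pattern = reference motif, subject = query)
## to mask notation: '*' identity, uppercase = substituted query base,
## lowercase = insertion in query, '-' = deletion from reference
.alignment_mask <- function(ref_gapped, qry_gapped) {
  r <- strsplit(ref_gapped, "")[[1]]
  q <- strsplit(qry_gapped, "")[[1]]
  mask <- character(length(r))
  for (i in seq_along(r)) {
    mask[i] <- if (r[i] == "-") tolower(q[i])
      else if (q[i] == "-") "-"
      else if (r[i] == q[i]) "*"
      else q[i]
  }
  paste(mask, collapse = "")
}

.mask_counts <- function(mask) {
  ch <- strsplit(mask, "")[[1]]
  list(n_sub = sum(ch %in% c("A", "C", "G", "T")),
       n_ins = sum(ch %in% c("a", "c", "g", "t")),
       n_del = sum(ch == "-"))
}

#' Scan a region for a motif within bounded edit distance
#'
#' Finds the best placement of `motif` inside `region`: minimum unit-cost
#' edit distance (substitutions and indels both cost 1), exact hits
#' reported at their leftmost occurrence. A hit is returned only when the
#' best placement respects both budgets; otherwise a no-hit. With budgets
#' (0, 0) this reduces to exact substring search.
#'
#' @param region nucleotide string to search.
#' @param motif reference motif (non-empty ACGT text).
#' @param max_sub maximum substitutions allowed.
#' @param max_indel maximum insertions + deletions allowed.
#' @return a `motif_hit` list (`motif`, `start`, `end` 1-based inclusive
#'   in the region, `n_substitutions`, `n_insertions`, `n_deletions`,
#'   `mask` in divergence-mask notation, `edit_distance`) or `NULL` for
#'   no-hit.
#' @export
scan_motif <- function(region, motif, max_sub = 9L, max_indel = 2L) {
  region <- check_nucleotide(region)
  if (!is.character(motif) || !nzchar(motif)) {
    stop("motif must be non-empty", call. = FALSE)
  }
  motif <- check_nucleotide(motif, allow_n = FALSE, what = "motif")
  if (nchar(region) < nchar(motif) - max_indel) {
    stop("region shorter than motif minus indel budget", call. = FALSE)
  }
  ## exact fast path: leftmost verbatim occurrence
  at <- regexpr(motif, region, fixed = TRUE)
  if (at > 0L) {
    return(structure(list(
      motif = motif, start = as.integer(at),
      end = as.integer(at) + nchar(motif) - 1L,
      n_substitutions = 0L, n_insertions = 0L, n_deletions = 0L,
      mask = strrep("*", nchar(motif)), edit_distance = 0L
    ), class = "motif_hit"))
  }
  if (max_sub == 0L && max_indel == 0L) return(NULL)
  al <- Biostrings::pairwiseAlignment(
    pattern = motif, subject = region, type = "global-local",
    substitutionMatrix = .edit_submat(), gapOpening = 0, gapExtension = 1
  )
  dist <- as.integer(-Biostrings::score(al))
  mask <- .alignment_mask(as.character(Biostrings::alignedPattern(al)),
                          as.character(Biostrings::alignedSubject(al)))
  cnt <- .mask_counts(mask)
  if (cnt$n_sub > max_sub || (cnt$n_ins + cnt$n_del) > max_indel) return(NULL)
  sbj <- Biostrings::subject(al)
  structure(list(
    motif = motif,
    start = as.integer(BiocGenerics::start(sbj)),
    end = as.integer(BiocGenerics::end(sbj)),
    n_substitutions = cnt$n_sub, n_insertions = cnt$n_ins,
    n_deletions = cnt$n_del, mask = mask, edit_distance = dist
  ), class = "motif_hit")
}

#' @export
print.motif_hit <- function(x, ...) {
  cat(sprintf("<motif_hit> %d-%d: %d sub, %d ins, %d del\n  %s\n  %s\n",
              x$start, x$end, x$n_substitutions, x$n_insertions,
              x$n_deletions, x$motif, x$mask))
  invisible(x)
}

#' Divergence mask between a reference motif and an observed sequence
#'
#' Global unit-cost alignment of `query` against `reference`, serialized
#' to the plain-text mask convention: `*` identity, an uppercase base the
#' substituted query base, a lowercase base an insertion in the query,
#' `-` a deletion from the reference. Removing insertions and restoring
#' identity positions reproduces the reference length, and
#' [apply_divergence_mask()] reconstructs the query exactly.
#'
#' @param reference,query non-empty nucleotide strings.
#' @return character mask with attributes `n_sub`, `n_ins`, `n_del`.
#' @export
divergence_mask <- function(reference, query) {
  reference <- check_nucleotide(reference, allow_n = FALSE, what = "reference")
  query <- check_nucleotide(query, allow_n = FALSE, what = "query")
  if (identical(reference, query)) {
    mask <- strrep("*", nchar(reference))
    attributes(mask) <- c(attributes(mask),
                          list(n_sub = 0L, n_ins = 0L, n_del = 0L))
    return(mask)
  }
  al <- Biostrings::pairwiseAlignment(
    pattern = reference, subject = query, type = "global",
    substitutionMatrix = .edit_submat(), gapOpening = 0, gapExtension = 1
  )
  mask <- .alignment_mask(as.character(Biostrings::alignedPattern(al)),
                          as.character(Biostrings::alignedSubject(al)))
  cnt <- .mask_counts(mask)
  attributes(mask) <- c(attributes(mask), cnt)
  mask
}

#' Reconstruct the query encoded by a divergence mask
#'
#' @param reference the reference motif the mask was computed against.
#' @param mask a [divergence_mask()] string.
#' @return the query sequence.
#' @export
apply_divergence_mask <- function(reference, mask) {
  ref <- strsplit(reference, "")[[1]]
  ch <- strsplit(as.character(mask), "")[[1]]
  out <- character(0)
  ri <- 1L
  for (c in ch) {
    if (c == "*") { out <- c(out, ref[ri]); ri <- ri + 1L }
    else if (c %in% c("A", "C", "G", "T")) { out <- c(out, c); ri <- ri + 1L }
    else if (c %in% c("a", "c", "g", "t")) { out <- c(out, toupper(c)) }
    else if (c == "-") { ri <- ri + 1L }
    else stop("invalid mask character '", c, "'", call. = FALSE)
  }
  if (ri != length(ref) + 1L) {
    stop("mask does not span the reference", call. = FALSE)
  }
  paste(out, collapse = "")
}

#' Maximal T-homopolymer runs
#'
#' @param region nucleotide string.
#' @param min_len minimum run length reported (default 5, the lower end
#'   of the run lengths seen between CSB-D and CSB-1 in carangids).
#' @return `data.frame` with columns `start`, `length`.
#' @export
find_t_homopolymers <- function(region, min_len = 5L) {
  m <- gregexpr(sprintf("T{%d,}", min_len), region)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), length = integer(0)))
  }
  data.frame(start = as.integer(m),
             length = attr(m, "match.length"))
}

#' Exhaustive small-period tandem-repeat scan
#'
#' Finds runs of >= `min_copies` exact consecutive copies of a unit of
#' `unit_range` bp. Homopolymeric units and units that are themselves
#' periodic are excluded (a unit must be its own minimal period), so a
#' T-homopolymer is not reported as a TT-repeat; and a run must span at
#' least `min_total` bp, so the chance few-bp periodicities of any
#' AT-rich sequence are not called repeats (the convention of standard
#' repeat finders, which score against exactly such background).
#'
#' @param region nucleotide string.
#' @param unit_range integer range of unit lengths (default 2-20).
#' @param min_copies minimum exact copies (default 3).
#' @param min_total minimum total span of the run in bp (default 12).
#' @return `data.frame` with columns `start`, `unit`, `copies`.
#' @export
find_tandem_repeats <- function(region, unit_range = 2:20, min_copies = 3L,
                                min_total = 12L) {
  out <- data.frame(start = integer(0), unit = character(0),
                    copies = integer(0), stringsAsFactors = FALSE)
  is_primitive <- function(u) {
    n <- nchar(u)
    if (length(unique(strsplit(u, "")[[1]])) == 1L) return(FALSE)
    for (p in seq_len(n %/% 2)) {
      if (n %% p == 0L &&
          u == strrep(substr(u, 1L, p), n / p)) return(FALSE)
    }
    TRUE
  }
  for (u in unit_range) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, min_copies - 1L)
    m <- gregexpr(pat, region, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    for (k in seq_along(m)) {
      run <- substr(region, m[k], m[k] + attr(m, "match.length")[k] - 1L)
      unit <- substr(run, 1L, u)
      if (!is_primitive(unit)) next
      if ((nchar(run) %/% u) * u < min_total) next
      out <- rbind(out, data.frame(start = as.integer(m[k]), unit = unit,
                                   copies = nchar(run) %/% u,
                                   stringsAsFactors = FALSE))
    }
  }
  out[order(out$start), , drop = FALSE]
}

#' Is one motif the reverse complement of another?
#'
#' The classic control-region palindrome pair TACAT / ATGTA are reverse
#' complements of each other; with `partner = NULL` the motif is tested
#' against itself (a true DNA palindrome).
#'
#' @param motif nucleotide string.
#' @param partner nucleotide string to compare against (default: the
#'   motif itself).
#' @return logical flag.
#' @export
palindrome_check <- function(motif, partner = NULL) {
  if (is.null(partner)) partner <- motif
  identical(revcomp(toupper(motif)), toupper(partner))
}

.csb_order <- c("CSB-F", "CSB-E", "CSB-D", "CSB-1", "CSB-2", "CSB-3")

#' Annotate a mitochondrial control region
#'
#' Scans for the six conserved sequence blocks and the 3'-terminal
#' sequence within per-motif edit budgets, checks their canonical order
#' (CSB-F < CSB-E < CSB-D < CSB-1 < CSB-2 < CSB-3; a violation warns but
#' hits are still reported), locates the GTGGG box inside the CSB-E hit,
#' exact palindromic TACAT/ATGTA occurrences, maximal T-homopolymer runs
#' of length >= 5 (flagging the one between CSB-D and CSB-1), and exact
#' tandem repeats of unit 2-20 bp with >= 3 copies.
#'
#' @param region control-region nucleotide string, length >= 200.
#' @param lib motif library data.frame; see [default_motif_library()].
#' @return list of class `"cr_annotation"`: `hits` (named list of
#'   `motif_hit`/`NULL`), `order_ok`, `gtggg_box`, `palindromes`,
#'   `homopolymers` (with `between_csbD_csb1` flag), `tandem_repeats`.
#' @export
annotate_control_region <- function(region, lib = default_motif_library()) {
  region <- check_nucleotide(region)
  if (nchar(region) < 200L) {
    stop("control region shorter than 200 bp", call. = FALSE)
  }
  wanted <- c(.csb_order, "terminal-3prime")
  hits <- stats::setNames(vector("list", length(wanted)), wanted)
  for (nm in wanted) {
    row <- lib[lib$name == nm, ]
    if (!nrow(row)) next
    hits[[nm]] <- scan_motif(region, row$sequence[1],
                             max_sub = row$max_sub[1],
                             max_indel = row$max_indel[1])
  }

  starts <- vapply(.csb_order, function(nm) {
    if (is.null(hits[[nm]])) NA_real_ else hits[[nm]]$start
  }, numeric(1))
  found <- !is.na(starts)
  order_ok <- all(found) && !is.unsorted(starts, strictly = TRUE)
  if (all(found) && !order_ok) {
    warning("CSB hits violate canonical order", call. = FALSE)
  }

  gtggg_box <- NULL
  if (!is.null(hits[["CSB-E"]])) {
    h <- hits[["CSB-E"]]
    sub <- substr(region, h$start, h$end)
    at <- regexpr("GTGGG", sub, fixed = TRUE)
    if (at > 0L) {
      gtggg_box <- list(start = h$start + as.integer(at) - 1L,
                        end = h$start + as.integer(at) + 3L)
    }
  }

  pal <- do.call(rbind, lapply(c("TACAT", "ATGTA"), function(p) {
    m <- gregexpr(p, region, fixed = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(motif = p, start = as.integer(m), stringsAsFactors = FALSE)
  }))
  if (is.null(pal)) {
    pal <- data.frame(motif = character(0), start = integer(0),
                      stringsAsFactors = FALSE)
  }

  homo <- find_t_homopolymers(region)
  homo$between_csbD_csb1 <- FALSE
  if (!is.null(hits[["CSB-D"]]) && !is.null(hits[["CSB-1"]]) && nrow(homo)) {
    lo <- hits[["CSB-D"]]$end
    hi <- hits[["CSB-1"]]$start
    homo$between_csbD_csb1 <- homo$start > lo & (homo$start + homo$length - 1L) < hi
  }

  structure(list(
    hits = hits, order_ok = order_ok, gtggg_box = gtggg_box,
    palindromes = pal, homopolymers = homo,
    tandem_repeats = find_tandem_repeats(region)
  ), class = "cr_annotation")
}

#' @export
print.cr_annotation <- function(x, ...) {
  found <- names(x$hits)[!vapply(x$hits, is.null, logical(1))]
  cat(sprintf("<cr_annotation> motifs found: %s\n",
              if (length(found)) paste(found, collapse = ", ") else "none"))
  cat(sprintf("  CSB order %s; GTGGG box %s; %d palindrome(s); %d T-run(s); %d tandem repeat(s)\n",
              if (x$order_ok) "canonical" else "violated/incomplete",
              if (is.null(x$gtggg_box)) "absent" else "present",
              nrow(x$palindromes), nrow(x$homopolymers),
              nrow(x$tandem_repeats)))
  invisible(x)
}
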