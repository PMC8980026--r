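#' Mitogenome records and gene features
#'
#' A mitogenome record is the package's central container: the (circular)
#' genome length, an optional nucleotide sequence, and an ordered table of
#' annotated gene features in 1-based inclusive coordinates, as printed in
#' GenBank flat files and in published annotation tables. Light-strand (L)
#' features are stored with heavy-strand (H) coordinates; their coding-strand
#' sequence is obtained by reverse complementation on extraction.
#'
#' @name mitogenome
NULL

.feature_categories <- c("PCG", "tRNA", "rRNA", "control_region")

## size sanity ranges per category (bp); outside -> validation warning
.category_size_range <- list(
  tRNA = c(60L, 100L),
  rRNA = c(900L, 1800L)
)

infer_category <- function(locus) {
  vapply(locus, function(x) {
    if (grepl("^tRNA", x, ignore.case = TRUE)) return("tRNA")
    if (grepl("rRNA|^12S|^16S", x, ignore.case = TRUE)) return("rRNA")
    if (grepl("D-?loop|control", x, ignore.case = TRUE)) return("control_region")
    "PCG"
  }, character(1), USE.NAMES = FALSE)
}

#' Build a validated gene-feature table
#'
#' @param locus character vector of locus labels (e.g. `"ND5"`, `"tRNA-Phe"`).
#' @param strand `"H"` (heavy) or `"L"` (light) per feature.
#' @param start,end 1-based inclusive coordinates; `end >= start` (no
#'   origin-spanning features).
#' @param category optional; one of `"PCG"`, `"tRNA"`, `"rRNA"`,
#'   `"control_region"`. Inferred from the locus label when missing.
#' @param anticodon optional 3-letter anticodon for tRNAs.
#' @return `data.frame` with columns `locus`, `strand`, `start`, `end`,
#'   `size`, `category`, `anticodon`, sorted by `start`.
#' @export
gene_features <- function(locus, strand, start, end,
                          category = NULL, anticodon = NULL) {
  n <- length(locus)
  stopifnot(length(strand) == n, length(start) == n, length(end) == n)
  start <- as.integer(start)
  end <- as.integer(end)
  if (anyNA(start) || anyNA(end)) {
    stop("malformed coordinate: non-numeric start/end", call. = FALSE)
  }
  if (any(start < 1L)) stop("start coordinates must be >= 1", call. = FALSE)
  bad <- which(end < start)
  if (length(bad)) {
    stop("end < start for feature(s): ", paste(locus[bad], collapse = ", "),
         call. = FALSE)
  }
  if (!all(strand %in% c("H", "L"))) {
    stop("strand must be 'H' or 'L'", call. = FALSE)
  }
  if (is.null(category) || all(is.na(category))) {
    category <- infer_category(locus)
  }
  if (!all(category %in% .feature_categories)) {
    stop("unknown category: ",
         paste(setdiff(category, .feature_categories), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(anticodon)) anticodon <- rep(NA_character_, n)
  anticodon[!nzchar(anticodon) | is.na(anticodon)] <- NA_character_
  df <- data.frame(
    locus = as.character(locus), strand = strand,
    start = start, end = end, size = end - start + 1L,
    category = category, anticodon = as.character(anticodon),
    stringsAsFactors = FALSE
  )
  if (is.unsorted(df$start)) {
    warning("features not sorted by start; sorting", call. = FALSE)
    df <- df[order(df$start), , drop = FALSE]
    rownames(df) <- NULL
  }
  for (cat in names(.category_size_range)) {
    rng <- .category_size_range[[cat]]
    off <- df$category == cat & (df$size < rng[1] | df$size > rng[2])
    if (any(off)) {
      warning(sprintf("%s feature(s) outside %d-%d bp sanity range: %s",
                      cat, rng[1], rng[2],
                      paste(df$locus[off], collapse = ", ")), call. = FALSE)
    }
  }
  df
}

#' Construct a mitogenome record
#'
#' @param id accession or sample label.
#' @param length total genome length in bp; defaults to the sequence length
#'   or the maximum feature end.
#' @param features a feature table from [gene_features()] (or a data.frame
#'   with compatible columns).
#' @param sequence optional H-strand nucleotide string over A/C/G/T/N.
#' @param circular logical flag; vertebrate mitogenomes are circular, but
#'   origin-spanning features are not modelled.
#' @return object of class `"mitogenome"`.
#' @export
mitogenome_record <- function(id, length = NULL, features = NULL,
                              sequence = NULL, circular = TRUE) {
  if (!is.null(sequence)) {
    sequence <- check_nucleotide(sequence)
  }
  if (is.null(features)) {
    warning("record '", id, "' has no features", call. = FALSE)
    features <- gene_features(character(), character(), integer(), integer())
  } else if (!nrow(features)) {
    warning("record '", id, "' has no features", call. = FALSE)
  } else {
    features <- gene_features(features$locus, features$strand,
                              features$start, features$end,
                              features$category, features$anticodon)
  }
  if (is.null(length)) {
    length <- if (!is.null(sequence)) nchar(sequence) else
      if (nrow(features)) max(features$end) else 0L
  }
  length <- as.integer(length)
  if (!is.null(sequence) && nchar(sequence) != length) {
    stop("sequence length (", nchar(sequence),
         ") does not match declared genome length (", length, ")",
         call. = FALSE)
  }
  if (nrow(features) && any(features$end > length)) {
    stop("feature(s) extend past genome length ", length, call. = FALSE)
  }
  structure(
    list(id = id, length = length, circular = circular,
         sequence = sequence, features = features),
    class = "mitogenome"
  )
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s: %s bp, %d features%s%s\n",
              x$id, format(x$length, big.mark = ","), nrow(x$features),
              if (x$circular) ", circular" else "",
              if (is.null(x$sequence)) " (no sequence)" else ""))
  tab <- table(factor(x$features$category, levels = .feature_categories))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Read an annotation table (TSV)
#'
#' Reads a tab-separated annotation table with header columns `locus`,
#' `strand`, `start`, `end` and optionally `size`, `category`, `anticodon`
#' (extra columns are kept but ignored). A `size` column, when present, is
#' cross-checked against `end - start + 1`; mismatches raise warnings and
#' the coordinate-derived size wins (never a silent correction).
#'
#' @param path path to the TSV file.
#' @param id record id; defaults to the file name.
#' @param sequence optional genome sequence to attach.
#' @return a [mitogenome_record()].
#' @export
read_annotation_table <- function(path, id = NULL, sequence = NULL) {
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  names(df) <- tolower(names(df))
  need <- c("locus", "strand", "start", "end")
  if (!all(need %in% names(df))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("malformed coordinate in column '", col, "' at data line ",
           bad[1], " of ", basename(path), call. = FALSE)
    }
    df[[col]] <- v
  }
  feats <- gene_features(df$locus, df$strand, df$start, df$end,
                         df$category, df$anticodon)
  if ("size" %in% names(df)) {
    derived <- df$end - df$start + 1L
    bad <- which(!is.na(df$size) & df$size != derived)
    if (length(bad)) {
      warning("size column disagrees with coordinates for: ",
              paste(df$locus[bad], collapse = ", "), call. = FALSE)
    }
  }
  rec <- mitogenome_record(id, features = feats, sequence = sequence)
  ## carry any codon annotation columns along for reporting
  for (col in c("start_codon", "stop_codon")) {
    if (col %in% names(df)) {
      rec$features[[col]] <- as.character(df[[col]])[order(df$start)]
    }
  }
  rec
}

#' Write an annotation table (TSV)
#'
#' Inverse of [read_annotation_table()]: writes `locus`, `strand`, `start`,
#' `end`, `category`, `anticodon` so that reading the file back reproduces
#' the feature table.
#'
#' @param record a `mitogenome` record.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(record, path) {
  df <- record$features[, c("locus", "strand", "start", "end",
                            "category", "anticodon")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' The Decapterus russelli annotation fixture
#'
#' The 38-feature annotation of the Indian scad mitogenome (16,542 bp;
#' 13 protein-coding genes, 22 tRNAs, 2 rRNAs, control region), shipped
#' with the package, including the published per-region base compositions
#' and start/stop codons.
#'
#' @param sequence optional sequence to attach (e.g. from the synthetic
#'   generator, which reproduces this layout).
#' @return a [mitogenome_record()] whose feature table additionally carries
#'   `start_codon`, `stop_codon` and `a_pct`/`t_pct`/`g_pct`/`c_pct` columns.
#' @export
decapterus_annotation <- function(sequence = NULL) {
  path <- system.file("extdata", "decapterus_russelli_table1.tsv",
                      package = "mitocomp", mustWork = TRUE)
  rec <- read_annotation_table(path, id = "D_russelli", sequence = sequence)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  for (col in c("a_pct", "t_pct", "g_pct", "c_pct")) {
    rec$features[[col]] <- df[[col]][order(df$start)]
  }
  rec$length <- 16542L
  rec
}

#' Extract the coding-strand sequence of a feature
#'
#' For H-strand features this is the slice of the genome sequence; for
#' L-strand features it is the reverse complement of that slice, i.e. the
#' strand actually read by the ribosome/structure. Length always equals the
#' feature size.
#'
#' @param record a `mitogenome` record carrying a sequence.
#' @param feature a one-row feature data.frame, or a locus name present in
#'   the record.
#' @return nucleotide string.
#' @export
extract_gene_sequence <- function(record, feature) {
  if (is.null(record$sequence)) {
    stop("record '", record$id, "' carries no sequence", call. = FALSE)
  }
  if (is.character(feature)) {
    i <- match(feature, record$features$locus)
    if (is.na(i)) stop("no feature named '", feature, "'", call. = FALSE)
    feature <- record$features[i, ]
  }
  if (feature$start < 1L || feature$end > record$length) {
    stop("feature '", feature$locus, "' out of bounds [1, ",
         record$length, "]", call. = FALSE)
  }
  s <- substr(record$sequence, feature$start, feature$end)
  if (identical(feature$strand, "L")) s <- revcomp(s)
  s
}

#' Intergenic spacers and gene overlaps
#'
#' Walks consecutive feature pairs in genome (H-strand coordinate) order —
#' strand is ignored for adjacency, matching the single intergenic column of
#' published annotation tables — and classifies each junction as a spacer
#' (gap > 0), an overlap (shared bases), or adjacent (length 0). The pair
#' across the circular origin is not formed by default.
#'
#' @param record a `mitogenome` record (or a feature data.frame) with
#'   at least 2 features.
#' @param across_origin also form the last-to-first pair through the
#'   circular origin (default `FALSE`).
#' @return `data.frame` with columns `upstream`, `downstream`, `kind`
#'   (`"spacer"`/`"overlap"`/`"adjacent"`) and `length` (bp, >= 0).
#' @export
spacers_and_overlaps <- function(record, across_origin = FALSE) {
  feats <- if (inherits(record, "mitogenome")) record$features else record
  if (nrow(feats) < 2L) stop("need at least 2 features", call. = FALSE)
  if (is.unsorted(feats$start)) {
    warning("features not sorted by start; sorting", call. = FALSE)
    feats <- feats[order(feats$start), , drop = FALSE]
  }
  up <- feats[-nrow(feats), ]
  dn <- feats[-1L, ]
  gap <- dn$start - up$end - 1L
  out <- data.frame(
    upstream = up$locus, downstream = dn$locus,
    kind = ifelse(gap > 0L, "spacer", ifelse(gap < 0L, "overlap", "adjacent")),
    length = abs(gap),
    stringsAsFactors = FALSE
  )
  if (across_origin && inherits(record, "mitogenome")) {
    gap0 <- (record$length - feats$end[nrow(feats)]) + feats$start[1L] - 1L
    out <- rbind(out, data.frame(
      upstream = feats$locus[nrow(feats)], downstream = feats$locus[1L],
      kind = if (gap0 > 0L) "spacer" else if (gap0 < 0L) "overlap" else "adjacent",
      length = abs(gap0), stringsAsFactors = FALSE
    ))
  }
  out
}
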