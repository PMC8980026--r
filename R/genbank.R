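#' Read a GenBank flat file into a mitogenome record
#'
#' Minimal flat-file reader for annotated mitogenomes: parses the LOCUS
#' length, the FEATURES table (feature keys `CDS`, `tRNA`, `rRNA`,
#' `D-loop`; plain and `complement(..)` locations) and the ORIGIN sequence
#' block. `complement()` locations are assigned strand `L` and stored with
#' H-strand coordinates. Joined or origin-spanning locations are not
#' supported (they do not occur in the genomes modelled here).
#'
#' @param path path to a GenBank flat file.
#' @return a [mitogenome_record()]; if the file lacks an ORIGIN block the
#'   record carries no sequence and sequence-dependent operations will
#'   raise a "no sequence" error at their point of use.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1])) {
    stop("not a GenBank flat file (missing LOCUS line): ", basename(path),
         call. = FALSE)
  }
  id <- strsplit(trimws(sub("^LOCUS", "", lines[1])), "\\s+")[[1]][1]
  acc <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc)) {
    a <- strsplit(trimws(sub("^ACCESSION", "", acc[1])), "\\s+")[[1]][1]
    if (!is.na(a) && nzchar(a)) id <- a
  }

  feat_start <- grep("^FEATURES", lines)
  origin_start <- grep("^ORIGIN", lines)
  end_markers <- c(origin_start, grep("^//", lines), length(lines) + 1L)

  locus <- character(); strand <- character()
  fstart <- integer(); fend <- integer(); category <- character()

  if (length(feat_start)) {
    stop_at <- min(end_markers[end_markers > feat_start[1]])
    block <- lines[(feat_start[1] + 1L):(stop_at - 1L)]
    keymap <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                "D-loop" = "control_region")
    is_key <- grepl("^ {2,8}\\S", block)  # new feature: key indented < col 21
    idx <- which(is_key)
    for (k in seq_along(idx)) {
      line <- block[idx[k]]
      parts <- strsplit(trimws(line), "\\s+")[[1]]
      key <- parts[1]
      if (!key %in% names(keymap)) next
      loc <- if (length(parts) > 1) parts[2] else ""
      if (grepl("join|order", loc)) {
        stop("joined locations not supported: ", loc, call. = FALSE)
      }
      str <- if (grepl("^complement\\(", loc)) "L" else "H"
      m <- regmatches(loc, regexec("(\\d+)\\.\\.(\\d+)", loc))[[1]]
      if (length(m) < 3) {
        stop("cannot parse feature location: ", loc, call. = FALSE)
      }
      ## qualifiers up to the next key line
      qual_end <- if (k < length(idx)) idx[k + 1] - 1L else length(block)
      quals <- block[seq(idx[k], qual_end)]
      name <- NA_character_
      for (pat in c("/gene=\"([^\"]+)\"", "/product=\"([^\"]+)\"")) {
        hit <- regmatches(quals, regexec(pat, quals))
        hit <- hit[vapply(hit, length, 1L) == 2]
        if (length(hit)) { name <- hit[[1]][2]; break }
      }
      if (is.na(name)) name <- key
      locus <- c(locus, name); strand <- c(strand, str)
      fstart <- c(fstart, as.integer(m[2])); fend <- c(fend, as.integer(m[3]))
      category <- c(category, keymap[[key]])
    }
  }

  sequence <- NULL
  if (length(origin_start)) {
    stop_at <- grep("^//", lines)
    stop_at <- if (length(stop_at)) min(stop_at[stop_at > origin_start[1]]) else length(lines) + 1L
    seq_lines <- lines[(origin_start[1] + 1L):(stop_at - 1L)]
    sequence <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
    if (!nzchar(sequence)) sequence <- NULL
  }

  len <- NULL
  m <- regmatches(lines[1], regexec("(\\d+)\\s+bp", lines[1]))[[1]]
  if (length(m) == 2) len <- as.integer(m[2])

  feats <- if (length(locus)) {
    gene_features(locus, strand, fstart, fend, category)
  } else NULL
  mitogenome_record(id, length = len, features = feats, sequence = sequence)
}
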