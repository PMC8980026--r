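#' Assemble the full comparative-mitogenomics report bundle
#'
#' Runs every analysis stage that its inputs allow and writes one
#' tab-separated file per stage into `out_dir`: the per-region statistics
#' table, the spacer/overlap table, the codon-usage/RSCU table (sequence
#' required), per-gene evolutionary rates (>= 2 taxa per alignment
#' required), the tRNA wobble and site-frequency tables (structures
#' required), and the control-region motif hits with divergence masks.
#' Stages without inputs are skipped with a notice. Identical inputs
#' produce byte-identical outputs.
#'
#' @param record a [mitogenome_record()].
#' @param out_dir output directory (created if missing).
#' @param alignments optional named list of aligned gene sets (named
#'   character vectors) for [p_distance()] / [gene_average_kaks()].
#' @param trna_structs optional list of cloverleaf structures.
#' @param cr_lib motif library for the control region (the feature named
#'   `D-loop`/`control_region` in the record, when sequence is present).
#' @param rounding `"paper"` or `"full"`; see [region_stats_table()].
#' @return named character vector of the files written, invisibly.
#' @export
full_report <- function(record, out_dir, alignments = NULL,
                        trna_structs = NULL,
                        cr_lib = default_motif_library(),
                        rounding = "paper") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  wt <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    written[[name]] <<- path
  }

  wt(region_stats_table(record, rounding = rounding), "region_stats.tsv")
  if (nrow(record$features) >= 2L) {
    wt(spacers_and_overlaps(record), "spacers_overlaps.tsv")
  }

  if (!is.null(record$sequence)) {
    pcgs <- record$features[record$features$category == "PCG", ]
    if (nrow(pcgs)) {
      seqs <- vapply(seq_len(nrow(pcgs)), function(i) {
        extract_gene_sequence(record, pcgs[i, ])
      }, character(1))
      cu <- rscu(count_codons(seqs))
      wt(as.data.frame(cu), "codon_rscu.tsv")
    }
    cr <- record$features[record$features$category == "control_region", ]
    if (nrow(cr) == 1L) {
      ann <- annotate_control_region(
        extract_gene_sequence(record, cr[1, ]), lib = cr_lib)
      hits <- do.call(rbind, lapply(names(ann$hits), function(nm) {
        h <- ann$hits[[nm]]
        if (is.null(h)) {
          data.frame(motif = nm, start = NA, end = NA, n_sub = NA,
                     n_ins = NA, n_del = NA, mask = "no-hit")
        } else {
          data.frame(motif = nm, start = h$start, end = h$end,
                     n_sub = h$n_substitutions, n_ins = h$n_insertions,
                     n_del = h$n_deletions, mask = h$mask)
        }
      }))
      wt(hits, "control_region_motifs.tsv")
    }
  } else {
    message("record has no sequence: codon and control-region stages skipped")
  }

  if (!is.null(alignments)) {
    rates <- do.call(rbind, lapply(names(alignments), function(g) {
      aln <- alignments[[g]]
      kk <- gene_average_kaks(aln)
      data.frame(
        gene = g,
        mean_p_all = p_distance(aln, "all")$mean_p,
        mean_p_pos12 = p_distance(aln, "pos12")$mean_p,
        mean_p_pos3 = p_distance(aln, "pos3")$mean_p,
        mean_ka = kk$mean_ka, mean_ks = kk$mean_ks,
        mean_kaks = kk$mean_kaks, stringsAsFactors = FALSE)
    }))
    wt(rates, "rates.tsv")
  } else {
    message("no alignments supplied: rates stage skipped")
  }

  if (!is.null(trna_structs)) {
    ws <- wobble_table(trna_structs)
    wt(ws$table, "trna_wobble.tsv")
    wt(site_frequencies(trna_structs), "trna_site_frequencies.tsv")
  } else {
    message("no tRNA structures supplied: tRNA stage skipped")
  }

  invisible(unlist(written))
}
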