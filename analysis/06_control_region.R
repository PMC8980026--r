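#!/usr/bin/env Rscript
# Control-region annotation: ordered CSB motif detection by bounded edit
# distance, divergence masks, palindromic TACAT/ATGTA motifs, the
# T homopolymer between CSB-D and CSB-1, and the tandem-repeat scan.
#
# A synthetic 840-bp control region is generated with recorded edits
# planted on three of the blocks; the annotation recovers every motif at
# its planted position and edit counts, the palindromes cluster at the
# 5' end, and no tandem repeats are called — the pattern reported across
# carangid control regions.

suppressPackageStartupMessages(library(mitocomp))
dir.create("results", showWarnings = FALSE)

spec <- generator_spec(seed = 1, motif_edits = list(
  "CSB-F" = c(2L, 0L), "CSB-E" = c(3L, 0L), "CSB-1" = c(2L, 1L)))
crg <- generate_control_region(spec)
ann <- annotate_control_region(crg$region, spec$motif_lib)

hits <- do.call(rbind, lapply(names(ann$hits), function(nm) {
  h <- ann$hits[[nm]]
  tr <- crg$truth$motifs[[nm]]
  data.frame(motif = nm, start = h$start, end = h$end,
             n_sub = h$n_substitutions, n_ins = h$n_insertions,
             n_del = h$n_deletions, planted_start = tr$start,
             planted_sub = tr$n_sub, mask = h$mask)
}))
write.table(hits, "results/06_control_region_hits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(hits[, c("motif", "start", "n_sub", "n_ins", "n_del",
               "planted_start", "planted_sub")], row.names = FALSE)

cat(sprintf("\nCSB order canonical: %s; GTGGG box: %s\n", ann$order_ok,
            !is.null(ann$gtggg_box)))
cat(sprintf("Palindromes (TACAT/ATGTA): %d, first at positions %s\n",
            nrow(ann$palindromes),
            paste(head(sort(ann$palindromes$start), 3), collapse = ", ")))
run <- ann$homopolymers[ann$homopolymers$between_csbD_csb1, ]
cat(sprintf("T homopolymer between CSB-D and CSB-1: %d nt at %d\n",
            run$length[1], run$start[1]))
cat(sprintf("Tandem repeats called: %d\n", nrow(ann$tandem_repeats)))
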