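#!/usr/bin/env Rscript
# Annotation arithmetic of the Decapterus russelli mitogenome.
#
# Re-derives every per-locus size from the printed 1-based coordinates,
# sums them by category, and walks consecutive junctions for intergenic
# spacers and gene overlaps. Finding: 13 PCGs sum to 11,425 bp (69% of
# the 16,542 bp genome), 22 tRNAs to 1,555 bp, the two rRNAs to 2,677 bp,
# the control region is 840 bp; 11 spacers (1-38 bp, the largest between
# tRNA-Asn and tRNA-Cys) and 7 overlaps (1-7 bp, the largest ATP8/ATP6).

suppressPackageStartupMessages(library(mitocomp))
dir.create("results", showWarnings = FALSE)

rec <- decapterus_annotation()
f <- rec$features

sizes <- data.frame(
  category = c("PCG", "tRNA", "rRNA", "control_region", "genome"),
  total_bp = c(sum(f$size[f$category == "PCG"]),
               sum(f$size[f$category == "tRNA"]),
               sum(f$size[f$category == "rRNA"]),
               sum(f$size[f$category == "control_region"]),
               rec$length),
  n_features = c(sum(f$category == "PCG"), sum(f$category == "tRNA"),
                 sum(f$category == "rRNA"),
                 sum(f$category == "control_region"), nrow(f)))
write.table(sizes, "results/01_category_sizes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

so <- spacers_and_overlaps(rec)
write.table(so, "results/01_spacers_overlaps.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Category totals (bp):\n")
print(sizes, row.names = FALSE)
cat(sprintf("\n%d spacers (max %d bp: %s-%s), %d overlaps (max %d bp: %s-%s)\n",
            sum(so$kind == "spacer"),
            max(so$length[so$kind == "spacer"]),
            so$upstream[so$kind == "spacer"][which.max(so$length[so$kind == "spacer"])],
            so$downstream[so$kind == "spacer"][which.max(so$length[so$kind == "spacer"])],
            sum(so$kind == "overlap"),
            max(so$length[so$kind == "overlap"]),
            so$upstream[so$kind == "overlap"][which.max(so$length[so$kind == "overlap"])],
            so$downstream[so$kind == "overlap"][which.max(so$length[so$kind == "overlap"])]))
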