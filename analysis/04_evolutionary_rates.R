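#!/usr/bin/env Rscript
# Evolutionary-rate statistics: codon-partitioned p-distances and
# Nei-Gojobori Ka/Ks on simulated gene families with known generating
# regimes.
#
# Three regimes bracket the biology: pure synonymous drift (the Ka/Ks -> 0
# limit of a strongly purified gene such as COI), unconstrained change,
# and pure nonsynonymous change (Ks = 0). Third-position p-distances
# exceed first+second-position distances whenever changes are synonymous,
# the pattern the published cross-species comparison reports.

suppressPackageStartupMessages(library(mitocomp))
dir.create("results", showWarnings = FALSE)

regimes <- c(synonymous = "synonymous", mixed = "any",
             nonsynonymous = "nonsynonymous")
rows <- lapply(names(regimes), function(nm) {
  fam <- simulate_gene_family(n_taxa = 6, n_codons = 150, n_subs = 20,
                              mode = regimes[[nm]],
                              spec = generator_spec(seed = match(nm, names(regimes))))
  kk <- gene_average_kaks(fam)
  data.frame(
    regime = nm,
    mean_p_all = round(p_distance(fam, "all")$mean_p, 4),
    mean_p_pos12 = round(p_distance(fam, "pos12")$mean_p, 4),
    mean_p_pos3 = round(p_distance(fam, "pos3")$mean_p, 4),
    mean_ka = round(kk$mean_ka, 4), mean_ks = round(kk$mean_ks, 4),
    mean_kaks = round(kk$mean_kaks, 4), n_undefined = kk$n_undefined)
})
tab <- do.call(rbind, rows)
write.table(tab, "results/04_rates_by_regime.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(tab, row.names = FALSE)

syn <- tab[tab$regime == "synonymous", ]
stopifnot(syn$mean_ka == 0, syn$mean_p_pos3 > syn$mean_p_pos12)
cat("\nSynonymous regime: Ka = 0 exactly; third-position p-distance",
    sprintf("(%.3f) dominates positions 1+2 (%.3f), as expected.\n",
            syn$mean_p_pos3, syn$mean_p_pos12))
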