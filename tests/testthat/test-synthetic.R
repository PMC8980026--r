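test_that("the generator is deterministic in its seed", {
  g1 <- generate_mitogenome(generator_spec(seed = 131))
  g2 <- generate_mitogenome(generator_spec(seed = 131))
  expect_identical(g1$record$sequence, g2$record$sequence)
  g3 <- generate_mitogenome(generator_spec(seed = 132))
  expect_false(identical(g1$record$sequence, g3$record$sequence))

  t1 <- generate_trna_set(generator_spec(seed = 131))
  t2 <- generate_trna_set(generator_spec(seed = 131))
  expect_identical(t1$truth, t2$truth)
})

test_that("the default layout reproduces the worked-example gene arithmetic", {
  g <- generate_mitogenome(generator_spec(seed = 133))
  f <- g$record$features
  expect_equal(g$record$length, 16542L)
  expect_equal(sum(f$size[f$category == "PCG"]), 11425L)
  expect_equal(sum(f$size[f$category == "tRNA"]), 1555L)
  ## planted mTERF site is recovered inside tRNA-Leu(TAA)
  leu <- extract_gene_sequence(g$record, "tRNA-Leu(TAA)")
  hit <- mterf_site_check(leu)
  expect_true(hit$hit)
  expect_equal(hit$start, g$truth$mterf$offset_in_gene)
})

test_that("genome composition tracks the generating probabilities within 3 s.e.", {
  spec <- generator_spec(seed = 134)
  g <- generate_mitogenome(spec)
  comp <- base_composition(g$record$sequence)
  n <- g$record$length
  for (b in c("A", "C", "G", "T")) {
    p <- spec$base_probs[[b]]
    se <- sqrt(p * (1 - p) / n)
    got <- comp$counts[[b]] / n
    ## coding constraints perturb base usage slightly; 3 s.e. on the
    ## genome scale still brackets the target composition
    expect_lt(abs(got - p), max(3 * se, 0.02))
  }
})

test_that("balanced base probabilities produce near-zero whole-genome skews", {
  spec <- generator_spec(seed = 135,
                         base_probs = c(A = 0.3, C = 0.2, T = 0.3, G = 0.2),
                         layout = gene_features(
                           locus = c("12S-rRNA", "16S-rRNA"),
                           strand = c("H", "H"),
                           start = c(1L, 1001L), end = c(1000L, 2800L),
                           category = c("rRNA", "rRNA")))
  g <- generate_mitogenome(spec)
  sk <- skews(base_composition(g$record$sequence))
  ## binomial error on (A-T)/(A+T) at ~60% of 2800 AT bases
  expect_lt(abs(sk$at_skew), 3 / sqrt(0.6 * 2800))
  expect_lt(abs(sk$gc_skew), 3 / sqrt(0.4 * 2800))
})

test_that("planted protein-coding genes are in frame with legal codons", {
  g <- generate_mitogenome(generator_spec(seed = 136))
  code <- vertebrate_mito_code()
  for (locus in c("ND1", "COI", "ND2", "Cytb")) {
    s <- g$truth$pcg_seqs[[locus]]
    expect_equal(substr(s, 1, 3), g$truth$start_codons[[locus]])
    n_full <- nchar(s) %/% 3
    cods <- substring(s, 3 * seq_len(n_full) - 2, 3 * seq_len(n_full))
    internal <- cods[-c(1, n_full)]
    expect_false(any(code[internal] == "*"))
  }
})

test_that("tRNA group wobble fractions match their generating probabilities", {
  spec <- generator_spec(seed = 137, n_species = 3)
  ts <- generate_trna_set(spec)
  truth <- ts$truth
  for (strand in c("H", "L")) {
    rows <- truth[truth$strand == strand, ]
    wob <- sum(rows$wobble_AA + rows$wobble_DHU + rows$wobble_AC +
                 rows$wobble_TPsiU)
    pairs <- sum(rows$total_pairs)
    expect_gt(pairs, 500)
    p <- spec$wobble_p[[strand]]
    se <- sqrt(p * (1 - p) / pairs)
    expect_lt(abs(wob / pairs - p), 3 * se + 1e-9)
  }
  ## Ser(GCT) structures come without a DHU arm and still partition
  ser <- Filter(function(s) s$name == "tRNA-Ser(GCT)", ts$structs)
  expect_true(length(ser) >= 1)
  expect_false(any(vapply(ser, function(s) s$dhu_present, logical(1))))
})

test_that("layout overflow is a spec error", {
  one_gene <- gene_features("ND1", "H", 1L, 999L, "PCG")
  one_gene$start_codon <- "ATG"; one_gene$stop_codon <- "TAA"
  g <- generate_mitogenome(generator_spec(seed = 138, layout = one_gene))
  expect_equal(g$record$length, 999L)  # layout defines the genome span
  expect_error(
    generate_control_region(generator_spec(seed = 139, cr_length = 150L)),
    "overflow")
})

test_that("a full report bundle is written for a synthetic genome", {
  g <- generate_mitogenome(generator_spec(seed = 140))
  ts <- generate_trna_set(generator_spec(seed = 140))
  fam <- simulate_gene_family(3, 50, 6, "any", generator_spec(seed = 140))
  out <- tempfile("report")
  files <- full_report(g$record, out, alignments = list(ND1 = fam),
                       trna_structs = ts$structs)
  expect_true(all(file.exists(files)))
  expect_setequal(names(files),
                  c("region_stats.tsv", "spacers_overlaps.tsv",
                    "codon_rscu.tsv", "control_region_motifs.tsv",
                    "rates.tsv", "trna_wobble.tsv",
                    "trna_site_frequencies.tsv"))
  stats <- read.delim(files[["region_stats.tsv"]])
  expect_equal(nrow(stats), 39L)
  rates <- read.delim(files[["rates.tsv"]])
  expect_equal(rates$gene, "ND1")
  ## skipped stages are announced, not errors
  expect_message(
    full_report(decapterus_annotation(), tempfile("report2")),
    "skipped")
})
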