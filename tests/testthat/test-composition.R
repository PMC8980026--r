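test_that("base composition percentages and A+T content are exact", {
  c1 <- base_composition("AATT")
  expect_equal(c(c1$a_pct, c1$t_pct, c1$g_pct, c1$c_pct), c(50, 50, 0, 0))
  c2 <- base_composition("ACGT")
  expect_equal(c(c2$a_pct, c2$t_pct, c2$g_pct, c2$c_pct), rep(25, 4))
  expect_error(base_composition(""), "empty")
  expect_error(base_composition("NNNN"), "all-N")
  expect_warning(base_composition("ACGTNN"), "ambiguous")
})

test_that("at_pct + gc_pct is exactly 100 before rounding", {
  set.seed(11)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 50 + i, replace = TRUE,
                      prob = c(0.4, 0.1, 0.2, 0.3)), collapse = "")
    comp <- base_composition(s)
    expect_equal(comp$at_pct + comp$gc_pct, 100)
  }
})

test_that("skews from the printed control-region composition match the narrative", {
  sk <- skew_pair(33.0, 30.6, 16.3, 20.1)
  expect_equal(round_half_up(sk$at_skew, 3), 0.038)
  expect_equal(round_half_up(sk$gc_skew, 3), -0.104)
  expect_equal(33.0 + 30.6, 63.6)   # highest A+T content of any region
  ## balanced sequence has zero skew; zero denominator is missing, not 0
  z <- skew_pair(25, 25, 25, 25)
  expect_equal(c(z$at_skew, z$gc_skew), c(0, 0))
  u <- skew_pair(0, 0, 50, 50)
  expect_true(is.na(u$at_skew))
  expect_equal(u$gc_skew, 0)
})

test_that("skews are computed at full precision, not from rounded display", {
  set.seed(21)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 201, replace = TRUE,
                      prob = c(0.35, 0.3, 0.15, 0.2)), collapse = "")
    comp <- base_composition(s)
    sk <- skews(comp)
    cnt <- comp$counts
    expect_equal(sk$at_skew,
                 (cnt[["A"]] - cnt[["T"]]) / (cnt[["A"]] + cnt[["T"]]),
                 tolerance = 1e-9)
    expect_equal(sk$gc_skew,
                 (cnt[["G"]] - cnt[["C"]]) / (cnt[["G"]] + cnt[["C"]]),
                 tolerance = 1e-9)
  }
})

test_that("reverse complementation flips both skews", {
  set.seed(31)
  for (i in 1:15) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    fwd <- skews(base_composition(s))
    rev <- skews(base_composition(revcomp(s)))
    expect_equal(rev$at_skew, -fwd$at_skew, tolerance = 1e-12)
    expect_equal(rev$gc_skew, -fwd$gc_skew, tolerance = 1e-12)
  }
})

test_that("stop classification follows gene length modulo 3", {
  make_gene <- function(n, start = "ATG", tail = NULL) {
    body_len <- n - nchar(start) - sum(nchar(tail))
    body <- strrep("GCC", body_len / 3)
    paste0(start, body, paste(tail, collapse = ""))
  }
  g1 <- make_gene(1045, tail = "T")            # ND2-style
  cc1 <- classify_codons(g1)
  expect_equal(cc1$stop_kind, "T_incomplete")
  expect_equal(cc1$stop_text, "T--")
  expect_equal(cc1$start_codon, "ATG")

  g2 <- make_gene(785, tail = "TA")            # COIII-style
  cc2 <- classify_codons(g2)
  expect_equal(cc2$stop_kind, "TA_incomplete")
  expect_equal(cc2$stop_text, "TA-")

  g3 <- make_gene(1551, start = "GTG", tail = "TAA")  # COI-style
  cc3 <- classify_codons(g3)
  expect_equal(cc3$stop_kind, "complete")
  expect_equal(cc3$stop_text, "TAA")
  expect_equal(cc3$start_codon, "GTG")

  expect_error(classify_codons("ATGT"), "shorter than 6")
  expect_warning(classify_codons("ATGGCCGGC"), "not a vertebrate mitochondrial stop")
})

test_that("the per-region table mirrors the annotation on synthetic sequence", {
  g <- generate_mitogenome(generator_spec(seed = 101))
  st <- region_stats_table(g$record)
  expect_equal(nrow(st), 39L)  # 38 features + genome row
  expect_equal(sum(st$size[st$category %in% "PCG"]), 11425L)
  ## planted codons recovered for genes not clipped by an overlap
  expect_equal(st$start_codon[st$locus == "ND1"], "ATG")
  expect_equal(st$stop_codon[st$locus == "ND1"], "TAA")
  expect_equal(st$stop_codon[st$locus == "ND2"], "T--")
  expect_equal(st$stop_codon[st$locus == "COIII"], "TA-")
  ## percentages round-trip the genome row against a direct computation
  comp <- base_composition(g$record$sequence)
  grow <- st[st$locus == "genome", ]
  expect_equal(grow$a_pct, round_half_up(comp$a_pct, 1))
  expect_equal(grow$at_skew, round_half_up(skews(comp)$at_skew, 3))
})

test_that("the table degrades gracefully without sequence", {
  rec <- decapterus_annotation()
  st <- region_stats_table(rec)
  expect_equal(nrow(st), 39L)
  expect_true(all(is.na(st$a_pct)))
  expect_equal(st$size[st$locus == "D-loop"], 840L)
  expect_false(anyNA(st$intergenic[1:37]))

  single <- suppressWarnings(mitogenome_record("one", length = 2000L,
    features = data.frame(locus = "12S", strand = "H", start = 1L,
                          end = 954L, category = "rRNA", anticodon = NA)))
  st1 <- region_stats_table(single)
  expect_equal(nrow(st1), 2L)
  expect_true(is.na(st1$intergenic[1]))
})
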