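# hand-built canonical cloverleaf: AA 7 bp, DHU 4 bp, AC 5 bp, TPsiU 5 bp
canon_trna <- function() {
  seq <- paste0(
    "GCGGAUU", "UA",                       # AA 5' + spacer
    "GCUC", "AGUUGGG", "GAGC", "G",        # DHU arm
    "CCAGA", "CUGAAGA", "UCUGG",           # AC arm (anticodon GAA at centre)
    "AGGU",                                # variable loop
    "CCUGU", "GUUCGAU", "ACAGG",           # TPsiU arm
    "AAUCCGC", "A")                        # AA 3' + discriminator
  db <- paste0(
    "(((((((", "..",
    "((((", ".......", "))))", ".",
    "(((((", ".......", ")))))",
    "....",
    "(((((", ".......", ")))))",
    ")))))))", ".")
  list(seq = seq, db = db)
}

test_that("a canonical four-helix structure partitions into the four arms", {
  ct <- canon_trna()
  cl <- partition_cloverleaf(ct$seq, ct$db, name = "tRNA-Phe", strand = "H")
  expect_true(cl$dhu_present)
  expect_equal(vapply(cl$stems, nrow, integer(1)),
               c(AA = 7L, DHU = 4L, AC = 5L, TPsiU = 5L))
  expect_equal(lengths(cl$loops),
               c(DHU = 7L, AC = 7L, variable = 4L, TPsiU = 7L))
  ## anticodon sits at the centre of the AC loop
  ac_loop <- cl$loops$AC
  expect_true(all(diff(ac_loop) == 1))
  ## stems + loops + spacers partition all positions exactly once
  stem_pos <- unlist(lapply(cl$stems, function(h) c(h[, 1], h[, 2])))
  loop_pos <- unlist(cl$loops)
  expect_equal(anyDuplicated(c(stem_pos, loop_pos)), 0L)
  ## total pairs recorded equals the stem pair sum
  expect_equal(nrow(cl$pairs), sum(vapply(cl$stems, nrow, integer(1))))
})

test_that("three-helix structures lose the DHU arm, not the others", {
  ct <- canon_trna()
  ## remove the DHU helix brackets -> Ser(GCT)-like structure
  db3 <- sub("\\(\\(\\(\\(\\.\\.\\.\\.\\.\\.\\.\\)\\)\\)\\)", "...............",
             ct$db)
  cl <- partition_cloverleaf(ct$seq, db3, name = "tRNA-Ser(GCT)", strand = "H")
  expect_false(cl$dhu_present)
  expect_null(cl$stems$DHU)
  expect_equal(nrow(cl$stems$AC), 5L)
  expect_equal(nrow(cl$stems$TPsiU), 5L)
})

test_that("non-cloverleaf structures are rejected", {
  expect_error(partition_cloverleaf("AAAGGG", "((..))"), "not a cloverleaf")
  expect_error(partition_cloverleaf("AAAGGG", "((..)."), "unbalanced")
  expect_error(partition_cloverleaf("AAAGGG", "([..])"), "pseudoknot|allowed")
  expect_error(partition_cloverleaf("AAAG", "((..))"), "lengths differ")
})

test_that("pair classification distinguishes WC, wobble and named mismatches", {
  expect_equal(classify_pair("G", "C")$category, "watson_crick")
  expect_equal(classify_pair("A", "U")$category, "watson_crick")
  expect_equal(classify_pair("G", "U")$category, "wobble_GU")
  ac <- classify_pair("A", "C")
  expect_equal(ac$category, "mismatch")
  expect_equal(ac$mismatch_label, "A-C")
  expect_error(classify_pair("A", "X"), "bases")
  ## symmetry over all base pairs
  for (b1 in c("A", "C", "G", "T")) {
    for (b2 in c("A", "C", "G", "T")) {
      expect_identical(classify_pair(b1, b2), classify_pair(b2, b1))
    }
  }
})

test_that("canonical site labels cover 25 sites and anchor correctly", {
  sm <- canonical_site_map()
  expect_equal(sum(lengths(sm)), 25L)
  expect_true(all(c("1-87", "2-86", "8-80") %in% sm$AA))
  expect_true("12-32" %in% sm$DHU)
  expect_true("40-48" %in% sm$AC)
  expect_true("64-74" %in% sm$TPsiU)
})

test_that("site frequencies tally single structures and mixtures exactly", {
  ct <- canon_trna()
  cl <- partition_cloverleaf(ct$seq, ct$db, name = "x", strand = "H")
  sf1 <- site_frequencies(list(cl))
  present <- sf1[sf1$n > 0, ]
  expect_equal(nrow(present), 21L)  # 7 + 4 + 5 + 5 pairs
  ## single structure: every present site 100% in exactly one category
  cat_sum <- present$pct_wc + present$pct_wobble + present$pct_mismatch
  expect_equal(cat_sum, rep(100, nrow(present)))
  expect_true(all(pmax(present$pct_wc, present$pct_wobble,
                       present$pct_mismatch) == 100))

  ## two structures differing at one site -> 50/50 there
  seq2 <- ct$seq
  ## make pair 1 of the AA stem G-U instead of G-C (partner of position 1
  ## is the last AA-stem base, position 70)
  substr(seq2, 70, 70) <- "U"
  cl2 <- partition_cloverleaf(seq2, ct$db, name = "x", strand = "H")
  sf2 <- site_frequencies(list(cl, cl2))
  row <- sf2[sf2$site == "1-87", ]
  expect_equal(row$n, 2L)
  expect_equal(row$pct_wc, 50)
  expect_equal(row$pct_wobble, 50)
  expect_equal(row$pct_bonded, 100)
})

test_that("wobble tallies reproduce the generator's planted counts exactly", {
  spec <- generator_spec(seed = 91, n_species = 2)
  ts <- generate_trna_set(spec)
  ws <- wobble_table(ts$structs)
  truth <- ts$truth
  agg <- aggregate(truth[c("wobble_AA", "wobble_DHU", "wobble_AC",
                           "wobble_TPsiU", "total_pairs")],
                   by = truth[c("trna", "strand")], FUN = sum)
  m <- merge(ws$table, agg, by.x = c("trna", "strand"),
             by.y = c("trna", "strand"), suffixes = c("", ".truth"))
  expect_equal(nrow(m), 22L)
  for (col in c("wobble_AA", "wobble_DHU", "wobble_AC", "wobble_TPsiU")) {
    expect_equal(m[[col]], m[[paste0(col, ".truth")]])
  }
  expect_equal(m$total_pairs, m$total_pairs.truth)
  ## totals additive across stems
  expect_equal(ws$table$total_wobble,
               ws$table$wobble_AA + ws$table$wobble_DHU +
                 ws$table$wobble_AC + ws$table$wobble_TPsiU)
})

test_that("zero wobble probability yields an all-zero wobble table", {
  ts <- generate_trna_set(generator_spec(seed = 92, wobble_p = c(H = 0, L = 0)))
  ws <- wobble_table(ts$structs)
  expect_true(all(ws$table$total_wobble == 0))
  expect_equal(ws$grand_pct, 0)
})

test_that("the strand comparison matches a brute-force rank-sum count", {
  tab <- data.frame(
    trna = paste0("t", 1:8),
    strand = rep(c("H", "L"), each = 4),
    pct = c(1.0, 2.0, 0.0, 3.0, 8.0, 12.0, 9.0, 15.0))
  sc <- strand_comparison(tab)
  expect_equal(sc$U, oracle_rank_sum_U(tab$pct[1:4], tab$pct[5:8]))
  expect_lt(sc$p_value, 0.05)

  ## identical groups: U at its midpoint, p near 1
  tab2 <- data.frame(trna = paste0("t", 1:8),
                     strand = rep(c("H", "L"), each = 4),
                     pct = rep(c(2, 4, 6, 8), 2))
  sc2 <- strand_comparison(tab2)
  expect_equal(sc2$U, 8)  # n1*n2/2
  expect_gt(sc2$p_value, 0.8)

  expect_error(strand_comparison(data.frame(trna = "a", strand = "H", pct = 1)),
               "both H and L")
})

test_that("the mTERF tridecamer is located with bounded mismatches", {
  hit <- mterf_site_check("AACGTGGCAGAGCCCGGTTACG")
  expect_true(hit$hit)
  expect_equal(hit$start, 5L)
  expect_equal(hit$n_mismatches, 0L)

  mut <- "AACGTGGCAGTGCCCGGTTACG"  # one substitution inside the motif
  expect_false(mterf_site_check(mut)$hit)
  hit1 <- mterf_site_check(mut, max_mismatch = 1L)
  expect_true(hit1$hit)
  expect_equal(hit1$n_mismatches, 1L)

  set.seed(93)
  rnd <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  expect_false(mterf_site_check(rnd)$hit)
})
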