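test_that("motif scanning finds verbatim, edited and absent motifs", {
  lib <- default_motif_library()
  csbd <- lib$sequence[lib$name == "CSB-D"]
  set.seed(111)
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                                    prob = c(.33, .2, .16, .31)), collapse = "")
  region <- paste0(flank(50), csbd, flank(50))
  hit <- scan_motif(region, csbd, 9, 2)
  expect_equal(hit$start, 51L)
  expect_equal(hit$end, 50L + nchar(csbd))
  expect_equal(hit$n_substitutions, 0L)
  expect_equal(hit$mask, strrep("*", nchar(csbd)))

  ## plant exactly 2 substitutions
  mut <- csbd
  substr(mut, 5, 5) <- "A"    # T -> A
  substr(mut, 12, 12) <- "T"  # C -> T
  region2 <- paste0(flank(40), mut, flank(40))
  hit2 <- scan_motif(region2, csbd, 3, 2)
  expect_equal(hit2$start, 41L)
  expect_equal(hit2$n_substitutions, 2L)
  expect_equal(hit2$n_insertions + hit2$n_deletions, 0L)
  ## the mask carries exactly 2 uppercase query bases
  expect_equal(nchar(gsub("[^ACGT]", "", hit2$mask)), 2L)

  ## absent motif under tight bounds
  expect_null(scan_motif(flank(120), csbd, 1, 0))
  expect_error(scan_motif(region, ""), "non-empty")
})

test_that("zero-budget scanning is exact substring search", {
  set.seed(112)
  for (rep in 1:20) {
    region <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                    collapse = "")
    motif <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                   collapse = "")
    want <- oracle_substring_search(region, motif)
    got <- scan_motif(region, motif, 0, 0)
    if (is.na(want)) {
      expect_null(got)
    } else {
      expect_equal(got$start, want)
      expect_equal(got$edit_distance, 0L)
    }
  }
})

test_that("divergence masks serialize substitutions, insertions and deletions", {
  ref <- "TATTATAATATTTCACAT"
  expect_equal(as.character(divergence_mask(ref, ref)), strrep("*", 18))

  ## the single C substitution at reference position 7
  qry <- "TATTATCATATTTCACAT"
  m <- divergence_mask(ref, qry)
  expect_equal(as.character(m), "******C***********")
  expect_equal(attr(m, "n_sub"), 1L)

  ## one inserted base -> exactly one lowercase letter
  qry_ins <- "TATTATAGATATTTCACAT"
  mi <- divergence_mask(ref, qry_ins)
  expect_equal(attr(mi, "n_ins"), 1L)
  expect_equal(nchar(gsub("[^acgt]", "", as.character(mi))), 1L)

  ## one deleted base -> exactly one dash
  qry_del <- "TATTATATATTTCACAT"
  md <- divergence_mask(ref, qry_del)
  expect_equal(attr(md, "n_del"), 1L)
  expect_equal(lengths(regmatches(as.character(md),
                                  gregexpr("-", as.character(md)))), 1L)
})

test_that("applying a mask to the reference reconstructs the query", {
  set.seed(113)
  for (rep in 1:15) {
    ref <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
                 collapse = "")
    qry <- ref
    ## random edits: substitutions plus maybe an indel
    b <- strsplit(qry, "")[[1]]
    for (k in 1:3) {
      i <- sample(length(b), 1)
      b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
    }
    if (rep %% 3 == 0) b <- b[-sample(length(b), 1)]
    if (rep %% 3 == 1) {
      b <- append(b, sample(c("A", "C", "G", "T"), 1),
                  after = sample(length(b), 1))
    }
    qry <- paste(b, collapse = "")
    m <- divergence_mask(ref, qry)
    expect_identical(apply_divergence_mask(ref, m), qry)
  }
})

test_that("control-region annotation recovers all planted features in order", {
  spec <- generator_spec(seed = 121)
  crg <- generate_control_region(spec)
  ann <- annotate_control_region(crg$region, spec$motif_lib)
  expect_true(ann$order_ok)
  for (nm in names(crg$truth$motifs)) {
    h <- ann$hits[[nm]]
    tr <- crg$truth$motifs[[nm]]
    expect_false(is.null(h))
    expect_equal(h$start, tr$start)
    expect_equal(h$n_substitutions, tr$n_sub)
    expect_equal(h$n_insertions + h$n_deletions, tr$n_ins + tr$n_del)
  }
  ## GTGGG box detected inside the (unmutated) CSB-E hit
  expect_false(is.null(ann$gtggg_box))
  ## planted palindromes are among the reported exact occurrences
  for (i in seq_len(nrow(crg$truth$palindromes))) {
    p <- crg$truth$palindromes[i, ]
    expect_true(any(ann$palindromes$motif == p$motif &
                      ann$palindromes$start == p$start))
  }
  ## the planted T run is reported and flagged between CSB-D and CSB-1
  tr <- crg$truth$t_run
  row <- ann$homopolymers[ann$homopolymers$start == tr$start, ]
  expect_equal(row$length, tr$length)
  expect_true(row$between_csbD_csb1)
})

test_that("edited planted motifs are recovered with their exact edit counts", {
  spec <- generator_spec(seed = 122, motif_edits = list(
    "CSB-E" = c(3L, 0L), "CSB-1" = c(2L, 1L), "CSB-D" = c(5L, 0L)))
  crg <- generate_control_region(spec)
  ann <- annotate_control_region(crg$region, spec$motif_lib)
  e <- ann$hits[["CSB-E"]]
  expect_equal(e$n_substitutions, 3L)
  d <- ann$hits[["CSB-D"]]
  expect_equal(d$n_substitutions, 5L)
  one <- ann$hits[["CSB-1"]]
  expect_equal(one$n_substitutions, 2L)
  expect_equal(one$n_insertions + one$n_deletions, 1L)
})

test_that("T-homopolymer runs are measured exactly", {
  runs <- find_t_homopolymers("CCTTTTTTTAA")
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$length, 7L)
  expect_equal(runs$start, 3L)
  expect_equal(nrow(find_t_homopolymers("ACGTACGT")), 0L)
})

test_that("the tandem-repeat scan stays silent on random sequence but finds planted repeats", {
  set.seed(123)
  for (rep in 1:5) {
    rnd <- paste(sample(c("A", "C", "G", "T"), 840, replace = TRUE,
                        prob = c(.33, .2, .16, .31)), collapse = "")
    expect_equal(nrow(find_tandem_repeats(rnd)), 0L)
  }
  planted <- paste0(strrep("ACGT", 10), strrep("TTAGG", 4), strrep("ACGT", 10))
  tr <- find_tandem_repeats(planted)
  expect_true(any(tr$unit == "TTAGG" & tr$copies == 4))
  ## a pure T homopolymer is not a tandem repeat
  expect_equal(nrow(find_tandem_repeats(strrep("T", 30))), 0L)
})

test_that("palindrome partners are recognized by reverse complement", {
  expect_true(palindrome_check("TACAT", "ATGTA"))
  expect_true(palindrome_check("AAAA", "TTTT"))
  expect_false(palindrome_check("AAAA", "AAAA"))
  expect_true(palindrome_check("GAATTC"))  # EcoRI-style true palindrome
})
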