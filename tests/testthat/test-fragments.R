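test_that("count_pairs counts A-T and G-C pairs and rejects bad input", {
  expect_equal(count_pairs("ATGC"), c(n_at = 2L, n_gc = 2L))
  expect_equal(count_pairs("AAAA"), c(n_at = 4L, n_gc = 0L))
  expect_equal(count_pairs("atgc"), c(n_at = 2L, n_gc = 2L))
  hundred <- paste0(strrep("AT", 25), strrep("GC", 25))
  expect_equal(count_pairs(hundred), c(n_at = 50L, n_gc = 50L))
  expect_error(count_pairs(""), "non-empty")
  expect_error(count_pairs("ACGY"), "position 4")
  expect_error(count_pairs("ACGN"), "non-ACGT")
})

test_that("count_pairs is strand-invariant", {
  set.seed(42)
  for (len in c(5, 20, 137)) {
    s <- random_dna(len)
    expect_identical(count_pairs(s), count_pairs(reverse_complement(s)))
  }
})

test_that("molecular weight matches per-pair defaults and is additive", {
  expect_equal(molecular_weight(1, 0), 617.4)
  expect_equal(molecular_weight(0, 1), 618.4)
  expect_equal(molecular_weight(50, 50), 61790.0)
  expect_error(molecular_weight(0, 0), "zero-length")
  # additivity with a non-zero end correction: joining two fragments drops
  # one end term
  k <- mass_constants(end_correction = 36.04)
  expect_equal(molecular_weight(3, 4, k) + molecular_weight(2, 1, k) -
                 k$end_correction,
               molecular_weight(5, 5, k))
})

test_that("pair-count molecular weight equals the nucleotide-by-nucleotide sum", {
  set.seed(7)
  k <- mass_constants(end_correction = 36.04)
  for (i in 1:50) {
    s <- random_dna(sample(5:300, 1))
    p <- count_pairs(s)
    expect_equal(molecular_weight(p[["n_at"]], p[["n_gc"]], k),
                 brute_force_mw(s, k), tolerance = 1e-12)
  }
})

test_that("copies_per_ul applies q * 1e-9 * N_A / MW and its invariants", {
  expect_equal(copies_per_ul(1.0, 6.02214076e14), 1.0)
  expect_equal(copies_per_ul(0, 1234), 0)
  expect_equal(copies_per_ul(10, 61790), 9.746e10, tolerance = 1e-4)
  # strictly monotone: increasing in q, decreasing in mw
  expect_gt(copies_per_ul(10.1, 61790), copies_per_ul(10, 61790))
  expect_lt(copies_per_ul(10, 61791), copies_per_ul(10, 61790))
  expect_error(copies_per_ul(1, 0), "> 0")
  expect_error(copies_per_ul(-1, 100), ">= 0")
})

test_that("mass of N copies converts back to N copies per uL", {
  k <- mass_constants()
  set.seed(11)
  for (i in 1:20) {
    s <- random_dna(sample(50:500, 1))
    p <- count_pairs(s)
    mw <- molecular_weight(p[["n_at"]], p[["n_gc"]], k)
    n_copies <- 10^runif(1, 2, 12)
    q_ng_ul <- n_copies * mw / k$avogadro * 1e9
    expect_equal(copies_per_ul(q_ng_ul, mw, k), n_copies, tolerance = 1e-9)
  }
})

test_that("concentration measurements average replicates and flag scatter", {
  m <- concentration_measurement("f", c(9.8, 10.0, 10.2))
  expect_equal(m$q_mean, 10.0)
  expect_equal(concentration_measurement("f", c(5, NA, NA))$q_mean, 5)
  expect_error(concentration_measurement("f", c(NA_real_)), "replicate")
  expect_error(concentration_measurement("f", c(-1, 2)), ">= 0")
  expect_warning(concentration_measurement("f", c(1, 2, 3)), "CV")
})

test_that("quantify_stock chains composition, mass and copy number", {
  st <- quantify_stock("f1", strrep("ATGC", 25), c(9.8, 10.0, 10.2))
  expect_equal(st$q_mean, 10.0)
  expect_equal(st$length_bp, 100L)
  expect_equal(st$molecular_weight, 61790.0)
  expect_equal(st$copies_per_ul, 9.746e10, tolerance = 1e-4)
  # linearity in q
  half <- quantify_stock("f1", strrep("ATGC", 25), 5.0)
  expect_equal(half$copies_per_ul, st$copies_per_ul / 2)
  zero <- quantify_stock("f1", strrep("ATGC", 25), c(0, 0, 0))
  expect_equal(zero$copies_per_ul, 0)
  expect_error(
    quantify_stock("f1", "ATGC", concentration_measurement("other", 1)),
    "for fragment 'other'")
})

test_that("quantify_stocks joins FASTA sequences to the measurement table", {
  seqs <- c(f1 = strrep("ATGC", 25), f2 = strrep("AT", 30))
  meas <- data.frame(fragment_id = c("f1", "f2"),
                     rep1 = c(9.8, 4), rep2 = c(10.0, 4), rep3 = c(10.2, 4))
  out <- quantify_stocks(seqs, meas)
  expect_equal(nrow(out), 2L)
  expect_equal(out$mw_g_per_mol, c(61790.0, 60 * 617.4))
  expect_equal(out$copies_per_ul[1], 9.746e10, tolerance = 1e-4)
  expect_error(quantify_stocks(seqs["f1"], meas), "f2")
})
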