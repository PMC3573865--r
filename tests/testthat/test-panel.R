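test_that("parse_panel reads the bundled panel and enforces the schema", {
  pan <- example_panel()
  expect_s3_class(pan, "primer_panel")
  expect_equal(sum(pan$in_multiplex), 7L)
  expect_equal(sum(!pan$in_multiplex), 1L)
  expect_equal(range(pan$size_bp[pan$in_multiplex]), c(86, 228))

  expect_error(parse_panel(tempfile()), "not found")

  # duplicated multiplex target -> schema error
  dup <- as.data.frame(pan)
  dup <- rbind(dup, dup[7, ])
  expect_error(primer_panel(dup), "duplicate multiplex target")

  # malformed sequence names its row
  bad <- as.data.frame(pan)
  bad$fwd_seq[3] <- "ACGTX"
  expect_error(primer_panel(bad), "row 3")

  # empty file
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("target\tfwd_name\tfwd_seq\trev_name\trev_seq\tconc_uM\tsize_bp\tin_multiplex", f)
  expect_error(parse_panel(f), "empty")
})

test_that("spacing_check applies the platform resolution to adjacent sizes", {
  pan <- example_panel(platform = "capillary")
  sp <- spacing_check(pan)
  expect_equal(sp$gap, c(21, 22, 15, 23, 31, 30))
  expect_equal(sp$pass, c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(sp$target_small[!sp$pass], "Oreonebria castanea")

  mk <- function(sizes, platform) {
    n <- length(sizes)
    primer_panel(data.frame(
      target = paste0("t", seq_len(n)), fwd_name = paste0("f", seq_len(n)),
      fwd_seq = "ACGTACGTAC", rev_name = paste0("r", seq_len(n)),
      rev_seq = "ACGTACGTAC", conc_uM = 0.2, size_bp = sizes,
      in_multiplex = TRUE), platform = platform)
  }
  ag <- spacing_check(mk(c(100, 150), "agarose"))
  expect_true(ag$pass)
  expect_equal(ag$min_gap, 30)
  # above 300 bp the agarose rule scales with fragment size
  ag2 <- spacing_check(mk(c(400, 430), "agarose"))
  expect_equal(ag2$min_gap, 40)
  expect_false(ag2$pass)
  # single product: vacuous pass
  expect_equal(nrow(spacing_check(mk(100, "capillary"))), 0L)
  # permutation invariance: findings depend only on the sorted size multiset
  a <- spacing_check(mk(c(86, 228, 144, 107, 198, 129, 167), "capillary"))
  expect_equal(a$gap, sp$gap)
})

test_that("degraded-DNA rule fails products of 300 bp and over, when active", {
  pan <- example_panel(degraded_dna_mode = TRUE)
  chk <- degraded_dna_check(pan)
  expect_equal(nrow(chk), 7L)
  expect_true(all(chk$pass))  # all bundled products < 300 bp

  long <- as.data.frame(pan)
  long$size_bp[7] <- 300
  chk2 <- degraded_dna_check(primer_panel(long, degraded_dna_mode = TRUE))
  expect_false(chk2$pass[chk2$size_bp == 300])  # boundary: "less than 300"

  expect_equal(nrow(degraded_dna_check(example_panel())), 0L)  # mode off
})

test_that("panel_qc aggregates the checks into one verdict", {
  rep <- panel_qc(example_panel(), tm_tolerance = 20,
                  dimer_score_threshold = 25, dimer_anchored_threshold = 25)
  expect_s3_class(rep, "qc_report")
  # the 129/144 capillary gap fails regardless of generous other thresholds
  expect_false(rep$overall_pass)
  expect_output(print(rep), "Overall: FAIL")
})

test_that("predict_amplicon finds degeneracy-compatible products", {
  fwd <- "ACGTACGTAC"
  rev <- "TTGCATTGCA"
  tmpl <- paste0(fwd, strrep("A", 50), reverse_complement(rev))
  hits <- predict_amplicon(tmpl, c(fwd, rev))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 0L)
  expect_equal(hits$length_bp, nchar(fwd) + 50L + nchar(rev))
  expect_equal(hits$end, nchar(tmpl))

  # Y in the primer matches C in the template
  fwd_y <- sub("C", "Y", fwd)
  expect_equal(nrow(predict_amplicon(tmpl, c(fwd_y, rev))), 1L)
  # no reverse site -> empty, not an error
  expect_equal(nrow(predict_amplicon(paste0(fwd, strrep("A", 50)),
                                     c(fwd, rev))), 0L)
  # max product length filter
  expect_equal(nrow(predict_amplicon(tmpl, c(fwd, rev),
                                     max_product_len = 50)), 0L)
})

test_that("templates built from a pair's own footprints round-trip", {
  pan <- example_panel()
  set.seed(13)
  for (i in seq_len(nrow(pan))) {
    tmpl <- plexcal:::synthetic_template(pan$fwd_seq[i], pan$rev_seq[i],
                                         pan$size_bp[i])
    hits <- predict_amplicon(tmpl, pan[i, ])
    expect_equal(nrow(hits), 1L, info = pan$target[i])
    expect_equal(hits$length_bp, pan$size_bp[i], info = pan$target[i])
  }
})
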