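mk_grid <- function(grid_def, target = "t1", condition = "single_target") {
  # grid_def: named list level -> vector of rfu values (one per replicate)
  do.call(rbind, lapply(names(grid_def), function(lv) {
    data.frame(target = target, copies = as.numeric(lv),
               condition = condition,
               replicate = seq_along(grid_def[[lv]]), rfu = grid_def[[lv]])
  }))
}

test_that("detection is an inclusive threshold on RFU", {
  expect_true(is_detected(0.1))
  expect_false(is_detected(0.099))
  expect_false(is_detected(0))
  expect_equal(is_detected(c(0.05, 0.5), threshold = 0.2), c(FALSE, TRUE))
  expect_error(is_detected(-0.1), ">= 0")
})

test_that("LOD is the lowest stable level; partial levels become unstable", {
  g <- mk_grid(list(`7` = c(0.3, 0.2, 0.05), `20` = c(0.5, 0.4, 0.3),
                    `100` = c(1.2, 0.9, 1.0)))
  r <- lod_from_grid(g, "t1", "single_target")
  expect_equal(r$lod_copies, 20)
  expect_equal(r$unstable_range, 7)

  # all levels fully detected: LOD is the smallest tested level
  g2 <- mk_grid(list(`5` = c(0.2, 0.3), `50` = c(0.5, 0.6)))
  expect_equal(lod_from_grid(g2, "t1", "single_target")$lod_copies, 5)

  # no level fully detected: LOD undefined, partial levels reported
  g3 <- mk_grid(list(`5` = c(0.05, 0.3), `50` = c(0.5, 0.06)))
  r3 <- lod_from_grid(g3, "t1", "single_target")
  expect_true(is.na(r3$lod_copies))
  expect_equal(r3$unstable_range, c(5, 50))

  # a failure above a clean level leaves the LOD at the stable suffix only
  g4 <- mk_grid(list(`10` = c(0.3, 0.3), `20` = c(0.05, 0.3),
                     `100` = c(0.5, 0.5)))
  r4 <- lod_from_grid(g4, "t1", "single_target")
  expect_equal(r4$lod_copies, 100)
  expect_equal(r4$unstable_range, 20)

  expect_error(lod_from_grid(g, "nope", "single_target"), "no readings")
  expect_error(check_readings_fail <- lod_from_grid(
    transform(g, condition = "weird"), "t1", "weird"), "condition")
})

test_that("LOD is monotone under added evidence", {
  g <- mk_grid(list(`7` = c(0.3, 0.2, 0.05), `20` = c(0.5, 0.4, 0.3),
                    `100` = c(1.2, 0.9, 1.0)))
  base_lod <- lod_from_grid(g, "t1", "single_target")$lod_copies
  # a detected replicate below the LOD never raises it
  plus_low <- rbind(g, data.frame(target = "t1", copies = 7,
                                  condition = "single_target",
                                  replicate = 4, rfu = 0.4))
  expect_lte(lod_from_grid(plus_low, "t1", "single_target")$lod_copies,
             base_lod)
  # a failed replicate at/above the LOD never lowers it
  plus_fail <- rbind(g, data.frame(target = "t1", copies = 20,
                                   condition = "single_target",
                                   replicate = 4, rfu = 0.01))
  new_lod <- lod_from_grid(plus_fail, "t1", "single_target")$lod_copies
  expect_true(is.na(new_lod) || new_lod >= base_lod)
})

test_that("LOD depends only on the detected/not relation, not RFU magnitudes", {
  g <- mk_grid(list(`7` = c(0.3, 0.2, 0.05), `20` = c(0.5, 0.4, 0.3)))
  r1 <- lod_from_grid(g, "t1", "single_target")
  shuffled <- g[sample(nrow(g)), ]
  rescaled <- g
  rescaled$rfu <- ifelse(rescaled$rfu >= 0.1, rescaled$rfu * 7, rescaled$rfu)
  r2 <- lod_from_grid(shuffled, "t1", "single_target")
  r3 <- lod_from_grid(rescaled, "t1", "single_target")
  expect_equal(r1$lod_copies, r2$lod_copies)
  expect_equal(r1$lod_copies, r3$lod_copies)
  expect_equal(r1$unstable_range, r3$unstable_range)
})

test_that("signal summaries use the median and flag missing targets", {
  g <- rbind(
    mk_grid(list(`100` = c(0.4, 0.5, 0.6)), target = "a",
            condition = "target_mix"),
    mk_grid(list(`100` = c(0.7, 0.7, 0.7)), target = "b",
            condition = "target_mix"))
  s <- summarize_signals(g, 100, "target_mix")
  expect_equal(s$rfu[s$target == "a"], 0.5)
  expect_equal(s$rfu[s$target == "b"], 0.7)
  expect_equal(s$rfu_min[s$target == "a"], 0.4)
  expect_error(summarize_signals(g, 100, "target_mix",
                                 targets = c("a", "b", "c")), "c")
  expect_error(summarize_signals(g, 999, "target_mix"), "999")
})

test_that("the sensitivity grid is the full factorial layout", {
  g <- design_sensitivity_grid(paste0("t", 1:7), c(100, 200, 1000, 2100),
                               replicates = 3)
  expect_equal(nrow(g), 7 * 4 * 4 * 3)  # 336
  expect_equal(nrow(design_sensitivity_grid("t1", 10,
                                            conditions = "single_target",
                                            replicates = 1)), 1L)
  m <- design_sensitivity_grid(example_panel(), c(10000, 2100, 1000, 200, 100))
  expect_setequal(unique(m$copies), c(10000, 2100, 1000, 200, 100))
  expect_equal(unique(m$background_ng[grepl("background", m$condition)]), 300)
  expect_equal(unique(m$background_ng[!grepl("background", m$condition)]), 0)
})
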