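test_that("enzyme ratio is the fill-in peak over the mean dATP/dTTP peak", {
  expect_equal(enzyme_ratio(rec(c(4, 10, 6, 1, 0, 1))), 2.0)
  expect_equal(enzyme_ratio(rec(c(1, 1, 1, 1, 0, 1))), 1.0)
  expect_equal(enzyme_ratio(rec(c(3, 7.5, 2, 1, 0, 1))), 3.0)
  expect_error(enzyme_ratio(rec(c(0, 5, 0, 1, 0, 1))), "s1")
})

test_that("LUMA methylation follows (1 - HpaII/MspI) x 100", {
  p <- luma_pair(0.5, 2.0)
  expect_equal(luma_methylation(p$h, p$m), 75.0)
  p <- luma_pair(1.3, 1.3)
  expect_equal(luma_methylation(p$h, p$m), 0.0)
  p <- luma_pair(0, 2.0)
  expect_equal(luma_methylation(p$h, p$m), 100.0)
  expect_error(luma_methylation(rec(c(1, 1, 1, 1, 0, 1), id = "a"),
                                rec(c(1, 1, 1, 1, 0, 1), id = "b")),
               "different samples")
})

test_that("LUMA methylation is invariant to rescaling one record's peaks", {
  p <- luma_pair(0.7, 2.4)
  base <- luma_methylation(p$h, p$m)
  scaled <- rec(unlist(p$h[paste0("peak", 1:6)]) * 3.7)
  expect_equal(luma_methylation(scaled, p$m), base, tolerance = 1e-12)
})

test_that("QC rules fire strictly and enumerate every violated rule", {
  ## informative peak 1.5 < 2 excludes a blood sample but not a cell sample
  h <- rec(c(1.5, 5, 10, 1, 0, 0.1)); m <- rec(c(10, 20, 10, 1, 0, 1))
  expect_false(luma_qc(h, m, "blood")$keep)
  expect_match(luma_qc(h, m, "blood")$reason, "< 2")
  expect_true(luma_qc(h, m, "cell")$keep)
  ## MspI/MfeI ratio 4.5 > 4.2
  m45 <- rec(c(10, 45, 10, 1, 0, 1))
  expect_false(luma_qc(rec(c(10, 5, 10, 1, 0, 1)), m45, "cell")$keep)
  ## dispensation-6 fraction of exactly 0.25 is retained ("more than" is strict)
  h25 <- rec(c(10, 5, 10, 1, 0, 2.5))
  expect_true(luma_qc(h25, rec(c(10, 20, 10, 1, 0, 1)), "cell")$keep)
  ## multiple rules are all reported
  bad <- luma_qc(rec(c(0.5, 5, 10, 1, 0, 5)), m45, "blood")
  expect_false(bad$keep)
  expect_match(bad$reason, "< 2")
  expect_match(bad$reason, "4.2")
  expect_match(bad$reason, "25%")
})

test_that("LINE-1 averaging: CpG sites, duplicates, then runs", {
  one <- data.frame(sample_id = "s", run_id = "r1",
                    cpg1 = 70, cpg2 = 72, cpg3 = 68, cpg4 = 74,
                    conversion_ok = TRUE)
  expect_equal(line1_methylation(one), 71.0)
  runs <- rbind(one, within(one, { run_id <- "r2"; cpg1 <- 72; cpg2 <- 74
                                   cpg3 <- 70; cpg4 <- 76 }))
  expect_equal(line1_methylation(runs), 72.0)
  dups <- rbind(one, within(one, { cpg1 <- 71; cpg2 <- 73; cpg3 <- 69
                                   cpg4 <- 75 }))
  expect_equal(line1_methylation(dups), 71.5)
  ## failed conversion reads are dropped; all-failed excludes the sample
  mixed <- rbind(one, within(one, { conversion_ok <- FALSE; cpg1 <- 0 }))
  expect_message(v <- line1_methylation(mixed), "conversion")
  expect_equal(v, 71.0)
  allbad <- within(one, conversion_ok <- FALSE)
  expect_error(suppressMessages(line1_methylation(allbad)), "excluded")
})

test_that("two-point calibration maps the controls to 0 and 100", {
  ctl <- list(low_pct = 3.37, high_pct = 75.08)
  expect_equal(as.numeric(calibrate_methylation(3.37, ctl)), 0)
  expect_equal(as.numeric(calibrate_methylation(75.08, ctl)), 100)
  expect_equal(as.numeric(calibrate_methylation(50, ctl)), 65.03,
               tolerance = 1e-4)
  ## out-of-range results are flagged, not clipped
  v <- calibrate_methylation(80, ctl)
  expect_gt(as.numeric(v), 100)
  expect_true(attr(v, "out_of_range"))
  expect_error(calibrate_methylation(50, list(low_pct = 5, high_pct = 5)),
               "controls")
})

test_that("interassay CV is the mean of per-pair CVs", {
  expect_equal(interassay_cv(cbind(c(10, 20), c(10, 20))), 0)
  expect_equal(interassay_cv(cbind(99, 101)), 100 * sqrt(2) / 100,
               tolerance = 1e-10)
  expect_equal(interassay_cv(rbind(c(10, 10), c(99, 101))),
               mean(c(0, sqrt(2))), tolerance = 1e-10)
  expect_warning(interassay_cv(rbind(c(-1, 1), c(2, 2))), "zero-mean")
})
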