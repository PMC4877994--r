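test_that("default configuration reproduces the study's group sizes", {
  s <- default_sheet(1)
  expect_equal(nrow(s), 238)
  expect_equal(as.vector(table(s$subset)[c("MCF7", "SHSY5Y", "blood")]),
               c(73, 34, 131))
  ## every sample carries both assay values and a treatment label
  expect_false(anyNA(s$line1_pct))
  expect_false(anyNA(s$luma_pct))
  expect_true(all(nzchar(s$treatment)))
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_samples(synth_config(seed = 99))
  b <- generate_samples(synth_config(seed = 99))
  expect_identical(a, b)
  c <- generate_samples(synth_config(seed = 100))
  expect_false(identical(a$line1_pct, c$line1_pct))
})

test_that("independent preset yields near-zero rank correlation", {
  p <- subset_preset("null", 1e4, 50, 5, 50, 5, rho_spearman = 0)
  z <- generate_samples(synth_config(presets = list(null = p),
                                     plans = list(), seed = 3))
  expect_lt(abs(cor(z$line1_pct, z$luma_pct, method = "spearman")), 0.03)
})

test_that("large draws are calibrated to the preset marginals", {
  for (nm in c("MCF7", "blood")) {
    p0 <- default_presets()[[nm]]
    p <- subset_preset(nm, 2e4, p0$mean_line1, p0$sd_line1, p0$mean_luma,
                       p0$sd_luma, p0$rho_spearman)
    z <- generate_samples(synth_config(presets = stats::setNames(list(p), nm),
                                       plans = list(), seed = 11,
                                       clamp = FALSE))
    se <- p0$sd_line1 / sqrt(2e4)
    expect_lt(abs(mean(z$line1_pct) - p0$mean_line1), 3 * se)
    expect_lt(abs(mean(z$luma_pct) - p0$mean_luma),
              3 * p0$sd_luma / sqrt(2e4))
    expect_lt(abs(sd(z$line1_pct) - p0$sd_line1), 3 * se)
    expect_lt(abs(cor(z$line1_pct, z$luma_pct, method = "spearman") -
                    p0$rho_spearman), 0.05)
  }
})

test_that("treatment plans preserve subset totals while separating conditions", {
  s <- default_sheet(1)
  m <- s[s$subset == "MCF7", ]
  p <- default_presets()$MCF7
  ## pooled marginals stay near the preset values (within sampling noise)
  expect_lt(abs(mean(m$line1_pct) - p$mean_line1), 4 * p$sd_line1 / sqrt(73))
  ## the demethylating agent lowers methylation relative to control
  aza <- m$line1_pct[m$treatment == "5-Aza-CdR"]
  ctl <- m$line1_pct[m$treatment %in% c("untreated", "DMSO")]
  expect_lt(mean(aza), mean(ctl))
})

test_that("impossible shift/correlation structure errors with the preset name", {
  p <- subset_preset("tiny", 10, 50, 2, 50, 2, 0.5,
                     sd_diff = 0.1)
  plan <- treatment_plan("tiny", c("a", "b"), c(5, 5),
                         effect_line1 = c(-30, 30))
  expect_error(generate_samples(synth_config(presets = list(tiny = p),
                                             plans = list(tiny = plan),
                                             seed = 1)),
               "tiny")
})

test_that("pyrogram round trip recovers both assay targets exactly", {
  cfg <- synth_config(seed = 4)
  s <- generate_samples(cfg)
  idx <- sample(seq_len(nrow(s)), 100)
  sub <- s[idx, ]
  py <- generate_pyrograms(sub, cfg)
  sheet <- quantify_pyrograms(py$pyrograms, py$line1_reads, py$controls)
  expect_false(any(sheet$qc_excluded))
  m <- match(sub$sample_id, sheet$sample_id)
  expect_lt(max(abs(sheet$luma_pct[m] - sub$luma_pct)), 1e-6)
  expect_lt(max(abs(sheet$line1_pct[m] - sub$line1_pct)), 1e-6)
})

test_that("QC violations are injected and caught at the configured rate", {
  cfg <- synth_config(seed = 8)
  s <- generate_samples(cfg)[1:60, ]
  py0 <- generate_pyrograms(s, cfg, qc_violation_frac = 0)
  sh0 <- quantify_pyrograms(py0$pyrograms, py0$line1_reads, py0$controls)
  expect_equal(sum(sh0$qc_excluded), 0)
  py <- generate_pyrograms(s, cfg, qc_violation_frac = 0.1)
  sh <- quantify_pyrograms(py$pyrograms, py$line1_reads, py$controls)
  expect_gt(sum(sh$qc_excluded), 0)
  expect_true(all(nzchar(sh$qc_reason[sh$qc_excluded])))
})

test_that("targets outside the percentage scale are rejected", {
  s <- sheet(c(50, 101), c(50, 50))
  expect_error(generate_pyrograms(s, synth_config(seed = 1)),
               "outside")
})
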