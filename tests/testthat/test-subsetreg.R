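test_that("an exact linear relation is recovered with zero residuals", {
  x <- c(10, 20, 30, 40, 15, 25, 35)
  z <- sheet(2 * x + 1, x, "A")
  f <- subset_lm(z)
  expect_equal(f$theta1, 1, tolerance = 1e-10)
  expect_equal(f$theta2, 2, tolerance = 1e-10)
  expect_lt(max(abs(residuals(f))), 1e-10)
})

test_that("the all-free specification equals per-subset OLS closed forms", {
  set.seed(131)
  z <- rbind(sheet(rnorm(30, 60, 8), rnorm(30, 55, 7), "A"),
             sheet(rnorm(25, 80, 5), rnorm(25, 70, 6), "B"),
             sheet(rnorm(40, 40, 9), rnorm(40, 45, 8), "C"))
  spec <- subset_spec(c("A", "B", "C"), free_int = rep(TRUE, 3),
                      free_slope = rep(TRUE, 3))
  f <- subset_lm(z, spec)
  for (s in c("A", "B", "C")) {
    zi <- z[z$subset == s, ]
    ols <- coef(lm(line1_pct ~ luma_pct, zi))
    i <- match(s, f$effective$subset)
    expect_equal(f$effective$intercept[i], unname(ols[1]), tolerance = 1e-8)
    expect_equal(f$effective$slope[i], unname(ols[2]), tolerance = 1e-8)
  }
  ## ML sigma2 is RSS/n and -2LL follows from it
  expect_equal(f$minus2LL, f$n * log(2 * pi * f$sigma2) + f$n,
               tolerance = 1e-10)
  ## the redundant decomposition errors when normalisation is refused
  expect_error(subset_lm(z, spec, normalize = FALSE), "unidentifiable")
})

test_that("likelihood-ratio boundary conventions are strict", {
  fake <- function(m2ll, npar) structure(list(minus2LL = m2ll, npar = npar,
                                              n = 100), class = "subset_lm")
  expect_true(lrt_step(fake(95, 4), fake(100, 3))$keep)    # delta -5
  expect_false(lrt_step(fake(98, 4), fake(100, 3))$keep)   # delta -2
  expect_false(lrt_step(fake(96.16, 4), fake(100, 3))$keep) # delta -3.84 exactly
  expect_error(lrt_step(fake(95, 3), fake(100, 3)), "nested")
})

test_that("freeing parameters never increases -2LL (nesting property)", {
  s <- default_sheet(1)
  fit <- build_final_model(s)
  fwd <- fit$step_log[fit$step_log$phase == "forward" &
                        !is.na(fit$step_log$delta), ]
  expect_true(all(fwd$delta <= 1e-8))
})

test_that("data from a single global line rarely retains subset terms", {
  set.seed(141)
  spurious <- replicate(100, {
    x <- c(rnorm(25, 50, 10), rnorm(25, 60, 10), rnorm(25, 70, 10))
    z <- sheet(10 + 0.8 * x + rnorm(75, 0, 3), x)
    z$subset <- rep(c("A", "B", "C"), each = 25)
    fit <- build_final_model(z)
    any(fit$spec$int_group > 0) || any(fit$spec$slope_group > 0) ||
      fit$spec$int_base == "zero"
  })
  ## a subset modulator survives forward testing and backward pruning only
  ## through consecutive type-I errors, so the final-model rate stays low
  expect_lt(mean(spurious), 0.15)
})

test_that("model building recovers the generating structure", {
  ## structure: subset A on a zero intercept, B and C off it; A and B share
  ## a slope, C has its own
  set.seed(151)
  hits <- replicate(300, {
    xA <- rnorm(73, 68, 12); xB <- rnorm(34, 56, 12); xC <- rnorm(131, 72, 3)
    z <- rbind(sheet(0 + 1.02 * xA + rnorm(73, 0, 2), xA, "A"),
               sheet(9 + 1.02 * xB + rnorm(34, 0, 2), xB, "B"),
               sheet(71.1 + 0.33 * xC + rnorm(131, 0, 2), xC, "C"))
    fit <- build_final_model(z)
    sp <- fit$spec
    iA <- match("A", sp$subsets); iB <- match("B", sp$subsets)
    iC <- match("C", sp$subsets)
    ok_int <- sp$int_base == "zero" && sp$int_group[iA] == 0 &&
      sp$int_group[iB] > 0 && sp$int_group[iC] > 0 &&
      sp$int_group[iB] != sp$int_group[iC]
    sg <- sp$slope_group
    shared_cells <- (sg[iA] == sg[iB] && sg[iA] > 0) ||
      (sg[iA] == 0 && sg[iB] == 0)
    blood_own <- sg[iC] != sg[iA]
    ok_int && shared_cells && blood_own
  })
  expect_gte(mean(hits), 0.9)
})

test_that("bootstrap confidence intervals behave", {
  x <- c(10, 20, 30, 40, 50, 60)
  z <- rbind(sheet(5 + 2 * x, x, "A"), sheet(7 + 2 * x, x, "B"))
  spec <- subset_spec(c("A", "B"), free_int = c(FALSE, TRUE))
  ## zero noise: every resample refits the same exact line
  ci <- bootstrap_ci(z, spec, n_boot = 50, seed = 1)
  expect_equal(unname(ci$ci[, 1]), unname(ci$estimates), tolerance = 1e-8)
  expect_equal(unname(ci$ci[, 2]), unname(ci$estimates), tolerance = 1e-8)
  ## endpoints ordered, deterministic under seed
  set.seed(161)
  z2 <- rbind(sheet(5 + 2 * x + rnorm(6), x, "A"),
              sheet(7 + 2 * x + rnorm(6), x, "B"))
  c1 <- bootstrap_ci(z2, spec, n_boot = 200, seed = 9)
  c2 <- bootstrap_ci(z2, spec, n_boot = 200, seed = 9)
  expect_identical(c1, c2)
  expect_true(all(c1$ci[, 1] <= c1$ci[, 2] + 1e-12))
})

test_that("model methods: predict, simulate, logLik are consistent", {
  s <- default_sheet(1)
  fit <- build_final_model(s)
  expect_equal(predict(fit, s), unname(fitted(fit)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(as.numeric(logLik(fit)), -fit$minus2LL / 2)
  sim <- simulate(fit, nsim = 2, seed = 3)
  expect_equal(dim(sim), c(fit$n, 2))
  expect_lt(abs(sd(sim$sim_1 - fitted(fit)) - sqrt(fit$sigma2)), 0.5)
})
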