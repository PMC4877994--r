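test_that("Pareto density estimate approximates known densities", {
  set.seed(61)
  x <- rnorm(1e4)
  g <- pde(x)
  expect_lt(max(abs(g$density - dnorm(g$x))), 0.03)
  u <- runif(1e4)
  gu <- pde(u)
  mid <- gu$x > 0.1 & gu$x < 0.9
  expect_lt(max(abs(gu$density[mid] - 1)), 0.1)
  ## unit trapezoidal integral by construction
  integ <- sum((g$density[-1] + g$density[-length(g$density)]) / 2 * diff(g$x))
  expect_lt(abs(integ - 1), 1e-3)
  expect_error(pde(rep(3, 50)), "constant")
  expect_error(pde(1:5), "at least 10")
})

test_that("mixture fitting recovers known structures and is deterministic", {
  set.seed(71)
  x1 <- rnorm(2000, 5, 2)
  f1 <- fit_gmm(x1, seed = 1)
  expect_equal(f1$M, 1)
  expect_lt(abs(f1$means - 5), 0.15)
  expect_lt(abs(f1$sds - 2), 0.15)
  x2 <- c(rnorm(500, -10, 1), rnorm(500, 10, 1))
  f2 <- fit_gmm(x2, seed = 1)
  expect_equal(f2$M, 2)
  expect_lt(max(abs(f2$means - c(-10, 10))), 0.2)
  expect_identical(fit_gmm(x2, seed = 5)[c("w", "means", "sds")],
                   fit_gmm(x2, seed = 5)[c("w", "means", "sds")])
  expect_error(fit_gmm(rnorm(30), M_range = 1:5), "at least 10")
})

test_that("three-component recovery on a resolvable mixture", {
  ## layout resembling the observed interassay-difference pattern, with
  ## components separated enough to be identifiable
  set.seed(81)
  x <- c(rnorm(700, -13, 4), rnorm(500, 1, 4), rnorm(1180, 20, 3.3))
  f <- fit_gmm(x, M_range = 3, seed = 2)
  expect_lt(max(abs(f$means - c(-13, 1, 20))), 1)
  expect_equal(sum(f$w), 1, tolerance = 1e-9)
  expect_true(all(diff(f$means) > 0))
})

test_that("independent oracle agrees with the selected component count", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(91)
  x <- c(rnorm(400, -8, 2), rnorm(600, 8, 2))
  f <- fit_gmm(x, seed = 3)
  mc <- Mclust(x, G = 1:5, modelNames = "V", verbose = FALSE)
  expect_equal(f$M, mc$G)
  o <- order(mc$parameters$mean)
  expect_lt(max(abs(f$means - mc$parameters$mean[o])), 0.5)
})

test_that("Bayes boundaries sit where posteriors cross", {
  sym <- structure(list(w = c(0.5, 0.5), means = c(-1, 1), sds = c(1, 1)),
                   class = "gmm_fit")
  expect_equal(bayes_boundaries(sym), 0, tolerance = 1e-8)
  ## closed form with unequal weights: boundary at delta/2 + s^2 ln(w1/w2)/delta
  skewed <- structure(list(w = c(0.9, 0.1), means = c(0, 2), sds = c(1, 1)),
                      class = "gmm_fit")
  expect_warning(b <- bayes_boundaries(skewed), "changeover")
  expect_equal(b, 1 + log(9) / 2, tolerance = 1e-3)
  ## posterior at a boundary is 0.5/0.5 for the adjacent pair
  set.seed(101)
  x <- c(rnorm(300, -6, 2), rnorm(300, 6, 2))
  f <- fit_gmm(x, M_range = 2, seed = 1)
  post_at_b <- component_assignment(f$boundaries, f)$posterior
  expect_lt(abs(post_at_b[1, 1] - 0.5), 1e-6)
})

test_that("posterior assignment matches a brute-force Bayes computation", {
  set.seed(111)
  x <- c(rnorm(200, -5, 1.5), rnorm(300, 4, 2))
  f <- fit_gmm(x, M_range = 2, seed = 1)
  a <- component_assignment(x, f)
  expect_equal(unname(rowSums(a$posterior)), rep(1, length(x)),
               tolerance = 1e-12)
  brute <- sapply(1:2, function(i) f$w[i] * dnorm(x, f$means[i], f$sds[i]))
  brute <- brute / rowSums(brute)
  expect_equal(a$posterior, brute, tolerance = 1e-12,
               ignore_attr = TRUE)
  ## a point at a well-separated component mean is assigned with certainty
  expect_gt(component_assignment(f$means[1], f)$posterior[1, 1], 0.99)
})

test_that("chi-squared association handles perfect dependence", {
  lab3 <- rep(c("a", "b", "c"), each = 30)
  expect_equal(association_chi2(lab3, lab3)$statistic, 180)
  expect_equal(association_chi2(lab3, lab3)$df, 4)
  lab2 <- rep(c("x", "y"), each = 10)
  expect_equal(association_chi2(lab2, lab2)$statistic, 20)
  expect_error(association_chi2(rep("a", 10), rep(1:2, 5)), "2 rows")
})

test_that("tissue tree: perfect mapping, independence, and majority bound", {
  lab <- rep(c("A", "B", "C"), each = 40)
  tr <- tissue_tree(lab, rep(1:3, each = 40), seed = 1)
  expect_equal(tr$cv_accuracy, 1.0)
  expect_true(all(abs(rowSums(tr$leaf_class_props) - 1) < 1e-9))
  ## component independent of tissue: accuracy near the majority prior
  set.seed(121)
  comp <- sample(1:3, 240, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  tr0 <- tissue_tree(rep(c("A", "B", "C"), each = 80), comp,
                     n_rep = 200, seed = 2)
  prior <- max(table(comp)) / 240
  expect_lt(abs(tr0$cv_accuracy - prior), 0.1)
  expect_gt(tr0$cv_accuracy, prior - 0.05)
})
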