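#' Bland-Altman agreement analysis of two assays
#'
#' For paired measurements the per-sample difference `d = line1 - luma` is
#' summarised by the fixed bias (mean difference, with a one-sample t test
#' against zero and a t-based 95 % CI), the 95 % limits of agreement
#' `mean(d) +/- 1.96 * sd(d)`, and the proportional bias: the ordinary
#' least-squares slope of `d` on the pairwise average `(line1 + luma)/2`,
#' with its CI and two-sided p value.  Normality of the differences is
#' assessed with a Kolmogorov-Smirnov-type test; because the normal
#' parameters are estimated from the data, the Lilliefors-corrected test
#' is the default, with the naive KS test available for comparison.
#'
#' @param samples sample sheet with `line1_pct` and `luma_pct`, or a
#'   two-column matrix/data.frame of paired values.
#' @param ks `"lilliefors"` (default) or `"naive"`.
#' @return An object of class `"bland_altman"`.
#' @export
bland_altman <- function(samples, ks = c("lilliefors", "naive")) {
  ks <- match.arg(ks)
  xy <- paired_values(samples)
  n <- nrow(xy)
  if (n < 3) stop("Bland-Altman analysis needs at least 3 paired values")
  d <- xy[, 1] - xy[, 2]
  avg <- rowMeans(xy)
  md <- mean(d); sdd <- stats::sd(d)
  se <- sdd / sqrt(n)
  tq <- stats::qt(0.975, n - 1)
  t_p <- if (sdd > 0) stats::t.test(d)$p.value else NA_real_
  loa <- c(lower = md - 1.96 * sdd, upper = md + 1.96 * sdd)
  ## proportional bias: OLS of d on the average
  if (stats::var(avg) > 0 && sdd > 0) {
    fit <- stats::lm(d ~ avg)
    sl <- suppressWarnings(summary(fit))$coefficients["avg", ]
    ci <- suppressWarnings(stats::confint(fit))["avg", ]
    slope <- unname(sl["Estimate"]); slope_p <- unname(sl["Pr(>|t|)"])
    slope_ci <- unname(ci)
  } else {
    slope <- NA_real_; slope_p <- NA_real_; slope_ci <- c(NA_real_, NA_real_)
  }
  kst <- if (sdd > 0 && n >= 5) {
    if (ks == "lilliefors") nortest::lillie.test(d)
    else suppressWarnings(stats::ks.test(d, "pnorm", md, sdd))
  } else NULL
  structure(list(
    n = n, mean_diff = md, sd_diff = sdd,
    diff_ci = c(lower = md - tq * se, upper = md + tq * se),
    t_p = t_p, loa = loa,
    prop_slope = slope, slope_ci = slope_ci, slope_p = slope_p,
    ks_D = if (is.null(kst)) NA_real_ else unname(kst$statistic),
    ks_p = if (is.null(kst)) NA_real_ else kst$p.value,
    ks_method = ks, differences = d, averages = avg),
    class = "bland_altman")
}

paired_values <- function(samples) {
  if (is.data.frame(samples) && all(c("line1_pct", "luma_pct") %in% names(samples)))
    xy <- cbind(samples$line1_pct, samples$luma_pct)
  else xy <- as.matrix(samples)[, 1:2]
  storage.mode(xy) <- "double"
  xy[stats::complete.cases(xy), , drop = FALSE]
}

#' @export
print.bland_altman <- function(x, digits = 3, ...) {
  cat("Bland-Altman agreement analysis (n =", x$n, ")\n")
  cat(sprintf("  fixed bias (mean difference): %.*f  [%.*f, %.*f], t-test p = %s\n",
              digits, x$mean_diff, digits, x$diff_ci[1], digits, x$diff_ci[2],
              format.pval(x$t_p, digits)))
  cat(sprintf("  95%% limits of agreement:      [%.*f, %.*f]\n",
              digits, x$loa[1], digits, x$loa[2]))
  if (is.finite(x$prop_slope))
    cat(sprintf("  proportional bias slope:      %.*f  [%.*f, %.*f], p = %s\n",
                digits, x$prop_slope, digits, x$slope_ci[1], digits,
                x$slope_ci[2], format.pval(x$slope_p, digits)))
  else cat("  proportional bias slope:      undefined\n")
  cat(sprintf("  normality of differences (%s): D = %.4f, p = %s\n",
              x$ks_method, x$ks_D, format.pval(x$ks_p, digits)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$averages, x$differences,
                 xlab = "average of assays (% methylation)",
                 ylab = "LINE-1 - LUMA (% methylation)", ...)
  graphics::abline(h = 0, col = "magenta")
  graphics::abline(h = x$mean_diff, col = "blue")
  graphics::abline(h = x$loa, col = "red", lty = 2)
  invisible(x)
}

#' Spearman correlation with bootstrap confidence interval
#'
#' Point estimate on the full data; the 95 % CI is the 2.5th/97.5th
#' percentile of the correlation over `n_boot` resamples of sample pairs
#' with replacement.  Deterministic under `seed`.
#'
#' @param samples paired values (see [bland_altman()]).
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @return List with `rho`, `ci`, `p`, `n_boot`.
#' @export
spearman_bootstrap <- function(samples, n_boot = 1000, seed = 1L) {
  xy <- paired_values(samples)
  n <- nrow(xy)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(xy[, 1]) == 0 || stats::sd(xy[, 2]) == 0)
    stop("Spearman correlation undefined for a constant vector")
  rho <- stats::cor(xy[, 1], xy[, 2], method = "spearman")
  p <- suppressWarnings(
    stats::cor.test(xy[, 1], xy[, 2], method = "spearman"))$p.value
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    if (stats::sd(xy[i, 1]) == 0 || stats::sd(xy[i, 2]) == 0) return(NA_real_)
    stats::cor(xy[i, 1], xy[i, 2], method = "spearman")
  }, numeric(1))
  ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(rho = rho, ci = c(lower = ci[1], upper = ci[2]), p = p,
       n_boot = n_boot)
}

#' Paired distribution tests for two assays
#'
#' Two-sided Wilcoxon signed-rank test of the paired values (exact null
#' distribution for n <= 25 without ties/zeros, normal approximation with
#' continuity correction otherwise) and a normality test of the
#' differences (see [bland_altman()] for the KS variants).
#'
#' @inheritParams bland_altman
#' @return List with `wilcoxon_V`, `wilcoxon_p`, `ks_D`, `ks_p`.
#' @export
paired_tests <- function(samples, ks = c("lilliefors", "naive")) {
  ks <- match.arg(ks)
  xy <- paired_values(samples)
  n <- nrow(xy)
  if (n < 5) stop("paired tests need at least 5 pairs")
  d <- xy[, 1] - xy[, 2]
  if (all(d == 0)) {
    warning("all differences zero: Wilcoxon statistic undefined")
    w <- list(statistic = NA_real_, p.value = NA_real_)
  } else {
    w <- suppressWarnings(
      stats::wilcox.test(xy[, 1], xy[, 2], paired = TRUE,
                         exact = n <= 25, correct = TRUE))
  }
  kst <- if (ks == "lilliefors") nortest::lillie.test(d)
         else suppressWarnings(stats::ks.test(d, "pnorm", mean(d), stats::sd(d)))
  list(wilcoxon_V = unname(w$statistic), wilcoxon_p = w$p.value,
       ks_D = unname(kst$statistic), ks_p = kst$p.value)
}

#' Repeated-measures ANOVA of assay by data subset
#'
#' Mixed two-way ANOVA with "assay" (LINE-1 vs LUMA) as the within-subject
#' factor and "data subset" as the between-subject factor, followed by
#' per-subset post-hoc Wilcoxon signed-rank tests with Bonferroni
#' correction (p multiplied by the number of subsets, capped at 1).
#'
#' @param samples sample sheet with `subset`, `line1_pct`, `luma_pct`.
#' @return List with the three F statistics and p values (`assay`,
#'   `subset`, `interaction`) and a data.frame `posthoc`.
#' @export
rm_anova <- function(samples) {
  samples <- samples[stats::complete.cases(samples[, c("line1_pct", "luma_pct")]), ]
  subsets <- unique(samples$subset)
  if (length(subsets) < 2) stop("need at least 2 subsets")
  ns <- table(samples$subset)
  if (any(ns < 2)) stop("subset(s) with fewer than 2 samples: ",
                        paste(names(ns)[ns < 2], collapse = ", "))
  d <- samples$line1_pct - samples$luma_pct
  if (all(d == 0)) {
    ## identical assay columns: the within-subject strata carry no variance
    ow <- summary(stats::aov(rowMeans(cbind(samples$line1_pct,
                                            samples$luma_pct)) ~
                               factor(samples$subset)))[[1]]
    zero <- c(F = 0, p = 1)
    posthoc <- data.frame(subset = subsets, V = NA_real_, p = 1,
                          p_bonferroni = 1)
    return(list(assay = zero,
                subset = c(F = ow[1, "F value"], p = ow[1, "Pr(>F)"]),
                interaction = zero, posthoc = posthoc))
  }
  long <- data.frame(
    id = factor(rep(samples$sample_id, 2)),
    subset = factor(rep(samples$subset, 2)),
    assay = factor(rep(c("LINE1", "LUMA"), each = nrow(samples))),
    pct = c(samples$line1_pct, samples$luma_pct))
  fit <- stats::aov(pct ~ assay * subset + Error(id), data = long)
  s <- summary(fit)
  between <- s[["Error: id"]][[1]]
  within <- s[["Error: Within"]][[1]]
  grab <- function(tab, term) {
    i <- grep(paste0("^", term, "\\s*$"), rownames(tab))
    c(F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
  }
  bs <- grab(between, "subset")
  wa <- grab(within, "assay")
  wi <- grab(within, "assay:subset")
  posthoc <- do.call(rbind, lapply(subsets, function(su) {
    z <- samples[samples$subset == su, ]
    w <- suppressWarnings(
      stats::wilcox.test(z$line1_pct, z$luma_pct, paired = TRUE,
                         exact = nrow(z) <= 25, correct = TRUE))
    data.frame(subset = su, V = unname(w$statistic), p = w$p.value,
               p_bonferroni = min(1, w$p.value * length(subsets)))
  }))
  list(assay = wa, subset = bs, interaction = wi, posthoc = posthoc)
}

#' Per-subset agreement report
#'
#' Assembles, per data subset, the descriptive statistics, paired tests,
#' bootstrap Spearman correlation, and Bland-Altman agreement block into a
#' single table (one row per subset).
#'
#' @param samples sample sheet (`subset`, `line1_pct`, `luma_pct`).
#' @param n_boot bootstrap resamples for the Spearman CI.
#' @param seed integer seed for the bootstrap.
#' @param ks normality test variant, see [bland_altman()].
#' @return data.frame with one row per subset.
#' @export
agreement_report <- function(samples, n_boot = 1000, seed = 1L,
                             ks = c("lilliefors", "naive")) {
  ks <- match.arg(ks)
  do.call(rbind, lapply(split(samples, samples$subset), function(z) {
    ba <- bland_altman(z, ks = ks)
    pt <- paired_tests(z, ks = ks)
    sp <- spearman_bootstrap(z, n_boot = n_boot, seed = seed)
    data.frame(
      subset = z$subset[1], n = ba$n,
      mean_line1 = mean(z$line1_pct), sd_line1 = stats::sd(z$line1_pct),
      mean_luma = mean(z$luma_pct), sd_luma = stats::sd(z$luma_pct),
      wilcoxon_V = pt$wilcoxon_V, wilcoxon_p = pt$wilcoxon_p,
      spearman_rho = sp$rho, rho_lo = sp$ci[1], rho_hi = sp$ci[2],
      rho_p = sp$p,
      mean_diff = ba$mean_diff, diff_lo = ba$diff_ci[1],
      diff_hi = ba$diff_ci[2], t_p = ba$t_p,
      ks_D = ba$ks_D, ks_p = ba$ks_p,
      loa_lower = ba$loa[1], loa_upper = ba$loa[2],
      prop_slope = ba$prop_slope, slope_lo = ba$slope_ci[1],
      slope_hi = ba$slope_ci[2], slope_p = ba$slope_p,
      row.names = NULL)
  }))
}
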