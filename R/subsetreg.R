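#' Specification of the subset-specific linear calibration model
#'
#' The full model relates the two assays per data subset s as
#' `line1 = (Intersection + theta_Int,s) + (Slope * theta_Slope,s) * luma + e`.
#' The global Intersection (theta1) is either estimated or fixed at 0,
#' the global Slope (theta2) either estimated or fixed at 1; each
#' subset-specific modulator is estimated or fixed at its neutral value
#' (0 for intercept offsets, 1 for slope factors), and equality ties
#' constrain modulators of several subsets to a common estimate.  A
#' subset with both modulators neutral lies on the global line; with
#' theta1 fixed at 0 a neutral intercept offset pins that subset's
#' effective intercept to zero.
#'
#' @param subsets character vector of subset names (defines the order
#'   Subset1..SubsetK).
#' @param free_int,free_slope logical vectors (length K): estimate the
#'   subset's intercept offset / slope factor.
#' @param int_ties,slope_ties lists of character vectors; each element
#'   names subsets whose free modulator is shared.
#' @param int_base `"free"` (estimate theta1) or `"zero"` (fix it at 0).
#' @param slope_base `"free"` (estimate theta2) or `"one"` (fix it at 1).
#' @return Object of class `"subset_spec"`.
#' @export
subset_spec <- function(subsets, free_int = rep(FALSE, length(subsets)),
                        free_slope = rep(FALSE, length(subsets)),
                        int_ties = list(), slope_ties = list(),
                        int_base = c("free", "zero"),
                        slope_base = c("free", "one")) {
  K <- length(subsets)
  stopifnot(length(free_int) == K, length(free_slope) == K)
  int_base <- match.arg(int_base)
  slope_base <- match.arg(slope_base)
  grp <- function(free, ties) {
    g <- integer(K); nxt <- 1L
    for (tie in ties) {
      i <- match(tie, subsets)
      if (anyNA(i)) stop("tie names unknown subset: ",
                         paste(tie[is.na(i)], collapse = ", "))
      if (!all(free[i])) stop("ties may only join free parameters")
      g[i] <- nxt; nxt <- nxt + 1L
    }
    for (i in seq_len(K)) if (free[i] && g[i] == 0L) { g[i] <- nxt; nxt <- nxt + 1L }
    g
  }
  new_subset_spec(subsets, int_base, slope_base,
                  grp(free_int, int_ties), grp(free_slope, slope_ties))
}

new_subset_spec <- function(subsets, int_base, slope_base, int_group,
                            slope_group) {
  structure(list(subsets = subsets, int_base = int_base,
                 slope_base = slope_base,
                 int_group = renumber(int_group),
                 slope_group = renumber(slope_group)),
            class = "subset_spec")
}

renumber <- function(g) {
  u <- unique(g[g > 0])
  g[g > 0] <- match(g[g > 0], u)
  g
}

spec_npar <- function(spec) {
  (spec$int_base == "free") + (spec$slope_base == "free") +
    length(unique(spec$int_group[spec$int_group > 0])) +
    length(unique(spec$slope_group[spec$slope_group > 0]))
}

#' Fit the subset-specific linear model by maximum likelihood
#'
#' With a single additive Gaussian residual the maximum-likelihood fit is
#' the constrained least-squares solution; `-2LL = n log(2 pi sigma2) + n`
#' with `sigma2` the ML residual variance (so the fit is deterministic and
#' exactly reproducible).  When every subset's intercept offset (slope
#' factor) is freed while the global Intersection (Slope) is also
#' estimated, the decomposition is redundant; with `normalize = TRUE` the
#' global parameter is fixed at its neutral value and the modulators
#' absorb the effective values, otherwise the redundancy is an error.
#'
#' @param samples sample sheet with `subset`, `line1_pct`, `luma_pct`.
#' @param spec a [subset_spec()]; default: the reduced model (one global
#'   line, no subset deviations).
#' @param normalize resolve over-parameterised specs (see above).
#' @return Object of class `"subset_lm"`.
#' @export
subset_lm <- function(samples, spec = NULL, normalize = TRUE) {
  samples <- samples[stats::complete.cases(samples[, c("line1_pct", "luma_pct")]), ]
  subsets <- unique(samples$subset)
  if (is.null(spec)) spec <- subset_spec(subsets)
  if (!setequal(spec$subsets, subsets))
    stop("spec subsets do not match the data")
  K <- length(spec$subsets)
  s_idx <- match(samples$subset, spec$subsets)
  ns <- tabulate(s_idx, K)
  needs <- spec$int_group > 0 | spec$slope_group > 0
  if (any(needs & ns < 3))
    stop("subset(s) with free parameters but fewer than 3 samples: ",
         paste(spec$subsets[needs & ns < 3], collapse = ", "))
  all_int_free <- all(spec$int_group > 0)
  all_slope_free <- all(spec$slope_group > 0)
  if (all_int_free && spec$int_base == "free") {
    if (!normalize)
      stop("unidentifiable specification: all subset intercept offsets are ",
           "free alongside the global Intersection (theta1)", call. = FALSE)
    spec$int_base <- "zero"
  }
  if (all_slope_free && spec$slope_base == "free") {
    if (!normalize)
      stop("unidentifiable specification: all subset slope factors are ",
           "free alongside the global Slope (theta2)", call. = FALSE)
    spec$slope_base <- "one"
  }
  y <- samples$line1_pct
  x <- samples$luma_pct
  n <- length(y)

  anchored_slope <- spec$slope_group[s_idx] == 0
  offset <- if (spec$slope_base == "one") x * anchored_slope else 0
  cols <- list(); cn <- character(0)
  if (spec$int_base == "free") {
    cols <- c(cols, list(rep(1, n))); cn <- c(cn, "theta1")
  }
  for (g in sort(unique(spec$int_group[spec$int_group > 0]))) {
    cols <- c(cols, list(as.numeric(spec$int_group[s_idx] == g)))
    cn <- c(cn, paste0("int_g", g))
  }
  if (spec$slope_base == "free") {
    cols <- c(cols, list(x * anchored_slope)); cn <- c(cn, "theta2")
  }
  for (g in sort(unique(spec$slope_group[spec$slope_group > 0]))) {
    cols <- c(cols, list(x * (spec$slope_group[s_idx] == g)))
    cn <- c(cn, paste0("slope_g", g))
  }
  if (!length(cols)) stop("empty model specification")
  X <- do.call(cbind, cols)
  colnames(X) <- cn
  fit <- stats::lm.fit(X, y - offset)
  if (fit$rank < ncol(X))
    stop("design is rank deficient; specification not identifiable")
  beta <- fit$coefficients
  res <- fit$residuals
  sigma2 <- sum(res^2) / n
  m2ll <- n * log(2 * pi * sigma2) + n

  theta1 <- if (spec$int_base == "free") unname(beta["theta1"]) else 0
  theta2 <- if (spec$slope_base == "free") unname(beta["theta2"]) else 1
  alpha <- rep(theta1, K); slope <- rep(theta2, K)
  for (s in seq_len(K)) {
    gi <- spec$int_group[s]
    if (gi > 0) alpha[s] <- theta1 + unname(beta[paste0("int_g", gi)])
    gs <- spec$slope_group[s]
    if (gs > 0) slope[s] <- unname(beta[paste0("slope_g", gs)])
  }
  structure(list(
    coefficients = beta, theta1 = theta1, theta2 = theta2,
    theta_int = stats::setNames(alpha - theta1, spec$subsets),
    theta_slope = stats::setNames(slope / theta2, spec$subsets),
    effective = data.frame(subset = spec$subsets, n = ns,
                           intercept = alpha, slope = slope),
    sigma2 = sigma2, minus2LL = m2ll,
    npar = ncol(X) + 1L, n = n, spec = spec,
    X = X, y = y, offset = offset, subset_idx = s_idx,
    fitted.values = fit$fitted.values + offset, residuals = res,
    data = samples),
    class = "subset_lm")
}

#' @export
print.subset_lm <- function(x, digits = 4, ...) {
  cat("Subset-specific linear model:",
      "line1 = (Intersection + theta_Int,s) + (Slope * theta_Slope,s) * luma + e\n")
  tag <- function(v, fixed) paste0(format(round(v, digits)),
                                   if (fixed) " (fixed)" else "")
  cat("  Intersection (theta1):", tag(x$theta1, x$spec$int_base == "zero"), "\n")
  cat("  Slope        (theta2):", tag(x$theta2, x$spec$slope_base == "one"), "\n")
  eff <- x$effective
  eff$theta_int <- ifelse(x$spec$int_group > 0,
                          format(round(x$theta_int, digits)), "0 (fixed)")
  eff$theta_slope <- ifelse(x$spec$slope_group > 0,
                            format(round(x$theta_slope, digits)), "1 (fixed)")
  print(format(eff, digits = digits), row.names = FALSE)
  cat(sprintf("  sigma2 = %.4g,  -2LL = %.3f,  n = %d, parameters = %d\n",
              x$sigma2, x$minus2LL, x$n, x$npar))
  invisible(x)
}

#' @export
coef.subset_lm <- function(object, ...) object$coefficients

#' @export
logLik.subset_lm <- function(object, ...) {
  structure(-object$minus2LL / 2, df = object$npar, nobs = object$n,
            class = "logLik")
}

#' @export
predict.subset_lm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  i <- match(newdata$subset, object$spec$subsets)
  if (anyNA(i)) stop("newdata contains unknown subsets")
  object$effective$intercept[i] + object$effective$slope[i] * newdata$luma_pct
}

#' @export
residuals.subset_lm <- function(object, ...) object$residuals

#' @export
fitted.subset_lm <- function(object, ...) object$fitted.values

#' @export
simulate.subset_lm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim, object$fitted.values +
                     stats::rnorm(object$n, 0, sqrt(object$sigma2)),
                   simplify = FALSE)
  as.data.frame(stats::setNames(out, paste0("sim_", seq_len(nsim))))
}

#' @export
summary.subset_lm <- function(object, ...) {
  p <- ncol(object$X)
  s2_ols <- sum(object$residuals^2) / (object$n - p)
  XtXi <- chol2inv(chol(crossprod(object$X)))
  se <- sqrt(diag(XtXi) * s2_ols)
  coefs <- cbind(Estimate = object$coefficients, `Std. Error` = se,
                 `pct SEE` = 100 * se / abs(object$coefficients))
  out <- list(coefficients = coefs, effective = object$effective,
              sigma2 = object$sigma2, minus2LL = object$minus2LL,
              n = object$n)
  class(out) <- "summary.subset_lm"
  out
}

#' @export
print.summary.subset_lm <- function(x, digits = 4, ...) {
  stats::printCoefmat(x$coefficients, digits = digits)
  cat("\nEffective per-subset regression lines:\n")
  print(format(x$effective, digits = digits), row.names = FALSE)
  cat(sprintf("\nsigma2 = %.4g, -2LL = %.3f, n = %d\n",
              x$sigma2, x$minus2LL, x$n))
  invisible(x)
}

#' Likelihood-ratio decision between nested model fits
#'
#' `Delta(-2LL) = (-2LL of the full model) - (-2LL of the reduced model)`;
#' the additional parameter(s) are retained iff the change is strictly
#' below the negated 0.95 chi-squared quantile for the parameter-count
#' difference (-3.84 for one degree of freedom, so a change of exactly
#' -3.84 drops the parameter).
#'
#' @param fit_full,fit_reduced nested [subset_lm()] fits on the same data.
#' @param alpha significance level.
#' @return List with `keep`, `delta`, `df`, `p`, `criterion`.
#' @export
lrt_step <- function(fit_full, fit_reduced, alpha = 0.05) {
  if (fit_full$n != fit_reduced$n) stop("fits are on different data sets")
  df <- fit_full$npar - fit_reduced$npar
  if (df <= 0) stop("models are not nested (full model has no extra parameters)")
  delta <- fit_full$minus2LL - fit_reduced$minus2LL
  crit <- -stats::qchisq(1 - alpha, df)
  list(keep = delta < crit, delta = delta, df = df,
       p = stats::pchisq(-delta, df, lower.tail = FALSE), criterion = crit)
}

## ---- spec edits used by the stepwise search (internal) --------------------

free_modulator <- function(spec, what, s) {
  g <- if (what == "int") spec$int_group else spec$slope_group
  g[s] <- max(g) + 1L
  if (what == "int") new_subset_spec(spec$subsets, spec$int_base,
                                     spec$slope_base, g, spec$slope_group)
  else new_subset_spec(spec$subsets, spec$int_base, spec$slope_base,
                       spec$int_group, g)
}

tie_classes <- function(spec, what, g1, g2) {
  g <- if (what == "int") spec$int_group else spec$slope_group
  g[g == g2] <- g1
  if (what == "int") new_subset_spec(spec$subsets, spec$int_base,
                                     spec$slope_base, g, spec$slope_group)
  else new_subset_spec(spec$subsets, spec$int_base, spec$slope_base,
                       spec$int_group, g)
}

## pin the equivalence class containing subset s to the absolute neutral
## value (intercept 0 / slope 1).  When the global parameter was still
## estimated, the subsets that sat on it get their own free modulator (an
## equivalent reparameterisation) before the base is fixed, so only the
## target class loses its degree of freedom.
pin_class <- function(spec, what, s) {
  base_free <- (if (what == "int") spec$int_base else spec$slope_base) == "free"
  g <- if (what == "int") spec$int_group else spec$slope_group
  cls <- g[s]
  if (cls > 0) {
    members <- g == cls
    if (base_free && any(g == 0)) g[g == 0] <- max(g) + 1L
    g[members] <- 0L
  }
  if (what == "int")
    new_subset_spec(spec$subsets, "zero", spec$slope_base, g, spec$slope_group)
  else
    new_subset_spec(spec$subsets, spec$int_base, "one", spec$int_group, g)
}

## merge the class of subset s back onto the estimated global parameter
merge_to_anchor <- function(spec, what, s) {
  g <- if (what == "int") spec$int_group else spec$slope_group
  g[g == g[s]] <- 0L
  if (what == "int") new_subset_spec(spec$subsets, spec$int_base,
                                     spec$slope_base, g, spec$slope_group)
  else new_subset_spec(spec$subsets, spec$int_base, spec$slope_base,
                       spec$int_group, g)
}

#' Stepwise likelihood-ratio model building
#'
#' Starting from the reduced model (one global line shared by all
#' subsets), the search proceeds in a fixed, documented order: (1)
#' subset-specific intercept offsets are tested in subset order, then (2)
#' subset-specific slope factors (a step that would merely reparameterise
#' the model without adding a degree of freedom is logged and skipped);
#' (3) equality ties between pairs of free parameters are tested, slopes
#' first; (4) a backward pass re-tests every parameter class against its
#' parsimonious reference - an intercept class against the absolute zero
#' y-intersection or the shared estimated Intersection, a slope class
#' against the shared estimated Slope - accepting any reduction that does
#' not significantly worsen the fit.  Each decision uses [lrt_step()] at level `alpha`; the complete
#' decision log is returned so alternative orders can be audited.
#'
#' @param samples sample sheet.
#' @param alpha significance level for each step.
#' @return The final [subset_lm()] fit, with the decision log in
#'   `$step_log`.
#' @export
build_final_model <- function(samples, alpha = 0.05) {
  subsets <- unique(samples$subset)
  cur <- subset_lm(samples, subset_spec(subsets))
  log_ <- NULL
  add_log <- function(phase, param, st, decision) {
    log_ <<- rbind(log_, data.frame(
      phase = phase, parameter = param,
      delta = if (is.null(st)) NA_real_ else st$delta,
      df = if (is.null(st)) NA_integer_ else st$df,
      p = if (is.null(st)) NA_real_ else st$p,
      decision = decision, stringsAsFactors = FALSE))
  }
  lab <- function(what, s) paste0("theta_", if (what == "int") "Int," else
                                    "Slope,", paste(s, collapse = "="))
  ## (1)-(2) forward: within each phase, introduce the candidate giving the
  ## largest fit improvement first, while improvements stay significant
  for (what in c("int", "slope")) {
    repeat {
      g <- if (what == "int") cur$spec$int_group else cur$spec$slope_group
      todo <- which(g == 0)
      cands <- list()
      for (s in todo) {
        cand_spec <- free_modulator(cur$spec, what, s)
        cand <- subset_lm(samples, cand_spec)
        if (cand$npar <= cur$npar) {
          add_log("forward", lab(what, subsets[s]), NULL,
                  "equivalent reparameterisation, skipped")
          next
        }
        cands[[as.character(s)]] <- cand
      }
      if (!length(cands)) break
      m2 <- vapply(cands, function(f) f$minus2LL, numeric(1))
      best <- which.min(m2)
      s <- as.integer(names(cands)[best])
      st <- lrt_step(cands[[best]], cur, alpha)
      add_log("forward", lab(what, subsets[s]), st,
              if (st$keep) "retained" else "dropped")
      if (!st$keep) break
      cur <- cands[[best]]
    }
  }
  ## (3) equality ties
  for (what in c("slope", "int")) {
    repeat {
      g <- if (what == "int") cur$spec$int_group else cur$spec$slope_group
      gids <- sort(unique(g[g > 0]))
      if (length(gids) < 2) break
      tied <- FALSE
      pairs <- utils::combn(gids, 2)
      for (k in seq_len(ncol(pairs))) {
        m1 <- subsets[g == pairs[1, k]]; m2 <- subsets[g == pairs[2, k]]
        cand <- subset_lm(samples, tie_classes(cur$spec, what,
                                               pairs[1, k], pairs[2, k]))
        st <- lrt_step(cur, cand, alpha)
        add_log("tie", lab(what, c(m1, m2)), st,
                if (st$keep) "tie rejected" else "tie accepted")
        if (!st$keep) { cur <- cand; tied <- TRUE; break }
      }
      if (!tied) break
    }
  }
  ## (4) backward: pin classes to the neutral reference / global line
  repeat {
    changed <- FALSE
    for (what in c("int", "slope")) {
      g <- if (what == "int") cur$spec$int_group else cur$spec$slope_group
      base_free <- (if (what == "int") cur$spec$int_base else
                      cur$spec$slope_base) == "free"
      for (cls in unique(g)) {
        s <- which(g == cls)[1]
        cands <- list()
        ## intercept classes are tested against the absolute zero reference;
        ## slope classes only against the shared estimated slope (a fixed
        ## unit slope is only meaningful jointly with a zero intercept and
        ## is not part of the search)
        if (what == "int" && !(cls == 0 && !base_free))
          cands <- c(cands, list(list(spec = pin_class(cur$spec, what, s),
                                      tag = "pin to zero")))
        if (cls > 0 && base_free)
          cands <- c(cands, list(list(spec = merge_to_anchor(cur$spec, what, s),
                                      tag = "merge with global")))
        for (cd in cands) {
          cand <- try(subset_lm(samples, cd$spec), silent = TRUE)
          if (inherits(cand, "try-error") || cand$npar >= cur$npar) next
          st <- lrt_step(cur, cand, alpha)
          add_log("backward", paste(lab(what, subsets[g == cls]), cd$tag),
                  st, if (st$keep) "reduction rejected" else "reduced")
          if (!st$keep) { cur <- cand; changed <- TRUE; break }
        }
        if (changed) break
      }
      if (changed) break
    }
    if (!changed) break
  }
  cur$step_log <- log_
  cur
}

#' Bootstrap confidence intervals for the model parameters
#'
#' Resamples samples with replacement (stratified by subset by default,
#' preserving the group sizes), refits the given specification, and
#' returns the 2.5th/97.5th percentile interval for every structural
#' parameter and every effective per-subset intercept and slope.  Failed
#' refits are redrawn and counted.
#'
#' @param samples sample sheet.
#' @param spec a [subset_spec()] (e.g. from the final model).
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @param stratify resample within subsets (keeps group sizes fixed).
#' @return List with `ci` (matrix, one row per parameter), `estimates`,
#'   `n_failed`.
#' @export
bootstrap_ci <- function(samples, spec, n_boot = 1000, seed = 1L,
                         stratify = TRUE) {
  fit0 <- subset_lm(samples, spec)
  set.seed(seed)
  idx_by_subset <- split(seq_len(nrow(samples)), samples$subset)
  draw <- function() {
    if (stratify)
      unlist(lapply(idx_by_subset, function(i) sample(i, length(i), TRUE)))
    else sample.int(nrow(samples), nrow(samples), TRUE)
  }
  par_vec <- function(f)
    c(theta1 = f$theta1, theta2 = f$theta2,
      stats::setNames(f$theta_int, paste0("theta_Int,", f$spec$subsets)),
      stats::setNames(f$theta_slope, paste0("theta_Slope,", f$spec$subsets)),
      stats::setNames(f$effective$intercept,
                      paste0("intercept,", f$spec$subsets)),
      stats::setNames(f$effective$slope, paste0("slope,", f$spec$subsets)),
      sigma2 = f$sigma2)
  est <- par_vec(fit0)
  n_failed <- 0L
  boot <- matrix(NA_real_, n_boot, length(est),
                 dimnames = list(NULL, names(est)))
  b <- 1L
  while (b <= n_boot) {
    f <- try(subset_lm(samples[draw(), ], spec), silent = TRUE)
    if (inherits(f, "try-error")) { n_failed <- n_failed + 1L; next }
    boot[b, ] <- par_vec(f)
    b <- b + 1L
  }
  ci <- t(apply(boot, 2, stats::quantile, probs = c(0.025, 0.975)))
  if (n_failed > 0)
    message(n_failed, " bootstrap refit(s) failed and were redrawn")
  list(ci = ci, estimates = est, n_failed = n_failed)
}

#' @export
confint.subset_lm <- function(object, parm, level = 0.95, n_boot = 1000,
                              seed = 1L, ...) {
  stopifnot(level == 0.95)
  bootstrap_ci(object$data, object$spec, n_boot = n_boot, seed = seed)$ci
}
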