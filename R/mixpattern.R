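#' Pareto density estimation
#'
#' Kernel density estimate of a univariate sample using a uniform (ball)
#' kernel whose radius is the Pareto radius: the 18th percentile of the
#' pairwise absolute differences (computed on a random subsample of at
#' most 1000 points for large n).  The density is evaluated on a regular
#' grid of `ngrid` points spanning the data range extended by three radii
#' and normalised to unit trapezoidal integral.
#'
#' @param x numeric sample (n >= 10, non-constant).
#' @param ngrid number of grid points.
#' @param radius optional kernel radius override (% methylation units).
#' @return Object of class `"pde_grid"`: list with `x`, `density`,
#'   `radius`.
#' @export
pde <- function(x, ngrid = 512, radius = NULL) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 10) stop("PDE needs at least 10 observations")
  if (stats::sd(x) == 0) stop("PDE is degenerate for constant input")
  if (is.null(radius)) {
    idx <- if (n > 1000) sample.int(n, 1000) else seq_len(n)
    pd <- abs(outer(x[idx], x[idx], "-"))
    radius <- stats::quantile(pd[upper.tri(pd)], 0.18, names = FALSE)
  }
  g <- seq(min(x) - 3 * radius, max(x) + 3 * radius, length.out = ngrid)
  xs <- sort(x)
  cnt <- findInterval(g + radius, xs) - findInterval(g - radius, xs)
  dens <- cnt / (2 * radius * n)
  z <- sum((dens[-1] + dens[-ngrid]) / 2 * diff(g))
  structure(list(x = g, density = dens / z, radius = radius),
            class = "pde_grid")
}

gmm_density <- function(x, w, means, sds) {
  out <- 0
  for (i in seq_along(w)) out <- out + w[i] * stats::dnorm(x, means[i], sds[i])
  out
}

## one EM run from a given mean initialisation
em_run <- function(x, mu, max_iter = 300, tol = 1e-8, sd_floor) {
  M <- length(mu)
  s <- rep(diff(range(x)) / (4 * M), M)
  w <- rep(1 / M, M)
  ll0 <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(M),
                   function(i) w[i] * stats::dnorm(x, mu[i], s[i]),
                   numeric(length(x)))
    if (M == 1) dens <- matrix(dens, ncol = 1)
    tot <- pmax(rowSums(dens), 1e-300)
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- pmax(colSums(resp), 1e-12)
    w <- nk / length(x)
    mu <- colSums(resp * x) / nk
    s <- vapply(seq_len(M),
                function(i) sqrt(sum(resp[, i] * (x - mu[i])^2) / nk[i]),
                numeric(1))
    if (any(s < sd_floor)) {
      warning("mixture component with vanishing SD floored during EM")
      s <- pmax(s, sd_floor)
    }
    if (abs(ll - ll0) < tol) break
    ll0 <- ll
  }
  list(w = w, means = mu, sds = s, loglik = ll)
}

#' Fit a univariate Gaussian mixture against a Pareto density estimate
#'
#' Models the distribution of interassay differences as
#' `p(x) = sum_i w_i N(x | mean_i, sd_i)`.  For each candidate component
#' count M the mixture is fitted by expectation-maximisation from
#' quantile-based initialisations (several restarts, ranked by the root
#' mean square error between the mixture curve and the PDE curve, which is
#' the fit criterion throughout), optionally followed by direct
#' minimisation of that RMSE.  The component count is then chosen by BIC
#' by default; `select = "rmse"` instead picks the smallest M whose RMSE
#' lies within 5 % of the best over all candidates (see the vignette for
#' why BIC is the default).
#'
#' @param x numeric sample of differences.
#' @param M_range candidate component counts (a fixed single value pins M).
#' @param seed integer seed (restart jitter is the only randomness).
#' @param select `"bic"` or `"rmse"`.
#' @param refine logical: run direct RMSE minimisation after EM.
#' @param restarts EM restarts per M.
#' @param grid optional precomputed [pde()] grid.
#' @return Object of class `"gmm_fit"` with elements `M`, `w`, `means`,
#'   `sds` (sorted by mean), `rmse_to_pde`, `boundaries`, `candidates`
#'   (per-M table), `grid`.
#' @export
fit_gmm <- function(x, M_range = 1:5, seed = 1L,
                    select = c("bic", "rmse"), refine = TRUE,
                    restarts = 8L, grid = NULL) {
  select <- match.arg(select)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 10 * max(M_range)) stop("need at least 10 observations per component")
  set.seed(seed)
  if (is.null(grid)) grid <- pde(x)
  sd_floor <- 1e-3 * stats::sd(x)
  rmse_of <- function(f) sqrt(mean((gmm_density(grid$x, f$w, f$means, f$sds) -
                                      grid$density)^2))
  fits <- list(); cand <- NULL
  for (M in M_range) {
    best <- NULL
    for (r in seq_len(restarts)) {
      mu0 <- if (r <= ceiling(restarts / 2)) {
        p <- (seq_len(M) - 0.5) / M
        if (r > 1) p <- pmin(0.99, pmax(0.01, p + stats::runif(M, -0.4 / M, 0.4 / M)))
        stats::quantile(x, probs = sort(p), names = FALSE)
      } else if (M > 1) {
        sort(stats::kmeans(x, M, nstart = 1)$centers[, 1])
      } else mean(x)
      f <- suppressWarnings(em_run(x, mu0, sd_floor = sd_floor))
      f$rmse <- rmse_of(f)
      if (is.null(best) || f$rmse < best$rmse) best <- f
    }
    if (refine) {
      obj <- function(par) {
        w <- exp(par[1:M]); w <- w / sum(w)
        sqrt(mean((gmm_density(grid$x, w, par[(M + 1):(2 * M)],
                               pmax(exp(par[(2 * M + 1):(3 * M)]), sd_floor)) -
                     grid$density)^2))
      }
      par0 <- c(log(best$w), best$means, log(best$sds))
      o <- try(stats::optim(par0, obj, method = "BFGS",
                            control = list(maxit = 200)), silent = TRUE)
      if (!inherits(o, "try-error") && o$value < best$rmse) {
        w <- exp(o$par[1:M])
        best$w <- w / sum(w)
        best$means <- o$par[(M + 1):(2 * M)]
        best$sds <- pmax(exp(o$par[(2 * M + 1):(3 * M)]), sd_floor)
        best$rmse <- o$value
        best$loglik <- sum(log(pmax(gmm_density(x, best$w, best$means,
                                                best$sds), 1e-300)))
      }
    }
    fits[[as.character(M)]] <- best
    cand <- rbind(cand, data.frame(M = M, rmse = best$rmse,
                                   loglik = best$loglik,
                                   bic = -2 * best$loglik + (3 * M - 1) * log(n)))
  }
  M_sel <- if (select == "bic") cand$M[which.min(cand$bic)]
           else cand$M[cand$rmse <= 1.05 * min(cand$rmse)][1]
  f <- fits[[as.character(M_sel)]]
  o <- order(f$means)
  out <- structure(list(M = M_sel, w = f$w[o], means = f$means[o],
                        sds = f$sds[o], rmse_to_pde = f$rmse,
                        loglik = f$loglik, candidates = cand,
                        select = select, n = n, grid = grid,
                        boundaries = numeric(0)),
                   class = "gmm_fit")
  if (M_sel >= 2) out$boundaries <- bayes_boundaries(out)
  out
}

#' @export
print.gmm_fit <- function(x, digits = 3, ...) {
  cat("Gaussian mixture fit (M =", x$M, ", selected by", x$select, ")\n")
  print(round(data.frame(weight = x$w, mean = x$means, sd = x$sds), digits))
  cat("RMSE to PDE:", signif(x$rmse_to_pde, digits), "\n")
  if (length(x$boundaries))
    cat("Bayes decision boundaries:",
        paste(round(x$boundaries, digits), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.gmm_fit <- function(x, ...) {
  graphics::plot(x$grid$x, x$grid$density, type = "l",
                 xlab = "interassay difference (% methylation)",
                 ylab = "density", ...)
  graphics::lines(x$grid$x, gmm_density(x$grid$x, x$w, x$means, x$sds),
                  col = "red")
  for (i in seq_along(x$w))
    graphics::lines(x$grid$x,
                    x$w[i] * stats::dnorm(x$grid$x, x$means[i], x$sds[i]),
                    col = "blue", lty = 3)
  graphics::abline(v = x$boundaries, col = "magenta")
  invisible(x)
}

#' @export
logLik.gmm_fit <- function(object, ...) {
  structure(object$loglik, df = 3 * object$M - 1, class = "logLik")
}

#' Bayes decision boundaries of a fitted mixture
#'
#' For each pair of adjacent components (ordered by mean) the boundary is
#' the point where the two weighted component densities are equal, i.e.
#' where the posterior membership probabilities of the two components
#' cross 0.5/0.5.  The root is searched between the two means; when the
#' weighted densities do not cross there (extreme weight imbalance) the
#' posterior-argmax changeover is located on a fine grid extended three
#' SDs beyond the means, with a warning.
#'
#' @param model a `"gmm_fit"` (or list with sorted `w`, `means`, `sds`).
#' @return Ordered numeric vector of M - 1 boundaries.
#' @export
bayes_boundaries <- function(model) {
  M <- length(model$w)
  if (M < 2) stop("boundaries need at least 2 components")
  vapply(seq_len(M - 1), function(i) {
    w1 <- model$w[i]; m1 <- model$means[i]; s1 <- model$sds[i]
    w2 <- model$w[i + 1]; m2 <- model$means[i + 1]; s2 <- model$sds[i + 1]
    g <- function(z) log(w2) + stats::dnorm(z, m2, s2, log = TRUE) -
      log(w1) - stats::dnorm(z, m1, s1, log = TRUE)
    if (g(m1) * g(m2) < 0)
      return(stats::uniroot(g, c(m1, m2), tol = 1e-10)$root)
    ## no crossing between the means: scan for the argmax changeover
    lo <- m1 - 3 * max(s1, s2); hi <- m2 + 3 * max(s1, s2)
    zz <- seq(lo, hi, length.out = 20001)
    sg <- sign(g(zz))
    flip <- which(diff(sg) != 0)
    if (!length(flip)) {
      warning("no posterior changeover between components ", i, " and ",
              i + 1, "; returning midpoint of means")
      return((m1 + m2) / 2)
    }
    mid <- (m1 + m2) / 2
    j <- flip[which.min(abs(zz[flip] - mid))]
    warning("Bayes boundary between components ", i, " and ", i + 1,
            " located by grid changeover (no crossing between means)")
    stats::uniroot(g, c(zz[j], zz[j + 1]), tol = 1e-10)$root
  }, numeric(1))
}

#' Posterior component membership of data points
#'
#' Bayes' theorem applied to the fitted mixture: the posterior probability
#' that point x belongs to component i is `w_i N(x | mean_i, sd_i)`
#' normalised over components.  The hard label is the posterior argmax.
#'
#' @param x numeric vector of differences.
#' @param model a `"gmm_fit"`.
#' @return List with `component` (integer labels, components ordered by
#'   mean) and `posterior` (n x M matrix, rows sum to 1).
#' @export
component_assignment <- function(x, model) {
  M <- length(model$w)
  dens <- vapply(seq_len(M),
                 function(i) model$w[i] * stats::dnorm(x, model$means[i],
                                                       model$sds[i]),
                 numeric(length(x)))
  if (!is.matrix(dens)) dens <- matrix(dens, nrow = length(x))
  post <- dens / pmax(rowSums(dens), 1e-300)
  list(component = max.col(post), posterior = post)
}

#' @export
predict.gmm_fit <- function(object, newdata,
                            type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  a <- component_assignment(newdata, object)
  if (type == "class") a$component else a$posterior
}

#' Chi-squared association between tissue and mixture component
#'
#' Pearson chi-squared test (no continuity correction) of the tissue by
#' component contingency table; empty rows/columns are dropped with a
#' warning.
#'
#' @param labels tissue labels per sample.
#' @param components assigned component per sample.
#' @return List with `statistic`, `df`, `p`, `table`.
#' @export
association_chi2 <- function(labels, components) {
  tab <- table(labels, components)
  empty_r <- rowSums(tab) == 0; empty_c <- colSums(tab) == 0
  if (any(empty_r) || any(empty_c)) {
    warning("dropping empty rows/columns from contingency table")
    tab <- tab[!empty_r, !empty_c, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("contingency table needs at least 2 rows and 2 columns")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}

#' Decision tree predicting mixture component from tissue
#'
#' Fits a classification tree with the tissue label as the only predictor
#' using the information (entropy) impurity `f(p) = -p ln(p)`, and
#' estimates out-of-sample accuracy by a leave-k-out scheme: a random
#' tenth of the samples (by default) is held out, the tree is rebuilt on
#' the remainder and scored on the holdout, repeated `n_rep` times.
#'
#' @param labels tissue labels.
#' @param components assigned component labels.
#' @param k_frac fraction held out per repetition.
#' @param n_rep number of repetitions.
#' @param seed integer seed.
#' @return Object of class `"tissue_tree"` with the fitted `rpart` tree,
#'   `cv_accuracy`, per-leaf class proportions and the label table.
#' @export
tissue_tree <- function(labels, components, k_frac = 1 / 10, n_rep = 100,
                        seed = 1L) {
  df <- data.frame(tissue = factor(labels), comp = factor(components))
  if (nlevels(df$tissue) < 2 || nlevels(df$comp) < 2)
    stop("need at least 2 tissues and 2 components")
  small <- table(df$tissue) < 2
  if (any(small))
    warning("tissue(s) with fewer than 2 samples: ",
            paste(names(small)[small], collapse = ", "))
  ctrl <- rpart::rpart.control(minsplit = 2, minbucket = 1, cp = 0.001,
                               xval = 0)
  fit <- rpart::rpart(comp ~ tissue, data = df, method = "class",
                      parms = list(split = "information"), control = ctrl)
  n <- nrow(df)
  k <- ceiling(n * k_frac)
  majority <- names(which.max(table(df$comp)))
  set.seed(seed)
  acc <- vapply(seq_len(n_rep), function(r) {
    ho <- sample.int(n, k)
    train <- df[-ho, , drop = FALSE]
    f <- rpart::rpart(comp ~ tissue, data = train, method = "class",
                      parms = list(split = "information"), control = ctrl)
    pred <- tryCatch(as.character(predict(f, df[ho, , drop = FALSE],
                                          type = "class")),
                     error = function(e) rep(majority, k))
    mean(pred == as.character(df$comp[ho]))
  }, numeric(1))
  leaves <- fit$frame[fit$frame$var == "<leaf>", , drop = FALSE]
  ## yval2 columns: predicted class, class counts, class proportions, node prob
  nclass <- nlevels(df$comp)
  yv <- leaves$yval2
  leaf_props <- yv[, (1 + nclass + 1):(1 + 2 * nclass), drop = FALSE]
  colnames(leaf_props) <- levels(df$comp)
  structure(list(tree = fit, cv_accuracy = mean(acc), cv_reps = acc,
                 leaf_class_props = leaf_props,
                 table = table(df$tissue, df$comp)),
            class = "tissue_tree")
}

#' @export
print.tissue_tree <- function(x, digits = 3, ...) {
  cat("Tissue -> mixture-component decision tree\n")
  print(x$tree)
  cat(sprintf("cross-validated accuracy: %.1f %% (%d leave-k-out repetitions)\n",
              100 * x$cv_accuracy, length(x$cv_reps)))
  invisible(x)
}

#' @export
predict.tissue_tree <- function(object, newdata, ...) {
  if (!is.data.frame(newdata)) newdata <- data.frame(tissue = factor(newdata))
  predict(object$tree, newdata, type = "class")
}
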