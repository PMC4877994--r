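#' Cohen's d with pooled standard deviation
#'
#' `d = (mean_a - mean_b) / s_pooled` with
#' `s_pooled = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`.
#' The optional Hedges correction multiplies d by `1 - 3/(4(n_a+n_b)-9)`,
#' which matters for the very small treatment groups typical of cell-line
#' panels; the uncorrected value is the default.
#'
#' @param group_a,group_b numeric vectors (each n >= 2).
#' @param hedges apply the small-sample correction.
#' @return The standardized mean difference.
#' @export
cohens_d <- function(group_a, group_b, hedges = FALSE) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("both groups need at least 2 values")
  sp <- sqrt(((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
               (na + nb - 2))
  if (sp == 0) stop("zero pooled standard deviation")
  d <- (mean(group_a) - mean(group_b)) / sp
  if (hedges) d <- d * (1 - 3 / (4 * (na + nb) - 9))
  d
}

#' Pairwise treatment effect sizes under both assays
#'
#' Within each cell line, the DMSO solvent control is combined with the
#' untreated condition, conditions with fewer than `min_n` samples are
#' skipped (with a warning), and Cohen's d is computed for every
#' unordered pair of the remaining conditions under each assay.  The two
#' resulting effect-size profiles are compared by Spearman correlation.
#'
#' @param samples sample sheet with `subset`, `treatment`, `line1_pct`,
#'   `luma_pct`, restricted to the treated cell-line subsets (pass only
#'   the samples whose conditions should be compared).
#' @param combine_control merge `"DMSO"` and `"untreated"` into `"control"`.
#' @param min_n minimum per-condition group size.
#' @param conditions optional named list restricting, per subset, which
#'   conditions enter the comparison.
#' @param hedges passed to [cohens_d()].
#' @return List with `records` (one row per pair: cell line, conditions,
#'   group sizes, `d_line1`, `d_luma`), `rho` and `p` (cross-assay
#'   Spearman), and `n_pairs`.
#' @export
pairwise_effects <- function(samples, combine_control = TRUE, min_n = 2,
                             conditions = NULL, hedges = FALSE) {
  samples <- samples[!samples$qc_excluded %in% TRUE, ]
  if (combine_control)
    samples$treatment[samples$treatment %in% c("DMSO", "untreated")] <- "control"
  recs <- NULL
  for (cl in unique(samples$subset)) {
    z <- samples[samples$subset == cl, ]
    conds <- unique(z$treatment)
    if (!is.null(conditions) && !is.null(conditions[[cl]]))
      conds <- intersect(conds, conditions[[cl]])
    if (length(conds) < 2) next
    sizes <- table(z$treatment)[conds]
    drop <- sizes < min_n
    if (any(drop)) {
      warning("skipping condition(s) with n < ", min_n, " in ", cl, ": ",
              paste(conds[drop], collapse = ", "))
      conds <- conds[!drop]
    }
    if (length(conds) < 2) next
    pairs <- utils::combn(conds, 2)
    for (k in seq_len(ncol(pairs))) {
      a <- z[z$treatment == pairs[1, k], ]
      b <- z[z$treatment == pairs[2, k], ]
      recs <- rbind(recs, data.frame(
        cell_line = cl, condition_a = pairs[1, k], condition_b = pairs[2, k],
        n_a = nrow(a), n_b = nrow(b),
        d_line1 = cohens_d(a$line1_pct, b$line1_pct, hedges),
        d_luma = cohens_d(a$luma_pct, b$luma_pct, hedges),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(recs)) stop("no comparable condition pairs found")
  ct <- suppressWarnings(
    stats::cor.test(recs$d_line1, recs$d_luma, method = "spearman"))
  list(records = recs, rho = unname(ct$estimate), p = ct$p.value,
       n_pairs = nrow(recs))
}
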