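#' Subset preset: the target joint distribution of one data subset
#'
#' A preset describes the marginal distribution of paired LINE-1 and LUMA
#' percent-methylation readings in one data subset (a cell line or a blood
#' cohort pool), together with their interassay dependence.  Samples are
#' drawn from a bivariate Gaussian copula whose Pearson correlation is
#' obtained from the rank correlation via `r = 2 sin(pi * rho / 6)` (exact
#' for the bivariate normal).
#'
#' When a preset additionally carries a target standard deviation for the
#' per-sample interassay difference (`sd_diff`) and a treatment plan with
#' shared per-condition shifts, the marginal variance is decomposed into a
#' between-condition part (the shifts) and a within-condition part, and the
#' within-condition correlation is solved so that the realised difference
#' SD equals `sd_diff`.  This reproduces the situation, common in treated
#' cell-line panels, where treatment effects move both assays together, so
#' the covariance between assays greatly exceeds what the rank correlation
#' of the pooled sample alone would imply.
#'
#' @param name subset label, e.g. `"MCF7"`.
#' @param n number of samples to draw by default.
#' @param mean_line1,sd_line1 marginal mean and SD of LINE-1 % methylation.
#' @param mean_luma,sd_luma marginal mean and SD of LUMA % methylation.
#' @param rho_spearman target rank correlation between the assays, in
#'   \[-1, 1\]; used directly for presets without a treatment plan.
#' @param range_line1,range_luma observed ranges (informational; draws are
#'   not truncated to them).
#' @param sd_diff optional target SD of the per-sample difference
#'   (LINE-1 minus LUMA) in % methylation; only used when a treatment plan
#'   with shifts is attached.  `NA` means "implied by the copula".
#' @return An object of class `"subset_preset"`.
#' @export
subset_preset <- function(name, n, mean_line1, sd_line1, mean_luma, sd_luma,
                          rho_spearman, range_line1 = c(0, 100),
                          range_luma = c(0, 100), sd_diff = NA_real_) {
  stopifnot(n > 0, sd_line1 > 0, sd_luma > 0, abs(rho_spearman) <= 1)
  if (mean_line1 < range_line1[1] || mean_line1 > range_line1[2])
    stop("range_line1 must contain mean_line1 for preset ", name)
  if (mean_luma < range_luma[1] || mean_luma > range_luma[2])
    stop("range_luma must contain mean_luma for preset ", name)
  structure(list(name = name, n = as.integer(n),
                 mean_line1 = mean_line1, sd_line1 = sd_line1,
                 mean_luma = mean_luma, sd_luma = sd_luma,
                 rho_spearman = rho_spearman,
                 range_line1 = range_line1, range_luma = range_luma,
                 sd_diff = sd_diff),
            class = "subset_preset")
}

#' Treatment plan for one cell line or cohort
#'
#' Assigns treatment conditions (with replicate counts) to the samples of a
#' preset and attaches an additive shift in % methylation per condition.
#' Shifts act on both assays equally unless `effect_luma` is given.
#'
#' @param cell_line subset name the plan applies to.
#' @param condition character vector of condition labels (unique).
#' @param n_replicates integer vector of replicate counts (all >= 1).
#' @param effect_line1 additive shift per condition for LINE-1 (% points).
#' @param effect_luma additive shift for LUMA; defaults to `effect_line1`.
#' @return An object of class `"treatment_plan"`.
#' @export
treatment_plan <- function(cell_line, condition, n_replicates,
                           effect_line1, effect_luma = effect_line1) {
  stopifnot(length(condition) == length(n_replicates),
            length(condition) == length(effect_line1),
            length(condition) == length(effect_luma),
            all(n_replicates >= 1))
  if (anyDuplicated(condition))
    stop("conditions within a cell line must be unique")
  structure(list(cell_line = cell_line, condition = condition,
                 n_replicates = as.integer(n_replicates),
                 effect_line1 = effect_line1, effect_luma = effect_luma),
            class = "treatment_plan")
}

#' Default subset presets
#'
#' The three data subsets of the reference study: MCF7 and SHSY5Y cell
#' lines treated with modulators of DNA methylation, and human whole
#' blood (healthy volunteers plus two pain-patient cohorts).  Marginal
#' means/SDs/ranges, rank correlations and (for the treated cell lines)
#' difference SDs implied by the published 95 % limits of agreement.
#'
#' @return Named list of [subset_preset()] objects.
#' @export
default_presets <- function() {
  list(
    MCF7 = subset_preset("MCF7", 73, 60.96, 11.99, 67.80, 11.99, 0.58,
                         range_line1 = c(34, 76.18),
                         range_luma = c(34.36, 78.34),
                         sd_diff = (5.8 + 19.5) / (2 * 1.96)),
    SHSY5Y = subset_preset("SHSY5Y", 34, 59.01, 11.54, 55.66, 11.99, 0.80,
                           range_line1 = c(31.91, 71.65),
                           range_luma = c(24.89, 67.65),
                           sd_diff = (11.3 + 4.6) / (2 * 1.96)),
    blood = subset_preset("blood", 131, 92.4, 2.75, 72.3, 3.1, 0.35,
                          range_line1 = c(77.9, 98.8),
                          range_luma = c(61.9, 78.5))
  )
}

#' Default treatment plans
#'
#' Condition labels and replicate counts follow the reference study's
#' sample table (13 MCF7 conditions, 7 SHSY5Y conditions, 3 blood
#' cohorts).  The per-condition shifts are synthetic choices: the
#' demethylating agents 5-Aza-CdR and RG108 lower methylation (strongly
#' and moderately, respectively), the methyl donor SAM and the pollutant
#' DCP raise it, methadone raises it slightly, and combinations act
#' roughly additively with SAM partially rescuing 5-Aza-CdR.  Blood
#' cohorts carry no shift.
#'
#' @return Named list of [treatment_plan()] objects.
#' @export
default_plans <- function() {
  list(
    MCF7 = treatment_plan(
      "MCF7",
      condition = c("untreated", "DMSO", "5-Aza-CdR", "SAM", "DCP",
                    "Methadone", "RG108", "5-Aza-CdR+SAM", "5-Aza-CdR+DCP",
                    "5-Aza-CdR+Methadone", "5-Aza-CdR+SAM+DCP",
                    "RG108+DCP", "SAM+DCP"),
      n_replicates = c(6, 7, 9, 7, 5, 11, 6, 4, 2, 9, 2, 2, 3),
      effect_line1 = c(0, 0, -22, 6, 4, 3, -10, -10, -15, -18, -8, -5, 7)),
    SHSY5Y = treatment_plan(
      "SHSY5Y",
      condition = c("untreated", "DMSO", "5-Aza-CdR", "SAM", "Methadone",
                    "5-Aza-CdR+SAM", "5-Aza-CdR+Methadone"),
      n_replicates = c(7, 7, 12, 1, 3, 1, 3),
      effect_line1 = c(0, 0, -20, 5, 3, -12, -16)),
    blood = treatment_plan(
      "blood",
      condition = c("healthy", "pain.opioid", "pain.nonopioid"),
      n_replicates = c(83, 29, 19),
      effect_line1 = c(0, 0, 0))
  )
}

#' Synthetic-data configuration
#'
#' @param presets list of [subset_preset()] objects.
#' @param plans list of [treatment_plan()] objects (may be empty); a plan
#'   is matched to a preset by name and its replicate counts must sum to
#'   the preset's `n`.
#' @param seed integer seed; a fixed seed makes the output byte-identical.
#' @param clamp clip generated percentages to \[0, 100\] (count of clamped
#'   draws is attached as an attribute).
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(presets = default_presets(),
                         plans = default_plans(),
                         seed = 1L, clamp = TRUE) {
  structure(list(presets = presets, plans = plans,
                 seed = as.integer(seed), clamp = isTRUE(clamp)),
            class = "synth_config")
}

## variance decomposition of one preset given its plan (NULL plan -> pure copula)
preset_params <- function(preset, plan) {
  r_tot <- 2 * sin(pi * preset$rho_spearman / 6)
  if (is.null(plan) || all(plan$effect_line1 == 0 & plan$effect_luma == 0)) {
    return(list(mu1 = preset$mean_line1, mu2 = preset$mean_luma,
                s1 = preset$sd_line1, s2 = preset$sd_luma, r = r_tot,
                shift1 = NULL, shift2 = NULL))
  }
  p <- plan$n_replicates / sum(plan$n_replicates)
  m1 <- sum(p * plan$effect_line1)
  m2 <- sum(p * plan$effect_luma)
  v1 <- sum(p * (plan$effect_line1 - m1)^2)
  v2 <- sum(p * (plan$effect_luma - m2)^2)
  v12 <- sum(p * (plan$effect_line1 - m1) * (plan$effect_luma - m2))
  if (v1 >= preset$sd_line1^2 || v2 >= preset$sd_luma^2)
    stop("treatment shifts of preset '", preset$name,
         "' carry more variance than the preset marginals allow")
  s1b <- sqrt(preset$sd_line1^2 - v1)
  s2b <- sqrt(preset$sd_luma^2 - v2)
  ## within-condition correlation: from the target difference SD when given,
  ## otherwise from the total covariance implied by the rank correlation
  if (is.finite(preset$sd_diff)) {
    var_d_within <- preset$sd_diff^2 -
      sum(p * ((plan$effect_line1 - m1) - (plan$effect_luma - m2))^2)
    rb <- (s1b^2 + s2b^2 - var_d_within) / (2 * s1b * s2b)
  } else {
    rb <- (r_tot * preset$sd_line1 * preset$sd_luma - v12) / (s1b * s2b)
  }
  if (!is.finite(rb) || abs(rb) > 1)
    stop("implied within-condition correlation for preset '", preset$name,
         "' is not positive definite (", format(rb), ")")
  list(mu1 = preset$mean_line1 - m1, mu2 = preset$mean_luma - m2,
       s1 = s1b, s2 = s2b, r = rb,
       shift1 = rep(plan$effect_line1, plan$n_replicates),
       shift2 = rep(plan$effect_luma, plan$n_replicates))
}

#' Generate paired methylation samples
#'
#' Draws, per preset, `n` paired (LINE-1, LUMA) percent-methylation values
#' from a bivariate Gaussian copula calibrated to the preset's marginals
#' and correlation; treatment-plan shifts are added before clamping.
#' Output is deterministic under the config seed.
#'
#' @param config a [synth_config()].
#' @return A `data.frame` (the sample sheet) with columns `sample_id`,
#'   `subset`, `treatment`, `line1_pct`, `luma_pct`, `qc_excluded`,
#'   `qc_reason`; the number of clamped draws is in `attr(, "n_clamped")`.
#' @export
generate_samples <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  out <- vector("list", length(config$presets))
  n_clamped <- 0L
  for (i in seq_along(config$presets)) {
    preset <- config$presets[[i]]
    plan <- config$plans[[preset$name]]
    if (!is.null(plan) && sum(plan$n_replicates) != preset$n)
      stop("plan for '", preset$name, "' covers ", sum(plan$n_replicates),
           " replicates but the preset asks for ", preset$n)
    pp <- preset_params(preset, plan)
    z1 <- stats::rnorm(preset$n)
    z2 <- pp$r * z1 + sqrt(1 - pp$r^2) * stats::rnorm(preset$n)
    line1 <- pp$mu1 + pp$s1 * z1
    luma <- pp$mu2 + pp$s2 * z2
    if (!is.null(pp$shift1)) {
      line1 <- line1 + pp$shift1
      luma <- luma + pp$shift2
    }
    if (config$clamp) {
      bad <- line1 < 0 | line1 > 100 | luma < 0 | luma > 100
      n_clamped <- n_clamped + sum(bad)
      line1 <- pmin(pmax(line1, 0), 100)
      luma <- pmin(pmax(luma, 0), 100)
    }
    treatment <- if (is.null(plan)) rep("untreated", preset$n)
                 else rep(plan$condition, plan$n_replicates)
    out[[i]] <- data.frame(
      sample_id = sprintf("%s_%03d", preset$name, seq_len(preset$n)),
      subset = preset$name, treatment = treatment,
      line1_pct = line1, luma_pct = luma,
      qc_excluded = FALSE, qc_reason = "",
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_clamped") <- n_clamped
  res
}

#' Generate pyrogram-level records for a sample sheet
#'
#' Inverts the assay arithmetic: for every sample it emits one HpaII+MfeI
#' and one MspI+MfeI six-step peak-height record whose ratios reproduce
#' the sample's LUMA target, plus duplicate four-CpG LINE-1 reads in two
#' runs reproducing the LINE-1 target, and per-run 0 %/100 % control
#' readings for both assays.  Peak jitter and read scatter are placed
#' antisymmetrically within duplicates so replicate averaging recovers the
#' targets to floating-point accuracy.  A configurable fraction of LUMA
#' record pairs is made to violate each QC rule, to exercise the filters.
#'
#' @param samples sample sheet as from [generate_samples()].
#' @param config a [synth_config()]; its seed drives the jitter.
#' @param qc_violation_frac fraction (per rule) of samples whose LUMA
#'   records violate the low-peak, MspI-ratio, and dispensation-6 rules.
#' @param samples_per_run number of samples grouped into one run.
#' @param line1_controls,luma_controls raw readings of the unmethylated /
#'   fully methylated controls (two-point calibration anchors).
#' @return List with data.frames `pyrograms`, `line1_reads`, `controls`.
#' @export
generate_pyrograms <- function(samples, config = synth_config(),
                               qc_violation_frac = 0,
                               samples_per_run = 24,
                               line1_controls = c(3.37, 75.08),
                               luma_controls = c(0.4, 95.7)) {
  if (any(samples$luma_pct < 0 | samples$luma_pct > 100) ||
      any(samples$line1_pct < 0 | samples$line1_pct > 100))
    stop("target methylation outside [0, 100]")
  set.seed(config$seed + 7L)
  n <- nrow(samples)
  run_of <- ceiling(seq_len(n) / samples_per_run)
  run_id <- sprintf("run%02d", run_of)

  ## --- LUMA: two records per sample ---------------------------------------
  raw_luma <- luma_controls[1] +
    samples$luma_pct / 100 * diff(luma_controls)
  q <- 1 - raw_luma / 100                    # HpaII/MspI quotient
  ratio_m <- pmin(2 + stats::runif(n, -0.5, 0.5), 4.0)
  e <- stats::runif(n, -1, 1)                # antisymmetric dATP/dTTP jitter
  denom <- 10
  mk_rec <- function(reaction, ratio) {
    data.frame(sample_id = samples$sample_id, subset = samples$subset,
               run_id = run_id, reaction = reaction,
               peak1 = denom + e, peak2 = ratio * denom,
               peak3 = denom - e, peak4 = 0.8 * ratio * denom,
               peak5 = 0, peak6 = 0.1 * (denom + e),
               stringsAsFactors = FALSE)
  }
  hpa <- mk_rec("HpaII+MfeI", q * ratio_m)
  msp <- mk_rec("MspI+MfeI", ratio_m)
  if (qc_violation_frac > 0) {
    k <- max(1L, round(qc_violation_frac * n))
    viol <- split(sample.int(n, min(3 * k, n)),
                  rep(c("low", "ratio", "disp6"), length.out = min(3 * k, n)))
    if (length(viol$low))
      for (j in viol$low) {                  # shrink peaks below threshold
        thr <- if (samples$subset[j] == "blood") 2 else 1
        sc <- 0.5 * thr / min(hpa[j, c("peak1", "peak2", "peak3")])
        hpa[j, paste0("peak", 1:6)] <- hpa[j, paste0("peak", 1:6)] * sc
      }
    if (length(viol$ratio))
      msp$peak2[viol$ratio] <- 4.5 * denom   # MspI/MfeI ratio 4.5 > 4.2
    if (length(viol$disp6))
      msp$peak6[viol$disp6] <- 0.4 * msp$peak1[viol$disp6]
  }
  pyro <- rbind(hpa, msp)

  ## --- LINE-1: duplicate reads in two runs --------------------------------
  raw_line1 <- line1_controls[1] +
    samples$line1_pct / 100 * diff(line1_controls)
  run_jit <- abs(stats::rnorm(n, 0, 0.4))
  dup_jit <- abs(stats::rnorm(n, 0, 0.3))
  reads <- vector("list", 4L)
  idx <- 1L
  for (run in 1:2) {
    run_mean <- raw_line1 + ifelse(run == 1, run_jit, -run_jit)
    for (dup in 1:2) {
      read_mean <- run_mean + ifelse(dup == 1, dup_jit, -dup_jit)
      o1 <- stats::rnorm(n, 0, 0.8); o2 <- stats::rnorm(n, 0, 0.8)
      reads[[idx]] <- data.frame(
        sample_id = samples$sample_id, subset = samples$subset,
        run_id = sprintf("%s_L%d", run_id, run),
        cpg1 = read_mean + o1, cpg2 = read_mean - o1,
        cpg3 = read_mean + o2, cpg4 = read_mean - o2,
        conversion_ok = TRUE, stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  line1 <- do.call(rbind, reads)

  ## --- controls ------------------------------------------------------------
  runs_luma <- unique(run_id)
  runs_l1 <- unique(line1$run_id)
  controls <- rbind(
    data.frame(run_id = runs_luma, assay = "LUMA",
               low_pct = luma_controls[1], high_pct = luma_controls[2],
               stringsAsFactors = FALSE),
    data.frame(run_id = runs_l1, assay = "LINE1",
               low_pct = line1_controls[1], high_pct = line1_controls[2],
               stringsAsFactors = FALSE))

  list(pyrograms = pyro, line1_reads = line1, controls = controls)
}
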