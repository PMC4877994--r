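#' Enzyme ratio from a LUMA pyrogram record
#'
#' The LUMA dispensation order is dATPaS (step 1), dGTP+dCTP (step 2),
#' dTTP (step 3), dGTP+dCTP (step 4), water (step 5), dATPaS (step 6).
#' The enzyme/MfeI ratio of a reaction is the fill-in signal of the first
#' dGTP+dCTP dispensation divided by the mean of the dATP and dTTP peaks:
#' `peak2 / mean(peak1, peak3)`.  The second dGTP+dCTP peak and the
#' trailing dATPaS peak are used only in quality control.
#'
#' @param record one pyrogram record: a list or one-row data.frame with a
#'   numeric `peak1..peak6` (or a `peaks` 6-vector) and a `sample_id`.
#' @return The dimensionless ratio.
#' @export
enzyme_ratio <- function(record) {
  p <- record_peaks(record)
  denom <- mean(p[c(1, 3)])
  if (!is.finite(denom) || denom <= 0)
    stop("zero dATP/dTTP denominator in record of sample ",
         record_id(record))
  p[2] / denom
}

record_peaks <- function(record) {
  p <- if (!is.null(record$peaks)) as.numeric(record$peaks)
       else as.numeric(unlist(record[paste0("peak", 1:6)]))
  if (length(p) != 6 || anyNA(p)) stop("a pyrogram record needs 6 peaks")
  if (any(p < 0)) stop("negative peak heights in record of sample ",
                       record_id(record))
  p
}

record_id <- function(record) {
  id <- record$sample_id
  if (is.null(id)) "<unknown>" else as.character(id)[1]
}

#' Raw LUMA percent methylation from a pair of digestion records
#'
#' Computes the HpaII/MspI ratio `(HpaII/MfeI) / (MspI/MfeI)` and converts
#' it to methylation: `(1 - HpaII/MspI) * 100`.  The quotient is 1 for
#' completely unmethylated DNA (0 %) and approaches 0 for completely
#' methylated DNA (100 %).
#'
#' @param hpaII_rec,mspI_rec records of the same sample's HpaII+MfeI and
#'   MspI+MfeI reactions.
#' @return Raw (uncalibrated) % methylation.
#' @export
luma_methylation <- function(hpaII_rec, mspI_rec) {
  if (!identical(record_id(hpaII_rec), record_id(mspI_rec)))
    stop("records belong to different samples: ", record_id(hpaII_rec),
         " vs ", record_id(mspI_rec))
  rh <- enzyme_ratio(hpaII_rec)
  rm_ <- enzyme_ratio(mspI_rec)
  if (rm_ <= 0) stop("MspI/MfeI ratio is zero for sample ",
                     record_id(mspI_rec))
  (1 - rh / rm_) * 100
}

#' LUMA quality-control filter
#'
#' A record pair is excluded when any rule fires: an informative peak
#' (dispensations 1-3) below 2 (blood samples) or below 1 (cell samples);
#' an MspI/MfeI ratio above 4.2; or a dispensation-6 peak of more than
#' 25 % of the dispensation-1 peak.  All comparisons are strict, so a
#' peak-6 fraction of exactly 0.25 is retained.  QC never raises an error
#' on record content; the returned reason enumerates every fired rule.
#'
#' @param hpaII_rec,mspI_rec the sample's paired records.
#' @param subset_kind `"blood"` or `"cell"`, selecting the peak threshold.
#' @return List with `keep` (logical) and `reason` (character, `""` when
#'   retained).
#' @export
luma_qc <- function(hpaII_rec, mspI_rec, subset_kind = c("cell", "blood")) {
  subset_kind <- match.arg(subset_kind)
  thr <- if (subset_kind == "blood") 2 else 1
  reasons <- character(0)
  ph <- record_peaks(hpaII_rec); pm <- record_peaks(mspI_rec)
  if (any(ph[1:3] < thr) || any(pm[1:3] < thr))
    reasons <- c(reasons, sprintf("peak height < %g", thr))
  rm_ <- pm[2] / mean(pm[c(1, 3)])
  if (is.finite(rm_) && rm_ > 4.2)
    reasons <- c(reasons, "MspI/MfeI ratio > 4.2")
  if (ph[6] > 0.25 * ph[1] || pm[6] > 0.25 * pm[1])
    reasons <- c(reasons, "dispensation-6 peak > 25% of peak 1")
  list(keep = length(reasons) == 0L, reason = paste(reasons, collapse = "; "))
}

#' Raw LINE-1 percent methylation from pyrosequencing reads
#'
#' Each read carries the % methylation of the four CpG sites of the
#' LINE-1 promoter amplicon; a read value is their mean.  Duplicate reads
#' within a run are averaged, then run means are averaged across runs.
#' Reads failing the bisulfite-conversion check are dropped (with a
#' message); if none survive, the sample is excluded with an error.
#'
#' @param reads data.frame of one sample's reads with columns
#'   `cpg1..cpg4`, `run_id`, `conversion_ok`.
#' @return Raw % methylation (mean over runs of within-run duplicate means).
#' @export
line1_methylation <- function(reads) {
  stopifnot(nrow(reads) >= 1)
  bad <- !reads$conversion_ok
  if (any(bad)) {
    message(sum(bad), " LINE-1 read(s) dropped: bisulfite conversion check")
    reads <- reads[!bad, , drop = FALSE]
  }
  if (nrow(reads) == 0L)
    stop("all LINE-1 reads failed the conversion check; sample excluded")
  cpg <- as.matrix(reads[, paste0("cpg", 1:4)])
  if (any(cpg < 0 | cpg > 100)) stop("CpG percentages must be in [0, 100]")
  read_means <- rowMeans(cpg)
  run_means <- tapply(read_means, reads$run_id, mean)
  mean(run_means)
}

#' Two-point control calibration
#'
#' Maps a raw % methylation reading onto the 0-100 scale anchored by the
#' run's unmethylated (`low_pct`) and fully methylated (`high_pct`)
#' control readings: `(raw - low) / (high - low) * 100`.  Values that
#' calibrate outside \[0, 100\] are returned unchanged (they keep the
#' linear transform) but flagged via the `"out_of_range"` attribute.
#'
#' @param raw raw % methylation value(s).
#' @param controls list or one-row data.frame with `low_pct`, `high_pct`.
#' @return Calibrated % methylation with attribute `out_of_range`.
#' @export
calibrate_methylation <- function(raw, controls) {
  lo <- controls$low_pct; hi <- controls$high_pct
  if (hi <= lo) stop("invalid controls: high_pct <= low_pct")
  cal <- (raw - lo) / (hi - lo) * 100
  attr(cal, "out_of_range") <- cal < 0 | cal > 100
  cal
}

#' Interassay coefficient of variation of duplicate measurements
#'
#' Per duplicate pair, CV = SD/mean * 100; the report is the arithmetic
#' mean of per-pair CVs.  Pairs with zero mean are skipped with a warning.
#' (A pooled root-mean-square aggregation would weight large-CV pairs more
#' heavily; the arithmetic mean is used here.)
#'
#' @param pairs two-column matrix or data.frame of duplicate values.
#' @return Mean CV in percent.
#' @export
interassay_cv <- function(pairs) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2, nrow(pairs) >= 1)
  m <- rowMeans(pairs)
  zero <- m == 0
  if (any(zero)) {
    warning(sum(zero), " zero-mean pair(s) skipped in CV computation")
    pairs <- pairs[!zero, , drop = FALSE]; m <- m[!zero]
  }
  cv <- apply(pairs, 1, stats::sd) / m * 100
  mean(cv)
}

#' Quantify a full set of pyrogram-level records
#'
#' End-to-end quantification: pairs each sample's LUMA digestion records,
#' applies the QC filter, computes raw LUMA and LINE-1 values, calibrates
#' both against the run controls, and assembles the per-sample sheet.
#' Calibrated values outside \[0, 100\] are kept (flagged), so downstream
#' agreement statistics see the untruncated linear transform.
#'
#' @param pyrograms LUMA record table (`sample_id`, `subset`, `run_id`,
#'   `reaction`, `peak1..peak6`).
#' @param line1_reads LINE-1 read table (`sample_id`, `subset`, `run_id`,
#'   `cpg1..cpg4`, `conversion_ok`).
#' @param controls control table (`run_id`, `assay`, `low_pct`, `high_pct`).
#' @param treatments optional named vector mapping sample_id to treatment.
#' @return A sample sheet `data.frame` (one row per sample) with QC
#'   columns; excluded samples carry `qc_excluded = TRUE` and a reason.
#' @export
quantify_pyrograms <- function(pyrograms, line1_reads, controls,
                               treatments = NULL) {
  ids <- unique(pyrograms$sample_id)
  ctrl_key <- paste(controls$run_id, controls$assay)
  get_ctrl <- function(run, assay) {
    i <- match(paste(run, assay), ctrl_key)
    if (is.na(i)) stop("no ", assay, " controls for run ", run)
    controls[i, ]
  }
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    recs <- pyrograms[pyrograms$sample_id == id, , drop = FALSE]
    hpa <- recs[recs$reaction == "HpaII+MfeI", , drop = FALSE]
    msp <- recs[recs$reaction == "MspI+MfeI", , drop = FALSE]
    if (nrow(hpa) != 1L || nrow(msp) != 1L)
      stop("sample ", id, " needs exactly one HpaII+MfeI and one MspI+MfeI record")
    subset <- hpa$subset
    kind <- if (identical(subset, "blood")) "blood" else "cell"
    qc <- luma_qc(hpa, msp, kind)
    luma_cal <- NA_real_; line1_cal <- NA_real_
    reason <- qc$reason
    if (qc$keep) {
      raw_luma <- luma_methylation(hpa, msp)
      luma_cal <- as.numeric(
        calibrate_methylation(raw_luma, get_ctrl(hpa$run_id, "LUMA")))
    }
    reads <- line1_reads[line1_reads$sample_id == id, , drop = FALSE]
    l1_ok <- tryCatch({
      run_vals <- vapply(split(reads, reads$run_id), function(rr) {
        raw <- line1_methylation(rr)
        as.numeric(calibrate_methylation(raw, get_ctrl(rr$run_id[1], "LINE1")))
      }, numeric(1))
      line1_cal <- mean(run_vals)
      TRUE
    }, error = function(e) {
      reason <<- paste(c(reason[nzchar(reason)], conditionMessage(e)),
                       collapse = "; ")
      FALSE
    })
    excl <- !qc$keep || !l1_ok
    rows[[k]] <- data.frame(
      sample_id = id, subset = subset,
      treatment = if (is.null(treatments)) "" else
        unname(treatments[as.character(id)]),
      line1_pct = line1_cal, luma_pct = luma_cal,
      qc_excluded = excl, qc_reason = reason,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
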