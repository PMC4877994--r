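## shared fixtures built in code

rec <- function(peaks, id = "s1", subset = "MCF7") {
  as.list(c(list(sample_id = id, subset = subset, run_id = "run01"),
            stats::setNames(as.list(peaks), paste0("peak", seq_along(peaks)))))
}

luma_pair <- function(ratio_h, ratio_m, id = "s1") {
  list(h = rec(c(10, ratio_h * 10, 10, 1, 0, 1), id),
       m = rec(c(10, ratio_m * 10, 10, 1, 0, 1), id))
}

## paired sheet from explicit vectors
sheet <- function(line1, luma, subset = "A", treatment = "untreated") {
  data.frame(sample_id = paste0(subset, "_", seq_along(line1)),
             subset = subset, treatment = treatment,
             line1_pct = line1, luma_pct = luma,
             qc_excluded = FALSE, qc_reason = "")
}

default_sheet <- local({
  cache <- NULL
  function(seed = 1) {
    if (is.null(cache) || attr(cache, "seed") != seed) {
      cache <<- generate_samples(synth_config(seed = seed))
      attr(cache, "seed") <<- seed
    }
    cache
  }
})
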