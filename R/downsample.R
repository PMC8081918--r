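#' Downsample reads to a fixed depth without replacement
#'
#' Equalises library size across samples by drawing a uniformly random
#' subset of exactly `n` reads per sample (both strands pooled), seed
#' reproducible. The pipeline default of 7.7 million matches the depth to
#' which the XR-seq time-course libraries are equalised before spot
#' calling.
#'
#' @param reads Read tibble; if a `sample` column is present each sample is
#'   downsampled independently.
#' @param n Target depth (reads per sample).
#' @param seed Optional integer seed.
#' @param allow_short If `TRUE`, samples with fewer than `n` reads are kept
#'   in full with a warning instead of erroring.
#' @return Downsampled read tibble (original order preserved within
#'   sample).
#' @export
downsample_reads <- function(reads, n = 7700000L, seed = NULL,
                             allow_short = FALSE) {
  validate_reads(reads)
  assert_that(n >= 0, "n must be non-negative")
  groups <- if ("sample" %in% names(reads)) {
    split(seq_len(nrow(reads)), reads$sample)
  } else {
    list(all = seq_len(nrow(reads)))
  }
  with_seed_maybe(seed, {
    keep <- lapply(names(groups), function(g) {
      idx <- groups[[g]]
      if (length(idx) < n) {
        if (!allow_short) {
          abort(sprintf(
            "sample '%s' has %d reads, fewer than the downsampling target %d",
            g, length(idx), n))
        }
        warn(sprintf("sample '%s': keeping all %d reads (< target %d)",
                     g, length(idx), n))
        return(idx)
      }
      sort(sample(idx, n))
    })
    reads[sort(unlist(keep)), , drop = FALSE]
  })
}
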