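#' Per-bin thymine + cytosine content
#'
#' Fraction of T+C bases on the strand-specific sequence of each bin (for
#' the minus strand, computed on the reverse complement, i.e. A+G on the
#' plus-strand representation). Pyrimidine content is the substrate
#' availability covariate of the damage/repair bias model. `N` bases are
#' excluded from numerator and denominator; an all-N bin gets `NA`.
#'
#' @param bins Bin tibble (`chrom`, `start`, `end`).
#' @param genome A `DNAStringSet` covering all bins.
#' @param strand `"+"` or `"-"`.
#' @return Numeric vector in `[0, 1]`, one value per bin.
#' @export
compute_tc_content <- function(bins, genome, strand = "+") {
  assert_that(all(bins$chrom %in% names(genome)),
              "genome does not cover all bin chromosomes")
  tc <- numeric(nrow(bins))
  for (ch in unique(bins$chrom)) {
    i <- which(bins$chrom == ch)
    v <- Biostrings::Views(genome[[ch]],
                           IRanges::IRanges(start = bins$start[i] + 1L,
                                            end = bins$end[i]))
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T", "N"))
    pyr <- if (strand == "+") freq[, "C"] + freq[, "T"] else
      freq[, "A"] + freq[, "G"]
    denom <- (bins$end[i] - bins$start[i]) - freq[, "N"]
    tc[i] <- ifelse(denom > 0, pyr / denom, NA_real_)
  }
  tc
}
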