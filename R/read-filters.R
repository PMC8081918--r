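#' Remove duplicate reads sharing identical 5' and 3' end coordinates
#'
#' PCR/optical duplicates are collapsed to a single representative: at most
#' one read is kept per (`chrom`, `start`, `end`, `strand`) key (the strand
#' determines which coordinate is the 5' end, so it is part of the key by
#' default). The first-encountered read of each group is kept and input
#' order is otherwise preserved. When a `sample` column is present,
#' deduplication is per sample.
#'
#' @param reads Read tibble.
#' @param use_strand Include the strand in the duplicate key (default
#'   `TRUE`).
#' @return Deduplicated read tibble; the number of removed reads is
#'   recorded in attribute `n_removed`.
#' @export
deduplicate_reads <- function(reads, use_strand = TRUE) {
  validate_reads(reads)
  key <- c("chrom", "start", "end")
  if (use_strand) key <- c(key, "strand")
  if ("sample" %in% names(reads)) key <- c("sample", key)
  out <- dplyr::distinct(reads, dplyr::across(dplyr::all_of(key)),
                         .keep_all = TRUE)
  attr(out, "n_removed") <- nrow(reads) - nrow(out)
  out
}

#' Filter reads on mapping quality and length
#'
#' Keeps reads with mapping quality of at least `min_mapq` (default 21,
#' i.e. strictly greater than 20) and length within `len_range` inclusive
#' (default 21-31 nt, the excision-product size range). Per-filter
#' rejection counts are reported via `message()` and attached as attribute
#' `rejected`.
#'
#' @param reads Read tibble with a `mapq` column.
#' @param min_mapq Minimum mapping quality kept (inclusive).
#' @param len_range Inclusive `c(min, max)` read length in bp.
#' @param quiet Suppress the rejection-count message.
#' @return Filtered read tibble.
#' @export
filter_reads <- function(reads, min_mapq = 21L, len_range = c(21L, 31L),
                         quiet = FALSE) {
  validate_reads(reads, require = "mapq")
  len <- reads$end - reads$start
  keep_mapq <- reads$mapq >= min_mapq
  keep_len <- len >= len_range[1] & len <= len_range[2]
  rejected <- c(mapq = sum(!keep_mapq),
                length = sum(keep_mapq & !keep_len))
  out <- reads[keep_mapq & keep_len, , drop = FALSE]
  if (!quiet) {
    inform(sprintf(
      "filter_reads: kept %d/%d (rejected %d on MAPQ < %d, %d on length)",
      nrow(out), nrow(reads), rejected[["mapq"]], min_mapq,
      rejected[["length"]]))
  }
  attr(out, "rejected") <- rejected
  out
}
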