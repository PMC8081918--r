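#' Assign reads to genes as transcribed / nontranscribed strand
#'
#' A read overlapping a gene by at least 1 bp is attributed to the
#' transcribed strand (TS) when its strand is opposite the gene's
#' annotated strand (excision products read out the template relationship;
#' `ts_convention = "sense"` flips this) and to the nontranscribed strand
#' (NTS) otherwise. Reads overlapping several genes are counted for each;
#' reads outside genes are ignored.
#'
#' @param reads Read tibble (with `sample` column for multi-sample input).
#' @param genes Gene tibble: `id`, `chrom`, `start`, `end`, `strand`.
#' @param ts_convention `"antisense"` (default) or `"sense"`.
#' @return Tibble `id`, `sample`, `ts_count`, `nts_count` (every gene x
#'   sample combination, zero-filled).
#' @export
assign_reads_to_genes <- function(reads, genes,
                                  ts_convention = c("antisense", "sense")) {
  validate_reads(reads)
  ts_convention <- match.arg(ts_convention)
  if (!"sample" %in% names(reads)) reads$sample <- "sample1"
  samples <- unique(reads$sample)
  hits <- overlap_hits(reads, genes)
  skeleton <- tidyr::expand_grid(id = genes$id, sample = samples)
  if (nrow(hits) == 0) {
    return(dplyr::mutate(skeleton, ts_count = 0L, nts_count = 0L))
  }
  assigned <- tibble::tibble(
    id = genes$id[hits$b],
    sample = reads$sample[hits$a],
    anti = reads$strand[hits$a] != genes$strand[hits$b]
  )
  assigned$is_ts <- if (ts_convention == "antisense") assigned$anti else
    !assigned$anti
  counts <- assigned |>
    dplyr::group_by(.data$id, .data$sample) |>
    dplyr::summarise(ts_count = sum(.data$is_ts),
                     nts_count = sum(!.data$is_ts), .groups = "drop")
  skeleton |>
    dplyr::left_join(counts, by = c("id", "sample")) |>
    dplyr::mutate(ts_count = tidyr::replace_na(.data$ts_count, 0L),
                  nts_count = tidyr::replace_na(.data$nts_count, 0L))
}

#' Count TT/TC dinucleotides per gene and strand
#'
#' Damage-substrate (dipyrimidine) availability per gene: overlapping
#' TT + TC dinucleotide counts on the plus-strand sequence and on its
#' reverse complement (AA + GA on the plus representation).
#'
#' @param genes Gene tibble.
#' @param genome A `DNAStringSet`.
#' @return `genes` with columns `tt_tc_plus`, `tt_tc_minus`.
#' @export
count_tt_tc <- function(genes, genome) {
  res <- matrix(0L, nrow(genes), 2)
  for (ch in unique(genes$chrom)) {
    i <- which(genes$chrom == ch)
    v <- Biostrings::Views(genome[[ch]],
                           IRanges::IRanges(start = genes$start[i] + 1L,
                                            end = genes$end[i]))
    di <- Biostrings::oligonucleotideFrequency(v, width = 2)
    res[i, 1] <- di[, "TT"] + di[, "TC"]
    res[i, 2] <- di[, "AA"] + di[, "GA"]
  }
  dplyr::mutate(genes, tt_tc_plus = res[, 1], tt_tc_minus = res[, 2])
}

#' Gene-level quality control filter
#'
#' Keeps genes that (i) carry at least `min_dinuc` TT or TC dinucleotides
#' on either strand, (ii) are shorter than `max_length` bp (strict), and
#' (iii) accumulate at least `min_reads` reads in total across all
#' samples. Per-criterion rejection tallies are attached as attribute
#' `rejected`.
#'
#' @param genes Gene tibble with `tt_tc_plus`/`tt_tc_minus` (see
#'   [count_tt_tc()]).
#' @param gene_counts Output of [assign_reads_to_genes()] across all
#'   samples.
#' @param min_dinuc,max_length,min_reads Filter thresholds (defaults 10,
#'   300 kb, 10).
#' @return Filtered gene tibble.
#' @export
filter_genes <- function(genes, gene_counts, min_dinuc = 10L,
                         max_length = 300000L, min_reads = 10L) {
  assert_that(all(c("tt_tc_plus", "tt_tc_minus") %in% names(genes)),
              "genes need tt_tc_plus/tt_tc_minus; run count_tt_tc() first")
  totals <- gene_counts |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(total = sum(.data$ts_count + .data$nts_count),
                     .groups = "drop")
  g <- dplyr::left_join(genes, totals, by = "id") |>
    dplyr::mutate(total = tidyr::replace_na(.data$total, 0L))
  pass_dinuc <- g$tt_tc_plus >= min_dinuc | g$tt_tc_minus >= min_dinuc
  pass_len <- (g$end - g$start) < max_length
  pass_reads <- g$total >= min_reads
  out <- genes[pass_dinuc & pass_len & pass_reads, , drop = FALSE]
  attr(out, "rejected") <- c(dinucleotides = sum(!pass_dinuc),
                             length = sum(!pass_len),
                             reads = sum(!pass_reads))
  out
}

#' Reads per kilobase per million mapped reads
#'
#' @param count Read counts.
#' @param length_bp Feature lengths in bp (> 0).
#' @param lib_size Total mapped reads of the sample.
#' @return RPKM values.
#' @export
rpkm <- function(count, length_bp, lib_size) {
  assert_that(all(length_bp > 0), "zero-length feature in RPKM")
  assert_that(all(lib_size > 0), "library sizes must be positive")
  count / (length_bp / 1000) / (lib_size / 1e6)
}

#' Gene-level strand-resolved repair table
#'
#' Combines TS/NTS read assignment, gene QC filtering, RPKM
#' normalisation, and the TS/(TS+NTS) ratio — the gene-level summary of
#' transcription-coupled versus global repair (the ratio is bounded in
#' [0, 1]; 0.5 means no strand preference).
#'
#' @param reads Read tibble across samples.
#' @param genes Gene tibble.
#' @param genome Optional `DNAStringSet` for the dinucleotide QC criterion
#'   (skipped when absent).
#' @param lib_sizes Optional named per-sample mapped-read totals; default
#'   counts reads per sample.
#' @param filter Apply [filter_genes()] (default `TRUE`).
#' @param ts_convention Passed to [assign_reads_to_genes()].
#' @return Tibble per gene x sample: `id`, `sample`, `ts_count`,
#'   `nts_count`, `ts_rpkm`, `nts_rpkm`, `ratio` (`NA` where
#'   TS + NTS = 0).
#' @export
gene_repair_table <- function(reads, genes, genome = NULL, lib_sizes = NULL,
                              filter = TRUE,
                              ts_convention = c("antisense", "sense")) {
  ts_convention <- match.arg(ts_convention)
  if (!"sample" %in% names(reads)) reads$sample <- "sample1"
  if (is.null(lib_sizes)) {
    lib_sizes <- table(reads$sample)
    lib_sizes <- setNames(as.integer(lib_sizes), names(lib_sizes))
  }
  counts <- assign_reads_to_genes(reads, genes, ts_convention)
  if (filter) {
    if (!is.null(genome) && !"tt_tc_plus" %in% names(genes)) {
      genes <- count_tt_tc(genes, genome)
    }
    if (!"tt_tc_plus" %in% names(genes)) {
      warn("no genome/dinucleotide counts: applying length+reads QC only")
      genes$tt_tc_plus <- genes$tt_tc_minus <- .Machine$integer.max
    }
    genes <- filter_genes(genes, counts)
    counts <- counts[counts$id %in% genes$id, , drop = FALSE]
  }
  glen <- setNames(genes$end - genes$start, genes$id)
  counts |>
    dplyr::mutate(
      ts_rpkm = rpkm(.data$ts_count, glen[.data$id],
                     lib_sizes[.data$sample]),
      nts_rpkm = rpkm(.data$nts_count, glen[.data$id],
                      lib_sizes[.data$sample]),
      ratio = dplyr::if_else(.data$ts_count + .data$nts_count > 0,
                             .data$ts_count /
                               (.data$ts_count + .data$nts_count),
                             NA_real_))
}

#' PCA repair trajectory across the time course
#'
#' Ranks genes by variance of `log2(RPKM + 1)` across samples, keeps the
#' `top_n` most variable, centres genes, and computes principal
#' components by SVD. PC1's sign is fixed so that it increases with
#' time-point rank (when time information is supplied), making trajectory
#' plots reproducible.
#'
#' @param repair A long tibble with columns `id`, `sample`, and a value
#'   column (default `rpkm`), e.g. [gene_repair_table()] output with
#'   `rpkm = ts_rpkm + nts_rpkm`.
#' @param value Name of the value column.
#' @param top_n Number of highly variable genes retained (all genes, with
#'   a warning, when fewer are available).
#' @param sample_info Optional tibble `sample`, `time_point`.
#' @param time_levels Optional time-point labels in temporal order.
#' @return Tibble per sample with `PC1`, `PC2` (and `time_point` when
#'   known), carrying attribute `var_explained`; class `repair_pca`.
#' @export
pca_trajectory <- function(repair, value = "rpkm", top_n = 2000L,
                           sample_info = NULL, time_levels = NULL) {
  assert_that(all(c("id", "sample", value) %in% names(repair)),
              "repair needs id, sample, and the value column")
  wide <- repair |>
    dplyr::select(dplyr::all_of(c("id", "sample", value))) |>
    tidyr::pivot_wider(names_from = "sample",
                       values_from = dplyr::all_of(value),
                       values_fill = 0)
  mat <- log2(as.matrix(wide[, -1, drop = FALSE]) + 1)
  assert_that(ncol(mat) >= 3, "need at least 3 samples for a trajectory")
  v <- apply(mat, 1, var)
  assert_that(any(v > 0), "degenerate input: all genes constant")
  if (nrow(mat) < top_n) {
    warn(sprintf("only %d genes available (top_n = %d): using all",
                 nrow(mat), top_n))
    top_n <- nrow(mat)
  }
  keep <- order(v, decreasing = TRUE)[seq_len(top_n)]
  centered <- t(scale(t(mat[keep, , drop = FALSE]), center = TRUE,
                      scale = FALSE))
  pc <- prcomp(t(centered), center = FALSE)
  scores <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  out <- tibble::tibble(sample = colnames(mat),
                        PC1 = scores[, 1],
                        PC2 = if (ncol(scores) > 1) scores[, 2] else 0)
  if (!is.null(sample_info)) {
    out <- dplyr::left_join(out, sample_info, by = "sample")
    if (is.null(time_levels)) time_levels <- unique(sample_info$time_point)
    rank <- match(out$time_point, time_levels)
    if (cor(out$PC1, rank, method = "spearman") < 0) out$PC1 <- -out$PC1
    out$time_rank <- rank
  }
  var_exp <- pc$sdev^2 / sum(pc$sdev^2)
  attr(out, "var_explained") <- var_exp[seq_len(min(2, length(var_exp)))]
  class(out) <- c("repair_pca", class(out))
  out
}
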