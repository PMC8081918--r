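#' Tile chromosomes with consecutive fixed-width bins
#'
#' Segments each chromosome into consecutive `width`-bp bins (0-based
#' half-open, `ceiling(L / width)` bins for a chromosome of length `L`);
#' the final bin of a chromosome whose length is not a multiple of `width`
#' is clipped and flagged `partial`.
#'
#' @param sizes Chromosome sizes: named vector, two-column data frame, or
#'   path to a `chrom.sizes` file.
#' @param width Bin width in bp (default 50, the scale at which repair
#'   super hotspots/coldspots are defined).
#' @return Tibble `chrom`, `start`, `end`, `partial`, `masked` with
#'   attribute `bin_width`.
#' @export
make_bins <- function(sizes, width = 50L) {
  sizes <- as_chrom_sizes(sizes)
  assert_that(width >= 1, "bin width must be >= 1")
  width <- as.integer(width)
  bins <- purrr::map_dfr(names(sizes), function(ch) {
    L <- sizes[[ch]]
    n <- ceiling(L / width)
    start <- (seq_len(n) - 1L) * width
    tibble::tibble(chrom = ch, start = start,
                   end = pmin(start + width, L))
  })
  bins <- dplyr::mutate(bins, partial = (.data$end - .data$start) < width,
                        masked = FALSE)
  attr(bins, "bin_width") <- width
  attr(bins, "sizes") <- sizes
  bins
}

bin_lookup <- function(bins) {
  sizes <- attr(bins, "sizes")
  width <- attr(bins, "bin_width")
  assert_that(!is.null(sizes) && !is.null(width),
              "bins must come from make_bins()")
  n_per <- ceiling(sizes / width)
  offsets <- c(0L, cumsum(n_per))[seq_along(n_per)]
  names(offsets) <- names(n_per)
  list(sizes = sizes, width = width, offsets = offsets)
}

#' Mask bins overlapping blacklist intervals
#'
#' Flags any bin overlapping a blacklist interval (assembly gaps,
#' segmental duplications, repeats, ...) by at least 1 bp; masked bins are
#' excluded from spot calling, model fitting, and bootstrap sampling.
#'
#' @param x A bin tibble from [make_bins()] or a [bin_count_matrix()].
#' @param blacklist Interval tibble (`chrom`, `start`, `end`) or BED path.
#' @return `x` with the `masked` flag set.
#' @export
apply_blacklist <- function(x, blacklist) {
  if (is.character(blacklist)) blacklist <- read_bed(blacklist)
  if (inherits(x, "bin_counts")) {
    x$bins <- apply_blacklist(x$bins, blacklist)
    return(x)
  }
  if (nrow(blacklist) == 0) return(x)
  hits <- overlap_hits(x, blacklist)
  x$masked[unique(hits$a)] <- TRUE
  x
}

# Strand-aware assignment point of a read: its 5' end ("fivep") or
# midpoint.
read_assignment_point <- function(reads, assign = c("fivep", "midpoint")) {
  assign <- match.arg(assign)
  switch(assign,
         fivep = ifelse(reads$strand == "+", reads$start, reads$end - 1L),
         midpoint = (reads$start + reads$end) %/% 2L)
}

#' Count reads of one strand per genomic bin
#'
#' Each strand-matched read increments exactly one bin: the bin containing
#' its strand-aware 5' end (default) or midpoint. Reads on other strands
#' are ignored; reads on unknown chromosomes or with out-of-bounds
#' assignment points are tallied in attribute `skipped`, not errors.
#'
#' @param reads Read tibble.
#' @param bins Bins from [make_bins()].
#' @param strand `"+"` or `"-"`.
#' @param assign `"fivep"` (default) or `"midpoint"`.
#' @return Integer vector of counts, one per bin row, with attribute
#'   `skipped`.
#' @export
count_reads_per_bin <- function(reads, bins, strand,
                                assign = c("fivep", "midpoint")) {
  validate_reads(reads)
  lk <- bin_lookup(bins)
  r <- reads[reads$strand == strand, , drop = FALSE]
  counts <- integer(nrow(bins))
  skipped <- 0L
  if (nrow(r) > 0) {
    pt <- read_assignment_point(r, assign)
    known <- r$chrom %in% names(lk$sizes)
    inb <- known
    inb[known] <- pt[known] >= 0 & pt[known] < lk$sizes[r$chrom[known]]
    skipped <- sum(!inb)
    if (any(inb)) {
      idx <- lk$offsets[r$chrom[inb]] + pt[inb] %/% lk$width + 1L
      tab <- tabulate(idx, nbins = nrow(bins))
      counts <- as.integer(tab)
    }
  }
  attr(counts, "skipped") <- skipped
  counts
}

new_bin_count_matrix <- function(bins, counts, strand, lib_sizes, samples,
                                 damage_type = "64PP", skipped = 0L) {
  structure(
    list(bins = bins, counts = counts, strand = strand,
         lib_sizes = lib_sizes, samples = tibble::as_tibble(samples),
         damage_type = damage_type, skipped = skipped),
    class = "bin_counts"
  )
}

#' Build a strand-specific bin-by-sample count matrix
#'
#' Bins the reads of every sample (see [count_reads_per_bin()]) into one
#' integer matrix for the requested strand. Library sizes default to the
#' per-sample number of strand-matched in-bounds reads, matching the
#' normalisation constant of the Poisson null model.
#'
#' @param reads Read tibble with a `sample` column (plus `time_point`,
#'   `replicate` if available).
#' @param bins Bins from [make_bins()] (after [apply_blacklist()] if
#'   masking is wanted).
#' @param strand `"+"` or `"-"`; the two strands are analysed separately.
#' @param genome Optional `DNAStringSet`; when given, per-bin T+C content
#'   is attached (needed by the null model).
#' @param samples Optional sample sheet; defaults to the distinct
#'   `sample`/`time_point`/`replicate` rows of `reads`.
#' @param lib_sizes Optional named per-sample totals overriding the
#'   default.
#' @param damage_type `"64PP"` or `"CPD"`.
#' @param assign Read-to-bin assignment point, see [count_reads_per_bin()].
#' @return A `bin_counts` object: list with `bins` (tibble, incl. `tc` if
#'   `genome` given), `counts` (bins x samples integer matrix), `strand`,
#'   `lib_sizes`, `samples`, `damage_type`.
#' @export
bin_count_matrix <- function(reads, bins, strand, genome = NULL,
                             samples = NULL, lib_sizes = NULL,
                             damage_type = "64PP",
                             assign = c("fivep", "midpoint")) {
  validate_reads(reads, require = "sample")
  if (is.null(samples)) {
    cols <- intersect(c("sample", "time_point", "replicate"), names(reads))
    samples <- dplyr::distinct(reads[cols])
  }
  assign <- match.arg(assign)
  cols <- lapply(samples$sample, function(s) {
    count_reads_per_bin(reads[reads$sample == s, , drop = FALSE],
                        bins, strand, assign)
  })
  skipped <- sum(vapply(cols, function(x) attr(x, "skipped"), integer(1)))
  counts <- do.call(cbind, cols)
  colnames(counts) <- samples$sample
  if (is.null(lib_sizes)) {
    lib_sizes <- setNames(colSums(counts), samples$sample)
  }
  if (!is.null(genome)) {
    bins <- dplyr::mutate(bins, tc = compute_tc_content(bins, genome, strand))
  }
  new_bin_count_matrix(bins, counts, strand, lib_sizes, samples,
                       damage_type, skipped)
}

#' @export
print.bin_counts <- function(x, ...) {
  cat("<bin_counts>", x$strand, "strand:", nrow(x$counts), "bins x",
      ncol(x$counts), "samples;", sum(x$bins$masked), "masked bins\n")
  invisible(x)
}

#' Tidy a bin count matrix into long format
#'
#' @param x A `bin_counts` object.
#' @param ... Unused.
#' @return Long tibble: one row per bin x sample with `chrom`, `start`,
#'   `end`, `masked`, `strand`, `sample`, `count`.
#' @export
tidy.bin_counts <- function(x, ...) {
  long <- tibble::as_tibble(x$counts)
  long <- dplyr::bind_cols(
    x$bins[rep(seq_len(nrow(x$bins)), 1), c("chrom", "start", "end", "masked")],
    long)
  long <- tidyr::pivot_longer(long, cols = -(1:4), names_to = "sample",
                              values_to = "count")
  dplyr::mutate(long, strand = x$strand, .before = "sample")
}
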