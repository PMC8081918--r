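# Internal helpers shared across modules. Coordinates are 0-based,
# half-open throughout; strands are "+" / "-".

STRANDS <- c("+", "-")
BASES <- c("A", "C", "G", "T")

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# Run `expr` under a fixed RNG seed when `seed` is given, otherwise use the
# current RNG stream. Offsets keep operation streams separate while staying
# within 32-bit integer range.
with_seed_maybe <- function(seed, expr, offset = 0L) {
  if (is.null(seed)) return(expr)
  withr::with_seed(derive_seed(seed, offset), expr)
}

derive_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) * 1009 + offset) %% .Machine$integer.max)
}

#' Validate a tibble of aligned reads
#'
#' Reads are plain tibbles with 0-based half-open coordinates: columns
#' `chrom`, `start`, `end`, `strand`, and optionally `mapq`, `seq`,
#' `sample`, `time_point`, `replicate`.
#'
#' @param reads A data frame of reads.
#' @param require Character vector of additionally required columns.
#' @return The input, invisibly, after validation.
#' @keywords internal
validate_reads <- function(reads, require = character()) {
  needed <- unique(c("chrom", "start", "end", "strand", require))
  missing <- setdiff(needed, names(reads))
  assert_that(length(missing) == 0,
              paste0("reads are missing column(s): ",
                     paste(missing, collapse = ", ")))
  if (nrow(reads) > 0) {
    assert_that(all(reads$start < reads$end),
                "malformed reads: start must be < end (negative lengths)")
    assert_that(all(reads$strand %in% STRANDS),
                "read strand must be '+' or '-'")
  }
  invisible(reads)
}

# Coerce chromosome sizes given as a named vector, two-column data frame, or
# chrom.sizes file path into a named integer vector.
as_chrom_sizes <- function(sizes) {
  if (is.character(sizes) && length(sizes) == 1 && file.exists(sizes)) {
    tab <- readr::read_tsv(sizes, col_names = c("chrom", "size"),
                           col_types = "ci", progress = FALSE)
    sizes <- setNames(tab$size, tab$chrom)
  }
  if (is.data.frame(sizes)) {
    sizes <- setNames(as.integer(sizes[[2]]), as.character(sizes[[1]]))
  }
  assert_that(!is.null(names(sizes)) && all(nzchar(names(sizes))),
              "chromosome sizes must be named")
  assert_that(all(sizes > 0), "chromosome sizes must be positive")
  storage.mode(sizes) <- "integer"
  sizes
}

genome_sizes <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

# Interval tibble (chrom/start/end) -> GRanges; strand optional.
as_granges <- function(x, use_strand = FALSE) {
  strand <- if (use_strand && "strand" %in% names(x)) x$strand else "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

# Any-overlap hits between two interval tibbles (>= min_overlap bp).
overlap_hits <- function(a, b, min_overlap = 1L, use_strand = FALSE) {
  h <- GenomicRanges::findOverlaps(
    as_granges(a, use_strand), as_granges(b, use_strand),
    minoverlap = min_overlap,
    ignore.strand = !use_strand
  )
  tibble::tibble(a = S4Vectors::queryHits(h), b = S4Vectors::subjectHits(h))
}

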