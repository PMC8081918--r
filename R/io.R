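# Plain-text genomics IO. Coordinates follow BED conventions: 0-based,
# half-open. FASTA goes through Biostrings; tab formats through readr.

#' Read / write BED intervals
#'
#' `read_bed()` reads BED3/BED6 into a tibble (`chrom`, `start`, `end`
#' and, when present, `name`, `score`, `strand`); `write_bed()` writes a
#' tibble back, using `mapq` as the score column for read tibbles.
#'
#' @param path File path.
#' @return A tibble of intervals.
#' @export
read_bed <- function(path) {
  tab <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         progress = FALSE, show_col_types = FALSE)
  names6 <- c("chrom", "start", "end", "name", "score", "strand")
  names(tab) <- names6[seq_len(min(ncol(tab), 6))]
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tibble::as_tibble(tab)
}

#' @rdname read_bed
#' @param x Interval or read tibble.
#' @export
write_bed <- function(x, path) {
  score <- x[["score"]] %||% x[["mapq"]] %||% rep(0L, nrow(x))
  out <- tibble::tibble(
    chrom = x$chrom, start = x$start, end = x$end,
    name = x[["name"]] %||% x[["sample"]] %||% rep(".", nrow(x)),
    score = score,
    strand = x[["strand"]] %||% rep(".", nrow(x)))
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read / write BEDPE interaction pairs
#'
#' @param path File path.
#' @return Tibble `chrom1`, `start1`, `end1`, `chrom2`, `start2`, `end2`
#'   (extra columns preserved as `name`/`score`).
#' @export
read_bedpe <- function(path) {
  tab <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(tab) < 6) {
    abort(sprintf("malformed BEDPE '%s': %d column(s), need >= 6",
                  path, ncol(tab)))
  }
  nm <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "name",
          "score")
  names(tab) <- nm[seq_len(min(ncol(tab), 8))]
  for (cc in c("start1", "end1", "start2", "end2")) {
    v <- suppressWarnings(as.integer(tab[[cc]]))
    if (anyNA(v) && !anyNA(tab[[cc]])) {
      abort(sprintf("malformed BEDPE '%s': non-integer %s at line %d",
                    path, cc, which(is.na(v))[1]))
    }
    tab[[cc]] <- v
  }
  tibble::as_tibble(tab)
}

#' @rdname read_bedpe
#' @param x BEDPE tibble.
#' @export
write_bedpe <- function(x, path) {
  readr::write_tsv(
    x[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2")],
    path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read / write chromosome sizes
#'
#' @param path Two-column `chrom.sizes` file.
#' @return Named integer vector.
#' @export
read_chrom_sizes <- function(path) as_chrom_sizes(path)

#' @rdname read_chrom_sizes
#' @param sizes Named sizes vector.
#' @export
write_chrom_sizes <- function(sizes, path) {
  sizes <- as_chrom_sizes(sizes)
  readr::write_tsv(tibble::tibble(chrom = names(sizes),
                                  size = unname(sizes)),
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read / write a genome FASTA
#'
#' @param path FASTA file path.
#' @return A `DNAStringSet`.
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_genome
#' @param genome A `DNAStringSet`.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read aligned reads from BED6
#'
#' BED score is interpreted as MAPQ, per the pipeline's read BED
#' convention.
#'
#' @param path BED6 path.
#' @param sample Optional sample id attached as a column.
#' @return Read tibble.
#' @export
read_reads_bed <- function(path, sample = NULL) {
  tab <- read_bed(path)
  assert_that(all(c("score", "strand") %in% names(tab)),
              "read BED must have 6 columns (score = MAPQ, strand)")
  out <- tibble::tibble(chrom = tab$chrom, start = tab$start, end = tab$end,
                        strand = tab$strand, mapq = as.integer(tab$score))
  if (!is.null(sample)) out$sample <- sample
  validate_reads(out)
  out
}
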