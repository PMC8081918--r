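#' Infer lesion positions from Damage-seq reads
#'
#' Damage-seq primer extension stops before the lesion, so the lesion
#' dinucleotide lies immediately 5' of the read's 5' end on the read's
#' strand: a plus-strand read starting at `s` places it at `[s-2, s)`, a
#' minus-strand read ending at `e` at `[e, e+2)`. The pileup is keyed by
#' the leftmost genomic base of the dinucleotide. Reads whose inferred
#' lesion falls outside its chromosome are tallied in attribute `skipped`.
#'
#' @param reads Read tibble.
#' @param sizes Optional chromosome sizes for bounds checking.
#' @return Pileup tibble `chrom`, `pos`, `strand`, `count`, sorted.
#' @export
infer_damage_positions <- function(reads, sizes = NULL) {
  validate_reads(reads)
  pos <- ifelse(reads$strand == "+", reads$start - 2L, reads$end)
  keep <- pos >= 0
  if (!is.null(sizes)) {
    sizes <- as_chrom_sizes(sizes)
    keep <- keep & reads$chrom %in% names(sizes)
    keep[keep] <- pos[keep] + 2L <= sizes[reads$chrom[keep]]
  }
  out <- tibble::tibble(chrom = reads$chrom[keep], pos = as.integer(pos[keep]),
                        strand = reads$strand[keep]) |>
    dplyr::count(.data$chrom, .data$pos, .data$strand, name = "count") |>
    dplyr::arrange(.data$chrom, .data$pos, .data$strand)
  attr(out, "skipped") <- sum(!keep)
  out
}

#' Call single-nucleotide damage hotspots from a lesion pileup
#'
#' Positions supported by at least `min_reads` reads (inclusive),
#' reported per strand.
#'
#' @param pileup Pileup from [infer_damage_positions()].
#' @param min_reads Minimum supporting reads (default 10).
#' @return Sorted tibble of hotspot positions (`chrom`, `pos`, `strand`,
#'   `count`), where `pos` is the leftmost base of the lesion
#'   dinucleotide.
#' @export
call_damage_hotspots <- function(pileup, min_reads = 10L) {
  pileup |>
    dplyr::filter(.data$count >= min_reads) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$strand)
}

#' Quantify damage over spot sets with flank extensions
#'
#' Sums pileup lesion counts (both strands by default) within each region
#' extended by `extensions` bp at both ends (clipped to the chromosome) —
#' the device used to compare damage levels at repair super hotspots,
#' super coldspots, and random spots despite shallow damage sequencing.
#'
#' @param pileup Lesion pileup.
#' @param regions Region tibble (`chrom`, `start`, `end`; a `category`
#'   column is carried through).
#' @param extensions Flank extensions in bp (default 0, 20, 500).
#' @param sizes Optional chromosome sizes for clipping.
#' @param by_strand Report per-strand counts instead of combined.
#' @return Tibble: one row per region x extension with `damage_count`
#'   (x strand if `by_strand`).
#' @export
quantify_damage_in_regions <- function(pileup, regions,
                                       extensions = c(0L, 20L, 500L),
                                       sizes = NULL, by_strand = FALSE) {
  if (!is.null(sizes)) sizes <- as_chrom_sizes(sizes)
  regions <- dplyr::mutate(regions, region_id = dplyr::row_number())
  pts <- tibble::tibble(chrom = pileup$chrom, start = pileup$pos,
                        end = pileup$pos + 1L)
  purrr::map_dfr(extensions, function(e) {
    ext <- dplyr::mutate(
      regions,
      start = pmax(0L, .data$start - as.integer(e)),
      end = if (is.null(sizes)) .data$end + as.integer(e) else
        pmin(as.integer(sizes[.data$chrom]), .data$end + as.integer(e)))
    hits <- overlap_hits(pts, ext)
    base <- dplyr::mutate(regions, extension = as.integer(e))
    if (nrow(hits) == 0) {
      if (by_strand) {
        return(tidyr::expand_grid(base, strand = STRANDS) |>
                 dplyr::mutate(damage_count = 0L))
      }
      return(dplyr::mutate(base, damage_count = 0L))
    }
    tab <- tibble::tibble(region_id = ext$region_id[hits$b],
                          count = pileup$count[hits$a],
                          strand = pileup$strand[hits$a])
    if (by_strand) {
      agg <- tab |>
        dplyr::group_by(.data$region_id, .data$strand) |>
        dplyr::summarise(damage_count = sum(.data$count), .groups = "drop")
      tidyr::expand_grid(base, strand = STRANDS) |>
        dplyr::left_join(agg, by = c("region_id", "strand")) |>
        dplyr::mutate(damage_count = tidyr::replace_na(.data$damage_count, 0L))
    } else {
      agg <- tab |>
        dplyr::group_by(.data$region_id) |>
        dplyr::summarise(damage_count = sum(.data$count), .groups = "drop")
      base |>
        dplyr::left_join(agg, by = "region_id") |>
        dplyr::mutate(damage_count = tidyr::replace_na(.data$damage_count, 0L))
    }
  })
}

#' Count overlaps between two spot/interval sets
#'
#' Symmetric any-overlap comparison with optional slack: intervals (or
#' positions given as 1-bp intervals) overlap when they come within
#' `slack` bp of each other.
#'
#' @param a,b Interval tibbles (`chrom`, `start`, `end`).
#' @param slack Allowed gap in bp (default 0 = direct overlap).
#' @return List with `n_pairs`, `n_a` / `n_b` (elements of each set in
#'   any pair), and the pair index tibble `pairs`.
#' @export
overlap_spot_sets <- function(a, b, slack = 0L) {
  a2 <- dplyr::mutate(a, start = pmax(0L, .data$start - as.integer(slack)),
                      end = .data$end + as.integer(slack))
  hits <- overlap_hits(a2, b)
  list(n_pairs = nrow(hits),
       n_a = length(unique(hits$a)),
       n_b = length(unique(hits$b)),
       pairs = hits)
}
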