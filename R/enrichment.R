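#' Proportion of spots overlapping an annotation
#'
#' Fraction of spot intervals overlapping at least one annotation
#' interval by at least `min_overlap` bp.
#'
#' @param spots Spot tibble (`chrom`, `start`, `end`).
#' @param annotation Annotation interval tibble.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return A single proportion in `[0, 1]`.
#' @export
overlap_proportion <- function(spots, annotation, min_overlap = 1L) {
  assert_that(nrow(spots) > 0,
              "overlap proportion undefined for an empty spot set")
  if (nrow(annotation) == 0) return(0)
  hits <- overlap_hits(spots, annotation, min_overlap = min_overlap)
  length(unique(hits$a)) / nrow(spots)
}

# Eligible gaps (complement of exclusions) per chromosome.
eligible_gaps <- function(sizes, exclusions = NULL) {
  full <- tibble::tibble(chrom = names(sizes), start = 0L,
                         end = as.integer(sizes))
  if (is.null(exclusions) || nrow(exclusions) == 0) return(full)
  gr_full <- as_granges(full)
  gr_exc <- GenomicRanges::reduce(as_granges(exclusions))
  gaps <- GenomicRanges::setdiff(gr_full, gr_exc, ignore.strand = TRUE)
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gaps)),
                 start = GenomicRanges::start(gaps) - 1L,
                 end = GenomicRanges::end(gaps))
}

#' Sample random regions uniformly over eligible genome space
#'
#' Places `n` intervals of the requested width(s) uniformly over the part
#' of the genome not covered by `exclusions` (blacklisted bins, called
#' spots, ...); every eligible start position is equally likely. Sampled
#' regions never overlap an exclusion; they may overlap each other.
#'
#' @param n Number of regions.
#' @param width Region width(s) in bp (recycled to length `n`).
#' @param sizes Chromosome sizes.
#' @param exclusions Optional interval tibble to avoid.
#' @param chrom Optional per-region chromosome assignment (length `n`);
#'   used to match spot sets chromosome-wise.
#' @param seed Optional seed.
#' @return Region tibble `chrom`, `start`, `end`.
#' @export
sample_random_spots <- function(n, width, sizes, exclusions = NULL,
                                chrom = NULL, seed = NULL) {
  sizes <- as_chrom_sizes(sizes)
  gaps <- eligible_gaps(sizes, exclusions)
  with_seed_maybe(seed, sample_from_gaps(n, width, gaps, chrom))
}

# Core placement: uniform over eligible start positions in precomputed
# gaps. Separated so the bootstrap can reuse the gap computation.
sample_from_gaps <- function(n, width, gaps, chrom = NULL) {
  width <- rep_len(as.integer(width), n)
  if (!is.null(chrom)) chrom <- rep_len(chrom, n)
  out_chrom <- character(n); out_start <- integer(n)
  for (w in unique(width)) {
    i <- which(width == w)
    g <- gaps[(gaps$end - gaps$start) >= w, , drop = FALSE]
    assert_that(nrow(g) > 0,
                sprintf("no eligible space for width-%d regions", w))
    starts_per_gap <- g$end - g$start - w + 1L
    if (is.null(chrom)) {
      gi <- sample.int(nrow(g), length(i), replace = TRUE,
                       prob = starts_per_gap)
    } else {
      gi <- integer(length(i))
      for (ch in unique(chrom[i])) {
        k <- which(chrom[i] == ch)
        gch <- which(g$chrom == ch)
        assert_that(length(gch) > 0,
                    sprintf("no eligible space on %s for width %d", ch, w))
        gi[k] <- gch[sample.int(length(gch), length(k), replace = TRUE,
                                prob = starts_per_gap[gch])]
      }
    }
    out_chrom[i] <- g$chrom[gi]
    out_start[i] <- g$start[gi] +
      floor(runif(length(i)) * starts_per_gap[gi])
  }
  tibble::tibble(chrom = out_chrom, start = as.integer(out_start),
                 end = as.integer(out_start + width))
}

# Fast any-overlap test of regions against a reduced, per-chromosome
# sorted interval index (list of tibbles with sorted start/end).
overlap_flag <- function(regions, index) {
  hit <- logical(nrow(regions))
  for (ch in unique(regions$chrom)) {
    ann <- index[[ch]]
    if (is.null(ann)) next
    i <- which(regions$chrom == ch)
    k <- findInterval(regions$end[i] - 1L, ann$start)
    ok <- k >= 1
    ok[ok] <- ann$end[k[ok]] > regions$start[i][ok]
    hit[i] <- ok
  }
  hit
}

interval_index <- function(x) {
  red <- GenomicRanges::reduce(as_granges(x))
  tab <- tibble::tibble(chrom = as.character(GenomicRanges::seqnames(red)),
                        start = GenomicRanges::start(red) - 1L,
                        end = GenomicRanges::end(red))
  split(tab[, c("start", "end")], tab$chrom)
}

#' Bootstrap overlap enrichment of a spot set against an annotation
#'
#' Compares the observed overlap proportion with a null distribution
#' obtained by repeatedly re-placing the spot set at random genomic
#' positions (widths matched exactly, per-chromosome counts matched by
#' default, exclusions respected). Empirical p-values use the add-one
#' formula `(1 + #(null >= obs)) / (B + 1)` for enrichment, the mirrored
#' lower tail for depletion, and `2 * min(tails)` two-sided; the null mean
#' estimates the genome-average overlap proportion.
#'
#' @param spots Spot tibble.
#' @param annotation Annotation interval tibble.
#' @param sizes Chromosome sizes.
#' @param B Number of bootstrap replicates (>= 100).
#' @param exclusions Optional intervals excluded from random placement.
#' @param match_chrom Match per-chromosome spot counts (default `TRUE`).
#' @param seed Optional seed.
#' @param spot_name,annotation_name Labels carried into the result.
#' @return An `enrichment_result` (one-row tibble: observed proportion,
#'   null mean/sd, empirical p-values, genome coverage fraction) with the
#'   null sample in attribute `null_sample`.
#' @export
bootstrap_enrichment <- function(spots, annotation, sizes, B = 1000L,
                                 exclusions = NULL, match_chrom = TRUE,
                                 seed = NULL, spot_name = "spots",
                                 annotation_name = "annotation") {
  assert_that(B >= 100, "B must be at least 100")
  sizes <- as_chrom_sizes(sizes)
  observed <- overlap_proportion(spots, annotation)
  widths <- spots$end - spots$start
  chrom <- if (match_chrom) spots$chrom else NULL
  index <- interval_index(annotation)
  gaps <- eligible_gaps(sizes, exclusions)
  null <- with_seed_maybe(seed, {
    vapply(seq_len(B), function(b) {
      r <- sample_from_gaps(nrow(spots), widths, gaps, chrom)
      mean(overlap_flag(r, index))
    }, numeric(1))
  })
  p_enrich <- (1 + sum(null >= observed)) / (B + 1)
  p_deplete <- (1 + sum(null <= observed)) / (B + 1)
  coverage <- sum(vapply(index, function(t) sum(as.numeric(t$end - t$start)),
                         numeric(1))) / sum(as.numeric(sizes))
  out <- tibble::tibble(
    spot_set = spot_name, annotation = annotation_name,
    n_spots = nrow(spots), observed = observed,
    null_mean = mean(null), null_sd = stats::sd(null),
    p_enrich = p_enrich, p_deplete = p_deplete,
    p_two_sided = min(1, 2 * min(p_enrich, p_deplete)),
    coverage_fraction = coverage, B = as.integer(B))
  attr(out, "null_sample") <- null
  class(out) <- c("enrichment_result", class(out))
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> %s vs %s: observed %.2f%% | null %.2f%% (genome %.2f%%) | p = %.4g\n",
    x$spot_set, x$annotation, 100 * x$observed, 100 * x$null_mean,
    100 * x$coverage_fraction, x$p_enrich))
  invisible(x)
}

#' Count significant interactions per spot
#'
#' Maps each spot (and each interaction anchor) to its containing
#' `anchor_width`-bp bin and counts interaction records with at least one
#' matching anchor bin. When `random_spots` are supplied, spot counts are
#' compared with the random counts by a one-sided Wilcoxon rank-sum test.
#'
#' @param spots Spot tibble.
#' @param interactions BEDPE tibble (`chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2`).
#' @param anchor_width Anchor bin size in bp (default 40 kb).
#' @param random_spots Optional matched random spot tibble.
#' @return `spots` with an `n_interactions` column; when compared, the
#'   rank-sum p-value in attribute `comparison`.
#' @export
count_interactions_per_spot <- function(spots, interactions,
                                        anchor_width = 40000L,
                                        random_spots = NULL) {
  needed <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  assert_that(all(needed %in% names(interactions)),
              "interactions must be BEDPE-like (chrom1..end2)")
  bin_key <- function(chrom, start, end) {
    paste0(chrom, ":", ((start + end) %/% 2L) %/% anchor_width)
  }
  count_for <- function(sp) {
    key <- bin_key(sp$chrom, sp$start, sp$end)
    k1 <- bin_key(interactions$chrom1, interactions$start1,
                  interactions$end1)
    k2 <- bin_key(interactions$chrom2, interactions$start2,
                  interactions$end2)
    vapply(key, function(k) sum(k1 == k | k2 == k), integer(1),
           USE.NAMES = FALSE)
  }
  spots$n_interactions <- if (nrow(interactions) == 0) {
    integer(nrow(spots))
  } else count_for(spots)
  if (!is.null(random_spots)) {
    rnd <- if (nrow(interactions) == 0) integer(nrow(random_spots)) else
      count_for(random_spots)
    test <- suppressWarnings(
      wilcox.test(spots$n_interactions, rnd, alternative = "greater"))
    attr(spots, "comparison") <- tibble::tibble(
      spot_median = median(spots$n_interactions),
      random_median = median(rnd), p_value = test$p.value)
  }
  spots
}

#' Mean per-base signal over spots
#'
#' Averages a per-base signal track (bedGraph-style intervals) over each
#' spot; uncovered bases count as 0. When a `category` column is present
#' the groups are compared by Kruskal-Wallis (attribute `comparison`).
#'
#' @param spots Spot tibble (optionally with `category`).
#' @param track Signal tibble `chrom`, `start`, `end`, `value`.
#' @return `spots` with a `mean_signal` column.
#' @export
aggregate_signal <- function(spots, track) {
  spots <- dplyr::mutate(spots, .spot_id = dplyr::row_number())
  mean_sig <- numeric(nrow(spots))
  if (nrow(track) > 0) {
    hits <- overlap_hits(spots, track)
    if (nrow(hits) > 0) {
      ov <- pmin(spots$end[hits$a], track$end[hits$b]) -
        pmax(spots$start[hits$a], track$start[hits$b])
      contrib <- tibble::tibble(id = hits$a, w = ov * track$value[hits$b])
      agg <- contrib |>
        dplyr::group_by(.data$id) |>
        dplyr::summarise(sum_w = sum(.data$w), .groups = "drop")
      mean_sig[agg$id] <- agg$sum_w
    }
  }
  spots$mean_signal <- mean_sig / (spots$end - spots$start)
  spots <- dplyr::select(spots, -".spot_id")
  if ("category" %in% names(spots) &&
      length(unique(spots$category)) > 1) {
    kt <- kruskal.test(spots$mean_signal, factor(spots$category))
    attr(spots, "comparison") <- tibble::tibble(
      test = "kruskal-wallis", p_value = kt$p.value)
  }
  spots
}

#' Chromatin-state composition of a spot set
#'
#' Assigns each spot to the state label with the largest overlap (ties
#' broken alphabetically) and reports the fraction of spots per label;
#' spots overlapping no state stay unassigned, so fractions sum to at
#' most 1.
#'
#' @param spots Spot tibble.
#' @param states Labelled annotation tibble `chrom`, `start`, `end`,
#'   `label`.
#' @return Tibble `label`, `n_spots`, `fraction`, covering every label in
#'   `states` (zero rows included).
#' @export
category_composition <- function(spots, states) {
  assert_that("label" %in% names(states), "states need a label column")
  labels <- sort(unique(states$label))
  hits <- overlap_hits(spots, states)
  assigned <- character(0)
  if (nrow(hits) > 0) {
    ov <- pmin(spots$end[hits$a], states$end[hits$b]) -
      pmax(spots$start[hits$a], states$start[hits$b])
    best <- tibble::tibble(spot = hits$a, label = states$label[hits$b],
                           overlap = ov) |>
      dplyr::group_by(.data$spot, .data$label) |>
      dplyr::summarise(overlap = sum(.data$overlap), .groups = "drop") |>
      dplyr::arrange(.data$spot, dplyr::desc(.data$overlap), .data$label) |>
      dplyr::distinct(.data$spot, .keep_all = TRUE)
    assigned <- best$label
  }
  tibble::tibble(label = labels) |>
    dplyr::left_join(
      tibble::tibble(label = assigned) |> dplyr::count(.data$label,
                                                       name = "n_spots"),
      by = "label") |>
    dplyr::mutate(n_spots = tidyr::replace_na(.data$n_spots, 0L),
                  fraction = .data$n_spots / nrow(spots))
}
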