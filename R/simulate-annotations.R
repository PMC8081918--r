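#' Simulate an annotation interval set with controlled spot co-location
#'
#' Emits `n_intervals` intervals of width `width`; a fraction
#' `co_location` of them (rounded) is placed to overlap the given spots
#' (cycling through the spot list, centred on the spot with a small
#' deterministic stagger) and the remainder uniformly at random over the
#' genome. Used to exercise overlap-enrichment machinery with a known
#' ground truth (FIRE-like and superenhancer-like fixtures).
#'
#' @param spots Spot tibble (`chrom`, `start`, `end`).
#' @param sizes Chromosome sizes (any form accepted by [make_bins()]).
#' @param n_intervals Number of annotation intervals.
#' @param width Interval width in bp.
#' @param co_location Fraction in `[0, 1]` of intervals placed on spots.
#' @param seed Optional seed.
#' @param name Annotation name stored in the `name` column.
#' @return Interval tibble `chrom`, `start`, `end`, `name`, sorted.
#' @export
simulate_annotations <- function(spots, sizes, n_intervals = 200L,
                                 width = 1000L, co_location = 0,
                                 seed = NULL, name = "annotation") {
  assert_that(co_location >= 0 && co_location <= 1,
              "co_location must be in [0, 1]")
  sizes <- as_chrom_sizes(sizes)
  n_on <- round(n_intervals * co_location)
  if (n_on > 0) {
    assert_that(nrow(spots) > 0, "co_location > 0 requires spots")
  }
  with_seed_maybe(seed, {
    on <- NULL
    if (n_on > 0) {
      pick <- rep(seq_len(nrow(spots)), length.out = n_on)
      centre <- (spots$start[pick] + spots$end[pick]) %/% 2L
      start <- centre - width %/% 2L
      chrom <- spots$chrom[pick]
      start <- pmax(0L, pmin(start, sizes[chrom] - width))
      on <- tibble::tibble(chrom = chrom, start = as.integer(start),
                           end = as.integer(start + width))
    }
    n_off <- n_intervals - n_on
    off <- NULL
    if (n_off > 0) {
      chrom <- sample(names(sizes), n_off, replace = TRUE,
                      prob = sizes / sum(sizes))
      start <- floor(runif(n_off) * (sizes[chrom] - width))
      off <- tibble::tibble(chrom = chrom, start = as.integer(start),
                            end = as.integer(start + width))
    }
    dplyr::bind_rows(on, off) |>
      dplyr::mutate(name = name) |>
      dplyr::arrange(.data$chrom, .data$start)
  })
}

#' Simulate a chromatin-interaction (BEDPE) list anchored at bins
#'
#' Background interactions connect uniformly random `anchor_width`-bp bin
#' pairs; on top, every spot's containing bin gains `excess_per_spot`
#' extra interactions to random partner bins, emulating the elevated
#' contact frequency of regulatory hubs.
#'
#' @param spots Spot tibble.
#' @param sizes Chromosome sizes.
#' @param n_background Number of background interactions.
#' @param excess_per_spot Extra interactions anchored at each spot's bin.
#' @param anchor_width Interaction anchor resolution in bp (default
#'   40 kb, typical Hi-C bin size).
#' @param seed Optional seed.
#' @return BEDPE-style tibble: `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2`.
#' @export
simulate_interactions <- function(spots, sizes, n_background = 200L,
                                  excess_per_spot = 0L,
                                  anchor_width = 40000L, seed = NULL) {
  sizes <- as_chrom_sizes(sizes)
  n_bins <- pmax(1L, sizes %/% anchor_width)
  random_anchor <- function(n) {
    chrom <- sample(names(sizes), n, replace = TRUE,
                    prob = n_bins / sum(n_bins))
    bin <- floor(runif(n) * n_bins[chrom])
    tibble::tibble(chrom = chrom, start = as.integer(bin * anchor_width),
                   end = as.integer(pmin((bin + 1) * anchor_width,
                                         sizes[chrom])))
  }
  with_seed_maybe(seed, {
    a1 <- random_anchor(n_background)
    a2 <- random_anchor(n_background)
    bedpe <- tibble::tibble(chrom1 = a1$chrom, start1 = a1$start,
                            end1 = a1$end, chrom2 = a2$chrom,
                            start2 = a2$start, end2 = a2$end)
    if (excess_per_spot > 0 && nrow(spots) > 0) {
      idx <- rep(seq_len(nrow(spots)), each = excess_per_spot)
      mid <- (spots$start[idx] + spots$end[idx]) %/% 2L
      bin <- mid %/% anchor_width
      a1 <- tibble::tibble(
        chrom = spots$chrom[idx],
        start = as.integer(bin * anchor_width),
        end = as.integer(pmin((bin + 1) * anchor_width,
                              sizes[spots$chrom[idx]])))
      a2 <- random_anchor(length(idx))
      bedpe <- dplyr::bind_rows(
        bedpe,
        tibble::tibble(chrom1 = a1$chrom, start1 = a1$start, end1 = a1$end,
                       chrom2 = a2$chrom, start2 = a2$start,
                       end2 = a2$end))
    }
    bedpe
  })
}

#' Simulate a non-overlapping gene annotation
#'
#' Places `n_genes` genes of the given lengths non-overlapping (with a
#' minimum gap) along the chromosomes, alternating strands. Optional
#' `early_fold`/`late_fold` columns give each gene a monotone expression
#' trajectory over the time course for [simulate_gene_reads()].
#'
#' @param config A [sim_config()].
#' @param n_genes Number of genes.
#' @param lengths Gene lengths in bp (recycled).
#' @param gap Minimum intergenic gap in bp.
#' @return Gene tibble `id`, `chrom`, `start`, `end`, `strand`.
#' @export
simulate_genes <- function(config, n_genes = 20L, lengths = 2000L,
                           gap = 500L) {
  sizes <- config$chrom_lengths
  lengths <- rep_len(as.integer(lengths), n_genes)
  chroms <- names(sizes)
  out <- vector("list", n_genes)
  ci <- 1L
  cursor <- setNames(rep(as.integer(gap), length(chroms)), chroms)
  for (g in seq_len(n_genes)) {
    placed <- FALSE
    for (try in seq_along(chroms)) {
      ch <- chroms[ci]
      if (cursor[ch] + lengths[g] + gap <= sizes[ch]) {
        out[[g]] <- tibble::tibble(
          id = sprintf("gene%03d", g), chrom = ch,
          start = cursor[[ch]], end = cursor[[ch]] + lengths[g],
          strand = if (g %% 2 == 0) "-" else "+")
        cursor[ch] <- cursor[ch] + lengths[g] + gap
        placed <- TRUE
        ci <- ci %% length(chroms) + 1L
        break
      }
      ci <- ci %% length(chroms) + 1L
    }
    assert_that(placed, "chromosomes too short to place all genes")
  }
  dplyr::bind_rows(out)
}

#' Simulate gene-body XR-seq reads with a controlled TS fraction
#'
#' Per gene and sample, the read count is Poisson with mean
#' `base_mean * fold`, where `fold` interpolates geometrically between the
#' gene's `early_fold` and `late_fold` over the time course (1 when
#' absent). Each read lands uniformly within the gene and is assigned to
#' the transcribed strand with probability `config$ts_fraction_per_gene`
#' (antisense to the gene under the default convention).
#'
#' @param config A [sim_config()].
#' @param genes Gene tibble from [simulate_genes()] (optionally with
#'   `early_fold`/`late_fold`).
#' @param base_mean Baseline reads per gene per sample.
#' @param ts_fraction Overrides `config$ts_fraction_per_gene` when given.
#' @return Read tibble across samples.
#' @export
simulate_gene_reads <- function(config, genes, base_mean = 50,
                                ts_fraction = NULL) {
  ts_fraction <- ts_fraction %||% config$ts_fraction_per_gene
  ranks <- time_rank(config, config$samples$time_point)
  early <- genes[["early_fold"]] %||% rep(1, nrow(genes))
  late <- genes[["late_fold"]] %||% rep(1, nrow(genes))
  with_seed_maybe(config$seed, offset = 6L, {
    purrr::map_dfr(seq_len(nrow(config$samples)), function(j) {
      fold <- planted_fold(early, late, ranks[j])
      n <- rpois(nrow(genes), base_mean * fold)
      idx <- rep.int(seq_len(nrow(genes)), n)
      if (length(idx) == 0) return(NULL)
      len <- sample_int_range(length(idx), config$read_length_range)
      start <- genes$start[idx] +
        floor(runif(length(idx)) * pmax(1, genes$end[idx] -
                                          genes$start[idx] - len))
      is_ts <- runif(length(idx)) < ts_fraction
      gene_strand <- genes$strand[idx]
      strand <- ifelse(is_ts,
                       ifelse(gene_strand == "+", "-", "+"),
                       gene_strand)
      tibble::tibble(chrom = genes$chrom[idx],
                     start = as.integer(start),
                     end = as.integer(start + len),
                     strand = strand, mapq = 60L,
                     sample = config$samples$sample[j],
                     time_point = config$samples$time_point[j],
                     replicate = config$samples$replicate[j])
    })
  })
}
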