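#' Canonical synthetic fixture configuration
#'
#' Two 1-Mb synthetic chromosomes (`chrS1`, `chrS2`), the eight-sample
#' (6-4)PP time course of [default_samples()] with unequal library sizes,
#' twenty planted repair super hotspots (early fold 50, late fold 0.1)
#' and ten super coldspots (the reverse, late fold 40), alternating
#' strands, placed clear of the fixture blacklist. Library sizes are set
#' so that after downsampling to the common depth the baseline is one
#' read per 50-bp bin per strand.
#'
#' @param seed Master seed.
#' @return A [sim_config()].
#' @export
fixture_config <- function(seed = 1L) {
  chroms <- c(chrS1 = 1000000L, chrS2 = 1000000L)
  hot1 <- seq(60000L, by = 90000L, length.out = 10)
  hot2 <- hot1 + 30000L
  cold1 <- seq(15000L, by = 180000L, length.out = 5)
  cold2 <- cold1 + 30000L
  hotspots <- tibble::tibble(
    chrom = rep(c("chrS1", "chrS2"), each = 10),
    start = c(hot1, hot2)) |>
    dplyr::mutate(end = .data$start + 50L,
                  strand = rep_len(STRANDS, 20),
                  early_fold = 50, late_fold = 0.1)
  coldspots <- tibble::tibble(
    chrom = rep(c("chrS1", "chrS2"), each = 5),
    start = c(cold1, cold2)) |>
    dplyr::mutate(end = .data$start + 50L,
                  strand = rep_len(STRANDS, 10),
                  early_fold = 0.1, late_fold = 40)
  sim_config(
    seed = seed, chrom_lengths = chroms, samples = default_samples(),
    library_sizes = setNames(rep_len(c(42000L, 46000L, 50000L), 8),
                             default_samples()$sample),
    hotspots = hotspots, coldspots = coldspots)
}

#' Fixture blacklist intervals
#'
#' Chromosome-start stretches plus an interior segment per chromosome,
#' standing in for assembly gaps and repeat regions.
#'
#' @param sizes Chromosome sizes.
#' @return Interval tibble.
#' @export
fixture_blacklist <- function(sizes) {
  sizes <- as_chrom_sizes(sizes)
  dplyr::bind_rows(
    tibble::tibble(chrom = names(sizes), start = 0L, end = 2000L),
    tibble::tibble(chrom = names(sizes),
                   start = as.integer(sizes %/% 2L + 210L),
                   end = as.integer(sizes %/% 2L + 5210L)))
}

#' Run the full repair-spot pipeline on synthetic data
#'
#' End-to-end composition of every stage on a simulated study: genome and
#' read simulation; deduplication and MAPQ/length filtering; fixed-depth
#' downsampling; 50-bp strand-specific binning with blacklist masking;
#' threshold calling of super hotspots and coldspots; Poisson null-model
#' fit and per-spot enrichment tests; gene-level TS/NTS repair and the
#' PCA trajectory; uniform-damage simulation, lesion pileup, damage
#' hotspot calling, and regional damage quantification; bootstrap overlap
#' enrichment against FIRE-like and superenhancer-like annotations plus
#' interaction counting; and damage-centred sequence context of hotspot
#' reads. Planted-truth recovery is scored with one-bin (50 bp) slack,
#' since 5'-end binning shifts a call up to one bin 5' of its lesion
#' cluster.
#'
#' @param config A [sim_config()], e.g. [fixture_config()].
#' @param downsample_to Per-sample downsampling depth (reads pooled over
#'   strands).
#' @param B Bootstrap replicates for annotation enrichment.
#' @param fire_co_location,se_co_location Planted co-location fractions of
#'   the FIRE-like and superenhancer-like fixture annotations.
#' @param n_random Random spots for damage/context comparisons.
#' @param seed Seed for the analysis-side randomness (downsampling,
#'   bootstrap, random spots); defaults to `config$seed + 1000`.
#' @param stages `"all"` runs every stage; `"spots"` stops after spot
#'   calling, null-model testing, and recovery scoring.
#' @return A `repair_pipeline_result` list; see element names.
#' @export
run_repair_pipeline <- function(config = fixture_config(),
                                downsample_to = 80000L, B = 200L,
                                fire_co_location = 0.035,
                                se_co_location = 0.05,
                                n_random = 100L, seed = NULL,
                                stages = c("all", "spots")) {
  stages <- match.arg(stages)
  seed <- seed %||% derive_seed(config$seed, 1000L)
  sizes <- config$chrom_lengths
  samples <- config$samples

  genome <- simulate_genome(config)
  reads <- simulate_xrseq_reads(config, genome)
  reads <- deduplicate_reads(reads)
  reads <- filter_reads(reads, quiet = TRUE)
  reads <- suppressWarnings(
    downsample_reads(reads, n = downsample_to, seed = derive_seed(seed, 1L),
                     allow_short = TRUE))

  bins <- make_bins(sizes, config$bin_width)
  blacklist <- fixture_blacklist(sizes)
  bins <- apply_blacklist(bins, blacklist)

  bcm <- lapply(STRANDS, function(s) {
    bin_count_matrix(reads, bins, s, genome = genome, samples = samples,
                     damage_type = config$damage_type)
  })
  names(bcm) <- STRANDS

  hot_rule <- hotspot_rule(samples)
  cold_rule <- coldspot_rule(samples)
  early_group <- hot_rule$early_samples
  calls <- purrr::map_dfr(STRANDS, function(s) {
    fit <- fit_null_model(bcm[[s]])
    hot <- call_spots(bcm[[s]], hot_rule)
    cold <- call_spots(bcm[[s]], cold_rule)
    both <- dplyr::bind_rows(hot, cold)
    if (nrow(both) > 0) {
      both <- test_enrichment(bcm[[s]], fit, both, group = early_group)
    }
    attr(both, "fit_glance") <- glance(fit)
    both
  })
  spots <- dplyr::arrange(calls, .data$chrom, .data$start, .data$strand)

  planted <- all_planted_spots(config)
  recovery <- score_recovery(spots, planted, slack = config$bin_width)

  if (stages == "spots") {
    return(structure(
      list(config = config, sizes = sizes, blacklist = blacklist,
           n_reads = nrow(reads), spots = spots, recovery = recovery,
           seed = seed),
      class = "repair_pipeline_result"))
  }

  # gene-level repair and trajectory
  genes <- simulate_genes(config, n_genes = 60L, lengths = 2000L)
  genes <- dplyr::mutate(
    genes,
    early_fold = rep_len(c(20, 1, 0.1), nrow(genes)),
    late_fold = rep_len(c(0.1, 1, 20), nrow(genes)))
  gene_reads <- simulate_gene_reads(config, genes, base_mean = 100)
  repair <- gene_repair_table(gene_reads, genes, genome = genome)
  pca <- pca_trajectory(
    dplyr::mutate(repair, rpkm = .data$ts_rpkm + .data$nts_rpkm),
    top_n = min(2000L, length(unique(repair$id))),
    sample_info = samples, time_levels = config$time_levels)

  # damage landscape: uniform at large scale
  damage_reads <- simulate_uniform_damage_reads(
    config, genome, mean_intensity = 0.01, seed = derive_seed(seed, 2L))
  pileup <- infer_damage_positions(damage_reads, sizes)
  damage_hotspots <- call_damage_hotspots(pileup, min_reads = 10L)
  exclusions <- dplyr::bind_rows(
    blacklist, spots[, c("chrom", "start", "end")])
  random_spots <- sample_random_spots(
    n_random, config$bin_width, sizes, exclusions = exclusions,
    seed = derive_seed(seed, 3L))
  damage_regions <- dplyr::bind_rows(
    spots[, c("chrom", "start", "end", "category")],
    dplyr::mutate(random_spots, category = "random"))
  damage_quant <- quantify_damage_in_regions(pileup, damage_regions,
                                             extensions = c(0L, 20L, 500L),
                                             sizes = sizes)

  # annotation enrichment with planted co-location
  hot_calls <- spots[spots$category == "hotspot",
                     c("chrom", "start", "end")]
  enr <- NULL
  interactions <- NULL
  if (nrow(hot_calls) > 0) {
    fire <- simulate_annotations(hot_calls, sizes, n_intervals = 140L,
                                 width = 1000L,
                                 co_location = fire_co_location,
                                 seed = derive_seed(seed, 4L),
                                 name = "FIRE")
    se <- simulate_annotations(hot_calls, sizes, n_intervals = 20L,
                               width = 2000L, co_location = se_co_location,
                               seed = derive_seed(seed, 5L),
                               name = "superenhancer")
    enr <- dplyr::bind_rows(
      bootstrap_enrichment(hot_calls, fire, sizes, B = B,
                           exclusions = blacklist,
                           seed = derive_seed(seed, 6L),
                           spot_name = "hotspots",
                           annotation_name = "FIRE"),
      bootstrap_enrichment(hot_calls, se, sizes, B = B,
                           exclusions = blacklist,
                           seed = derive_seed(seed, 7L),
                           spot_name = "hotspots",
                           annotation_name = "superenhancer"))
    bedpe <- simulate_interactions(hot_calls, sizes, n_background = 300L,
                                   excess_per_spot = 5L,
                                   seed = derive_seed(seed, 8L))
    interactions <- count_interactions_per_spot(
      hot_calls, bedpe, random_spots = random_spots)
  }

  # sequence context of hotspot-mapped reads
  seqcontext <- NULL
  if (nrow(hot_calls) > 0) {
    in_spot <- overlap_hits(reads, hot_calls)
    spot_reads <- reads[unique(in_spot$a), , drop = FALSE]
    if (nrow(spot_reads) > 0) {
      spot_reads <- add_read_sequences(spot_reads, genome)
      fm_spot <- nucleotide_frequency(spot_reads, config$damage_type,
                                      genome = genome)
      fm_ref <- reference_composition(genome)
      seqcontext <- list(
        freq = fm_spot,
        c_enrichment = compare_c_enrichment(fm_spot, fm_ref))
    }
  }

  structure(
    list(config = config, sizes = sizes, blacklist = blacklist,
         n_reads = nrow(reads), spots = spots, recovery = recovery,
         gene_repair = repair, pca = pca,
         damage = list(pileup_total = sum(pileup$count),
                       hotspots = damage_hotspots,
                       quantification = damage_quant),
         enrichment = enr, interactions = interactions,
         seqcontext = seqcontext, seed = seed),
    class = "repair_pipeline_result")
}

#' Score spot calls against planted truth
#'
#' Strand-matched comparison with positional slack: a planted spot is
#' recovered when a call of its category lies within `slack` bp; a call
#' is a false discovery when no planted spot of its category lies within
#' `slack` bp.
#'
#' @param calls Call tibble (`chrom`, `start`, `end`, `strand`,
#'   `category`).
#' @param planted Planted spot tibble with `category`.
#' @param slack Allowed distance in bp (default 50, one bin).
#' @return Tibble per category: `n_planted`, `n_called`, `n_recovered`,
#'   `recovery`, `n_false`, `fdp`.
#' @export
score_recovery <- function(calls, planted, slack = 50L) {
  purrr::map_dfr(unique(planted$category), function(cat) {
    p <- planted[planted$category == cat, , drop = FALSE]
    cl <- calls[calls$category == cat, , drop = FALSE]
    if (nrow(cl) == 0) {
      return(tibble::tibble(category = cat, n_planted = nrow(p),
                            n_called = 0L, n_recovered = 0L, recovery = 0,
                            n_false = 0L, fdp = NA_real_))
    }
    ov <- overlap_spot_sets(p, cl, slack = slack)
    strand_ok <- ov$pairs[p$strand[ov$pairs$a] == cl$strand[ov$pairs$b], ]
    tibble::tibble(
      category = cat, n_planted = nrow(p), n_called = nrow(cl),
      n_recovered = length(unique(strand_ok$a)),
      recovery = length(unique(strand_ok$a)) / nrow(p),
      n_false = nrow(cl) - length(unique(strand_ok$b)),
      fdp = (nrow(cl) - length(unique(strand_ok$b))) / nrow(cl))
  })
}

#' @export
print.repair_pipeline_result <- function(x, ...) {
  cat("<repair_pipeline_result>\n")
  cat("  reads after QC/downsampling:", x$n_reads, "\n")
  cat("  spot calls:", nrow(x$spots), "(",
      sum(x$spots$category == "hotspot"), "hotspots,",
      sum(x$spots$category == "coldspot"), "coldspots )\n")
  print(x$recovery)
  if (!is.null(x$enrichment)) print(x$enrichment)
  invisible(x)
}

#' Write the canonical synthetic fixture to disk
#'
#' Generates the [fixture_config()] study and writes every input an
#' external run would need: genome FASTA, `chrom.sizes`, per-sample read
#' BED6, gene BED6, blacklist BED, FIRE-like and superenhancer-like
#' annotation BEDs, and an interaction BEDPE.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed.
#' @return Invisibly, a named list of written paths.
#' @export
make_fixture <- function(dir, seed = 1L) {
  config <- fixture_config(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(config)
  reads <- simulate_xrseq_reads(config, genome)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    chrom_sizes = file.path(dir, "genome.chrom.sizes"),
    blacklist = file.path(dir, "blacklist.bed"),
    genes = file.path(dir, "genes.bed"),
    fire = file.path(dir, "fire.bed"),
    superenhancer = file.path(dir, "superenhancer.bed"),
    interactions = file.path(dir, "interactions.bedpe"))
  write_genome(genome, paths$genome)
  write_chrom_sizes(config$chrom_lengths, paths$chrom_sizes)
  write_bed(fixture_blacklist(config$chrom_lengths), paths$blacklist)
  genes <- simulate_genes(config, n_genes = 60L, lengths = 2000L)
  write_bed(dplyr::rename(genes, name = "id"), paths$genes)
  planted_hot <- config$hotspots[, c("chrom", "start", "end")]
  write_bed(simulate_annotations(planted_hot, config$chrom_lengths,
                                 n_intervals = 140L, width = 1000L,
                                 co_location = 0.035,
                                 seed = derive_seed(seed, 21L),
                                 name = "FIRE"), paths$fire)
  write_bed(simulate_annotations(planted_hot, config$chrom_lengths,
                                 n_intervals = 20L, width = 2000L,
                                 co_location = 0.05,
                                 seed = derive_seed(seed, 22L),
                                 name = "superenhancer"),
            paths$superenhancer)
  write_bedpe(simulate_interactions(planted_hot, config$chrom_lengths,
                                    n_background = 300L,
                                    excess_per_spot = 5L,
                                    seed = derive_seed(seed, 23L)),
              paths$interactions)
  for (s in unique(reads$sample)) {
    p <- file.path(dir, paste0("xrseq_", s, ".bed"))
    write_bed(reads[reads$sample == s, , drop = FALSE], p)
    paths[[paste0("reads_", s)]] <- p
  }
  invisible(paths)
}
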