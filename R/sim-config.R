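#' Configuration for the synthetic XR-seq study generator
#'
#' Bundles every knob of the synthetic-data module: a miniature genome,
#' per-sample library sizes over a repair time course, planted early-repair
#' (hotspot) and late-repair (coldspot) bins, and the bias structure of the
#' Poisson count model (per-bin propensity dispersion and pyrimidine-content
#' bias). All downstream generators (`simulate_genome()`,
#' `simulate_xrseq_reads()`, ...) are deterministic functions of this object.
#'
#' The per-bin expected count for sample `j` is
#' `N_j * beta_i * f_j(TC_i) * e_ij`, where `beta_i` is a log-normal bin
#' propensity normalised to sum to one per strand, `f_j` is a smooth
#' monotone function of the bin's T+C fraction, and `e_ij` is the planted
#' enrichment fold (1 outside planted spots). `N_j` (`library_sizes`) is
#' applied per strand, so a sample emits about `2 * N_j` reads in total.
#'
#' Each planted spot carries `lesions_per_spot` canonical damage motifs
#' (CTCA for (6-4)PP, TT for CPD) spread across the interval — real UV
#' damage hotspots contain multiple dipyrimidine sites — and read 3' ends
#' vary by `offset_jitter` nt around `lesion_offset`, mimicking the natural
#' variability of the dual-incision positions. Without both, 5'/3'-end
#' deduplication would cap any single lesion at ~11 distinct reads.
#'
#' @param seed Integer master seed; every generator derives its own stream.
#' @param chrom_lengths Named integer vector of chromosome lengths (bp),
#'   each a positive multiple of `bin_width`.
#' @param samples Tibble with columns `sample`, `time_point`, `replicate`.
#' @param library_sizes Named (by sample) positive integer per-strand
#'   expected read totals.
#' @param bin_width Bin width in bp (default 50).
#' @param hotspots,coldspots Tibbles of planted spots with columns `chrom`,
#'   `start`, `end`, `strand`, `early_fold`, `late_fold`. Hotspots default to
#'   fold 50 at the first time point decaying to 0.1 at the last; coldspots
#'   the reverse. Must be mutually disjoint.
#' @param beta_dispersion Log-scale SD of the log-normal per-bin propensity.
#' @param tc_bias_strength SD of the per-sample slope of
#'   `f_j = exp(b_j * (TC - mean(TC)))`; 0 disables the bias.
#' @param read_length_range Integer `c(min, max)` read length in nt.
#' @param damage_type `"64PP"` or `"CPD"`.
#' @param lesion_offset Distance (nt) of the lesion dinucleotide's 5' base
#'   from the read 3' end (default 6).
#' @param offset_jitter Max deviation (nt) of the realised lesion offset.
#' @param lesions_per_spot Number of damage motifs planted per spot.
#' @param flank_c_fraction Cytosine weight of the 6-bp flanks around planted
#'   motifs (remaining mass split over A/G/T).
#' @param flank_width Width (bp) of the cytosine-weighted flank on each side
#'   of a planted motif.
#' @param base_probs Background base probabilities, named A/C/G/T.
#' @param ts_fraction_per_gene Probability that a gene-overlapping read is
#'   assigned to the transcribed strand.
#' @param time_levels Time-point labels in temporal order (defaults to
#'   order of first appearance in `samples`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chrS1 = 100000L),
                       samples = default_samples(),
                       library_sizes = NULL,
                       bin_width = 50L,
                       hotspots = NULL,
                       coldspots = NULL,
                       beta_dispersion = 0.6,
                       tc_bias_strength = 1,
                       read_length_range = c(21L, 31L),
                       damage_type = c("64PP", "CPD"),
                       lesion_offset = 6L,
                       offset_jitter = 2L,
                       lesions_per_spot = 5L,
                       flank_c_fraction = 0.4,
                       flank_width = 6L,
                       base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       ts_fraction_per_gene = 0.5,
                       time_levels = NULL) {
  damage_type <- match.arg(damage_type)
  chrom_lengths <- as_chrom_sizes(chrom_lengths)
  assert_that(all(chrom_lengths %% bin_width == 0),
              "all chromosome lengths must be positive multiples of bin_width")
  samples <- tibble::as_tibble(samples)
  assert_that(all(c("sample", "time_point", "replicate") %in% names(samples)),
              "samples needs columns sample, time_point, replicate")
  assert_that(!anyDuplicated(samples$sample), "sample ids must be unique")
  if (is.null(time_levels)) time_levels <- unique(samples$time_point)
  assert_that(all(samples$time_point %in% time_levels),
              "every time_point must appear in time_levels")
  if (is.null(library_sizes)) {
    library_sizes <- setNames(rep(50000L, nrow(samples)), samples$sample)
  }
  if (is.null(names(library_sizes))) {
    names(library_sizes) <- samples$sample
  }
  assert_that(all(samples$sample %in% names(library_sizes)),
              "library_sizes must cover every sample")
  assert_that(all(library_sizes > 0), "library_sizes must all be positive")

  empty_spots <- tibble::tibble(chrom = character(), start = integer(),
                                end = integer(), strand = character(),
                                early_fold = double(), late_fold = double())
  hotspots <- tibble::as_tibble(hotspots %||% empty_spots)
  coldspots <- tibble::as_tibble(coldspots %||% empty_spots)
  check_spots <- function(sp, what) {
    if (nrow(sp) == 0) return(sp)
    assert_that(all(c("chrom", "start", "end", "strand") %in% names(sp)),
                paste(what, "need chrom/start/end/strand columns"))
    if (is.null(sp[["early_fold"]])) {
      sp$early_fold <- if (what == "hotspots") 50 else 0.1
    }
    if (is.null(sp[["late_fold"]])) {
      sp$late_fold <- if (what == "hotspots") 0.1 else 50
    }
    bad <- !sp$chrom %in% names(chrom_lengths) |
      sp$start < 0 | sp$end > chrom_lengths[sp$chrom]
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf("planted interval %s:%d-%d outside chromosome bounds",
                    sp$chrom[i], sp$start[i], sp$end[i]))
    }
    sp
  }
  hotspots <- check_spots(hotspots, "hotspots")
  coldspots <- check_spots(coldspots, "coldspots")
  if (nrow(hotspots) > 0 && nrow(coldspots) > 0) {
    assert_that(nrow(overlap_hits(hotspots, coldspots)) == 0,
                "planted hotspots and coldspots must be disjoint")
  }
  assert_that(length(read_length_range) == 2 &&
                read_length_range[1] <= read_length_range[2],
              "read_length_range must be c(min, max)")
  assert_that(flank_c_fraction >= 0 && flank_c_fraction <= 1,
              "flank_c_fraction must be in [0, 1]")
  assert_that(ts_fraction_per_gene >= 0 && ts_fraction_per_gene <= 1,
              "ts_fraction_per_gene must be in [0, 1]")
  base_probs <- base_probs[BASES] / sum(base_probs)

  structure(
    list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
         samples = samples, library_sizes = library_sizes,
         bin_width = as.integer(bin_width),
         hotspots = hotspots, coldspots = coldspots,
         beta_dispersion = beta_dispersion,
         tc_bias_strength = tc_bias_strength,
         read_length_range = as.integer(read_length_range),
         damage_type = damage_type,
         lesion_offset = as.integer(lesion_offset),
         offset_jitter = as.integer(offset_jitter),
         lesions_per_spot = as.integer(lesions_per_spot),
         flank_c_fraction = flank_c_fraction,
         flank_width = as.integer(flank_width),
         base_probs = base_probs,
         ts_fraction_per_gene = ts_fraction_per_gene,
         time_levels = time_levels),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$damage_type, "\n")
  cat("  genome:", length(x$chrom_lengths), "chromosome(s),",
      sum(as.numeric(x$chrom_lengths)), "bp;", x$bin_width, "bp bins\n")
  cat("  samples:", nrow(x$samples), "(",
      paste(unique(x$samples$time_point), collapse = ", "), ")\n")
  cat("  planted:", nrow(x$hotspots), "hotspot(s),",
      nrow(x$coldspots), "coldspot(s)\n")
  invisible(x)
}

#' Default XR-seq time-course sample sheet
#'
#' Eight samples mirroring a (6-4)PP repair time course: duplicated 1-min
#' and 4-h libraries (the samples the hotspot/coldspot rule uses) plus
#' single 5-min, 20-min, 1-h, and 2-h libraries.
#'
#' @return Tibble with columns `sample`, `time_point`, `replicate`.
#' @export
default_samples <- function() {
  tibble::tibble(
    sample = c("t1min_r1", "t1min_r2", "t5min_r1", "t20min_r1",
               "t1h_r1", "t2h_r1", "t4h_r1", "t4h_r2"),
    time_point = c("1min", "1min", "5min", "20min", "1h", "2h", "4h", "4h"),
    replicate = c(1L, 2L, 1L, 1L, 1L, 1L, 1L, 2L)
  )
}

# 0 for the earliest time point, 1 for the latest; used for geometric
# interpolation of planted folds across the course.
time_rank <- function(config, time_point) {
  lv <- config$time_levels
  if (length(lv) == 1) return(rep(0, length(time_point)))
  (match(time_point, lv) - 1) / (length(lv) - 1)
}

# Planted fold for one spot at one time point: geometric interpolation
# between early_fold (rank 0) and late_fold (rank 1).
planted_fold <- function(early_fold, late_fold, rank) {
  early_fold^(1 - rank) * late_fold^rank
}

all_planted_spots <- function(config) {
  dplyr::bind_rows(
    dplyr::mutate(config$hotspots, category = "hotspot"),
    dplyr::mutate(config$coldspots, category = "coldspot")
  )
}
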