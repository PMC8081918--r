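# Shared constructors for the test suite. Everything is generated in code;
# no binary fixtures.

# A small time-course configuration: one chromosome, two 1-min and two 4-h
# replicates plus middle time points.
tiny_samples <- function() {
  tibble::tibble(
    sample = c("e1", "e2", "m1", "l1", "l2"),
    time_point = c("1min", "1min", "1h", "4h", "4h"),
    replicate = c(1L, 2L, 1L, 1L, 2L))
}

tiny_config <- function(seed = 1L, chrom_len = 50000L, n = 5000L, ...) {
  sim_config(seed = seed, chrom_lengths = c(chrS1 = as.integer(chrom_len)),
             samples = tiny_samples(),
             library_sizes = setNames(rep(as.integer(n), 5),
                                      tiny_samples()$sample),
             ...)
}

# Null-model testbed: 10,000 bins (500 kb), 6 samples, mean depth `depth`.
null_model_config <- function(seed, depth = 5, n_bins = 10000L, ...) {
  samp <- tibble::tibble(sample = paste0("s", 1:6),
                         time_point = paste0("t", 1:6), replicate = 1L)
  len <- n_bins * 50L
  sim_config(seed = seed, chrom_lengths = c(chrS1 = len), samples = samp,
             library_sizes = setNames(rep(as.integer(depth * n_bins), 6),
                                      samp$sample), ...)
}

# Hand-built read tibble.
mk_reads <- function(start, end, strand = "+", chrom = "chrS1", mapq = 60L,
                     sample = NULL, seq = NULL) {
  n <- max(length(start), length(end))
  out <- tibble::tibble(chrom = rep_len(chrom, n),
                        start = as.integer(rep_len(start, n)),
                        end = as.integer(rep_len(end, n)),
                        strand = rep_len(strand, n),
                        mapq = as.integer(rep_len(mapq, n)))
  if (!is.null(sample)) out$sample <- rep_len(sample, n)
  if (!is.null(seq)) out$seq <- rep_len(seq, n)
  out
}

# Independent per-bin re-evaluation of a threshold rule, used as the
# brute-force oracle for call_spots().
oracle_call <- function(x, rule) {
  hits <- integer(0)
  for (i in seq_len(nrow(x$counts))) {
    if (x$bins$masked[i]) next
    e <- x$counts[i, rule$early_samples]
    l <- x$counts[i, rule$late_samples]
    ok <- if (rule$category == "hotspot") {
      all(e >= rule$min_early) && all(l <= rule$max_late)
    } else {
      all(e <= rule$max_early) && all(l >= rule$min_late)
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# Random bin_counts object for oracle tests (counts only, no genome).
random_bin_counts <- function(n_bins, samples = tiny_samples(),
                              lambda = 4, mask_frac = 0.05) {
  counts <- matrix(rpois(n_bins * nrow(samples), lambda), nrow = n_bins,
                   dimnames = list(NULL, samples$sample))
  bins <- make_bins(c(chrS1 = n_bins * 50L), 50L)
  bins$masked <- runif(n_bins) < mask_frac
  repairspot:::new_bin_count_matrix(
    bins = bins, counts = counts, strand = "+",
    lib_sizes = setNames(colSums(counts), samples$sample),
    samples = samples)
}
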