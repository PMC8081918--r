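# Synthetic-data generator: planted structure, count-model fidelity,
# determinism, conservation.

test_that("simulate_genome plants canonical motifs and is deterministic", {
  cfg <- sim_config(
    seed = 7, chrom_lengths = c(chrS1 = 10000L),
    samples = tiny_samples(),
    library_sizes = setNames(rep(200L, 5), tiny_samples()$sample),
    hotspots = tibble::tibble(chrom = "chrS1", start = 500L, end = 550L,
                              strand = "+", early_fold = 50,
                              late_fold = 0.1))
  g <- simulate_genome(cfg)
  expect_equal(unname(Biostrings::width(g)), 10000L)
  spot_seq <- as.character(Biostrings::subseq(g[["chrS1"]], 501, 552))
  expect_true(grepl("CTCA", spot_seq))
  sites <- planted_damage_sites(g)
  expect_true(all(sites$lesion_pos >= 500 & sites$lesion_pos < 550))
  # deterministic
  expect_identical(as.character(simulate_genome(cfg)), as.character(g))

  # CPD plants TT on the requested strand (minus here)
  cfg_cpd <- sim_config(
    seed = 7, chrom_lengths = c(chrS1 = 10000L), samples = tiny_samples(),
    library_sizes = setNames(rep(200L, 5), tiny_samples()$sample),
    damage_type = "CPD",
    hotspots = tibble::tibble(chrom = "chrS1", start = 500L, end = 550L,
                              strand = "-", early_fold = 50,
                              late_fold = 0.1))
  g2 <- simulate_genome(cfg_cpd)
  sites2 <- planted_damage_sites(g2)
  # TT on the minus strand reads AA on the plus representation
  for (p in sites2$lesion_pos) {
    expect_equal(as.character(Biostrings::subseq(g2[["chrS1"]], p + 1,
                                                 p + 2)), "AA")
  }
})

test_that("planted interval outside chromosome bounds errors", {
  expect_error(
    sim_config(seed = 1, chrom_lengths = c(chrS1 = 1000L),
               samples = tiny_samples(),
               library_sizes = setNames(rep(10L, 5),
                                        tiny_samples()$sample),
               hotspots = tibble::tibble(chrom = "chrS1", start = 950L,
                                         end = 1050L, strand = "+")),
    "outside chromosome bounds")
})

test_that("homogeneous null gives flat Poisson counts at mean N/bins", {
  cfg <- tiny_config(seed = 3, chrom_len = 100000L, n = 20000L,
                     beta_dispersion = 1e-9, tc_bias_strength = 0)
  g <- simulate_genome(cfg)
  y <- simulate_bin_counts(cfg, g)[["+"]]$counts
  n_bins <- nrow(y)
  target <- 20000 / n_bins
  se <- sqrt(target / length(y))
  expect_lt(abs(mean(y) - target), 3 * se)
})

test_that("expected read totals scale linearly in library size", {
  mk <- function(n) {
    cfg <- tiny_config(seed = 5, chrom_len = 1000000L, n = n)
    g <- simulate_genome(cfg)
    sum(simulate_bin_counts(cfg, g)[["+"]]$counts)
  }
  r <- mk(2000000L) / mk(1000000L)
  expect_lt(abs(r - 2), 0.02)
})

test_that("planted hotspot bins exceed the null 99.9th percentile", {
  hits <- vapply(1:25, function(s) {
    cfg <- tiny_config(
      seed = s, chrom_len = 50000L, n = 1000L,
      hotspots = tibble::tibble(chrom = "chrS1", start = 25000L,
                                end = 25050L, strand = "+",
                                early_fold = 50, late_fold = 0.1))
    g <- simulate_genome(cfg)
    y <- simulate_bin_counts(cfg, g)[["+"]]$counts
    spot_bin <- 25000 / 50 + 1
    early <- which(cfg$samples$time_point == "1min")
    null_counts <- y[-spot_bin, early]
    all(y[spot_bin, early] > quantile(null_counts, 0.999))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("count model passes a chi-square GOF test against its Poisson law", {
  pass <- vapply(1:20, function(s) {
    cfg <- tiny_config(seed = 100 + s, chrom_len = 100000L, n = 10000L)
    g <- simulate_genome(cfg)
    x <- simulate_bin_counts(cfg, g)[["+"]]
    lam <- attr(x, "truth")$lambda
    # 50 strata of pooled expected counts vs observed totals
    ord <- order(lam)
    strata <- cut(seq_along(ord), 50, labels = FALSE)
    obs <- tapply(as.vector(x$counts)[ord], strata, sum)
    exp <- tapply(as.vector(lam)[ord], strata, sum)
    stat <- sum((obs - exp)^2 / exp)
    stat < qchisq(0.99, df = 50)
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("reads are conserved, in bounds, and deterministic", {
  cfg <- tiny_config(seed = 9, chrom_len = 20000L, n = 2000L)
  g <- simulate_genome(cfg)
  r1 <- simulate_xrseq_reads(cfg, g)
  r2 <- simulate_xrseq_reads(cfg, g)
  expect_identical(r1, r2)
  expect_true(all(r1$start >= 0 & r1$end <= 20000))
  expect_true(all(r1$end - r1$start >= 21 & r1$end - r1$start <= 31))
  expect_setequal(unique(r1$sample), tiny_samples()$sample)
  # per-bin totals equal the emitted read count per sample/strand
  bins <- make_bins(cfg$chrom_lengths, 50)
  for (s in c("+", "-")) {
    sub <- r1[r1$sample == "e1" & r1$strand == s, ]
    cts <- count_reads_per_bin(sub, bins, s)
    expect_equal(sum(cts), nrow(sub))
  }
})

test_that("excessive planted folds raise a configuration error", {
  cfg <- tiny_config(
    seed = 2, chrom_len = 5000L, n = 10L,
    hotspots = tibble::tibble(chrom = "chrS1", start = 1000L, end = 1050L,
                              strand = "+", early_fold = 5000,
                              late_fold = 5000))
  g <- simulate_genome(cfg)
  expect_error(simulate_bin_counts(cfg, g), "10x library size")
})

test_that("damage read simulation follows the Poisson intensity", {
  cfg <- tiny_config(seed = 4, chrom_len = 50000L)
  g <- simulate_genome(cfg)
  # strong single position: pileup >= 10 with probability > 0.999
  prof <- tibble::tibble(chrom = "chrS1", pos = c(1000L, 2000L),
                         strand = c("+", "-"), intensity = 50)
  stopifnot(ppois(9, 50) < 0.001)  # oracle for the assertion below
  reads <- simulate_damage_reads(cfg, g, prof)
  pu <- infer_damage_positions(reads, cfg$chrom_lengths)
  expect_true(all(pu$count >= 10))
  expect_setequal(pu$pos, c(1000L, 2000L))
  # conservation: pileup total equals emitted reads
  expect_equal(sum(pu$count), nrow(reads))

  # uniform low intensity: no position reaches 10 reads
  ur <- simulate_uniform_damage_reads(cfg, g, mean_intensity = 0.01)
  pu2 <- infer_damage_positions(ur, cfg$chrom_lengths)
  # P(Pois(0.01) >= 10) ~ 2.6e-25 per position; 1e5 positions -> none
  expect_equal(nrow(call_damage_hotspots(pu2, 10)), 0)

  # empty profile -> empty read set
  empty <- simulate_damage_reads(cfg, g, prof[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("annotation co-location is honoured exactly by construction", {
  # sparse spots so chance overlap of the random half is negligible
  sizes <- c(chrS1 = 20000000L)
  spots <- tibble::tibble(chrom = "chrS1",
                          start = seq(10000L, by = 95000L,
                                      length.out = 210),
                          end = seq(10000L, by = 95000L,
                                    length.out = 210) + 50L)
  ann <- simulate_annotations(spots, sizes, n_intervals = 200, width = 200,
                              co_location = 0.5, seed = 8)
  hits <- overlap_spot_sets(spots, ann)
  expect_equal(hits$n_b, 100)  # exactly half the intervals sit on spots
  # full co-location with wide annotations covers every targeted spot
  ann1 <- simulate_annotations(spots[1:20, ], sizes, n_intervals = 20,
                               width = 200, co_location = 1, seed = 9)
  expect_equal(overlap_proportion(spots[1:20, ], ann1), 1)
  expect_error(simulate_annotations(spots, sizes, co_location = 1.5),
               "co_location")
})

test_that("gene read simulation respects the TS fraction", {
  cfg <- tiny_config(seed = 6, chrom_len = 100000L,
                     ts_fraction_per_gene = 1)
  genes <- simulate_genes(cfg, n_genes = 10, lengths = 3000L)
  expect_true(all(genes$end <= 100000))
  reads <- simulate_gene_reads(cfg, genes, base_mean = 40)
  counts <- assign_reads_to_genes(reads, genes)
  expect_true(all(counts$nts_count == 0))
  expect_gt(sum(counts$ts_count), 0)

  cfg5 <- tiny_config(seed = 6, chrom_len = 100000L,
                      ts_fraction_per_gene = 0.5)
  reads5 <- simulate_gene_reads(cfg5, genes, base_mean = 200)
  counts5 <- assign_reads_to_genes(reads5, genes)
  ratio <- with(counts5, ts_count / (ts_count + nts_count))
  se <- 0.5 / sqrt(sum(counts5$ts_count + counts5$nts_count) /
                     length(ratio)) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio, na.rm = TRUE) - 0.5), 3 * max(se, 0.01))
})
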