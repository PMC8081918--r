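# Overlap proportions, random-region sampling, the bootstrap null,
# interaction counting, signal aggregation, and state composition.

test_that("overlap proportion handles the degenerate layouts", {
  spots <- tibble::tibble(chrom = "chrS1",
                          start = c(100L, 200L, 300L, 400L),
                          end = c(150L, 250L, 350L, 450L))
  inside <- tibble::tibble(chrom = "chrS1", start = 0L, end = 1000L)
  expect_equal(overlap_proportion(spots, inside), 1)
  outside <- tibble::tibble(chrom = "chrS1", start = 5000L, end = 6000L)
  expect_equal(overlap_proportion(spots, outside), 0)
  expect_error(overlap_proportion(spots[0, ], inside), "empty spot set")

  # proportion by construction: 47 of 200 spots covered
  many <- tibble::tibble(chrom = "chrS1",
                         start = seq(0L, by = 1000L, length.out = 200))
  many$end <- many$start + 50L
  ann <- many[1:47, ]
  expect_equal(overlap_proportion(many, ann), 0.235)

  # invariant under annotation order and interval splitting
  ann_perm <- ann[sample(nrow(ann)), ]
  expect_equal(overlap_proportion(many, ann_perm), 0.235)
  split_ann <- rbind(
    dplyr::mutate(ann, end = start + 20L),
    dplyr::mutate(ann, start = start + 20L))
  expect_equal(overlap_proportion(many, split_ann), 0.235)
})

test_that("random spots land uniformly in eligible space only", {
  sizes <- c(chrS1 = 1000L)
  # exclusions leave a single 50-bp slot
  excl <- tibble::tibble(chrom = "chrS1", start = c(0L, 450L),
                         end = c(400L, 1000L))
  r <- sample_random_spots(1, 50, sizes, exclusions = excl, seed = 1)
  expect_equal(c(r$start, r$end), c(400L, 450L))
  expect_error(sample_random_spots(1, 80, sizes, exclusions = excl),
               "no eligible space")

  # determinism
  r1 <- sample_random_spots(20, 50, c(chrS1 = 100000L), seed = 3)
  r2 <- sample_random_spots(20, 50, c(chrS1 = 100000L), seed = 3)
  expect_identical(r1, r2)

  # per-base placement uniformity over eligible space (chi-square)
  sizes2 <- c(chrS1 = 2000L)
  excl2 <- tibble::tibble(chrom = "chrS1", start = 900L, end = 1100L)
  draws <- sample_random_spots(20000, 10, sizes2, exclusions = excl2,
                               seed = 4)
  expect_true(all(draws$end <= 900 | draws$start >= 1100))
  # expected bin masses follow the eligible start positions
  eligible <- c(0:890, 1100:1990)
  breaks <- seq(0, 2000, by = 100)
  expected <- table(cut(eligible, breaks))
  observed <- table(cut(draws$start, breaks))
  keep <- expected > 0
  expect_gt(chisq.test(observed[keep],
                       p = expected[keep] / sum(expected))$p.value, 0.01)
})

test_that("bootstrap enrichment is exact under full co-location", {
  sizes <- c(chrS1 = 500000L)
  spots <- sample_random_spots(50, 50, sizes, seed = 11)
  ann <- simulate_annotations(spots, sizes, n_intervals = 50, width = 500,
                              co_location = 1, seed = 12)
  e <- bootstrap_enrichment(spots, ann, sizes, B = 200, seed = 13)
  expect_equal(e$observed, 1)
  expect_equal(e$p_enrich, 1 / 201)
  expect_gt(e$p_enrich, 0)          # add-one formula never yields 0
  expect_equal(length(attr(e, "null_sample")), 200)
})

test_that("the bootstrap null mean estimates annotation coverage", {
  sizes <- c(chrS1 = 1000000L, chrS2 = 1000000L)
  spots <- sample_random_spots(100, 50, sizes, seed = 21)
  ann <- simulate_annotations(spots[0, ], sizes, n_intervals = 100,
                              width = 2000, co_location = 0, seed = 22)
  e <- bootstrap_enrichment(spots, ann, sizes, B = 1000, seed = 23)
  # a 50-bp spot overlaps iff its start falls within width + 49 bp of an
  # interval start, slightly above the raw coverage fraction
  eff <- e$coverage_fraction +
    49 * nrow(ann) / sum(as.numeric(sizes))
  se <- e$null_sd / sqrt(e$B)
  expect_lt(abs(e$null_mean - eff), 4 * se + 0.002)
})

test_that("interaction counts per spot match anchor-bin membership", {
  spots <- tibble::tibble(chrom = "chrS1", start = c(10000L, 90000L),
                          end = c(10050L, 90050L))
  bedpe <- tibble::tibble(
    chrom1 = "chrS1", start1 = c(0L, 0L, 0L, 40000L),
    end1 = c(40000L, 40000L, 40000L, 80000L),
    chrom2 = c("chrS1", "chrS2", "chrS1", "chrS1"),
    start2 = c(80000L, 0L, 120000L, 120000L),
    end2 = c(120000L, 40000L, 160000L, 160000L))
  out <- count_interactions_per_spot(spots, bedpe)
  expect_equal(out$n_interactions, c(3L, 1L))
  expect_equal(count_interactions_per_spot(spots,
                                           bedpe[0, ])$n_interactions,
               c(0L, 0L))

  # planted excess at spots yields a significant rank-sum difference
  sizes <- c(chrS1 = 1000000L, chrS2 = 1000000L)
  hot <- sample_random_spots(30, 50, sizes, seed = 31)
  rnd <- sample_random_spots(30, 50, sizes, seed = 32)
  bed2 <- simulate_interactions(hot, sizes, n_background = 100,
                                excess_per_spot = 5, seed = 33)
  cmp <- count_interactions_per_spot(hot, bed2, random_spots = rnd)
  expect_lt(attr(cmp, "comparison")$p_value, 0.01)
})

test_that("signal aggregation averages per-base coverage", {
  spots <- tibble::tibble(chrom = "chrS1", start = c(100L, 200L),
                          end = c(150L, 250L),
                          category = c("hotspot", "coldspot"))
  const <- tibble::tibble(chrom = "chrS1", start = 0L, end = 1000L,
                          value = 7)
  out <- aggregate_signal(spots, const)
  expect_equal(out$mean_signal, c(7, 7))
  # empty track gives zero means
  expect_equal(aggregate_signal(spots, const[0, ])$mean_signal, c(0, 0))
  # partial coverage is length-weighted (half the spot at value 10)
  half <- tibble::tibble(chrom = "chrS1", start = 125L, end = 1000L,
                         value = 10)
  expect_equal(aggregate_signal(spots, half)$mean_signal, c(5, 10))

  # elevated hotspot signal separates the groups
  sizes <- c(chrS1 = 100000L)
  hot <- sample_random_spots(25, 50, sizes, seed = 41)
  hot$category <- "hotspot"
  rnd <- sample_random_spots(25, 50, sizes, exclusions = hot, seed = 42)
  rnd$category <- "random"
  track <- rbind(
    tibble::tibble(chrom = "chrS1", start = 0L, end = 100000L, value = 1),
    dplyr::mutate(hot[, 1:3], value = 9))
  sig <- aggregate_signal(rbind(hot, rnd), track)
  w <- wilcox.test(mean_signal ~ category, data = sig,
                   alternative = "greater", exact = FALSE)
  expect_lt(w$p.value, 0.01)
})

test_that("state composition assigns by largest overlap", {
  states <- tibble::tibble(chrom = "chrS1",
                           start = c(0L, 130L),
                           end = c(130L, 1000L),
                           label = c("enhancer", "quiescent"))
  spots <- tibble::tibble(chrom = "chrS1", start = c(100L, 500L),
                          end = c(150L, 550L))
  # first spot: 30 bp enhancer vs 20 bp quiescent -> enhancer
  comp <- category_composition(spots, states)
  expect_equal(comp$fraction[comp$label == "enhancer"], 0.5)
  expect_equal(comp$fraction[comp$label == "quiescent"], 0.5)
  expect_lte(sum(comp$fraction), 1)

  # a single genome-covering label takes fraction 1
  whole <- tibble::tibble(chrom = "chrS1", start = 0L, end = 1000L,
                          label = "open")
  comp2 <- category_composition(spots, whole)
  expect_equal(comp2$fraction, 1)

  # alphabetical tie-break on equal overlap
  tie <- tibble::tibble(chrom = "chrS1", start = c(100L, 125L),
                        end = c(125L, 150L),
                        label = c("zeta", "alpha"))
  comp3 <- category_composition(spots[1, ], tie)
  expect_equal(comp3$n_spots[comp3$label == "alpha"], 1L)
  expect_equal(comp3$n_spots[comp3$label == "zeta"], 0L)
})
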