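# Binning, downsampling, blacklist masking, and the threshold caller.

test_that("make_bins tiles chromosomes with clipped final bins", {
  b <- make_bins(c(chrS1 = 10000L), 50)
  expect_equal(nrow(b), 200)
  expect_equal(b$start[1], 0)
  expect_equal(b$end[1], 50)
  expect_equal(b$start[200], 9950)
  expect_equal(b$end[200], 10000)
  expect_false(any(b$partial))

  b2 <- make_bins(c(chrS1 = 101L), 50)
  expect_equal(nrow(b2), 3)
  expect_equal(c(b2$start[3], b2$end[3]), c(100, 101))
  expect_true(b2$partial[3])

  expect_equal(attr(make_bins(c(chrS1 = 100L)), "bin_width"), 50L)
  expect_error(make_bins(c(chrS1 = -5L)), "positive")
})

test_that("downsampling draws an exact reproducible subset", {
  r <- mk_reads(start = seq_len(10000) * 3, end = seq_len(10000) * 3 + 25,
                sample = "s1")
  d1 <- downsample_reads(r, n = 1000, seed = 1)
  d2 <- downsample_reads(r, n = 1000, seed = 1)
  expect_equal(nrow(d1), 1000)
  expect_identical(d1, d2)
  expect_true(all(d1$start %in% r$start))
  d3 <- downsample_reads(r, n = 1000, seed = 2)
  expect_false(identical(d1$start, d3$start))

  expect_error(downsample_reads(r, n = 20000, seed = 1), "fewer than")
  expect_warning(out <- downsample_reads(r, n = 20000, seed = 1,
                                         allow_short = TRUE),
                 "keeping all")
  expect_equal(nrow(out), 10000)
  # default target matches the equal-depth design of the time course
  expect_equal(formals(downsample_reads)$n, 7700000L)
})

test_that("reads increment exactly one bin via the 5' assignment point", {
  bins <- make_bins(c(chrS1 = 10000L), 50)
  r <- mk_reads(start = 75, end = 101, strand = "+")
  cts <- count_reads_per_bin(r, bins, "+")
  expect_equal(sum(cts), 1)
  expect_equal(which(cts == 1), 2L)       # bin [50,100)

  # minus-strand 5' end is end - 1
  rm_ <- mk_reads(start = 75, end = 101, strand = "-")
  ctsm <- count_reads_per_bin(rm_, bins, "-")
  expect_equal(which(ctsm == 1), 3L)      # bin [100,150)

  # strands are analysed separately
  mix <- mk_reads(start = c(10, 20), end = c(36, 46),
                  strand = c("+", "-"))
  expect_equal(sum(count_reads_per_bin(mix, bins, "+")), 1)

  # conservation and skipped tally
  starts <- sample(0:9000, 1000, replace = TRUE)
  many <- mk_reads(start = starts, end = starts + 26L)
  cts2 <- count_reads_per_bin(many, bins, "+")
  expect_equal(sum(cts2), 1000)
  off <- mk_reads(start = 50, end = 76, chrom = "chrUnknown")
  cts3 <- count_reads_per_bin(off, bins, "+")
  expect_equal(sum(cts3), 0)
  expect_equal(attr(cts3, "skipped"), 1L)

  # midpoint assignment option
  r3 <- mk_reads(start = 40, end = 66, strand = "+")  # midpoint 53
  expect_equal(which(count_reads_per_bin(r3, bins, "+",
                                         assign = "midpoint") == 1), 2L)
})

test_that("blacklist masking flags any >= 1 bp overlap", {
  bins <- make_bins(c(chrS1 = 500L), 50)
  bl <- tibble::tibble(chrom = "chrS1", start = 60L, end = 70L)
  m <- apply_blacklist(bins, bl)
  expect_true(m$masked[2])
  expect_false(m$masked[1])

  expect_false(any(apply_blacklist(bins, bl[0, ])$masked))

  spanning <- tibble::tibble(chrom = "chrS1", start = 95L, end = 105L)
  m2 <- apply_blacklist(bins, spanning)
  expect_equal(which(m2$masked), c(2L, 3L))
})

test_that("the threshold rule applies inclusive replicate-wise bounds", {
  samples <- tiny_samples()
  counts <- rbind(
    c(15, 15, 3, 5, 5),   # hotspot: >=15 both early, <=5 both late
    c(15, 14, 3, 5, 5),   # fails: second early replicate at 14
    c(20, 30, 3, 6, 5),   # fails: first late replicate at 6
    c(1, 2, 3, 12, 10),   # coldspot: <=2 early, >=10 late
    c(1, 3, 3, 12, 10))   # fails coldspot: early replicate at 3
  x <- repairspot:::new_bin_count_matrix(
    bins = make_bins(c(chrS1 = 250L), 50), counts = counts,
    strand = "+", lib_sizes = setNames(colSums(counts), samples$sample),
    samples = samples)
  colnames(x$counts) <- samples$sample
  hot <- call_spots(x, hotspot_rule(samples))
  expect_equal(hot$start, 0L)
  cold <- call_spots(x, coldspot_rule(samples))
  expect_equal(cold$start, 150L)

  # masked bins are never called
  x$bins$masked[1] <- TRUE
  expect_equal(nrow(call_spots(x, hotspot_rule(samples))), 0)

  # rule referencing absent samples
  bad <- threshold_rule("hotspot", early_samples = "nope")
  expect_error(call_spots(x, bad), "absent sample")
})

test_that("call_spots matches the brute-force per-bin oracle", {
  samples <- tiny_samples()
  hot <- hotspot_rule(samples, min_early = 8, max_late = 3)
  cold <- coldspot_rule(samples, max_early = 1, min_late = 6)
  withr::with_seed(11, {
    for (rep in 1:5) {
      x <- random_bin_counts(1000, samples, lambda = 4)
      expect_equal(call_spots(x, hot)$bin_index, oracle_call(x, hot))
      expect_equal(call_spots(x, cold)$bin_index, oracle_call(x, cold))
    }
  })
})

test_that("hotspot calls are monotone in the thresholds", {
  samples <- tiny_samples()
  withr::with_seed(13, x <- random_bin_counts(2000, samples, lambda = 6))
  loose <- call_spots(x, hotspot_rule(samples, min_early = 7,
                                      max_late = 6))$bin_index
  tighter_early <- call_spots(x, hotspot_rule(samples, min_early = 9,
                                              max_late = 6))$bin_index
  tighter_late <- call_spots(x, hotspot_rule(samples, min_early = 7,
                                             max_late = 4))$bin_index
  expect_true(all(tighter_early %in% loose))
  expect_true(all(tighter_late %in% loose))
})

test_that("CPD coldspot calling is refused unless forced", {
  samples <- tiny_samples()
  withr::with_seed(17, x <- random_bin_counts(200, samples))
  x$damage_type <- "CPD"
  expect_error(call_spots(x, coldspot_rule(samples)),
               "transcription-coupled")
  expect_silent(call_spots(x, coldspot_rule(samples, max_early = 0,
                                            min_late = 99), force = TRUE))
})

test_that("adjacent qualifying bins merge only on request", {
  samples <- tiny_samples()
  counts <- matrix(0L, 4, 5, dimnames = list(NULL, samples$sample))
  counts[2, ] <- c(20, 20, 0, 0, 0)
  counts[3, ] <- c(25, 18, 0, 1, 0)
  x <- repairspot:::new_bin_count_matrix(
    bins = make_bins(c(chrS1 = 200L), 50), counts = counts, strand = "+",
    lib_sizes = setNames(pmax(colSums(counts), 1L), samples$sample),
    samples = samples)
  sep <- call_spots(x, hotspot_rule(samples))
  expect_equal(nrow(sep), 2)
  merged <- call_spots(x, hotspot_rule(samples), merge = TRUE)
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(50, 150))
})
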