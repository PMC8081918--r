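# TC content, the robust Poisson log-linear fit, expected counts, and
# per-bin enrichment testing.

test_that("TC content counts pyrimidines strand-specifically", {
  g <- Biostrings::DNAStringSet(c(chrS1 = paste0(
    strrep("T", 50),                    # bin 1: all T
    strrep("ACGT", 13))))               # bin 2: half pyrimidine
  bins <- make_bins(c(chrS1 = 102L), 50)
  tc_plus <- compute_tc_content(bins, g, "+")
  expect_equal(tc_plus[1], 1.0)
  expect_equal(tc_plus[2], 0.5)
  # minus strand: reverse complement of all-T is all-A -> TC 0; the
  # ACGT repeat stays balanced
  tc_minus <- compute_tc_content(bins, g, "-")
  expect_equal(tc_minus[1], 0.0)
  expect_equal(tc_minus[2], 0.5)

  g2 <- Biostrings::DNAStringSet(c(chrS1 = "AAAAATTTTT"))
  expect_equal(compute_tc_content(make_bins(c(chrS1 = 10L), 10), g2, "+"),
               0.5)

  # N bases drop out of numerator and denominator; all-N is NA
  g3 <- Biostrings::DNAStringSet(c(chrS1 = paste0("TTNNA", strrep("N", 5))))
  bins3 <- make_bins(c(chrS1 = 10L), 5)
  tc3 <- compute_tc_content(bins3, g3, "+")
  expect_equal(tc3[1], 2 / 3)
  expect_true(is.na(tc3[2]))
})

test_that("null-model fit recovers beta and f on simulated data", {
  cfg <- null_model_config(seed = 11)
  g <- simulate_genome(cfg)
  x <- simulate_bin_counts(cfg, g)[["+"]]
  fit <- fit_null_model(x)
  truth <- attr(x, "truth")
  expect_true(fit$converged)
  expect_gte(cor(fit$beta[fit$usable], truth$beta[fit$usable]), 0.95)

  # log-likelihood ascends within the final pass
  ll <- fit$loglik
  expect_true(all(diff(ll) >= -1e-9 * abs(ll[-length(ll)])))
})

test_that("with no TC bias the fitted f is flat within 5%", {
  cfg <- null_model_config(seed = 12, tc_bias_strength = 0)
  g <- simulate_genome(cfg)
  x <- simulate_bin_counts(cfg, g)[["+"]]
  fit <- fit_null_model(x)
  expect_lt(max(abs(fit$f_grid$f - 1)), 0.05)
})

test_that("fit is invariant to a common library-size rescaling", {
  cfg <- null_model_config(seed = 13, n_bins = 2000L)
  g <- simulate_genome(cfg)
  x <- simulate_bin_counts(cfg, g)[["+"]]
  fit1 <- fit_null_model(x)
  x2 <- x
  x2$lib_sizes <- x$lib_sizes * 10
  fit2 <- fit_null_model(x2)
  expect_equal(fit2$beta, fit1$beta, tolerance = 1e-12)
  expect_equal(fit2$f_grid$f, fit1$f_grid$f, tolerance = 1e-12)
})

test_that("a planted mega-bin is trimmed and its beta stays moderate", {
  cfg <- null_model_config(seed = 14, n_bins = 2000L)
  g <- simulate_genome(cfg)
  x <- simulate_bin_counts(cfg, g)[["+"]]
  # plant a bin holding as many reads as the rest of the genome combined
  x$counts[500, ] <- colSums(x$counts)
  fit <- fit_null_model(x)
  expect_true(fit$trimmed[500])
  expect_lt(fit$beta[500], 2 * median(fit$beta[fit$usable]))
})

test_that("expected counts reproduce N * beta * f exactly", {
  cfg <- null_model_config(seed = 15, n_bins = 1000L)
  g <- simulate_genome(cfg)
  x <- simulate_bin_counts(cfg, g)[["+"]]
  fit <- fit_null_model(x)
  lambda <- expected_counts(fit)
  expect_true(all(lambda[fit$usable, ] > 0))
  # brute force from the stored pieces
  for (j in c(1, 4)) {
    sm <- names(fit$N)[j]
    fj <- predict_f(fit, sm, x$bins$tc[fit$usable])
    expect_equal(lambda[fit$usable, j],
                 unname(fit$N[j] * fit$beta[fit$usable] * fj))
  }
  # per-sample fitted totals match N by the identifiability constraints
  expect_equal(unname(colSums(lambda[fit$usable, ])), unname(fit$N),
               tolerance = 1e-9)
})

test_that("zero-count samples are rejected", {
  cfg <- null_model_config(seed = 16, n_bins = 500L)
  g <- simulate_genome(cfg)
  x <- simulate_bin_counts(cfg, g)[["+"]]
  x$counts[, 2] <- 0L
  expect_error(fit_null_model(x), "zero reads")
})

test_that("enrichment p-values match the Poisson tail oracle", {
  cfg <- null_model_config(seed = 17, n_bins = 1000L)
  g <- simulate_genome(cfg)
  x <- simulate_bin_counts(cfg, g)[["+"]]
  fit <- fit_null_model(x)
  lambda <- expected_counts(fit)
  group <- c("s1", "s2")
  res <- test_enrichment(x, fit, group = group)
  lam <- rowSums(lambda[res$bin_index, group])
  y <- rowSums(x$counts[res$bin_index, group])
  expect_equal(res$p_value, ppois(y - 1, lam, lower.tail = FALSE))

  # extreme enrichment: y = 30 on expectation 2
  expect_lt(ppois(29, 2, lower.tail = FALSE), 1e-20)
  i <- res$bin_index[1]
  x$counts[i, group] <- c(15L, 15L)
  fit_lam <- rowSums(lambda[i, group, drop = FALSE])
  spot <- tibble::tibble(bin_index = i, category = "hotspot")
  out <- test_enrichment(x, fit, spot, group = group)
  expect_equal(out$p_value,
               ppois(29, fit_lam, lower.tail = FALSE), tolerance = 1e-6)

  # zero observed count has upper-tail p = 1
  x$counts[i, group] <- 0L
  out0 <- test_enrichment(x, fit, spot, group = group)
  expect_equal(out0$p_value, 1)

  # coldspots use the lower tail
  spot_cold <- tibble::tibble(bin_index = i, category = "coldspot")
  outc <- test_enrichment(x, fit, spot_cold, group = group)
  expect_equal(outc$p_value, ppois(0, fit_lam))

  expect_error(test_enrichment(x, fit, group = character(0)), "at least one")
})

test_that("randomized p-values are uniform against the generating null", {
  cfg <- null_model_config(seed = 18)
  g <- simulate_genome(cfg)
  x <- simulate_bin_counts(cfg, g)[["+"]]
  lambda_true <- attr(x, "truth")$lambda
  withr::with_seed(1, {
    res <- test_enrichment(x, lambda_true, group = c("s1", "s2"),
                           p_type = "randomized")
  })
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(res$p_value < 0.01) - 0.01), 0.005)
})

test_that("testing against a refitted null is conservative, not inflated", {
  cfg <- null_model_config(seed = 19)
  g <- simulate_genome(cfg)
  x <- simulate_bin_counts(cfg, g)[["+"]]
  fit <- fit_null_model(x)
  withr::with_seed(2, {
    res <- test_enrichment(x, fit, group = c("s1", "s2"),
                           p_type = "randomized")
  })
  expect_lte(mean(res$p_value < 0.01), 0.012)
})
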