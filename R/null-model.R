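# Robust iterative MLE for the cross-sample Poisson log-linear null model
#
#   Y_ij ~ Poisson(lambda_ij),  lambda_ij = N_j * beta_i * f_j(TC_i)
#
# beta_i is the bin-specific propensity (library-preparation/sequencing
# bias), f_j the sample-specific pyrimidine-content bias, N_j the fixed
# (downsampled) library size. f_j is estimated on TC-content quantile
# strata; within a stratum the update sum(Y_ij) / (N_j * sum(beta_i)) is
# the exact conditional MLE, so each alternating sweep is a coordinate
# ascent of the Poisson log-likelihood. Robustness: after a first converged
# pass, bins with |standardised Pearson residual| > resid_cut in any sample
# are frozen out of the update steps (their beta is replaced by the median
# beta of their TC stratum) and the model is refit.

#' Fit the Poisson log-linear null model to a bin count matrix
#'
#' Estimates per-bin propensities `beta` (normalised to sum to 1 over
#' unmasked bins) and per-sample TC-content bias functions `f`
#' (piecewise-constant on `n_strata` TC quantile strata, normalised to
#' beta-weighted mean 1) by robust alternating maximum likelihood. The
#' fitted expectations [expected_counts()] describe coverage in the
#' absence of biologically relevant repair enrichment.
#'
#' @param x A [bin_count_matrix()] with TC content attached (build with
#'   `genome =` or set `x$bins$tc`).
#' @param max_iter Maximum alternating sweeps per pass.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param resid_cut Standardised Pearson residual beyond which a bin is
#'   trimmed from the update steps (it is retained for testing).
#' @param beta_cut Robust z-score (median/MAD on the log propensity)
#'   beyond which a uniformly over-represented bin is trimmed; catches
#'   collapsed-repeat-like bins whose enrichment is consistent across
#'   samples and therefore invisible to the residual rule.
#' @param n_strata Number of TC-content quantile strata for `f`.
#' @param f_method Stratum estimator for `f`: `"ratio"` (stratum MLE,
#'   default) or `"median"` (median of per-bin ratios).
#' @return A `repair_null_fit` object: `beta` (per bin, `NA` for
#'   masked/untestable bins), `f_grid` (tibble `sample`, `stratum`,
#'   `tc_lo`, `tc_hi`, `tc_mid`, `f`), `N`, `strand`, `trimmed`,
#'   `iterations`, `loglik` (trace), `converged`.
#' @export
fit_null_model <- function(x, max_iter = 50L, tol = 1e-6, resid_cut = 3,
                           beta_cut = 5, n_strata = 20L,
                           f_method = c("ratio", "median")) {
  stopifnot(inherits(x, "bin_counts"))
  f_method <- match.arg(f_method)
  assert_that(ncol(x$counts) >= 2, "need at least 2 samples")
  assert_that(!is.null(x$bins$tc), "bins carry no TC content; pass a genome")
  usable <- !x$bins$masked & !is.na(x$bins$tc)
  assert_that(sum(usable) >= 100, "need at least 100 unmasked bins")
  Y <- x$counts[usable, , drop = FALSE]
  if (any(colSums(Y) == 0)) abort("sample with zero reads on usable bins")
  N <- as.numeric(x$lib_sizes[colnames(x$counts)])
  tc <- x$bins$tc[usable]

  breaks <- unique(quantile(tc, probs = seq(0, 1, length.out = n_strata + 1),
                            names = FALSE))
  stratum <- findInterval(tc, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)
  n_str <- length(breaks) - 1L
  n <- nrow(Y); p <- ncol(Y)

  run_pass <- function(beta, g, keep, iters) {
    ll_trace <- numeric(0)
    converged <- FALSE
    ll_prev <- -Inf
    for (it in seq_len(iters)) {
      # beta step (exact M-step given g)
      denomB <- as.vector(g[stratum, , drop = FALSE] %*% N)
      beta_new <- rowSums(Y) / denomB
      beta_new[!keep] <- beta[!keep]
      beta <- beta_new
      # f step (exact M-step given beta)
      for (s in seq_len(n_str)) {
        i <- which(stratum == s & keep)
        if (length(i) == 0) next
        if (f_method == "ratio") {
          g[s, ] <- colSums(Y[i, , drop = FALSE]) / (N * sum(beta[i]))
        } else {
          g[s, ] <- apply(Y[i, , drop = FALSE] / beta[i], 2, median) / N
        }
      }
      g[g <= 0] <- min(g[g > 0]) * 1e-3
      lambda <- (beta * g[stratum, , drop = FALSE]) %*% diag(N, p, p)
      ll <- sum(stats::dpois(Y[keep, , drop = FALSE],
                             lambda[keep, , drop = FALSE], log = TRUE))
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_prev) &&
          abs(ll - ll_prev) <= tol * (abs(ll_prev) + 1e-12)) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
    }
    list(beta = beta, g = g, lambda = lambda, loglik = ll_trace,
         converged = converged)
  }

  beta0 <- rowSums(Y) / sum(N)
  g0 <- matrix(1, n_str, p)
  pass1 <- run_pass(beta0, g0, keep = rep(TRUE, n), iters = max_iter)

  resid <- (Y - pass1$lambda) / sqrt(pmax(pass1$lambda, 1e-12))
  keep <- rowSums(abs(resid) > resid_cut) == 0
  keep[is.na(keep)] <- FALSE
  # uniformly over-represented bins (consistent across samples, so the
  # residual rule cannot see them): robust z on the log propensity
  lb <- log(pmax(pass1$beta, 1e-300))
  lb_mad <- stats::mad(lb[pass1$beta > 0])
  if (lb_mad > 0) {
    keep <- keep & (lb - median(lb[pass1$beta > 0])) / lb_mad <= beta_cut
  }
  if (all(keep)) {
    fit <- pass1
  } else {
    beta1 <- pass1$beta
    med_by_str <- vapply(seq_len(n_str), function(s) {
      i <- stratum == s & keep
      if (any(i)) median(beta1[i]) else median(beta1[keep])
    }, numeric(1))
    beta1[!keep] <- med_by_str[stratum[!keep]]
    fit <- run_pass(beta1, pass1$g, keep = keep, iters = max_iter)
    # trimmed bins: null propensity from their TC stratum, not their own
    # (possibly enriched) counts
    med_by_str <- vapply(seq_len(n_str), function(s) {
      i <- stratum == s & keep
      if (any(i)) median(fit$beta[i]) else median(fit$beta[keep])
    }, numeric(1))
    fit$beta[!keep] <- med_by_str[stratum[!keep]]
  }
  if (!fit$converged) {
    warn(sprintf(
      "null model did not converge in %d iterations (last rel. change %.3g)",
      max_iter,
      ifelse(length(fit$loglik) > 1,
             abs(diff(utils::tail(fit$loglik, 2))) /
               abs(fit$loglik[length(fit$loglik) - 1]), NA)))
  }

  # identifiability: sum(beta) = 1, then f to beta-weighted mean 1
  beta <- fit$beta
  g <- fit$g
  C <- sum(beta)
  beta <- beta / C
  g <- g * C
  wmean <- as.vector(crossprod(
    vapply(seq_len(n_str), function(s) sum(beta[stratum == s]), numeric(1)),
    g))
  g <- sweep(g, 2, wmean, "/")

  beta_full <- rep(NA_real_, nrow(x$counts))
  beta_full[usable] <- beta
  trimmed_full <- rep(NA, nrow(x$counts))
  trimmed_full[usable] <- !keep

  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  f_grid <- purrr::map_dfr(seq_len(p), function(j) {
    tibble::tibble(sample = colnames(x$counts)[j],
                   stratum = seq_len(n_str),
                   tc_lo = breaks[-length(breaks)], tc_hi = breaks[-1],
                   tc_mid = mids, f = g[, j])
  })

  structure(
    list(beta = beta_full, f_grid = f_grid, breaks = breaks,
         N = setNames(N, colnames(x$counts)), strand = x$strand,
         samples = x$samples, usable = usable, trimmed = trimmed_full,
         stratum = stratum, bins = x$bins,
         iterations = length(pass1$loglik) + length(fit$loglik),
         loglik = fit$loglik, converged = fit$converged,
         trimmed_fraction = mean(!keep), n_strata = n_str,
         resid_cut = resid_cut, beta_cut = beta_cut, f_method = f_method),
    class = "repair_null_fit"
  )
}

#' @export
print.repair_null_fit <- function(x, ...) {
  cat("<repair_null_fit>", x$strand, "strand:", sum(x$usable),
      "bins x", length(x$N), "samples\n")
  cat(sprintf("  iterations %d, logLik %.2f, trimmed %.2f%%, converged: %s\n",
              x$iterations, utils::tail(x$loglik, 1),
              100 * x$trimmed_fraction, x$converged))
  invisible(x)
}

#' Evaluate the fitted TC-bias function of one sample
#'
#' @param fit A `repair_null_fit`.
#' @param sample Sample id.
#' @param tc TC-content values.
#' @param method `"constant"` (stratum step function, the fit's internal
#'   form) or `"linear"` (piecewise-linear between stratum midpoints).
#' @return Numeric vector of `f` values.
#' @export
predict_f <- function(fit, sample, tc, method = c("constant", "linear")) {
  method <- match.arg(method)
  grid <- fit$f_grid[fit$f_grid$sample == sample, ]
  assert_that(nrow(grid) > 0, paste("unknown sample:", sample))
  if (method == "constant") {
    s <- findInterval(tc, fit$breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
    grid$f[s]
  } else {
    approx(grid$tc_mid, grid$f, xout = tc, rule = 2)$y
  }
}

#' Expected counts under the fitted null model
#'
#' `Lambda_ij = N_j * beta_i * f_j(TC_i)`: the coverage expected with no
#' biologically relevant repair enrichment.
#'
#' @param fit A `repair_null_fit`.
#' @return Numeric matrix (bins x samples); `NA` rows for masked bins.
#' @export
expected_counts <- function(fit) {
  n <- length(fit$beta); p <- length(fit$N)
  lambda <- matrix(NA_real_, n, p, dimnames = list(NULL, names(fit$N)))
  g <- matrix(fit$f_grid$f, ncol = p)  # strata x samples (sample-major cols)
  lam_use <- (fit$beta[fit$usable] * g[fit$stratum, , drop = FALSE]) %*%
    diag(fit$N, p, p)
  lambda[fit$usable, ] <- lam_use
  lambda
}

#' Tidy per-bin null-model estimates
#'
#' @param x A `repair_null_fit`.
#' @param ... Unused.
#' @return Tibble: `chrom`, `start`, `end`, `tc`, `beta`, `trimmed`.
#' @export
tidy.repair_null_fit <- function(x, ...) {
  dplyr::bind_cols(x$bins[, c("chrom", "start", "end", "masked", "tc")],
                   tibble::tibble(beta = x$beta, trimmed = x$trimmed))
}

#' One-row fit summary
#'
#' @param x A `repair_null_fit`.
#' @param ... Unused.
#' @return One-row tibble with iteration count, final log-likelihood,
#'   trimmed-bin fraction, and convergence flag.
#' @export
glance.repair_null_fit <- function(x, ...) {
  tibble::tibble(iterations = x$iterations,
                 logLik = utils::tail(x$loglik, 1),
                 trimmed_fraction = x$trimmed_fraction,
                 n_strata = x$n_strata,
                 converged = x$converged)
}

#' Test per-bin repair enrichment against the null model
#'
#' For each tested bin, counts are summed over the sample `group` (Poisson
#' additivity) and compared with the summed null expectation: upper-tail
#' probability for hotspot-style enrichment, lower tail for
#' coldspot-style early depletion. Benjamini-Hochberg q-values are
#' computed over the tested bins.
#'
#' Exact Poisson tail p-values are conservative because counts are
#' discrete; `p_type = "mid"` (half weight on the observed count) or
#' `"randomized"` (uniform on the achievable interval; exactly uniform
#' under the null) are available for calibration work.
#'
#' Because the tested counts also inform the fitted propensities, exact
#' p-values computed against a refitted null are additionally
#' conservative; passing a known expected-count matrix as `fit`
#' decouples testing from estimation (used when calibrating the test
#' itself).
#'
#' @param x The [bin_count_matrix()] the fit was built from.
#' @param fit A `repair_null_fit`, or an expected-count matrix
#'   (bins x samples, `NA` rows skipped) to test against directly.
#' @param spots Optional spot tibble from [call_spots()] (needs
#'   `bin_index`, `category`); `NULL` tests every usable bin.
#' @param group Character vector of sample ids sharing a time point
#'   (e.g. both 1-min replicates).
#' @param alternative `"auto"` (greater for hotspots, less for coldspots),
#'   `"greater"`, or `"less"`.
#' @param p_type `"exact"` (default), `"mid"`, or `"randomized"`.
#' @return `spots` with `p_value`/`q_value` filled (or a per-bin tibble
#'   when `spots` is `NULL`).
#' @export
test_enrichment <- function(x, fit, spots = NULL, group,
                            alternative = c("auto", "greater", "less"),
                            p_type = c("exact", "mid", "randomized")) {
  alternative <- match.arg(alternative)
  p_type <- match.arg(p_type)
  assert_that(length(group) >= 1, "group must name at least one sample")
  assert_that(all(group %in% colnames(x$counts)),
              "group contains unknown samples")
  if (is.matrix(fit)) {
    lambda <- fit
    if (is.null(colnames(lambda))) colnames(lambda) <- colnames(x$counts)
    usable <- stats::complete.cases(lambda) & !x$bins$masked
  } else {
    stopifnot(inherits(fit, "repair_null_fit"))
    lambda <- expected_counts(fit)
    usable <- fit$usable
  }
  lam <- rowSums(lambda[, group, drop = FALSE])
  yg <- rowSums(x$counts[, group, drop = FALSE])

  if (is.null(spots)) {
    idx <- which(usable)
    side <- rep(if (alternative == "less") "less" else "greater",
                length(idx))
  } else {
    assert_that(all(c("bin_index", "category") %in% names(spots)),
                "spots need bin_index and category columns")
    idx <- spots$bin_index
    side <- if (alternative == "auto") {
      ifelse(spots$category == "coldspot", "less", "greater")
    } else rep(alternative, nrow(spots))
  }
  p <- poisson_tail_p(yg[idx], lam[idx], side, p_type)
  q <- p.adjust(p, method = "BH")
  if (is.null(spots)) {
    out <- dplyr::bind_cols(x$bins[idx, c("chrom", "start", "end")],
                            tibble::tibble(strand = x$strand,
                                           bin_index = idx,
                                           observed = yg[idx],
                                           expected = lam[idx],
                                           p_value = p, q_value = q))
    return(out)
  }
  spots$p_value <- p
  spots$q_value <- q
  spots
}

poisson_tail_p <- function(y, lambda, side, p_type) {
  upper <- side == "greater"
  p <- numeric(length(y))
  switch(p_type,
    exact = {
      p[upper] <- ppois(y[upper] - 1, lambda[upper], lower.tail = FALSE)
      p[!upper] <- ppois(y[!upper], lambda[!upper])
    },
    mid = {
      p[upper] <- ppois(y[upper], lambda[upper], lower.tail = FALSE) +
        0.5 * stats::dpois(y[upper], lambda[upper])
      p[!upper] <- ppois(y[!upper] - 1, lambda[!upper]) +
        0.5 * stats::dpois(y[!upper], lambda[!upper])
    },
    randomized = {
      u <- runif(length(y))
      p[upper] <- ppois(y[upper], lambda[upper], lower.tail = FALSE) +
        u[upper] * stats::dpois(y[upper], lambda[upper])
      p[!upper] <- ppois(y[!upper] - 1, lambda[!upper]) +
        u[!upper] * stats::dpois(y[!upper], lambda[!upper])
    })
  pmin(p, 1)
}
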