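test_that("model constructor validates and sorts components", {
  m <- gmm(c(115.1, 69.7, 158.4), c(13, 4.2, 26.4), c(0.55, 0.19, 0.26))
  expect_equal(m$components$m, c(69.7, 115.1, 158.4))
  expect_equal(m$components$w, c(0.19, 0.55, 0.26))
  expect_equal(m$M, 3L)
  expect_error(gmm(c(1, 2), c(1, -1), c(0.5, 0.5)),
               class = "mepmix_argument_error")
  expect_error(gmm(c(1, 2), c(1, 1), c(0.6, 0.6)),
               class = "mepmix_argument_error")
})

test_that("pdf, cdf and quantile behave like a proper distribution", {
  one <- gmm(0, 1, 1)
  expect_equal(gmm_cdf(one, 0), 0.5)
  expect_equal(gmm_pdf(one, 0), dnorm(0))

  m <- ref_gmm()
  expect_equal(gmm_cdf(m, 1e6), 1)
  expect_equal(gmm_cdf(m, -1e6), 0)
  # pdf integrates to 1 (trapezoid over +/- 10 SD span)
  grid <- seq(69.7 - 10 * 26.4, 158.4 + 10 * 26.4, length.out = 20001)
  integral <- sum(diff(grid) * (head(gmm_pdf(m, grid), -1) +
                                  tail(gmm_pdf(m, grid), -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-6)
  # cdf is non-decreasing
  expect_true(all(diff(gmm_cdf(m, seq(0, 250, length.out = 500))) >= 0))
  # quantile round trip at interior points
  for (x in c(60, 100, 180)) {
    expect_equal(gmm_quantile(m, gmm_cdf(m, x)), x, tolerance = 1e-8)
  }
  p <- c(0.05, 0.5, 0.95)
  expect_equal(gmm_cdf(m, gmm_quantile(m, p)), p, tolerance = 1e-10)
  expect_error(gmm_quantile(m, 1.2), class = "mepmix_argument_error")
})

test_that("M = 1 fit is the closed-form Gaussian MLE", {
  x <- withr::with_seed(3, rnorm(500, 100, 12))
  fit <- em_fit(x, 1)
  expect_equal(fit$model$components$m, mean(x))
  expect_equal(fit$model$components$s, sqrt(mean((x - mean(x))^2)))
  expect_equal(fit$model$components$w, 1)
  expect_equal(fit$n_params, 2L)
  expect_equal(fit$loglik, sum(dnorm(x, mean(x),
                                     sqrt(mean((x - mean(x))^2)), log = TRUE)))
})

test_that("EM recovers the tri-modal generating parameters", {
  # per-seed tolerances reflect the ML sampling spread at n = 10,000: the
  # tight responder mean is pinned to a fraction of a percent while the
  # broad, overlapping third component wanders by several percent
  x <- sample_overall_changes(cohort_config(seed = 7), 10000)
  fit <- em_fit(x, 3, seed = 7)
  comp <- fit$model$components
  expect_true(fit$converged)
  expect_lt(abs(comp$m[1] - 69.7), 1.0)
  expect_lt(abs(comp$m[2] - 115.1), 1.0)
  expect_lt(abs(comp$m[3] - 158.4), 6.5)
  expect_lt(abs(max(comp$w) - 0.55), 0.05)
  expect_equal(sum(comp$w), 1, tolerance = 1e-9)
})

test_that("recovered component means are unbiased across seeds", {
  est <- vapply(1:20, function(sd0) {
    x <- sample_overall_changes(cohort_config(seed = sd0), 10000)
    em_fit(x, 3, seed = sd0)$model$components$m
  }, numeric(3))
  bias <- rowMeans(est) - c(69.7, 115.1, 158.4)
  expect_true(all(abs(bias) < 0.5))
})

test_that("duplicating the data leaves estimates fixed and doubles the loglik", {
  x <- sample_overall_changes(cohort_config(seed = 13), 400)
  f1 <- em_fit(x, 2, seed = 5)
  f2 <- em_fit(c(x, x), 2, seed = 5)
  expect_equal(f2$model$components$m, f1$model$components$m, tolerance = 1e-4)
  expect_equal(f2$model$components$s, f1$model$components$s, tolerance = 1e-4)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-6)
})

test_that("EM matches an independent reference implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  for (sd0 in 1:5) {
    x <- sample_overall_changes(
      cohort_config(component_means = c(80, 130), component_sds = c(8, 18),
                    component_weights = c(0.4, 0.6), seed = sd0), 500)
    fit <- em_fit(x, 2, seed = sd0)
    ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE,
                          control = mclust::emControl(tol = c(1e-10, 1e-10),
                                                      itmax = c(5000, 5000)))
    expect_lte(abs(fit$loglik - ref$loglik), 1e-4)
  }
})

test_that("fits reject infeasible inputs and degenerate data", {
  expect_error(em_fit(c(1, 2, 3), 2), class = "mepmix_argument_error")
  expect_error(em_fit(rep(c(1, 2), 50), 2), class = "mepmix_argument_error")
})

test_that("selection walks the likelihood-ratio ladder with a strict threshold", {
  x <- sample_overall_changes(cohort_config(seed = 1), 800)
  sel <- select_components(x, M_max = 3, seed = 1)
  expect_gte(sel$chosen_M, 2L)
  steps <- tidy(sel)
  expect_equal(steps$threshold, rep(qchisq(0.95, 1), 2))
  # chosen_M is the last rung of consecutive accepted steps
  expect_equal(sel$chosen_M,
               1L + sum(cumprod(as.numeric(steps$accepted))))
  expect_message(select_components(x, M_max = 2, lr_df = 3, seed = 1),
                 regexp = "df = 3")
})

test_that("selection rarely overfits a single Gaussian", {
  # the 1 -> 2 likelihood-ratio step of a multi-restart EM is known to be
  # mildly anti-conservative against chi-square(1); a k-means-initialized
  # reference EM measures a null exceedance near 0.10-0.15, so a clear
  # majority of null datasets must keep M = 1
  chosen <- vapply(1:50, function(sd0) {
    x <- withr::with_seed(sd0, rnorm(1000, 100, 10))
    select_components(x, M_max = 2, seed = sd0)$chosen_M
  }, integer(1))
  expect_gte(mean(chosen == 1L), 0.8)
})

test_that("QQ pairs line up for model-consistent data and never throw", {
  m <- ref_gmm()
  n <- 200
  exact <- gmm_quantile(m, (seq_len(n) - 0.5) / n)
  qq <- qq_pairs(m, sample(exact))
  expect_equal(qq$empirical, qq$theoretical, tolerance = 1e-8)

  x <- sample_overall_changes(cohort_config(seed = 17), 1000)
  qq2 <- qq_pairs(m, x)
  # oracle: 99% Kolmogorov-Smirnov band at n = 1000 is 1.6276/sqrt(1000)
  # on the probability scale; transported through the quantile function at
  # the observed points
  ks_ok <- mean(abs(gmm_cdf(m, qq2$empirical) -
                      gmm_cdf(m, qq2$theoretical)) < 0.0515)
  expect_gt(ks_ok, 0.99)

  far <- qq_pairs(m, c(1000, 2000, 3000))
  expect_true(all(is.finite(far$theoretical)))
})

test_that("RMSE against the PDE discriminates matched from shifted models", {
  x <- sample_overall_changes(cohort_config(seed = 23), 1e5)
  est <- pde(x)
  m <- ref_gmm()
  matched <- rmse_to_pde(m, est)
  expect_gte(matched, 0)
  expect_lt(matched, 0.002)
  shifted <- gmm(c(89.7, 135.1, 178.4), c(4.2, 13, 26.4), c(0.19, 0.55, 0.26))
  expect_gt(rmse_to_pde(shifted, est), matched)
})

test_that("models serialize to diffable text and back", {
  path <- withr::local_tempfile(fileext = ".txt")
  m <- ref_gmm()
  write_gmm(m, path)
  expect_equal(read_gmm(path), m)
  fit <- em_fit(sample_overall_changes(cohort_config(seed = 2), 200), 2,
                seed = 2)
  write_gmm(fit, path)
  expect_equal(read_gmm(path), fit$model)
  expect_true(any(grepl("loglik", readLines(path))))
})
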