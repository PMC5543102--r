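#' Fit a one-dimensional Gaussian mixture by expectation-maximization
#'
#' Maximum-likelihood EM with one deterministic initialization (quantile
#' partition of the sorted data into `M` segments) plus `n_restarts - 1`
#' seeded random restarts; the restart with the highest converged
#' log-likelihood wins. Component standard deviations are floored at
#' `1e-3` times the data range; a restart whose solution sits on that floor
#' is discarded as degenerate (a component collapsed onto a point), and the
#' fit errors only if every restart degenerates. Components are returned
#' sorted by ascending mean — the mixture likelihood is label-symmetric, so
#' the ordering is a labeling convention, not a constraint of the fit.
#'
#' @param values Numeric data vector (here, overall MEP changes in % of
#'   baseline) with at least `3 * M` distinct values.
#' @param M Number of components.
#' @param n_restarts Total number of EM starts (first one deterministic).
#' @param tol Convergence tolerance on the log-likelihood increase per
#'   iteration.
#' @param max_iter Iteration cap per restart.
#' @param seed Seed for the random restarts.
#' @return An object of class `mep_gmm_fit`: list with `model` (an
#'   [gmm()] object), `loglik`, `n_params` (`3 * M - 1`), `converged`,
#'   `n_iter`, `n` and `M`. Methods: [tidy()], [glance()], `print()`.
#' @export
#' @examples
#' x <- sample_overall_changes(cohort_config(seed = 1), 300)
#' fit <- em_fit(x, M = 3, seed = 1)
#' tidy(fit)
em_fit <- function(values, M, n_restarts = 20L, tol = 1e-8,
                   max_iter = 2000L, seed = 1L) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  M <- as.integer(M)
  if (M < 1L) {
    abort("`M` must be >= 1", class = "mepmix_argument_error")
  }
  if (length(unique(values)) < 3L * M) {
    abort(sprintf("need at least %d distinct values to fit M = %d components",
                  3L * M, M),
          class = "mepmix_argument_error")
  }
  s_floor <- 1e-3 * diff(range(values))

  if (M == 1L) {
    # closed form: mean and MLE (divide-by-n) standard deviation
    m <- mean(values)
    s <- max(sqrt(mean((values - m)^2)), s_floor)
    ll <- sum(dnorm(values, m, s, log = TRUE))
    return(new_gmm_fit(gmm(m, s, 1), ll, TRUE, 0L, length(values)))
  }

  starts <- c(list(quantile_init(values, M)),
              with_seed(seed, lapply(seq_len(max(n_restarts - 1L, 0L)),
                                     function(i) random_init(values, M))))
  # short-run/polish strategy: run every restart with a loose tolerance,
  # then iterate only the best candidate to full convergence
  best <- NULL
  for (init in starts) {
    run <- em_run(values, init, s_floor, max(tol, 1e-6), min(max_iter, 300L))
    if (run$degenerate) next
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (is.null(best)) {
    abort(sprintf("all %d EM restarts produced degenerate solutions (M = %d)",
                  length(starts), M),
          class = "mepmix_fit_error")
  }
  polished <- em_run(values, best[c("m", "s", "w")], s_floor, tol, max_iter)
  if (!isTRUE(polished$degenerate)) best <- polished
  new_gmm_fit(gmm(best$m, best$s, best$w), best$loglik, best$converged,
              best$n_iter, length(values))
}

new_gmm_fit <- function(model, loglik, converged, n_iter, n) {
  structure(
    list(model = model, loglik = loglik, n_params = 3L * model$M - 1L,
         converged = converged, n_iter = n_iter, n = n, M = model$M),
    class = "mep_gmm_fit"
  )
}

# deterministic start: split the sorted data into M equal-count segments
quantile_init <- function(values, M) {
  sv <- sort(values)
  seg <- cut(seq_along(sv), breaks = M, labels = FALSE)
  m <- vapply(split(sv, seg), mean, numeric(1))
  s <- vapply(split(sv, seg), function(v) {
    if (length(v) > 1L) sd(v) else 0
  }, numeric(1))
  s[!is.finite(s) | s <= 0] <- sd(values) / M
  list(m = as.numeric(m), s = as.numeric(s), w = rep(1 / M, M))
}

# random restart: a short k-means run from randomly drawn distinct centers,
# converted to component moments. Partition-based starts converge to the
# canonical local optima of the likelihood; fully unstructured starts tend to
# discover tiny "spike" components whose likelihood gain is real but breaks
# the chi-square calibration the likelihood-ratio ladder relies on.
random_init <- function(values, M) {
  centers <- sample(unique(values), M)
  km <- suppressWarnings(
    stats::kmeans(values, centers = centers, iter.max = 100L)
  )
  m <- as.numeric(km$centers)
  s <- vapply(split(values, km$cluster), function(v) {
    if (length(v) > 1L) sd(v) else 0
  }, numeric(1))
  s[!is.finite(s) | s <= 0] <- sd(values) / M
  list(m = m, s = as.numeric(s), w = km$size / length(values))
}

em_run <- function(values, init, s_floor, tol, max_iter) {
  n <- length(values)
  m <- init$m; s <- pmax(init$s, s_floor); w <- init$w / sum(init$w)
  M <- length(m)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E step in log space
    lx <- vapply(seq_len(M), function(i) {
      log(w[i]) + dnorm(values, m[i], s[i], log = TRUE)
    }, numeric(n))
    lx <- matrix(lx, nrow = n)
    lse <- row_logsumexp(lx)
    ll <- sum(lse)
    resp <- exp(lx - lse)
    # M step
    nk <- colSums(resp)
    if (any(nk < 1e-10)) {
      return(list(degenerate = TRUE))
    }
    w <- nk / n
    m <- colSums(resp * values) / nk
    s <- sqrt(colSums(resp * (outer(values, m, "-"))^2) / nk)
    s <- pmax(s, s_floor)
    if (is.finite(ll_old) && ll - ll_old < tol * max(1, abs(ll))) {
      converged <- ll - ll_old > -1e-9
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
  }
  hit_floor <- any(s <= s_floor * (1 + 1e-12))
  list(m = m, s = s, w = w, loglik = ll, converged = converged,
       n_iter = iter, degenerate = hit_floor)
}

#' @export
print.mep_gmm_fit <- function(x, ...) {
  cat(sprintf("<mep_gmm_fit> M = %d, logLik = %.3f, n = %d, %s after %d iteration(s)\n",
              x$M, x$loglik, x$n,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(as.data.frame(x$model$components), digits = 4)
  invisible(x)
}

#' @describeIn em_fit One row per fitted component (`component`, `m`, `s`, `w`).
#' @param x An `mep_gmm_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mep_gmm_fit <- function(x, ...) {
  tidy(x$model)
}

#' @describeIn em_fit One-row fit summary (`M`, `logLik`, `n_params`, `n`,
#'   `converged`, `n_iter`).
#' @exportS3Method generics::glance
glance.mep_gmm_fit <- function(x, ...) {
  tibble::tibble(M = x$M, logLik = x$loglik, n_params = x$n_params,
                 n = x$n, converged = x$converged, n_iter = x$n_iter)
}

#' Select the number of mixture components by likelihood-ratio ladder
#'
#' Fits mixtures with `M = 1 ... M_max` components and walks up the ladder:
#' the step from `M - 1` to `M` is accepted when the likelihood-ratio
#' statistic `-2 * (logLik_{M-1} - logLik_M)` strictly exceeds the chi-square
#' critical value at level `alpha`. The chosen order is the last rung reached
#' by consecutive accepted steps. Adding one Gaussian adds three parameters
#' (mean, SD, weight), but the operative convention in this literature tests
#' against the df = 1 critical value 3.84; `lr_df = 3` switches to the
#' parameter-count df (critical value 7.81), and the active threshold is
#' always recorded in the result.
#'
#' @param values Numeric data vector.
#' @param M_max Largest number of components to consider.
#' @param alpha Significance level of each likelihood-ratio step.
#' @param lr_df Degrees of freedom for the chi-square threshold (1 or 3).
#' @param n_restarts,seed Passed to [em_fit()].
#' @return An object of class `mep_gmm_selection`: list with `chosen_M`, the
#'   chosen `fit`, all `fits`, and a `steps` tibble (`M`, `delta_m2ll`,
#'   `threshold`, `accepted`). Methods: [tidy()], [glance()], `print()`.
#' @export
#' @examples
#' x <- sample_overall_changes(cohort_config(seed = 1), 400)
#' sel <- select_components(x, M_max = 3, seed = 1)
#' sel$chosen_M
select_components <- function(values, M_max = 4L, alpha = 0.05, lr_df = 1L,
                              n_restarts = 20L, seed = 1L) {
  if (!lr_df %in% c(1L, 3L)) {
    abort("`lr_df` must be 1 or 3", class = "mepmix_argument_error")
  }
  if (lr_df == 3L) {
    inform("likelihood-ratio threshold uses df = 3 (one added component = 3 parameters); the conventional default is df = 1")
  }
  threshold <- qchisq(1 - alpha, df = lr_df)
  fits <- list()
  for (M in seq_len(M_max)) {
    fit <- tryCatch(
      em_fit(values, M, n_restarts = n_restarts, seed = child_seed(seed, M)),
      mepmix_argument_error = function(e) e,
      mepmix_fit_error = function(e) e
    )
    if (inherits(fit, "error")) {
      # too few distinct values or all restarts degenerate: larger orders are
      # not estimable on these data, so the ladder ends here
      if (M == 1L) abort(conditionMessage(fit), class = "mepmix_fit_error")
      warn(sprintf("mixtures with %d+ components are not estimable on these data (%s); considering M = 1...%d",
                   M, conditionMessage(fit), M - 1L))
      break
    }
    fits[[M]] <- fit
  }
  M_max <- length(fits)
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  # a marginally smaller loglik at larger M is routine (EM can stop at an
  # interior optimum just below the nested fit) and simply rejects the step;
  # a gross decrease means the larger fit failed outright
  if (any(diff(ll) < -5)) {
    abort(paste0("log-likelihood decreased sharply with added components (EM failure); logLik by M: ",
                 paste(sprintf("%.4f", ll), collapse = ", ")),
          class = "mepmix_fit_error")
  }
  delta <- 2 * diff(ll)
  accepted <- delta > threshold  # strict: a tie with the threshold rejects
  chosen <- 1L
  for (i in seq_along(accepted)) {
    if (!accepted[i]) break
    chosen <- chosen + 1L
  }
  structure(
    list(
      chosen_M = chosen,
      fit = fits[[chosen]],
      fits = fits,
      steps = tibble::tibble(
        M = seq_len(M_max)[-1],
        delta_m2ll = delta,
        threshold = threshold,
        accepted = accepted
      ),
      alpha = alpha,
      lr_df = as.integer(lr_df),
      threshold = threshold
    ),
    class = "mep_gmm_selection"
  )
}

#' @export
print.mep_gmm_selection <- function(x, ...) {
  cat(sprintf("<mep_gmm_selection> chosen M = %d (alpha = %g, chi-square df = %d, threshold %.3f)\n",
              x$chosen_M, x$alpha, x$lr_df, x$threshold))
  print(as.data.frame(x$steps), digits = 4)
  invisible(x)
}

#' @describeIn select_components The ladder of likelihood-ratio steps as a
#'   tibble.
#' @param x An `mep_gmm_selection` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mep_gmm_selection <- function(x, ...) {
  x$steps
}

#' @describeIn select_components One-row summary with `chosen_M`, the chosen
#'   fit's log-likelihood and the threshold used.
#' @exportS3Method generics::glance
glance.mep_gmm_selection <- function(x, ...) {
  tibble::tibble(chosen_M = x$chosen_M, logLik = x$fit$loglik,
                 alpha = x$alpha, lr_df = x$lr_df, threshold = x$threshold)
}
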