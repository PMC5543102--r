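#' Construct a one-dimensional Gaussian mixture model
#'
#' A mixture p(x) = sum_i w_i N(x | m_i, s_i) over `M = length(means)`
#' components. Components are stored sorted by ascending mean; weights must
#' sum to 1.
#'
#' @param means Component means (here, % of baseline MEP).
#' @param sds Component standard deviations, all > 0.
#' @param weights Component weights, all in (0, 1], summing to 1.
#' @return An object of class `mep_gmm` with tibble field `components`
#'   (`m`, `s`, `w`) and count `M`.
#' @export
#' @examples
#' gmm(c(69.7, 115.1, 158.4), c(4.2, 13, 26.4), c(0.19, 0.55, 0.26))
gmm <- function(means, sds, weights = rep(1 / length(means), length(means))) {
  means <- as.numeric(means)
  sds <- as.numeric(sds)
  weights <- as.numeric(weights)
  if (length(means) < 1L ||
      length(sds) != length(means) || length(weights) != length(means)) {
    abort("means, sds and weights must have equal length >= 1",
          class = "mepmix_argument_error")
  }
  if (any(!is.finite(means)) || any(!is.finite(sds)) || any(!is.finite(weights))) {
    abort("mixture parameters must be finite", class = "mepmix_argument_error")
  }
  if (any(sds <= 0)) {
    abort("all component sds must be > 0", class = "mepmix_argument_error")
  }
  if (any(weights <= 0) || any(weights > 1)) {
    abort("all component weights must lie in (0, 1]",
          class = "mepmix_argument_error")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    abort("component weights must sum to 1 (tolerance 1e-9)",
          class = "mepmix_argument_error")
  }
  ord <- order(means)
  structure(
    list(
      components = tibble::tibble(m = means[ord], s = sds[ord], w = weights[ord]),
      M = length(means)
    ),
    class = "mep_gmm"
  )
}

as_gmm <- function(x) {
  if (inherits(x, "mep_gmm")) return(x)
  if (inherits(x, "mep_gmm_fit")) return(x$model)
  abort("expected an mep_gmm model or an em_fit() result",
        class = "mepmix_argument_error")
}

#' @export
print.mep_gmm <- function(x, ...) {
  cat(sprintf("<mep_gmm> %d component(s)\n", x$M))
  print(as.data.frame(x$components), digits = 4)
  invisible(x)
}

#' @describeIn gmm One row per component (`component`, `m`, `s`, `w`).
#' @param x An `mep_gmm` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mep_gmm <- function(x, ...) {
  dplyr::mutate(x$components, component = dplyr::row_number(),
                .before = "m")
}

# per-component log weighted densities, n x M matrix
log_component_densities <- function(model, x) {
  comp <- model$components
  vapply(seq_len(model$M), function(i) {
    log(comp$w[i]) + dnorm(x, comp$m[i], comp$s[i], log = TRUE)
  }, numeric(length(x)))
}

#' Mixture density, distribution and quantile functions
#'
#' `gmm_pdf()` evaluates p(x) = sum_i w_i N(x | m_i, s_i); `gmm_cdf()` the
#' corresponding distribution function sum_i w_i Phi((x - m_i)/s_i); and
#' `gmm_quantile()` its numerical inverse (monotone bisection refined to
#' |cdf(q) - p| < 1e-10).
#'
#' @param model An `mep_gmm` model (or an [em_fit()] result).
#' @param x Numeric vector of evaluation points.
#' @param p Probabilities in (0, 1).
#' @return Numeric vector matching the input length.
#' @export
gmm_pdf <- function(model, x) {
  model <- as_gmm(model)
  if (length(x) == 0L) return(numeric(0))
  lx <- log_component_densities(model, as.numeric(x))
  exp(row_logsumexp(matrix(lx, nrow = length(x))))
}

#' @rdname gmm_pdf
#' @export
gmm_cdf <- function(model, x) {
  model <- as_gmm(model)
  comp <- model$components
  vapply(as.numeric(x), function(xi) {
    sum(comp$w * pnorm(xi, comp$m, comp$s))
  }, numeric(1))
}

#' @rdname gmm_pdf
#' @export
gmm_quantile <- function(model, p) {
  model <- as_gmm(model)
  p <- as.numeric(p)
  if (any(!is.finite(p) | p <= 0 | p >= 1)) {
    abort("quantile probabilities must lie strictly in (0, 1)",
          class = "mepmix_argument_error")
  }
  comp <- model$components
  vapply(p, function(pi) {
    # bracket: all per-component quantiles bound the mixture quantile
    lo <- min(qnorm(pi, comp$m, comp$s))
    hi <- max(qnorm(pi, comp$m, comp$s))
    if (lo == hi) return(lo)
    uniroot(function(x) gmm_cdf(model, x) - pi, c(lo, hi),
            tol = .Machine$double.eps^0.75, extendInt = "upX")$root
  }, numeric(1))
}

#' Quantile-quantile pairs of data against a fitted mixture
#'
#' Pairs the i-th order statistic of the data with the model quantile at
#' probability (i - 0.5)/n — the standard diagnostic for judging whether the
#' fitted mixture reproduces the observed distribution.
#'
#' @param model An `mep_gmm` model (or fit result).
#' @param values Numeric data vector (length >= 2).
#' @return A tibble with columns `theoretical` and `empirical`, sorted.
#' @export
qq_pairs <- function(model, values) {
  model <- as_gmm(model)
  values <- sort(as.numeric(values))
  n <- length(values)
  if (n < 2L) {
    abort("qq_pairs() needs at least 2 values", class = "mepmix_argument_error")
  }
  tibble::tibble(
    theoretical = gmm_quantile(model, (seq_len(n) - 0.5) / n),
    empirical = values
  )
}

#' Root-mean-square deviation between a mixture and a density estimate
#'
#' Evaluates the mixture density on the grid of a Pareto density estimate and
#' returns the root mean square of the pointwise differences — the classical
#' visual-fit criterion, retained here as a reported diagnostic (model
#' selection itself is by likelihood ratio).
#'
#' @param model An `mep_gmm` model (or fit result).
#' @param density An `mep_pde` object.
#' @return Nonnegative scalar (units: one over % of baseline).
#' @export
rmse_to_pde <- function(model, density) {
  model <- as_gmm(model)
  if (!inherits(density, "mep_pde")) {
    abort("`density` must be an mep_pde object", class = "mepmix_argument_error")
  }
  sqrt(mean((gmm_pdf(model, density$grid) - density$density)^2))
}

#' Serialize or restore a mixture model as plain text
#'
#' Writes one `key = value` line per quantity (`M`, then `m`, `s`, `w` per
#' component, and optionally the log-likelihood), so fitted models are
#' human-readable and diffable.
#'
#' @param model An `mep_gmm` model or [em_fit()] result.
#' @param path File path.
#' @return `write_gmm()` returns `path` invisibly; `read_gmm()` returns an
#'   `mep_gmm`.
#' @export
write_gmm <- function(model, path) {
  loglik <- if (inherits(model, "mep_gmm_fit")) model$loglik else NA_real_
  model <- as_gmm(model)
  comp <- model$components
  lines <- c(
    sprintf("M = %d", model$M),
    sprintf("m_%d = %.17g", seq_len(model$M), comp$m),
    sprintf("s_%d = %.17g", seq_len(model$M), comp$s),
    sprintf("w_%d = %.17g", seq_len(model$M), comp$w)
  )
  if (is.finite(loglik)) {
    lines <- c(lines, sprintf("loglik = %.17g", loglik))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmm
#' @export
read_gmm <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(sub("\\s*=\\s*", "=", trimws(lines)), "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, "", 1)
  vals <- as.numeric(vapply(kv, `[[`, "", 2))
  m_count <- as.integer(vals[keys == "M"])
  get_vec <- function(prefix) vals[match(paste0(prefix, "_", seq_len(m_count)), keys)]
  gmm(get_vec("m"), get_vec("s"), get_vec("w"))
}
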