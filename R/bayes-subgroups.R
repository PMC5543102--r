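#' Posterior probability of component membership
#'
#' By Bayes' theorem, the probability that an observation x belongs to
#' component i of the mixture is
#' `w_i N(x | m_i, s_i) / sum_j w_j N(x | m_j, s_j)`. Computed in log space
#' so far-tail observations do not underflow to 0/0.
#'
#' @param model An `mep_gmm` model (or [em_fit()] result).
#' @param x Numeric vector of overall MEP changes (% of baseline).
#' @return A numeric matrix, one row per value of `x`, one column per
#'   component (columns `comp1`, `comp2`, ...); rows sum to 1.
#' @export
#' @examples
#' m <- gmm(c(69.7, 115.1, 158.4), c(4.2, 13, 26.4), c(0.19, 0.55, 0.26))
#' posterior(m, c(69.7, 100, 160))
posterior <- function(model, x) {
  model <- as_gmm(model)
  x <- as.numeric(x)
  if (any(!is.finite(x))) {
    abort("`x` must be finite", class = "mepmix_argument_error")
  }
  lx <- matrix(log_component_densities(model, x), nrow = length(x))
  p <- exp(lx - row_logsumexp(lx))
  colnames(p) <- paste0("comp", seq_len(model$M))
  p
}

#' Bayesian decision boundaries between adjacent mixture components
#'
#' For each adjacent pair of components (sorted by mean) the boundary is the
#' point between the two means where the weighted component densities
#' intersect — equivalently, where the posterior class membership switches.
#' The root of the log-density difference is bracketed on the open interval
#' between the two means; intersections outside that interval (which can
#' exist far in the tails when variances differ) are deliberately not
#' reported, so a model with M components yields exactly M - 1 limits.
#'
#' @param model An `mep_gmm` model with at least 2 components (or a fit).
#' @return A tibble with columns `lower_component`, `upper_component` and
#'   `boundary` (% of baseline), strictly increasing.
#' @export
#' @examples
#' m <- gmm(c(69.7, 115.1, 158.4), c(4.2, 13, 26.4), c(0.19, 0.55, 0.26))
#' decision_boundaries(m)
decision_boundaries <- function(model) {
  model <- as_gmm(model)
  if (model$M < 2L) {
    abort("decision boundaries need at least 2 components",
          class = "mepmix_argument_error")
  }
  comp <- model$components
  limits <- vapply(seq_len(model$M - 1L), function(k) {
    f <- function(x) {
      (log(comp$w[k]) + dnorm(x, comp$m[k], comp$s[k], log = TRUE)) -
        (log(comp$w[k + 1]) + dnorm(x, comp$m[k + 1], comp$s[k + 1], log = TRUE))
    }
    lo <- comp$m[k]
    hi <- comp$m[k + 1]
    if (!(lo < hi)) {
      abort(sprintf("components %d and %d have equal means; no boundary exists between them",
                    k, k + 1),
            class = "mepmix_boundary_error")
    }
    eps <- 1e-9 * (hi - lo)
    flo <- f(lo + eps)
    fhi <- f(hi - eps)
    if (sign(flo) == sign(fhi)) {
      abort(sprintf("weighted densities of components %d and %d do not cross between their means (extreme weight imbalance?)",
                    k, k + 1),
            class = "mepmix_boundary_error")
    }
    uniroot(f, c(lo + eps, hi - eps), tol = 1e-12)$root
  }, numeric(1))
  tibble::tibble(
    lower_component = seq_len(model$M - 1L),
    upper_component = seq_len(model$M - 1L) + 1L,
    boundary = limits
  )
}

subgroup_labels <- function(M) {
  if (M == 3L) {
    c("responder", "non-responder", "paradox-responder")
  } else if (M == 1L) {
    "component-1"
  } else {
    paste0("component-", seq_len(M))
  }
}

#' Assign subjects to responder subgroups
#'
#' Labels each subject by its position relative to the Bayesian decision
#' limits of [decision_boundaries()] — equivalently, by the arg-max
#' posterior between the two components adjacent to each limit. For a
#' tri-modal model the ascending-mean components carry the clinical names
#' responder / non-responder / paradox-responder; for any other order the
#' labels are `component-k`. A subject sitting exactly on a limit is
#' assigned to the lower-mean component.
#'
#' Interval membership and full arg-max posterior coincide everywhere except
#' in the extreme tails, where the widest component can dominate a tighter,
#' nearer one (for the reference tri-modal model, below about 53% of
#' baseline — far outside the support of real cohorts). Because the method
#' reports exactly M - 1 adjacent-pair limits, classification follows the
#' limits, keeping labels monotone in the overall MEP change.
#'
#' @param model An `mep_gmm` model (or [em_fit()] result).
#' @param timecourses A tibble with columns `subject_id` and
#'   `overall_change_pct` (see [summarize_subjects()]).
#' @return A tibble with `subject_id`, `overall_change_pct`, posterior
#'   columns `p_comp1` ... `p_compM`, `component` (integer) and `label`
#'   (factor).
#' @export
#' @examples
#' m <- gmm(c(69.7, 115.1, 158.4), c(4.2, 13, 26.4), c(0.19, 0.55, 0.26))
#' tc <- tibble::tibble(subject_id = c("a", "b"),
#'                      overall_change_pct = c(72, 150))
#' classify_cohort(m, tc)
classify_cohort <- function(model, timecourses) {
  model <- as_gmm(model)
  need <- c("subject_id", "overall_change_pct")
  if (!all(need %in% names(timecourses))) {
    abort("`timecourses` must have columns subject_id and overall_change_pct",
          class = "mepmix_argument_error")
  }
  x <- timecourses$overall_change_pct
  p <- posterior(model, x)
  comp <- if (model$M >= 2L) {
    limits <- tryCatch(decision_boundaries(model)$boundary,
                       mepmix_boundary_error = function(e) NULL)
    if (is.null(limits)) {
      # a low-weight component can be dominated everywhere between the
      # means, leaving no crossing; Bayes arg-max is still well defined
      warn("no density crossing between some adjacent components; labels assigned by arg-max posterior")
      apply(p, 1L, which.max)
    } else {
      # strictly-on-the-limit goes left (left.open): ties to the lower mean
      findInterval(x, limits, left.open = TRUE) + 1L
    }
  } else {
    rep(1L, length(x))
  }
  labs <- subgroup_labels(model$M)
  out <- tibble::tibble(
    subject_id = timecourses$subject_id,
    overall_change_pct = x
  )
  pcols <- tibble::as_tibble(p)
  names(pcols) <- paste0("p_", colnames(p))
  out <- dplyr::bind_cols(out, pcols)
  out$component <- as.integer(comp)
  out$label <- factor(labs[comp], levels = labs)
  out
}

#' @describeIn classify_cohort Subjects labeled responder under a tri-modal
#'   model (arg-max posterior in the lowest-mean component).
#' @param assignments Output of `classify_cohort()`.
#' @return `gmm_responders()`: character vector of subject ids.
#' @export
gmm_responders <- function(assignments) {
  assignments$subject_id[assignments$component == 1L &
                           assignments$label %in% c("responder", "component-1")]
}
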