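#' Paired t-test as a tidy one-row result
#'
#' Classical paired Student t-test on elementwise differences (df = n - 1,
#' two-sided p), via [stats::t.test()], returned as a tibble. Degenerate
#' inputs that the downstream pipeline must not silently absorb — unequal
#' lengths, fewer than two pairs, zero variance of the differences — raise
#' classed errors instead of `NaN`s.
#'
#' @param x,y Numeric vectors of equal length (paired observations).
#' @return A tibble with columns `statistic`, `df`, `p_value`,
#'   `mean_difference`.
#' @export
#' @examples
#' paired_t(c(1, 2, 3, 4), c(2, 2, 4, 5))
paired_t <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length", class = "mepmix_argument_error")
  }
  if (length(x) < 2L) {
    abort("paired t-test needs at least 2 pairs", class = "mepmix_argument_error")
  }
  d <- x - y
  if (sd(d) == 0) {
    abort("differences have zero variance; the paired t statistic is undefined",
          class = "mepmix_data_error")
  }
  ht <- t.test(x, y, paired = TRUE)
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_difference = unname(ht$estimate)
  )
}

#' Post-hoc comparison of each post-interventional block against baseline
#'
#' For every post block P1...P6, a paired t-test of the subgroup's
#' normalized block values against the 100% baseline level (equivalent to
#' testing the raw block means against each subject's own baseline). No
#' multiplicity correction is applied by default — six uncorrected tests —
#' and a note to that effect is emitted; `correct = "bonferroni"` adjusts
#' the p-values instead.
#'
#' @param timecourses Time courses of one subgroup (tibble with `P1`...`P6`
#'   columns in % of baseline, see [summarize_subjects()]); at least 2
#'   subjects.
#' @param correct `"none"` (default) or `"bonferroni"`.
#' @return A tibble with one row per block: `block`, `statistic`, `df`,
#'   `p_value`, `mean_difference`.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 6, component_means = 69.7,
#'                      component_sds = 4.2, component_weights = 1, seed = 1)
#' tc <- summarize_subjects(filter_trials(generate_cohort(cfg)))
#' posthoc_vs_baseline(tc)
posthoc_vs_baseline <- function(timecourses, correct = c("none", "bonferroni")) {
  correct <- match.arg(correct)
  if (!all(post_blocks() %in% names(timecourses))) {
    abort("`timecourses` must have columns P1...P6", class = "mepmix_argument_error")
  }
  if (nrow(timecourses) < 2L) {
    abort("post-hoc tests need a subgroup of at least 2 subjects",
          class = "mepmix_argument_error")
  }
  if (correct == "none") {
    inform("post-hoc p-values are uncorrected for the six block comparisons")
  }
  out <- purrr::map_dfr(post_blocks(), function(b) {
    res <- paired_t(timecourses[[b]], rep(100, nrow(timecourses)))
    dplyr::mutate(res, block = b, .before = 1L)
  })
  if (correct == "bonferroni") {
    out$p_value <- stats::p.adjust(out$p_value, method = "bonferroni")
  }
  out
}
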