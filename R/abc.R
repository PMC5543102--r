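#' Long-term-depression response transform
#'
#' Converts overall MEP change (% of baseline) into the LTD-like response
#' magnitude `100 - MEP[%]`, with any facilitation (values above 100%)
#' treated as absent response (0). This is the positive-valued quantity that
#' computed ABC analysis categorizes.
#'
#' @param timecourses Tibble with `subject_id` and `overall_change_pct`
#'   (see [summarize_subjects()]), or a numeric vector of overall changes.
#' @return A tibble with columns `subject_id` and `ltd_value` (>= 0).
#' @export
#' @examples
#' ltd_transform(tibble::tibble(subject_id = c("a", "b", "c"),
#'                              overall_change_pct = c(69.7, 100, 158.4)))
ltd_transform <- function(timecourses) {
  if (is.numeric(timecourses)) {
    timecourses <- tibble::tibble(
      subject_id = sprintf("S%02d", seq_along(timecourses)),
      overall_change_pct = as.numeric(timecourses)
    )
  }
  if (!all(c("subject_id", "overall_change_pct") %in% names(timecourses))) {
    abort("`timecourses` must have columns subject_id and overall_change_pct",
          class = "mepmix_argument_error")
  }
  if (any(!is.finite(timecourses$overall_change_pct))) {
    abort("overall_change_pct must be finite", class = "mepmix_argument_error")
  }
  tibble::tibble(
    subject_id = as.character(timecourses$subject_id),
    ltd_value = pmax(0, 100 - timecourses$overall_change_pct)
  )
}

# Deterministic ordering used throughout ABC: descending value, ties by
# subject id.
abc_order <- function(ltd) {
  ltd[order(-ltd$ltd_value, ltd$subject_id), , drop = FALSE]
}

#' Cumulative contribution (ABC) curve
#'
#' Sorts the LTD responses in descending order and accumulates their
#' contribution: point i is (i/n, sum of the i largest values / total).
#' The curve starts at (0, 0), ends at (1, 1), and is concave because the
#' values are sorted — the "effort vs yield" curve of ABC analysis.
#'
#' @param ltd Output of [ltd_transform()] (columns `subject_id`,
#'   `ltd_value`), or a numeric vector.
#' @return A tibble with columns `rank` (0...n), `subject_id` (`NA` for the
#'   origin row), `ltd_value`, `effort` and `yield`.
#' @export
#' @examples
#' abc_curve(c(30, 10, 5, 0))
abc_curve <- function(ltd) {
  if (is.numeric(ltd)) ltd <- ltd_transform(100 - ltd)
  if (any(ltd$ltd_value < 0)) {
    abort("ltd_value must be >= 0", class = "mepmix_argument_error")
  }
  total <- sum(ltd$ltd_value)
  if (total <= 0) {
    abort("ABC analysis needs at least one positive response (all values are 0)",
          class = "mepmix_data_error")
  }
  srt <- abc_order(ltd)
  n <- nrow(srt)
  tibble::tibble(
    rank = 0:n,
    subject_id = c(NA_character_, srt$subject_id),
    ltd_value = c(NA_real_, srt$ltd_value),
    effort = (0:n) / n,
    yield = c(0, cumsum(srt$ltd_value)) / total
  )
}

#' Computed ABC partition of LTD responses
#'
#' Splits positive-valued responses into the "important few" (set A), an
#' intermediate set B, and the "trivial many" (set C), from the cumulative
#' contribution curve of [abc_curve()]:
#'
#' * the A/B limit is the curve point closest (Euclidean) to the ideal point
#'   (0, 1) — maximal yield for minimal effort;
#' * the B/C limit is the last point whose segment slope exceeds 1, i.e. the
#'   break-even rank beyond which an item contributes less than the average;
#'   if that falls at or before the A/B limit, B is empty.
#'
#' Zero-valued responses (absent LTD response) can never enter A or B.
#'
#' @param ltd Output of [ltd_transform()], or a numeric vector of LTD values.
#' @return An object of class `mep_abc`: list with `sets` (tibble
#'   `subject_id`, `ltd_value`, `abc_set`), `curve`, `a_limit_index`,
#'   `b_limit_index`. Methods: [tidy()], [autoplot()], `print()`.
#' @export
#' @examples
#' part <- abc_partition(c(30.3, 25, 20, 0, 0, 0))
#' tidy(part)
abc_partition <- function(ltd) {
  if (is.numeric(ltd)) ltd <- ltd_transform(100 - ltd)
  curve <- abc_curve(ltd)
  srt <- abc_order(ltd)
  n <- nrow(srt)

  # A/B limit: curve index (0..n) minimizing distance to the ideal (0, 1);
  # ties resolve to the smaller index (less effort)
  d2 <- curve$effort^2 + (1 - curve$yield)^2
  a_limit <- which.min(d2) - 1L

  # B/C break-even: last rank whose piecewise-linear slope exceeds 1.
  # slope of segment i = (yield_i - yield_{i-1}) / (1/n) = n * v_i / total
  slopes <- n * srt$ltd_value / sum(srt$ltd_value)
  b_limit <- if (any(slopes > 1)) max(which(slopes > 1)) else 0L
  if (b_limit <= a_limit) b_limit <- a_limit  # B empty

  # zero responses are never important: clamp both limits above the zeros
  n_pos <- sum(srt$ltd_value > 0)
  a_limit <- min(a_limit, n_pos)
  b_limit <- min(b_limit, n_pos)

  set <- rep("C", n)
  if (a_limit >= 1L) set[seq_len(a_limit)] <- "A"
  if (b_limit > a_limit) set[(a_limit + 1L):b_limit] <- "B"
  sets <- tibble::tibble(
    subject_id = srt$subject_id,
    ltd_value = srt$ltd_value,
    abc_set = factor(set, levels = c("A", "B", "C"))
  )
  structure(
    list(sets = sets, curve = curve,
         a_limit_index = a_limit, b_limit_index = b_limit),
    class = "mep_abc"
  )
}

#' @export
print.mep_abc <- function(x, ...) {
  tab <- table(x$sets$abc_set)
  cat(sprintf("<mep_abc> A: %d, B: %d, C: %d (limits at ranks %d / %d of %d)\n",
              tab[["A"]], tab[["B"]], tab[["C"]],
              x$a_limit_index, x$b_limit_index, nrow(x$sets)))
  invisible(x)
}

#' @describeIn abc_partition Membership tibble (`subject_id`, `ltd_value`,
#'   `abc_set`), in descending-value order.
#' @param x An `mep_abc` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mep_abc <- function(x, ...) {
  x$sets
}

#' @describeIn abc_partition Plot of the cumulative contribution curve with
#'   the A/B and B/C limits marked.
#' @param object An `mep_abc` object.
#' @exportS3Method ggplot2::autoplot
autoplot.mep_abc <- function(object, ...) {
  curve <- object$curve
  n <- nrow(object$sets)
  vlines <- c(object$a_limit_index, object$b_limit_index) / n
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$effort, y = .data$yield)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = vlines, linetype = "dashed") +
    ggplot2::labs(x = "fraction of subjects (effort)",
                  y = "fraction of total LTD response (yield)",
                  title = "Computed ABC analysis") +
    ggplot2::theme_minimal()
}

#' Responders according to ABC analysis
#'
#' The union of sets A and B — the subjects whose contribution to the
#' LTD-like effect is important.
#'
#' @param partition An `mep_abc` object from [abc_partition()].
#' @return Character vector of subject ids.
#' @export
abc_responders <- function(partition) {
  if (!inherits(partition, "mep_abc")) {
    abort("`partition` must come from abc_partition()",
          class = "mepmix_argument_error")
  }
  partition$sets$subject_id[partition$sets$abc_set %in% c("A", "B")]
}
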