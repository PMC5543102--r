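#' Overlay of the Pareto density estimate and a fitted mixture
#'
#' The standard fit picture: the empirical density (PDE, solid line), the
#' mixture density (dashed), and each weighted component, with the Bayesian
#' decision limits as vertical lines when the model has 2+ components.
#'
#' @param density An `mep_pde` object.
#' @param model An `mep_gmm` model or [em_fit()] result.
#' @return A ggplot object.
#' @export
plot_gmm_overlay <- function(density, model) {
  model <- as_gmm(model)
  grid <- density$grid
  comp <- model$components
  comp_df <- purrr::map_dfr(seq_len(model$M), function(i) {
    tibble::tibble(
      x = grid,
      density = comp$w[i] * dnorm(grid, comp$m[i], comp$s[i]),
      component = factor(i)
    )
  })
  p <- ggplot2::ggplot(tidy(density), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$density, linetype = "PDE")) +
    ggplot2::geom_line(
      data = tibble::tibble(x = grid, density = gmm_pdf(model, grid)),
      ggplot2::aes(y = .data$density, linetype = "GMM")
    ) +
    ggplot2::geom_line(
      data = comp_df,
      ggplot2::aes(y = .data$density, colour = .data$component)
    ) +
    ggplot2::scale_linetype_manual(NULL, values = c(PDE = "solid", GMM = "dashed")) +
    ggplot2::labs(x = "overall MEP change [% of baseline]",
                  y = "probability density", colour = "component") +
    ggplot2::theme_minimal()
  if (model$M >= 2L) {
    p <- p + ggplot2::geom_vline(
      xintercept = decision_boundaries(model)$boundary, linetype = "dotted"
    )
  }
  p
}

#' Quantile-quantile plot of data against a fitted mixture
#'
#' @param model An `mep_gmm` model or fit result.
#' @param values Numeric data vector.
#' @return A ggplot object.
#' @export
plot_qq <- function(model, values) {
  ggplot2::ggplot(qq_pairs(model, values),
                  ggplot2::aes(x = .data$theoretical, y = .data$empirical)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "model quantiles [%]", y = "observed quantiles [%]",
                  title = "QQ plot: observed vs mixture") +
    ggplot2::theme_minimal()
}

#' Per-subgroup time courses of normalized MEP amplitude
#'
#' One line per subject across baseline (100%) and P1...P6, coloured by the
#' assigned subgroup.
#'
#' @param timecourses Output of [summarize_subjects()].
#' @param assignments Output of [classify_cohort()] for the same subjects.
#' @return A ggplot object.
#' @export
plot_timecourses <- function(timecourses, assignments) {
  long <- timecourses |>
    dplyr::select("subject_id", dplyr::all_of(post_blocks())) |>
    dplyr::mutate(B = 100, .before = "P1") |>
    tidyr::pivot_longer(-"subject_id", names_to = "block",
                        values_to = "pct") |>
    dplyr::mutate(block = factor(.data$block, levels = c("B", post_blocks()))) |>
    dplyr::left_join(dplyr::select(assignments, "subject_id", "label"),
                     by = "subject_id")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$block, y = .data$pct,
                                     group = .data$subject_id,
                                     colour = .data$label)) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "block", y = "MEP amplitude [% of baseline]",
                  colour = "subgroup") +
    ggplot2::theme_minimal()
}
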