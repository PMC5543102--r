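#' Exclude contaminated trials and the first trial of every block
#'
#' Mirrors the standard MEP preprocessing rules: every trial flagged for
#' pre-stimulus muscle activity is dropped, as is the first trial of each
#' recording block; all other rows pass through unchanged, in their original
#' order.
#'
#' A block left with a single surviving trial raises a warning (its block
#' mean rests on one trial); a block with no surviving trial is an error,
#' because the subject's time course can no longer be computed.
#'
#' @param trials A trial tibble (see [generate_cohort()] / [read_trials()]).
#' @return The filtered trial tibble.
#' @export
#' @examples
#' trials <- generate_cohort(cohort_config(n_subjects = 2, seed = 1))
#' nrow(filter_trials(trials))
filter_trials <- function(trials) {
  trials <- validate_trials(tibble::as_tibble(trials))
  kept <- dplyr::filter(trials, !.data$prestim_flag, .data$trial != 1L)

  counts <- dplyr::count(kept, .data$subject_id, .data$block, .drop = FALSE)
  present <- dplyr::distinct(trials, .data$subject_id, .data$block)
  counts <- dplyr::semi_join(counts, present, by = c("subject_id", "block"))

  empty <- dplyr::filter(counts, .data$n == 0L)
  if (nrow(empty) > 0L) {
    abort(sprintf("no trials survive exclusion for subject %s block %s",
                  empty$subject_id[1], as.character(empty$block[1])),
          class = "mepmix_data_error")
  }
  lone <- dplyr::filter(counts, .data$n == 1L)
  if (nrow(lone) > 0L) {
    warn(sprintf("only one trial survives exclusion in %d block(s) (first: subject %s block %s)",
                 nrow(lone), lone$subject_id[1], as.character(lone$block[1])))
  }
  kept
}

#' Per-subject time courses of normalized MEP amplitude
#'
#' Condenses a filtered trial table to one row per subject: the mean
#' amplitude of each block, a pooled baseline `baseline_mv` (mean of the B1
#' and B2 block means), the six post-interventional blocks expressed as % of
#' that baseline (`P1`...`P6`; values above 100 indicate facilitation, below
#' 100 depression), and `overall_change_pct`, the mean of the six normalized
#' post values — the quantity whose distribution the mixture model describes.
#'
#' @param trials A trial tibble, normally the output of [filter_trials()].
#'   Trials are averaged as given; no further exclusion is applied here.
#' @return A tibble with columns `subject_id`, `baseline_mv`, `P1`...`P6`
#'   (% of baseline) and `overall_change_pct`.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 3, trial_cv = 0, contamination_rate = 0,
#'                      seed = 1)
#' summarize_subjects(filter_trials(generate_cohort(cfg)))
summarize_subjects <- function(trials) {
  trials <- validate_trials(tibble::as_tibble(trials))

  have <- dplyr::distinct(trials, .data$subject_id, .data$block)
  missing <- tidyr::expand_grid(
    subject_id = unique(trials$subject_id),
    block = factor(block_levels(), levels = block_levels())
  )
  missing <- dplyr::anti_join(missing, have, by = c("subject_id", "block"))
  if (nrow(missing) > 0L) {
    abort(sprintf("subject %s has no trials in block %s",
                  missing$subject_id[1], as.character(missing$block[1])),
          class = "mepmix_data_error")
  }

  block_means <- trials |>
    dplyr::group_by(.data$subject_id, .data$block) |>
    dplyr::summarise(mean_mv = mean(.data$amplitude_mv), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "block", values_from = "mean_mv")

  out <- block_means |>
    dplyr::mutate(baseline_mv = (.data$B1 + .data$B2) / 2) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(post_blocks()),
                                ~ 100 * .x / .data$baseline_mv))
  out$overall_change_pct <- rowMeans(out[post_blocks()])
  dplyr::select(out, "subject_id", "baseline_mv",
                dplyr::all_of(post_blocks()), "overall_change_pct") |>
    dplyr::arrange(.data$subject_id)
}

#' Summarize a single subject
#'
#' Convenience wrapper around [summarize_subjects()] for one subject.
#'
#' @param trials A trial tibble.
#' @param subject_id The subject to summarize.
#' @return A one-row tibble (see [summarize_subjects()]).
#' @export
summarize_subject <- function(trials, subject_id) {
  sub <- dplyr::filter(tibble::as_tibble(trials),
                       .data$subject_id == .env$subject_id)
  if (nrow(sub) == 0L) {
    abort(sprintf("no trials for subject %s", subject_id),
          class = "mepmix_data_error")
  }
  summarize_subjects(sub)
}

#' @importFrom rlang .env
NULL

#' Write per-subject time courses to CSV
#'
#' @param timecourses Output of [summarize_subjects()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(timecourses, path) {
  readr::write_csv(timecourses, path)
  invisible(path)
}
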