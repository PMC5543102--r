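#' Simulate a trial-level MEP cohort
#'
#' Draws, for each subject, a true plasticity component and effect from the
#' configured Gaussian mixture, a baseline MEP amplitude (truncated below at
#' 0.1 mV), and then single-trial peak-to-peak amplitudes for every block:
#' baseline blocks around the subject's baseline, post blocks around
#' baseline times effect/100, with SD equal to `trial_cv` times the block's
#' true mean and truncation at 0 mV (amplitudes are physically positive).
#' Each trial is independently flagged as contaminated by pre-stimulus muscle
#' activity with probability `contamination_rate`.
#'
#' @param config An [cohort_config()] object.
#' @return A tibble of trial records with columns `subject_id`, `block`
#'   (factor B1, B2, P1...P6), `trial`, `amplitude_mv`, `prestim_flag`, and an
#'   attached ground-truth tibble in attribute `"truth"` with columns
#'   `subject_id`, `true_component`, `true_effect_pct`, `baseline_mv`
#'   (see [cohort_truth()]).
#' @seealso [cohort_truth()], [write_cohort()], [sample_overall_changes()]
#' @export
#' @examples
#' trials <- generate_cohort(cohort_config(n_subjects = 4, seed = 1))
#' dplyr::count(trials, block)
generate_cohort <- function(config) {
  if (!inherits(config, "mep_cohort_config")) {
    abort("`config` must be created by cohort_config()",
          class = "mepmix_config_error")
  }
  validate_cohort_config(config)
  with_seed(config$seed, {
    n <- config$n_subjects
    k <- length(config$component_means)
    comp <- sample.int(k, n, replace = TRUE, prob = config$component_weights)
    effect <- rnorm(n, config$component_means[comp], config$component_sds[comp])
    baseline <- rnorm_trunc(n, config$baseline_mean,
                            config$baseline_between_subject_sd, lower = 0.1)

    blocks <- config$block_labels
    nt <- config$n_trials_per_block
    grid <- tidyr::expand_grid(
      subject_id = sprintf("S%02d", seq_len(n)),
      block = blocks,
      trial = seq_len(nt)
    )
    idx <- match(grid$subject_id, sprintf("S%02d", seq_len(n)))
    is_post <- grid$block %in% post_blocks()
    true_mean <- ifelse(is_post, baseline[idx] * effect[idx] / 100, baseline[idx])
    amp <- rnorm_trunc(nrow(grid), true_mean, config$trial_cv * true_mean,
                       lower = 0)
    flag <- runif(nrow(grid)) < config$contamination_rate

    trials <- tibble::tibble(
      subject_id = grid$subject_id,
      block = factor(grid$block, levels = blocks),
      trial = grid$trial,
      amplitude_mv = amp,
      prestim_flag = flag
    )
    truth <- tibble::tibble(
      subject_id = sprintf("S%02d", seq_len(n)),
      true_component = comp,
      true_effect_pct = effect,
      baseline_mv = baseline
    )
    attr(trials, "truth") <- truth
    trials
  })
}

#' Ground truth of a simulated cohort
#'
#' @param trials A cohort generated by [generate_cohort()].
#' @return The sidecar tibble with per-subject `true_component`,
#'   `true_effect_pct` and `baseline_mv`.
#' @export
cohort_truth <- function(trials) {
  truth <- attr(trials, "truth")
  if (is.null(truth)) {
    abort("no ground-truth attribute: was this table produced by generate_cohort()?",
          class = "mepmix_argument_error")
  }
  truth
}

#' Sample overall MEP changes directly from the effect mixture
#'
#' Fast path that skips trial-level simulation and draws i.i.d. values from
#' the configured Gaussian mixture of subject effects — the distribution that
#' the density estimation and mixture-fitting stages model.
#'
#' @param config An [cohort_config()] object (only the mixture parameters and
#'   seed are used).
#' @param n Number of draws.
#' @return A numeric vector of overall MEP changes, % of baseline.
#' @export
#' @examples
#' x <- sample_overall_changes(cohort_config(seed = 1), 5)
sample_overall_changes <- function(config, n) {
  if (!inherits(config, "mep_cohort_config")) {
    abort("`config` must be created by cohort_config()",
          class = "mepmix_config_error")
  }
  validate_cohort_config(config)
  stopifnot_scalar_number(n, "n")
  if (n < 1) {
    abort("`n` must be >= 1", class = "mepmix_argument_error")
  }
  n <- as.integer(n)
  with_seed(config$seed, {
    comp <- sample.int(length(config$component_means), n, replace = TRUE,
                       prob = config$component_weights)
    rnorm(n, config$component_means[comp], config$component_sds[comp])
  })
}

#' Write a simulated cohort (and its ground truth) to CSV
#'
#' @param trials Cohort tibble from [generate_cohort()].
#' @param path Output CSV for the long trial table (columns
#'   `subject_id,block,trial,amplitude_mv,prestim_flag`).
#' @param truth_path Optional CSV for the ground-truth sidecar
#'   (`subject_id,true_component,true_effect_pct,baseline_mv`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(trials, path, truth_path = NULL) {
  readr::write_csv(dplyr::mutate(trials, block = as.character(.data$block)),
                   path)
  if (!is.null(truth_path)) {
    readr::write_csv(cohort_truth(trials), truth_path)
  }
  invisible(path)
}

#' Read a long-format trial CSV
#'
#' Expects the columns written by [write_cohort()]; validates amplitudes,
#' block labels and the uniqueness of (subject, block, trial).
#'
#' @param path CSV path.
#' @return A trial tibble as produced by [generate_cohort()] (without ground
#'   truth).
#' @export
read_trials <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("subject_id", "block", "trial", "amplitude_mv", "prestim_flag")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L) {
    abort(paste0("trial CSV is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "mepmix_data_error")
  }
  x <- tibble::as_tibble(x[need])
  x$subject_id <- as.character(x$subject_id)
  x$prestim_flag <- as.logical(x$prestim_flag)
  validate_trials(x)
}

# Shared validation of a trial table: positive amplitudes, known block
# labels, unique (subject, block, trial).
validate_trials <- function(trials) {
  if (nrow(trials) == 0L) {
    abort("trial table is empty", class = "mepmix_data_error")
  }
  if (!all(as.character(trials$block) %in% block_levels())) {
    abort(paste0("unknown block labels: ",
                 paste(setdiff(unique(as.character(trials$block)),
                               block_levels()), collapse = ", ")),
          class = "mepmix_data_error")
  }
  if (any(!is.finite(trials$amplitude_mv) | trials$amplitude_mv <= 0)) {
    abort("amplitude_mv must be finite and > 0", class = "mepmix_data_error")
  }
  key <- paste(trials$subject_id, trials$block, trials$trial)
  if (anyDuplicated(key)) {
    abort("duplicated (subject_id, block, trial) rows", class = "mepmix_data_error")
  }
  trials$block <- factor(as.character(trials$block), levels = block_levels())
  trials
}
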