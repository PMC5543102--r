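#' Configuration for the synthetic MEP cohort generator
#'
#' Bundles the parameters of the simulated paired-cTBS experiment: a cohort of
#' subjects whose true plasticity effect (overall MEP change, in % of baseline)
#' is drawn from a Gaussian mixture, each measured in two baseline blocks and
#' six post-interventional blocks of peak-to-peak MEP amplitudes.
#'
#' The defaults reproduce the study conditions the package targets: 31
#' subjects, blocks of 21 trials, a tri-modal subject-level effect
#' (means 69.7/115.1/158.4% of baseline, SDs 4.2/13/26.4, weights
#' 0.19/0.55/0.26, i.e. responders / non-responders / paradox responders),
#' baseline amplitudes near 0.99 mV with 0.17 mV between-subject SD, and a
#' within-block trial coefficient of variation of 0.2.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param component_means Subject-effect component means, % of baseline.
#' @param component_sds Component standard deviations, % of baseline.
#' @param component_weights Mixture weights; must sum to 1.
#' @param baseline_mean Mean baseline MEP amplitude, mV.
#' @param baseline_between_subject_sd Between-subject SD of baseline, mV.
#' @param trial_cv Within-block coefficient of variation of single-trial
#'   amplitudes (SD = `trial_cv` times the block's true mean amplitude).
#' @param n_trials_per_block Trials recorded per block (the first trial of
#'   every block is discarded during preprocessing, so at least 2).
#' @param contamination_rate Probability that a trial is flagged for
#'   pre-stimulus muscle activity and hence excluded downstream.
#' @param seed Integer seed governing all draws, or `NULL` for the current
#'   RNG state.
#'
#' @return An object of class `mep_cohort_config` (a named list).
#' @seealso [generate_cohort()], [sample_overall_changes()]
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 8, seed = 1)
#' cfg$component_means
cohort_config <- function(n_subjects = 31,
                          component_means = c(69.7, 115.1, 158.4),
                          component_sds = c(4.2, 13, 26.4),
                          component_weights = c(0.19, 0.55, 0.26),
                          baseline_mean = 0.99,
                          baseline_between_subject_sd = 0.17,
                          trial_cv = 0.2,
                          n_trials_per_block = 21,
                          contamination_rate = 0.05,
                          seed = NULL) {
  cfg <- structure(
    list(
      n_subjects = as.integer(n_subjects),
      component_means = as.numeric(component_means),
      component_sds = as.numeric(component_sds),
      component_weights = as.numeric(component_weights),
      baseline_mean = as.numeric(baseline_mean),
      baseline_between_subject_sd = as.numeric(baseline_between_subject_sd),
      trial_cv = as.numeric(trial_cv),
      n_trials_per_block = as.integer(n_trials_per_block),
      block_labels = block_levels(),
      contamination_rate = as.numeric(contamination_rate),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "mep_cohort_config"
  )
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  k <- length(cfg$component_means)
  bad <- function(msg) abort(msg, class = "mepmix_config_error")
  if (k < 1L ||
      length(cfg$component_sds) != k ||
      length(cfg$component_weights) != k) {
    bad("component_means, component_sds and component_weights must have equal length >= 1")
  }
  if (any(cfg$component_weights <= 0)) {
    bad("all component_weights must be > 0")
  }
  if (abs(sum(cfg$component_weights) - 1) > 1e-9) {
    bad("component_weights must sum to 1 (tolerance 1e-9)")
  }
  if (any(cfg$component_sds < 0)) {
    bad("component_sds must be >= 0")
  }
  if (is.na(cfg$n_subjects) || cfg$n_subjects < 1L) {
    bad("n_subjects must be >= 1")
  }
  if (is.na(cfg$n_trials_per_block) || cfg$n_trials_per_block < 2L) {
    bad("n_trials_per_block must be >= 2 (the first trial of each block is discarded downstream)")
  }
  if (!is.finite(cfg$baseline_mean) || cfg$baseline_mean <= 0) {
    bad("baseline_mean must be > 0")
  }
  if (!is.finite(cfg$baseline_between_subject_sd) ||
      cfg$baseline_between_subject_sd < 0) {
    bad("baseline_between_subject_sd must be >= 0")
  }
  if (!is.finite(cfg$trial_cv) || cfg$trial_cv < 0) {
    bad("trial_cv must be >= 0")
  }
  if (!is.finite(cfg$contamination_rate) ||
      cfg$contamination_rate < 0 || cfg$contamination_rate >= 1) {
    bad("contamination_rate must lie in [0, 1)")
  }
  cfg
}

#' Read a cohort configuration from a YAML file
#'
#' Keys match the arguments of [cohort_config()]; unknown keys are rejected
#' so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return An `mep_cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(cohort_config)), "")
  extra <- setdiff(names(raw), c(known, "block_labels"))
  if (length(extra) > 0L) {
    abort(paste0("unknown configuration keys: ", paste(extra, collapse = ", ")),
          class = "mepmix_config_error")
  }
  raw$block_labels <- NULL
  do.call(cohort_config, raw)
}

#' @export
print.mep_cohort_config <- function(x, ...) {
  cat("<mep_cohort_config>\n")
  cat(sprintf("  %d subjects, %d trials/block, blocks %s\n",
              x$n_subjects, x$n_trials_per_block,
              paste(x$block_labels, collapse = " ")))
  cat(sprintf("  effect mixture: means %s | sds %s | weights %s (%% of baseline)\n",
              paste(x$component_means, collapse = "/"),
              paste(x$component_sds, collapse = "/"),
              paste(x$component_weights, collapse = "/")))
  cat(sprintf("  baseline %.2f +/- %.2f mV, trial CV %.2f, contamination %.2f\n",
              x$baseline_mean, x$baseline_between_subject_sd,
              x$trial_cv, x$contamination_rate))
  if (!is.null(x$seed)) cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
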