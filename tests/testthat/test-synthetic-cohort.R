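test_that("config invariants are enforced", {
  expect_s3_class(cohort_config(), "mep_cohort_config")
  expect_error(cohort_config(component_weights = c(0.5, 0.4, 0.1 + 1e-6)),
               class = "mepmix_config_error")
  expect_error(cohort_config(component_weights = c(1.2, -0.2, 0)),
               class = "mepmix_config_error")
  expect_error(cohort_config(component_means = c(70, 110)),
               class = "mepmix_config_error", regexp = "equal length")
  expect_error(cohort_config(n_trials_per_block = 1),
               class = "mepmix_config_error")
  expect_error(cohort_config(baseline_mean = 0), class = "mepmix_config_error")
  expect_error(cohort_config(trial_cv = -0.1), class = "mepmix_config_error")
  expect_error(cohort_config(contamination_rate = 1),
               class = "mepmix_config_error")
})

test_that("config round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- cohort_config(n_subjects = 12, trial_cv = 0.1, seed = 5)
  yaml::write_yaml(unclass(cfg), path)
  expect_equal(read_cohort_config(path), cfg)
  yaml::write_yaml(c(unclass(cfg), list(typo_key = 1)), path)
  expect_error(read_cohort_config(path), class = "mepmix_config_error",
               regexp = "typo_key")
})

test_that("generated cohorts have the designed shape and ground truth", {
  cfg <- cohort_config(seed = 1)
  trials <- generate_cohort(cfg)
  expect_equal(nrow(trials), 31 * 8 * 21)
  expect_equal(levels(trials$block), c("B1", "B2", paste0("P", 1:6)))
  expect_true(all(trials$amplitude_mv > 0))
  truth <- cohort_truth(trials)
  expect_equal(nrow(truth), 31)
  expect_true(all(truth$true_component %in% 1:3))
  expect_true(all(truth$baseline_mv > 0.1))

  clean <- generate_cohort(cohort_config(contamination_rate = 0, seed = 2))
  expect_false(any(clean$prestim_flag))
})

test_that("generation is deterministic given the seed and leaves the RNG alone", {
  cfg <- cohort_config(n_subjects = 5, seed = 7)
  a <- generate_cohort(cfg)
  set.seed(123)
  before <- .Random.seed
  b <- generate_cohort(cfg)
  expect_identical(.Random.seed, before)
  expect_identical(a, b)
  expect_identical(sample_overall_changes(cfg, 50),
                   sample_overall_changes(cfg, 50))
})

test_that("subject effects follow the configured mixture", {
  # oracle: closed-form mixture mean sum(w*m) = 117.732
  cfg <- cohort_config(n_subjects = 10000, n_trials_per_block = 2, seed = 11)
  truth <- cohort_truth(generate_cohort(cfg))
  expect_equal(mean(truth$true_effect_pct), 117.732, tolerance = 0.01)
  # component frequencies match the weights
  freq <- as.numeric(table(truth$true_component)) / 10000
  expect_equal(freq, c(0.19, 0.55, 0.26), tolerance = 0.1)
})

test_that("fast-path sampler matches the closed-form mixture", {
  cfg <- cohort_config(seed = 3)
  x <- sample_overall_changes(cfg, 1e5)
  # oracle: mixture CDF at 80.9 = 0.1920478 (closed form), slack 0.01 absolute
  expect_lt(abs(mean(x < 80.9) - 0.1920478), 0.01)
  # oracle: closed-form mixture mean 117.732 and variance 1149.676
  expect_equal(mean(x), 117.732, tolerance = 0.01)
  expect_equal(var(x), 1149.676, tolerance = 0.01)
})

test_that("single tight component collapses to its mean", {
  cfg <- cohort_config(component_means = 100, component_sds = 1e-6,
                       component_weights = 1, seed = 4)
  x <- sample_overall_changes(cfg, 100)
  expect_equal(x, rep(100, 100), tolerance = 1e-4)
  expect_error(sample_overall_changes(cfg, 0), class = "mepmix_argument_error")
})

test_that("trial CSV round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  truth_path <- withr::local_tempfile(fileext = ".csv")
  trials <- generate_cohort(cohort_config(n_subjects = 3, seed = 9))
  write_cohort(trials, path, truth_path)
  back <- read_trials(path)
  expect_equal(back$amplitude_mv, trials$amplitude_mv)
  expect_equal(as.character(back$block), as.character(trials$block))
  expect_equal(nrow(readr::read_csv(truth_path, show_col_types = FALSE)), 3)
})
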