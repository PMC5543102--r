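test_that("LTD transform clamps facilitation to zero", {
  tc <- tibble::tibble(subject_id = c("a", "b", "c"),
                       overall_change_pct = c(69.7, 100, 158.4))
  ltd <- ltd_transform(tc)
  expect_equal(ltd$ltd_value, c(30.3, 0, 0))
  expect_error(ltd_transform(tibble::tibble(subject_id = "a",
                                            overall_change_pct = NA_real_)),
               class = "mepmix_argument_error")
})

test_that("ABC curve accumulates sorted contributions", {
  eq <- abc_curve(tibble::tibble(subject_id = letters[1:4],
                                 ltd_value = rep(10, 4)))
  expect_equal(eq$effort, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(eq$yield, c(0, 0.25, 0.5, 0.75, 1))

  skewed <- abc_curve(tibble::tibble(subject_id = c("a", "b", "c"),
                                     ltd_value = c(30, 0, 0)))
  expect_equal(skewed$yield, c(0, 1, 1, 1))
  expect_equal(skewed$effort, c(0, 1, 2, 3) / 3)

  x <- withr::with_seed(4, runif(20, 0, 40))
  cv <- abc_curve(tibble::tibble(subject_id = sprintf("s%02d", 1:20),
                                 ltd_value = x))
  expect_equal(cv$yield[1], 0)
  expect_equal(cv$yield[21], 1)
  expect_true(all(diff(cv$yield) >= 0))
  # concavity: segment slopes non-increasing because values are sorted
  expect_true(all(diff(diff(cv$yield)) <= 1e-12))

  expect_error(abc_curve(tibble::tibble(subject_id = "a", ltd_value = 0)),
               class = "mepmix_data_error")
})

test_that("partition is a disjoint monotone cover with zeros forced into C", {
  vals <- c(30.3, 25, 20, rep(0, 28))
  part <- abc_partition(tibble::tibble(subject_id = sprintf("s%02d", 1:31),
                                       ltd_value = vals))
  sets <- tidy(part)
  expect_equal(nrow(sets), 31)
  expect_equal(sum(sets$abc_set == "C"), 28)
  expect_true(all(sets$ltd_value[sets$abc_set != "C"] > 0))
  # monotone: every A value >= every B value >= every C value
  expect_gte(min(sets$ltd_value[sets$abc_set == "A"]),
             max(sets$ltd_value[sets$abc_set == "B"], 0))
  expect_gte(min(sets$ltd_value[sets$abc_set != "C"]),
             max(sets$ltd_value[sets$abc_set == "C"]))
})

test_that("a dominant contributor lands in A", {
  # oracle: enumerating distances to (0,1) for values 100,1,1,1,1 puts the
  # closest curve point at rank 1
  vals <- c(100, 1, 1, 1, 1)
  cum <- cumsum(sort(vals, decreasing = TRUE))
  d2 <- ((0:5) / 5)^2 + (1 - c(0, cum / sum(vals)))^2
  expect_equal(which.min(d2) - 1L, 1L)
  part <- abc_partition(tibble::tibble(subject_id = letters[1:5],
                                       ltd_value = vals))
  expect_equal(part$a_limit_index, 1L)
  expect_equal(tidy(part)$abc_set[tidy(part)$ltd_value == 100],
               factor("A", levels = c("A", "B", "C")))
})

test_that("partition is scale invariant and deterministic under ties", {
  vals <- tibble::tibble(subject_id = sprintf("s%02d", 1:12),
                         ltd_value = withr::with_seed(9, rexp(12, 1 / 10)))
  p1 <- tidy(abc_partition(vals))
  p2 <- tidy(abc_partition(dplyr::mutate(vals, ltd_value = ltd_value * 37)))
  expect_equal(p1$subject_id, p2$subject_id)
  expect_equal(p1$abc_set, p2$abc_set)

  tied <- tibble::tibble(subject_id = c("b", "a", "c"), ltd_value = c(5, 5, 5))
  expect_equal(tidy(abc_partition(tied))$subject_id, c("a", "b", "c"))
})

test_that("abc_responders returns the union of A and B", {
  vals <- tibble::tibble(subject_id = letters[1:6],
                         ltd_value = c(40, 25, 12, 3, 0, 0))
  part <- abc_partition(vals)
  sets <- tidy(part)
  expect_setequal(abc_responders(part),
                  sets$subject_id[sets$abc_set %in% c("A", "B")])

  lone <- abc_partition(tibble::tibble(subject_id = letters[1:5],
                                       ltd_value = c(17, 0, 0, 0, 0)))
  expect_equal(abc_responders(lone), "a")
})

test_that("GMM and ABC agree on the responders of the fixture cohort", {
  trials <- fixture_cohort()
  tc <- suppressWarnings(summarize_subjects(filter_trials(trials)))
  fit <- em_fit(tc$overall_change_pct, M = 3, seed = 1)
  assignments <- classify_cohort(fit, tc)
  gmm_set <- gmm_responders(assignments)
  abc_set <- abc_responders(abc_partition(ltd_transform(tc)))
  expect_setequal(abc_set, gmm_set)
})
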