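# Shared fixtures, built in code.

# The tri-modal reference mixture of overall MEP change used throughout the
# tests: responders / non-responders / paradox responders.
ref_gmm <- function() {
  gmm(means = c(69.7, 115.1, 158.4),
      sds = c(4.2, 13, 26.4),
      weights = c(0.19, 0.55, 0.26))
}

ref_config <- function(...) {
  cohort_config(...)
}

# Frozen seed of the bundled 31-subject fixture cohort used by the
# cross-method (GMM vs ABC) agreement checks.
FIXTURE_COHORT_SEED <- 20260921L

fixture_cohort <- function() {
  generate_cohort(cohort_config(seed = FIXTURE_COHORT_SEED))
}

# A tiny deterministic trial table: one subject, every block, constant
# amplitudes per block (no noise), no contamination.
flat_trials <- function(block_means, subject_id = "S01", n_trials = 21L) {
  stopifnot(length(block_means) == 8L)
  blocks <- c("B1", "B2", paste0("P", 1:6))
  tibble::tibble(
    subject_id = subject_id,
    block = factor(rep(blocks, each = n_trials), levels = blocks),
    trial = rep(seq_len(n_trials), times = 8L),
    amplitude_mv = rep(block_means, each = n_trials),
    prestim_flag = FALSE
  )
}
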