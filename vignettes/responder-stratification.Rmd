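---
title: "Responder stratification from MEP time courses: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Responder stratification from MEP time courses: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mepmix)
```

This vignette documents the statistical model behind `mepmix`, the tunable
parameters and their defaults, the numerical choices, and the points where
the design was genuinely open. It is the companion to the function
reference: the reference says *what* each function does, this document says
*why*.

## The measurement model

The unit of observation is a single-trial motor-evoked potential (MEP)
amplitude (peak-to-peak, mV). A session consists of eight blocks of 21
trials: two baseline blocks (B1, B2) before plasticity induction and six
post-interventional blocks (P1…P6) spanning roughly 5–50 minutes after it.
Preprocessing is deliberately minimal and fixed:

* trials flagged for pre-stimulus muscle activity are excluded, as is the
  first trial of every block (it is systematically atypical);
* surviving trials are averaged per block (plain arithmetic mean — no
  trimming, no medians);
* the baseline is the mean of the two baseline *block means*, not of the
  pooled trials. The two coincide when both blocks lose equally many
  trials; averaging block means keeps the two baseline measurements
  equally weighted when they do not;
* each post block is expressed as % of baseline and the six values are
  averaged into the subject's **overall MEP change**. Values below 100%
  indicate an LTD-like depression, above 100% facilitation.

Subjects missing a block are rejected, not imputed: the target designs have
complete data, and silent imputation would distort the distribution that
everything downstream models.

## The group-structure model

The overall MEP change across a cohort is modeled as a one-dimensional
Gaussian mixture

$$p(x) = \sum_{i=1}^{M} w_i\, \mathcal{N}(x \mid m_i, s_i), \qquad
\sum_i w_i = 1 .$$

In the tri-modal case the ascending-mean components are read as
**responders**, **non-responders** and **paradox responders**. Components
are indexed 1…M by ascending mean; the mixture likelihood is
label-symmetric, so this ordering is a convention applied after fitting,
not a constraint of the optimization.

### Pareto density estimation

Before any parametric fit, the empirical density is estimated with
`pde()`: a uniform (hypersphere-count) kernel whose radius is the 18th
percentile of the pairwise distances between observations
(`pareto_radius()`). The flat kernel with a data-derived radius preserves
multimodal structure that a wider Gaussian kernel tends to smooth away,
which is the reason this estimator is preferred for group discovery. The
radius rule is isolated behind a single function with a `quantile_level`
argument, so an alternative percentile can be substituted in one place.
For more than 5,000 observations the pairwise distances are computed on a
seeded subsample of 5,000 — the radius is a coarse quantile and does not
benefit from the full quadratic computation.

The PDE is diagnostic: the mixture is fitted to the raw values by maximum
likelihood, never to the density curve. The root-mean-square difference
between the fitted mixture and the PDE (`rmse_to_pde()`) is reported as a
goodness-of-fit number because it is the traditional visual-fit criterion,
but it is not the objective being optimized; a likelihood-based fit is
reproducible where an interactively adjusted one is not.

### EM: initialization, restarts, and why their form matters

`em_fit()` maximizes the likelihood with EM: responsibilities in log-space,
closed-form weighted-moment updates, a convergence tolerance of 1e-8 on the
relative log-likelihood increase, and at most 2,000 iterations. Twenty
starts are used: one deterministic (quantile partition of the sorted data
into M equal segments) plus nineteen seeded k-means partitions (Lloyd's
algorithm from randomly drawn distinct centers, run to convergence), each
advanced with a loose tolerance first and only the best candidate polished
to full convergence. The best non-degenerate solution wins.

The *form* of the restarts is a substantive choice, not a detail. The
mixture likelihood is unbounded: a component can collapse onto a handful of
near-identical points with arbitrarily small variance, and short of that, a
tiny "spike" component glued to a local clump buys a real but meaningless
likelihood gain. Fully unstructured starts (component means drawn as random
data points) discover such spikes routinely, and that has a downstream
consequence: the likelihood-ratio ladder below compares fitted likelihoods
against a χ²(1) critical value, a calibration that presumes the compared
optima are the canonical, structured ones. With spike-hunting restarts the
1→2 step on *unimodal* data exceeds the 3.84 threshold several times more
often than its nominal level; with partition-based (k-means) restarts the
exceedance stays near the 10–15% that standard k-means-initialized EM
implementations exhibit. Partition starts are therefore the default and
only restart scheme.

Two guards back this up numerically. Component SDs are floored at 1e-3
times the data range during iteration, and a solution still sitting on that
floor after convergence is discarded as degenerate (all-degenerate restarts
raise an error). On very small samples (a 31-subject cohort fitted with
M = 4) every restart can degenerate; `select_components()` then treats that
order — and all larger ones — as not estimable and ends the ladder at the
last feasible rung instead of failing the whole analysis.

### Choosing the number of components

`select_components()` fits M = 1…`M_max` (default 4) and walks up:
the step M−1 → M is accepted iff

$$\Delta_{-2LL} = -2\,(\log L_{M-1} - \log L_M) > \chi^2_{1-\alpha}(df),$$

strictly — a tie rejects. The chosen order is the last rung reached by
consecutive accepted steps. The default critical value is 3.84 (α = 0.05,
df = 1), the operative convention in this literature; a df = 3 variant
(7.81), matching the three parameters an extra component adds, is available
via `lr_df = 3` and announces itself when used. Two caveats are documented
rather than hidden:

* the regularity conditions behind the χ² approximation do not hold at the
  boundary of a mixture family, and the step statistic is mildly
  anti-conservative in practice — on unimodal data the ladder keeps M = 1
  in a clear majority of replicates, but less than the nominal 95%;
* a slightly *negative* step statistic is possible (EM at the larger order
  can stop at an interior optimum marginally below the nested solution);
  it simply rejects the step. Only a gross decrease (> 5 nats) is treated
  as an optimizer failure.

At the scale of a single 31-subject cohort the selected order genuinely
fluctuates: replicate simulated cohorts from a tri-modal truth are read as
bi-, tri- or quadri-modal depending on the draw. That is a property of the
likelihood-ratio criterion at n = 31, and one reason the acceptance-level
checks of order recovery are run at a hundred times the cohort size, where
the selection is stable.

### Posteriors, decision limits and labels

By Bayes' theorem the probability that observation x belongs to component i
is $w_i N(x|m_i,s_i) / \sum_j w_j N(x|m_j,s_j)$ (`posterior()`, computed in
log-space so tail observations do not underflow). Between each pair of
adjacent components the weighted densities intersect at exactly the point
where the posterior switches; `decision_boundaries()` finds that root on
the open interval between the two means with bracketed root-finding on the
log-density difference (|f(root)| < 1e-10).

Two deliberate restrictions:

* **Only adjacent-pair intersections on (mₖ, mₖ₊₁) are reported.** With
  unequal variances a second crossing always exists far in a tail; a
  tri-modal model reports exactly two limits, matching how such models are
  used and read.
* **Classification follows the limits**, i.e. the arg-max posterior
  restricted to the components adjacent to each limit, with an exact tie
  going to the lower-mean component. The unrestricted arg-max coincides
  with this everywhere except in the extreme tails, where the widest
  component eventually dominates a tighter, nearer one (for the reference
  tri-modal model, below ≈ 53% of baseline — outside the range where real
  overall MEP changes occur). Following the limits keeps labels monotone
  in the overall change, which is how decision limits are used clinically.

If a fitted low-weight component is dominated *everywhere* between the
means (its weighted density never crosses the neighbour's), no limit exists
there; `decision_boundaries()` raises an error for that pair, and
`classify_cohort()` falls back to the unrestricted arg-max posterior with a
warning — Bayes assignment is still well defined even when the partition
into intervals is not.

### Computed ABC analysis

The second, independent route to the responders starts from the LTD-like
response 100 − MEP[%], with facilitation treated as absent response
(clamped to 0). The responses are sorted in descending order and
accumulated into an effort/yield curve (point i = (i/n, share of the total
response contributed by the i largest)). Two limits cut the curve:

* the **A limit** is the curve point with minimal Euclidean distance to the
  ideal point (0, 1) — maximum yield for minimum effort;
* the **B limit** is the last point whose segment slope exceeds 1, the
  break-even rank beyond which an item contributes less than the average;
  if that falls at or before the A limit, B is empty.

Sets A and B are the "important few" — the ABC responders. Zero responses
can never enter A or B (the technique is defined for positive data; a
subject with no LTD response cannot be an important contributor to it).
Ties are ordered by subject id so the partition is deterministic. Both
limit rules live behind single functions; published ABC implementations
differ in edge handling (interpolated vs. data-point limits), and the
data-point convention used here is the simplest one that keeps the
partition a function of the ranks alone.

### Confirmatory statistics

`paired_t()` wraps the classical paired Student t-test, with classed errors
for the degenerate inputs a pipeline must not absorb silently (unequal
lengths, fewer than two pairs, zero-variance differences).
`posthoc_vs_baseline()` tests each post block against the 100% baseline
level within a subgroup — on the normalized scale, which is equivalent to
testing raw block means against each subject's own baseline and keeps the
test scale-free. No multiplicity correction is applied by default, because
the six per-block tests are descriptive follow-ups, and the function says
so; a Bonferroni option exists. The omnibus repeated-measures ANOVA
(block × group × sex × time-of-day) is deliberately out of scope — it
confirms a subgrouping rather than producing one, and standard tools
(`stats::aov`, `afex`, `ez`) do it well.

## The synthetic cohort generator

`generate_cohort()` emulates the study design the analysis targets, with
ground truth attached. Per subject: a true component drawn by the mixture
weights, a true effect e ~ N(m, s) on the % scale, a baseline
b ~ N(0.99, 0.17) mV truncated at 0.1 mV; per trial: amplitude
~ N(b, cv·b) in baseline blocks and N(b·e/100, cv·b·e/100) in post blocks,
truncated at 0 (amplitudes are physically positive), plus an independent
contamination flag with probability 0.05. Defaults (`cohort_config()`):

| parameter | default | rationale |
|---|---|---|
| `n_subjects` | 31 | target cohort size |
| `component_means` | 69.7 / 115.1 / 158.4 % | tri-modal plasticity effect |
| `component_sds` | 4.2 / 13 / 26.4 % | component spreads |
| `component_weights` | 0.19 / 0.55 / 0.26 | subgroup prevalences |
| `baseline_mean`, `baseline_between_subject_sd` | 0.99, 0.17 mV | typical 1-mV targeting |
| `trial_cv` | 0.2 | see below |
| `n_trials_per_block` | 21 | block design (first trial later discarded) |
| `contamination_rate` | 0.05 | occasional pre-stimulus muscle activity |

The within-block coefficient of variation of 0.2 was chosen once so that
simulated baseline-block SDs bracket the 0.14–0.26 mV range typical of
1-mV-targeted baseline blocks; block-level drift between B1 and B2 is *not*
modeled (whether such differences reflect drift or chance is not decidable
from block summaries, so one CV governs both blocks). The contamination
flag is generated, not inferred: simulating EMG traces to re-detect
background activation would add realism the downstream analysis never
sees — the flag stands in for the experimenter's real-time judgment.

What the generator deliberately does **not** emulate: EMG waveforms,
coil/threshold physics, slow within-session drift, non-Gaussian trial
noise, and within-subject dependence of post blocks beyond the shared true
effect. Tests passing on these cohorts therefore show that the *pipeline*
recovers the structure it assumes; they cannot show that real MEP data obey
that structure.

A fast path, `sample_overall_changes()`, draws overall changes directly
from the effect mixture for studies of the modeling stages in isolation.
All generation is deterministic given `seed` and restores the caller's RNG
state.

## Reproducibility and problem sizes

Every stochastic function takes a seed; `run_pipeline()` fans a master seed
out to fixed per-stage child seeds, so stages are independently
reproducible and two runs with the same inputs produce byte-identical
artifacts. The test suite exercises the distribution-level claims at sizes
chosen to make the checks sharp but quick: density and CDF oracles at
n = 10⁵ draws, EM recovery at n = 10⁴ (where the responder mean is pinned
to ±1% while the broad third component still wanders by a few percent —
its sampling error, not a fitting defect), order selection at n = 3,100,
null calibration of the selection step at n = 1,000 over 50 replicates, and
cohort-level properties at n = 31 over 1,000 replicate cohorts.

## Known limitations

* The χ²(df = 1) ladder is anti-conservative for mixtures; a bootstrap
  likelihood-ratio test would be better calibrated and is not implemented.
* Decision limits carry no uncertainty intervals (no bootstrap of the GMM).
* The ABC limit rules reconstruct the computed-ABC methodology from its
  published description; other implementations may differ at edge cases.
* Components are Gaussian by assumption; heavy-tailed or skewed responder
  distributions will be approximated by extra Gaussian components rather
  than detected.
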