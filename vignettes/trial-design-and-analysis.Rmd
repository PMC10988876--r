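---
title: "Designing and analyzing a gout non-inferiority trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analyzing a gout non-inferiority trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrial)
```

This vignette is the package's own account of its statistical content:
the models and procedures it implements, the assumptions behind them,
the parameters that matter, and the design choices made where the
methodology left room.

## 1. The non-inferiority design

The trial compares prednisolone (test treatment, TT) with colchicine
(standard treatment, ST) in acute gout. Both drugs work; the question is
whether prednisolone is *acceptably close*: with day-3 pain on the 0–10
numeric rating scale (NRS) as primary outcome and margin
$\delta = 1$ NRS unit,

$$H_0: \mu_{TT} - \mu_{ST} \ge \delta
  \qquad vs. \qquad
  H_1: \mu_{TT} - \mu_{ST} < \delta .$$

Sizing treats this as a one-sided two-sample $t$-test whose detectable
shift is the margin minus the planning difference. The defaults of
`design_assumptions()` are the trial's planning values:

| parameter | default | units | meaning |
|---|---|---|---|
| `alpha_one_sided` | 0.05 | — | sizing significance level |
| `power` | 0.90 | — | target power |
| `sigma` | 2.24 | NRS | common day-3 SD |
| `ni_margin` | 1 | NRS | non-inferiority margin |
| `assumed_diff` | 0.22 | NRS | planning difference (TT − ST) |
| `dropout_rate` | 0.10 | — | anticipated patient dropout |

```{r}
d <- design_assumptions()
required_n_per_arm(d)
inflate_for_dropout(required_n_per_arm(d), d$dropout_rate)
achieved_power(d, 142)
```

**Sign convention.** `assumed_diff` is the *excess pain expected under
prednisolone* ($\mu_{TT}-\mu_{ST}$), so the effective shift is
$\delta - 0.22 = 0.78$. Only this reading reproduces both the 142-per-arm
size and a positive ANCOVA treatment coefficient of 0.22 in recovery
simulations; the package uses it consistently everywhere.

**Exact versus approximate power.** Power is computed from the
noncentral $t$ distribution with $2n-2$ degrees of freedom — the
behavior of standard power software — rather than the normal
approximation, which is exposed only as the cross-check
`normal_approx_n()` (it undershoots by roughly one patient at these
sizes). `monte_carlo_power()` validates the analytic value by
simulation, and with `shift = 0` checks type-I error at the hypothesis
boundary.

**One-sided 5% sizing, two-sided 95% analysis.** The plan sizes with a
one-sided 5% test but analyzes with two-sided 95% confidence intervals,
an effective one-sided 2.5% rule. The package does not silently resolve
this asymmetry: the design module defaults to the sizing convention,
the analysis module to the analysis convention, and both are
parameterized.

**Dropout inflation** adds the *ceiling* of `dropout_rate × n` per arm
(142 → +15 → 157 per arm, 314 total), not a rounded or relative
inflation.

## 2. Randomization

`generate_pbr_lists()` produces one predefined allocation list per
recruiting center (default 60 centers × 30 entries): block lengths are
drawn uniformly from {2, 4, 6}, each block is a random permutation with
equal arm counts, and the concatenation is truncated to the list length.
Truncation (rather than padding the final block) is the right model
because recruitment only ever consumes a *prefix* of the list; a partial
final block behaves identically either way. Consequences tested in the
suite: every prefix of every list has imbalance at most
`max(block_sizes)/2 = 3`, and the marginal allocation probability at
every position is 1/2.

`generate_cr_lists()` is the complete-randomization comparator —
independent fair coins, no balance constraint — generated per center by
default (a pooled single list is available, since the granularity of
the comparator is not fixed by the design).

Two handling rules mirror trial practice: a seed is *required* and never
hard-coded (seed-setting is the sponsor's role, separate from the
statistician's code), and block boundaries are stored but concealed in
exports unless explicitly unblinded.

## 3. Recruitment imbalance simulation

Multicenter primary-care trials lose recruiting centers. The simulation
asks what that does to treatment-arm balance. Per replicate, each center
drops out with probability $p$; survivors recruit by one of two
zero-inflated Poisson formulations:

* **unrestricted** — center $i$ recruits $\mathrm{Poisson}(\lambda_i)$,
  capped at its 30-entry list (allocation beyond the predefined list is
  impossible, so the cap is structural). Total recruitment is random:
  neither reaching the target nor avoiding over-recruitment is
  guaranteed.
* **restricted** — the total $n=\sum_i \lambda_i$ is fixed and spread
  over surviving centers multinomially with probabilities proportional
  to $\lambda_i$ (the conditional law of independent Poissons given
  their sum), capped with multinomial reallocation of overflow; a
  capacity shortfall is flagged, not an error.

Recruits are then allocated along each center's list prefix and the
absolute arm difference recorded. `run_imbalance_grid()` crosses dropout
probabilities {0.1, …, 0.5} with recruitment means λ ∈ {4, 5, 6}
(clinicians expected 4–6 patients per practice), 1000 replicates per
cell, with an independent seeded substream per cell.

Choices worth stating: λ is applied homogeneously within a cell, with a
heterogeneous mode (per-center λ drawn uniformly from the set) as an
option, since only the 4–6 range — not the mixing law — is pinned down;
the restricted total defaults to $\sum\lambda_i$ per its definition, with
the trial's 314 available via `total_target`; and fresh lists are drawn
each replicate so the exceedance estimates average over list
realizations too.

Under PBR the imbalance is deterministically bounded by
(number of centers) × max(block)/2 and in practice tiny —
$P(|n_{TT}-n_{ST}|>20)$ stays below 1% in essentially every cell. Under
CR the signed difference has variance equal to the total recruited, and
the same exceedance probability averages around 15% over this grid
(roughly 7% in the smallest cells to 25% in the largest); the package
reports per-cell probabilities so any summary convention can be checked.
That qualitative gap — two orders of magnitude at the trial's scale — is
the design argument for permuted blocks in this setting.

## 4. The synthetic trial generator

`generate_trial()` draws complete patient-level datasets so that every
analysis stage is testable. What it emulates:

* **Daily pain** on a latent continuous scale: baseline
  $\mathcal N(7, 1.5^2)$; day $t$ equals baseline mean minus a decay
  profile (defaults 1.2, 2.2, 3.2, 3.8, 4.2, 4.5 NRS by day 6), plus a
  baseline carry-over calibrated to a baseline/day-3 correlation of 0.4,
  a center random intercept (SD 0.3), the arm effect (`true_diff`,
  default 0.22, applied to TT), and residual noise sized so the
  *marginal* day-3 SD is 2.24. Values are then rounded and clamped to
  the integer 0–10 grid — after the arm effect, so a small true
  difference survives in expectation. Baseline mean/SD, the correlation
  and the decay profile are generator defaults (the plan does not state
  them), chosen so the day-3 SD target is attainable; they are
  parameters, not protocol values.
* **Arms** always come from the randomization lists, never ad hoc.
* **Likert secondaries** (swelling/tenderness day 3, global success day
  6) by thresholding latent improvement plus noise.
* **Withdrawal** ("attrition prior day 6") with probability
  `dropout_rate` on days 1–5; the diary after the withdrawal day is
  missing. `MCAR` withdraws uniformly; `MAR` makes the withdrawal odds
  increase with observed baseline pain, with the intercept calibrated by
  root-finding so the marginal rate still matches — a logistic fit on
  generated data recovers the dependence.
* **Protocol deviations** at rate 0.30 across the qualifying list
  (incomplete medication use — reflected in the pill count —, late
  flare, realized exclusion criteria, other disease), plus attrition
  derived from withdrawal.
* **Gender**: a latent binary biological sex (80% male, typical of
  gout) under a non-binary label for ~3 patients; the label masks the
  latent value, which is retained (clearly marked synthetic ground
  truth) so imputation recovery is testable.
* **Safety**: solicited adverse events as independent Bernoulli draws
  with arm-specific rates (GI events elevated under colchicine); blood
  pressure with a small daily upward drift under prednisolone
  (0.8/0.4 mmHg per day systolic/diastolic) that the safety mixed model
  is meant to detect.
* **Baseline characteristics and labs** with sporadic 5% missingness,
  feeding the baseline table and subgroup flags.

What it does **not** emulate: gout pharmacodynamics, time-varying
treatment effects, informative missingness beyond the baseline-pain MAR
mechanism, center-level covariate effects, or any real DECT imaging
structure (DECT positivity is a configurable flag). Passing tests on
these data therefore validate the *statistical machinery* — estimator
correctness, coverage, error rates — not clinical realism.

## 5. The analysis engine

`primary_ancova()` fits the primary model by OLS and reports
$\beta_1$ with its two-sided CI; the non-inferiority verdict is
`upper CI bound < margin`. Degenerate inputs are handled explicitly: a
perfect fit (zero residual variance) collapses the CI onto the estimate
rather than failing; one-arm data and rank-deficient designs raise
errors. Biological sex enters all models as a two-level factor;
non-binary labels are unknown biological sex, resolved upstream by
imputation — never a third regression level, which would be
uninterpretable at an expected count of 3–4.

Secondary machinery, with the choices made where the plan was silent:

* **Mean pain days 1–6**: center-random-intercept linear mixed model
  (REML, `lme4`), covariates as in the primary model, independent
  residuals (no covariance structure was specified); keeps the NI
  framing. Variance components are bounded at zero; a single center or
  a zero variance estimate degrades gracefully to pooled OLS.
* **Likert outcomes**: Wilcoxon rank-sum, exact enumeration when both
  arms have ≤ 10 untied values, otherwise the tie-corrected normal
  approximation with continuity correction.
* **Binary outcomes**: logistic regression adjusted for treatment and
  baseline pain; complete separation raises a diagnostic error instead
  of diverging silently.
* **Subgroups**: one interaction at a time added to the primary model;
  Holm step-down over exactly the family of tests conducted in one call
  (the plan applies no multiplicity correction elsewhere, so primary and
  secondary outcomes are never pooled into the family); empty-cell
  subgroups are skipped with a logged reason and the family size is
  always reported.
* **Per-protocol rule**: "adhering until day 3" is applied
  *inclusively* — a qualifying deviation on days 0–3 excludes, one on
  day 4+ does not. ITT retains every randomized patient.
* **Adverse events**: Clopper–Pearson exact intervals from Beta
  quantiles, with the closed-form endpoints at 0 and $n$ events;
  appropriate because low event counts are expected.
* **Confounder adjustment** beyond the pre-specified set is an explicit
  opt-in covariate list, since no imbalance criterion was given.

## 6. Multiple imputation

`impute_trial()` implements chained equations directly: each incomplete
variable is regressed on all others (plus treatment), cycling by default
20 iterations per dataset, with per-dataset iteration means retained as
convergence traces. Integer pain variables use predictive mean matching
(5 donors, approximate Bayesian parameter draws), which keeps imputed
values on the observed 0–10 grid; biological sex uses a posterior-draw
logistic model with a marginal-frequency fallback under separation. The
day-1–6 diary serves as auxiliary predictors — the longitudinal
structure is the best source of information about a missing day. The
number of datasets is `max(10, ceiling(100 × missingness on the primary
outcome))` in auto mode and never below 10. `pool_results()` applies
Rubin's rules with the Barnard–Rubin degrees-of-freedom adjustment and
recomputes the CI and NI verdict from pooled quantities; the algebraic
guarantee that pooled variance is at least the mean within-imputation
variance is asserted in the tests. Under MCAR, complete-case analysis
agrees with the pooled estimate in expectation, which the suite checks;
MNAR sensitivity (δ-adjustment) is an acknowledged extension point, not
implemented.

## 7. Numerical and reproducibility choices

* Every stochastic entry point takes an explicit integer seed; child
  streams are derived arithmetically (kept below $2^{31}$) so grid cells
  and imputations are independently reproducible, and all generators
  restore the caller's RNG state.
* Sample-size search walks the exact noncentral-$t$ power function from
  the normal-approximation start, then verifies minimality
  ($power(n) \ge$ target $> power(n-1)$).
* Matrix solves add tiny ridge terms (1e−8) only inside the imputation
  parameter draws, where near-collinear chained models are routine;
  analysis models instead *fail loudly* on rank deficiency.
* Ties in the rank test fall back to the corrected approximation; a
  fully tied comparison returns $p = 1$ (the statistic is degenerate and
  carries no evidence).

## 8. Problem sizes used in the test suite

Simulation-backed tests run at sizes chosen to keep the full suite
around 1–2 minutes while leaving Monte-Carlo bands (3 standard errors)
informative: 1000 replicates per cell for the imbalance grids, 10,000
lists for randomization frequency checks, 10,000 replicates for the
Monte-Carlo power confirmation, 2000 simulated trials for the
boundary-null claim rate, 1000 for ANCOVA recovery, and 25–30
replicates for the expensive imputation recovery loops (with
correspondingly widened tolerances). Coverage of the Clopper–Pearson
interval is exhaustive, not simulated.

## 9. Known limitations

* The generator's unstated-by-the-plan parameters (baseline
  distribution, decay profile, AE and BP rates) are plausible but not
  data-derived; conclusions about *clinical* quantities should not be
  read off synthetic output.
* The mixed models assume independent residuals within patient/center;
  no serial correlation structure is offered.
* The imputer is a purpose-built chained-equations engine for this
  schema (numeric + binary variables), not a general framework; ordinal
  Likert secondaries are imputed through the same numeric machinery.
* Group-sequential features, adaptive designs and interim analyses are
  out of scope by design (the trial plans none).
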