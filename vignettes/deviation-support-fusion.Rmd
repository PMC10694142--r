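---
title: "Deviation-support fuzzy fusion: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deviation-support fuzzy fusion: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
options(dsfuse.quiet = TRUE)
library(dsfuse)
```

## The fusion problem

Several trained classifiers score the same cohort: classifier $c$ emits a
probability vector $P^c = (P^c_1, \dots, P^c_N)$ over the $N$ classes for
every sample, with $\sum_n P^c_n = 1$. In the motivating application the
cohort is breast-cancer patients labelled as long-term (0) or short-term (1)
survivors at a 5-year cutoff — a heavily imbalanced binary problem — and the
base classifiers are multi-modal deep models of unequal accuracy. The task
here is *decision-level* fusion: combine the probability tables, not the
features or the models.

A plain weighted average treats a classifier's 0.51 and its 0.99 as equally
trustworthy votes. This package instead quantifies, per class, how far each
prediction sits from full confidence and aggregates those quantities with a
fuzzy integral that knows how reliable each classifier — and each *coalition*
of classifiers — is.

## Model

**Transforms.** Each probability is mapped to a penalty and a reward:

$$D^c_n = 1 - \exp\!\left(-\tfrac{(P^c_n - 1)^2}{2}\right), \qquad
  S^c_n = 1 - \tanh\!\left(\tfrac{(P^c_n - 1)^2}{2}\right).$$

The deviation $D$ decreases strictly in $P$ from $1 - e^{-1/2} \approx
0.3935$ at $P = 0$ to $0$ at $P = 1$; the support $S$ increases strictly
from $1 - \tanh(1/2) \approx 0.5379$ to $1$. The two ranges do not overlap:
every support value exceeds every deviation value. That range dominance is
why the product diagnostic $R_n = \sum_c D^c_n S^c_n$ (exposed as
`multiplicative_relevance()`) is governed by the deviation factor, and it is
the rationale for the deviation-priority decision rule below.

**Fuzzy measure.** Classifier importances are accuracy-proportional
densities $g_i = \mathrm{acc}_i / \sum_j \mathrm{acc}_j$. Coalitions combine
through the Sugeno rule

$$g(A \cup \{j\}) = g(A) + g_j + \lambda\, g(A)\, g_j,$$

with $\lambda \in (-1, \infty)$ solving $1 + \lambda = \prod_i (1 + g_i
\lambda)$ so that the full coalition has measure exactly 1 and the empty one
measure 0. $\lambda = 0$ solves that equation for *any* densities; the
package returns it only when $\sum_i g_i = 1$ (where it is the
measure-consistent root, giving an additive measure) and otherwise returns
the unique non-zero root — positive when the densities undershoot 1,
in $(-1, 0)$ when they overshoot.

A consequence worth stating plainly: because `densities_from_accuracies()`
normalises, the accuracy-driven construction **always** lands in the
additive case, and the Choquet aggregation below reduces to an
accuracy-weighted mean of transformed scores. The genuinely non-additive
machinery is fully implemented and tested (it activates whenever
`lambda_measure(densities = ...)` is given unnormalised densities), and
`dsfuse()` logs the solved $\lambda$ on every fit so the degeneracy is
visible rather than silent.

**Choquet aggregation.** For each sample and class, the $C$ deviation scores
are sorted descending, $v_{(1)} \ge \dots \ge v_{(C)}$, and aggregated as

$$\mathcal{D}_n = \sum_{k=1}^{C} \left(v_{(k)} - v_{(k+1)}\right)
  g(A_k), \qquad v_{(C+1)} = 0,$$

where $A_k$ is the coalition of the $k$ highest-scoring classifiers; the
supports aggregate identically into $\mathcal{S}_n$. The printed telescoped
form of this sum only defines a Choquet integral when the values are paired
with *nested* coalitions, which forces the descending sort; ties are broken
by ascending classifier index for determinism.

**Decision rule.** The deviation pathway proposes
$\arg\min_n \mathcal{D}_n$, the support pathway $\arg\max_n \mathcal{S}_n$
(ties toward the lowest class index). When they clash, deviation wins.
Consequently the final label always equals the deviation argmin — the
support pathway cannot change a label, only flag disagreement — and the
per-sample agreement indicator is reported as a diagnostic. With a single
classifier the whole pipeline collapses, by monotonicity of the transforms,
to the classifier's own argmax.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `accuracies` | `dsfuse()`, manifest | — | classifier reliabilities in (0, 1], the only model input besides scores |
| `accuracy_policy` | CV harness, manifest | `"out-of-fold"` | whether fold-wise densities come from training-portion argmax accuracy (no test-label leakage) or from fixed manifest values |
| `k`, `seed` | `stratified_folds()` | 10, 1 | fold count and shuffle seed; per-class fold counts deviate from proportionality by at most one sample |
| `positive` | metrics | `"1"` | the minority/event class for sensitivity, precision, F1 |

Metric conventions: the standard definitions are used throughout —
sensitivity $tp/(tp+fn)$, specificity $tn/(tn+fp)$, precision $tp/(tp+fp)$,
F1 the harmonic mean of precision and sensitivity, balanced accuracy the
mean of sensitivity and specificity. (Applied reports sometimes swap the
prose descriptions of sensitivity and precision; the code follows the
standard quantities above.) A ratio with a zero denominator is reported as 0
with a warning rather than NaN, so that fold averages remain finite.

## What the simulator emulates — and what it does not

`simulate_cohort()` exists so the ensemble and its harness can be exercised
end-to-end without any external data. Its defaults mirror the motivating
cohort's shape: 1980 samples, binary labels with prior 1489:491, four
classifiers. Scores are drawn from a Dirichlet-type mechanism: sample $s$
with true class $y$ gets concentration
$\alpha = 20\,\pi + q_c\, e_y$ (prior $\pi$, quality boost $q_c$,
one-hot $e_y$); independent Gamma draws are taken once per sample (a shared
latent component) and once per classifier, mixed with weight `correlation`,
normalised to a probability row, and optionally temperature-scaled
(`miscalibration`, argmax-preserving).

Design of the defaults. The prior-anchored baseline (scale 20) makes a
zero-quality classifier a de-facto majority guesser, accuracy
$\approx \max \pi$. The boost at which the minority class becomes detectable
(sensitivity 0.5) is $20(\pi_0 - \pi_1) \approx 10.1$; the default qualities
$(10.5, 11, 12.5, 13)$ sit just above it, giving base sensitivities of about
0.53–0.70 — the regime real trained classifiers on such cohorts occupy, and
the regime in which averaging-type fusion is beneficial. Below the
crossover, fused sensitivity collapses toward 0 and fusion can *lower*
accuracy; that behaviour is reproducible by setting small qualities and is a
property of corner-of-ROC base classifiers, not a defect of the integral.

The generator has one quality knob, so it cannot decouple sensitivity from
specificity: its specificity is pinned near 1 by the prior anchoring and its
expected accuracies (≈0.88–0.93) run higher than typical published base
classifiers (≈0.77–0.82). It also emulates nothing upstream of the scores —
no features, no training, no fold-to-fold model variation, and
miscalibration that never moves the argmax. Tests passing on simulated
cohorts therefore validate the *fusion arithmetic and harness plumbing*, not
clinical performance claims.

## Numerical choices

* **λ root.** $f(\lambda) = \prod_i(1 + g_i\lambda) - (1 + \lambda)$ has a
  spurious root at 0 with $|f|$ of order machine epsilon nearby, so both
  bracket endpoints are kept away from 0 before Brent refinement, followed
  by a short Newton polish to residual $\le 10^{-12}$. A single classifier
  with $g_1 \ne 1$ admits no valid measure and errors.
* **Row sums.** Score rows off 1 by at most $10^{-9}$ pass unchanged (this
  tolerance absorbs 10-significant-digit serialisation drift, keeping
  write/read round-trips byte-stable); drift up to $10^{-6}$ is renormalised
  with a warning; beyond that is an error naming the row.
* **Ties.** Descending sort ties and argmin/argmax ties both resolve to the
  lowest classifier/class index.
* **Vectorisation.** Per-sample integrals share one measure, so the sort is
  a single `order()` over rows and the nested-coalition measures fold
  column-by-column; the scalar `choquet_integral()` delegates to the same
  path and is cross-checked in the tests against an independent brute-force
  sorted-difference implementation with closed-form subset measures,
  $g(A) = (\prod_{i \in A}(1 + \lambda g_i) - 1)/\lambda$.

Test problem sizes: the oracle-equivalence sweep uses 1000 random instances
with $C \le 5$; decision identities use $10^5$ random aggregate vectors;
the simulation-level checks use 20 replicates of the full 1980-sample,
4-classifier cohort under 10-fold cross-validation, which keeps the whole
suite around ten seconds on one core.

## Known limitations

* With accuracy-normalised densities the measure is additive; users wanting
  genuinely non-additive fusion must supply their own densities (summing
  away from 1) to `lambda_measure()`.
* The support pathway is computed, logged and returned but can never
  override the deviation argmin; its value is diagnostic (agreement rate).
* Binary metrics only; multi-class fusion works end-to-end, but
  `compute_metrics()` expects two classes.
* Accuracy is the only reliability notion fed to the densities; no
  calibration-aware weighting.

## A complete run

```{r}
coh <- simulate_cohort(simulation_config(n_samples = 400, seed = 7))
fit <- dsfuse(coh$score_tables, accuracies = coh$realized_accuracies)
summary(fit)

cv <- cross_validate_ensemble(coh$score_tables, coh$labels, k = 5, seed = 7)
round(cv$mean, 4)

# fixed-weight baseline on the same cohort
base <- weighted_average_baseline(coh$score_tables, coh$realized_accuracies)
mean(base != fit$labels)  # disagreement rate between the two fusions
```
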