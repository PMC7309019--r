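---
title: "Sensor-failure-tolerant classification by per-sensor plurality voting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensor-failure-tolerant classification by per-sensor plurality voting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An electronic nose monitors a perishable product (the motivating case is
beef) with an array of metal-oxide gas sensors — here 11 MQ-series channels,
each selective for a different family of volatiles — and a classifier maps
each minute's readings to an ordinal quality label (1 = excellent, 2 = good,
3 = acceptable, 4 = spoiled). Gas sensors drift and fail: a channel can stop
delivering usable values because of aging, humidity, temperature, or poisoning.
A conventional classifier trained on the joint 11-dimensional feature vector
has no principled response to a missing channel — something must be imputed,
and the imputed value silently distorts the decision.

This package takes the alternative route: train one *univariate* classifier
per sensor, and classify a sample by **plurality voting** over the
classifiers of the sensors that are still available. A failed channel is not
imputed; its classifier is simply never consulted. The ensemble degrades
gracefully — losing $f$ of $d$ sensors just shrinks the electorate to
$d - f$ voters.

## The method

Let $x \in \mathbb{R}^d$ be a sample, $a \in \{0,1\}^d$ its availability
mask, and $h_1, \dots, h_d$ the per-sensor classifiers. The ensemble label is

$$\hat{y}(x, a) \;=\; \operatorname*{arg\,max}_{c \in \{1..C\}}
  \sum_{j : a_j = 1} \mathbf{1}\!\left[ h_j(x_j) = c \right],$$

with argmax ties broken to the smallest label (configurable to the largest —
the most-spoiled label — where a conservative call is the safer failure
mode). Three base-classifier families are provided, all implemented in the
package and all usable on a single channel:

* **kNN** — stores the training column verbatim; predicts the plurality
  label among the $K$ nearest neighbours. Default $K = 1$ (parameter-free,
  in keeping with the method's simplicity); Euclidean distance by default,
  with Manhattan, Minkowski($q$) and cosine available. Distance ties break
  by lowest training-row index, label ties to the smallest label, so
  prediction is deterministic.
* **Decision tree** — CART-style greedy binary splits on (sensor,
  threshold) pairs maximising Gini impurity decrease, candidate thresholds
  at midpoints between consecutive distinct values, `value <= threshold`
  routed left. Equal-quality splits resolve to the lowest sensor index,
  then the smallest threshold, making the fit independent of row order.
  Defaults grow the tree to purity; `max_depth`, `min_split`, `min_leaf`
  and `min_decrease` regularise it.
* **LDA** — per-class means, pooled within-class covariance
  (denominator $n - C$), priors from class frequencies, and Bayes-rule
  classification under the shared-covariance Gaussian model; the
  $\le C-1$ leading eigenvectors of the within/between scatter problem are
  retained as the projection matrix for the dimension-reduction pathway.
  A ridge (default $10^{-9}$) on the pooled covariance guards
  zero-variance channels; on one channel the model reduces to 1-D Gaussian
  Bayes with pooled variance.

The baseline throughout is the **single joint classifier** ("Single CL"):
the same family trained once on all $d$ sensors. Since it cannot skip a
failed channel, failed test cells are filled by the training-set per-sensor
mean by default (zero-filling and listwise skipping are options; reports
always record the policy, because the baseline's behaviour under failures is
only defined relative to it).

Votes are hard labels. Summing the base classifiers' probability vectors
instead is available behind `vote_type = "prob"` for experimentation, and a
trained meta-classifier over base outputs is deliberately not implemented —
plurality voting is the method.

## Failure simulation

Failures are simulated at test time only (training data is assumed
loss-free). A *failure profile* assigns fractions of the test samples to
failure counts; two standard mixtures are built in:

* **ten-tier** — 10% of samples at each failure count 0–9 (the default
  benchmark condition);
* **five-tier** — 20% at each count 0–4.

Tier sizes are `fraction * n` rounded by the largest-remainder method, so
the realised histogram matches the mixture *exactly* for every `n`. Which
samples land in which tier and which sensors fail are drawn from R's
Mersenne-Twister generator under an explicit seed: masks are a pure function
of `(n, d, profile, seed)`. By default samples are randomly interleaved
across tiers; a contiguous-blocks option exists for debugging.

## Evaluation design

`run_experiment()` reproduces the benchmark grid: families × {single, SPVS}
× {clean, missing} under stratified 5-fold cross-validation. Stratification
uses a single round-robin dealing pointer shared across classes, so
per-class counts and overall fold sizes both differ by at most one between
folds. Min–max normalisation (the default; z-score is available) is fitted
on each training fold only and applied to its test fold — test values
outside the training range are not clipped, and a constant training column
maps to 0. Each fold's failure masks come from a fold-specific sub-seed
derived by hashing a component name with the master seed, so adding a
component never perturbs another's random stream, and two runs with the
same configuration and seed are byte-identical down to the report files.

Metrics follow the accuracy/sensitivity/specificity convention for
multi-class problems: CA is the confusion-matrix trace over the total;
sensitivity and specificity are one-vs-rest per class and macro-averaged
over the classes present in the truth (micro-averaging is a config option).
With exactly balanced classes, macro sensitivity coincides with CA — visible
in the synthetic benchmark, whose default schedule is balanced.

## The synthetic benchmark

The generator emulates the structure of a timed spoilage-monitoring run:
`n_samples` minutes (default 2200, one sample per minute), a label that
advances irreversibly through the four classes at fixed time fractions
(default quarters), and sensor $j$ at minute $t$ reading

$$\text{baseline}_j + \text{gain}_{j,\,\text{class}(t)} + \text{drift}_j
\cdot t + \varepsilon, \qquad \varepsilon \sim N(0, \sigma_j^2).$$

Informative sensors have gains rising monotonically with spoilage;
pure-noise sensors have constant gain rows and carry no label information by
construction. Three fixed presets are used by the test-suite:
`redundant_informative` (9 informative channels, adjacent-class gaps of
about 3 noise SDs — the redundancy regime the voting ensemble is designed
for), `half_noise` (6 informative / 5 noise), and `hard_overlap` (all
informative but heavily overlapping responses). Default problem sizes in the
tests — n = 2200 with 5 folds for the benchmark grid, n = 600 for the
byte-level determinism check, n = 20,000 for moment recovery — were chosen
as the smallest sizes at which the respective effects are stable.

What the generator does *not* model: adsorption kinetics and
cross-sensitivities of real MQ sensors, autocorrelated or heteroscedastic
noise, non-monotone transients, or the empirical class balance of any real
recording. Passing tests demonstrate the voting mechanism's failure
tolerance on class-informative redundant channels; they do not certify
accuracy figures on real e-nose data.

## Numerical and design choices

* All label ties anywhere (vote ties, leaf ties, posterior ties) break to
  the smallest label by one global rule; the vote tie-break alone is
  configurable, surfacing the food-safety trade-off.
* kNN distance ties break by training-row index, tree split ties by sensor
  index then threshold: every path is deterministic, and refits are
  bit-identical.
* The all-sensors-failed case errors by default; an explicit
  `fallback = "majority"` policy predicts the training majority label and
  flags the row. The ten-tier mixture never reaches this case (at most 9 of
  11 sensors fail).
* Labels are 1-based throughout all I/O and reports.
* Masked cells are represented as unavailable, never imputed at read time;
  the only imputation in the package is the single-classifier baseline's
  explicit test-time policy.
* Model archives are versioned JSON with numbers written at full precision,
  so a reloaded ensemble reproduces predictions exactly.

## Known limitations

* With hard plurality votes, weakly informative channels are not harmless:
  when the informative sensors disagree, near-uniform votes from noise
  channels can tip the plurality. On the `half_noise` preset, deliberately
  failing the 5 pure-noise sensors *raises* tree-ensemble accuracy by
  about 3 percentage points (least pronounced for LDA bases, about 1pp) —
  the ensemble is tolerant to losing noise channels in the sense of never
  doing worse, but their presence has a measurable cost unless the
  informative bloc votes near-unanimously. The test suite records this
  honestly: the noise-ablation invariance check is expected to fail at its
  2-percentage-point band under the tree family.
* Per-sensor training is $O(d)$ model fits; no attempt is made to share
  computation across sensors, which is irrelevant at $n \approx 2200$ but
  would matter for very long series.
* Failure masks model binary availability only — drift as a gradual
  corruption process is out of scope; a drifting-but-present sensor is the
  user's responsibility to detect upstream.
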