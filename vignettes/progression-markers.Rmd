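---
title: "Two-stage serum-proteomic screening of progression in preclinical systemic sclerosis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage serum-proteomic screening of progression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A small fraction of patients can be identified at a *preclinical* stage of
systemic sclerosis (SSc): Raynaud phenomenon, SSc-specific autoantibodies
and a scleroderma capillaroscopy pattern, without any sign of definite
disease. Roughly half of them progress to definite SSc within about five
years. Serum proteomics offers a way to characterize, at blood draw, which
of these subjects are on the progression trajectory.

`sscprog` implements a two-stage analysis of this question:

1. **Discovery** — on a small case/control cohort measured on a large
   aptamer-style panel (relative fluorescence units, RFU), screen for
   proteins whose baseline level predicts later progression.
2. **Validation** — on an independent prospective cohort with
   interval-censored progression times (progression is only ascertained at
   clinic visits), confirm candidate markers with survival methods built
   for interval censoring.

Because serum measurements of this kind are not publicly deposited, the
package also contains a synthetic-cohort generator that reproduces the
statistical structure of both cohorts, so every stage of the pipeline is
testable end to end.

## The synthetic cohorts

### What the generator emulates

* **Abundances.** Null proteins are log-normal: log2 values are
  Normal(mu_p, sigma) with protein-level means mu_p drawn once per cohort
  from Normal(10, 1) (RFUs of order a thousand) and a common within-protein
  SD `sigma = 0.5`. Log-normality matches positive, right-skewed abundance
  readouts; the particular scale parameters are conventions, since studies
  of this kind publish no distributional summaries of their RFUs.
* **Discovery design.** 13 cases, 8 healthy controls, 7 of the 13 cases
  progressors — the dimensions of the motivating study. A planted effect
  shifts case means by `log2_fc`, and progressor means by
  `log_hr * sigma` (so `log_hr` reads as a standardized two-group effect
  size at this stage).
* **Validation design.** 50 subjects followed on a yearly visit schedule
  over a 5-year horizon. Event times come from a proportional-hazards
  model with cumulative hazard `(b t)^k * exp(sum(log_hr * z))`, with the
  exponential default `k = 1` and `b = -log(0.6)/5` per year, so the
  5-year cumulative risk is 40% under the null — matching a cohort in
  which 20 of 50 subjects progress. A Weibull shape `k != 1` is exposed
  for misspecification experiments. Progression is ascertained only at
  visits: the recorded datum is the interval `(L, R]` between the last
  progression-free visit and the first visit with definite disease, with
  `R = Inf` (and `L` the last visit) when no progression is seen.
* **Planted validation effects.** The package's worked examples plant one
  harmful marker at log-HR +1.4 per SD and one protective marker at -1.4
  per SD, mirroring the strong transformed-data hazard ratios reported for
  endostatin-like (harmful-high) and bFGF/PAF-AHbeta-like
  (protective-high) markers in this literature.
* **Missingness.** Missing cells are inserted completely at random at a
  configurable rate (never emptying a row), exercising the imputation
  step. Real missingness mechanisms are not characterized in this setting,
  so nothing more structured is attempted.

### What it does not emulate

Assay chemistry: limits of detection/quantitation, plate and batch
effects, aptamer cross-reactivity, and protein-protein correlation
structure are all absent. Passing tests therefore demonstrate the
statistical machinery under the model the analysis itself assumes — not
robustness to those real-data artifacts.

Every cohort is a deterministic function of its design object, including
the seed: a single seeded generator drives all draws.

## Stage 1: the discovery screen

### Fold-change filter

With so few samples, only proteins clearly shifted against healthy
controls are tested. The per-protein fold change is the difference of
arithmetic means of log2 values (equivalently the log2 ratio of geometric
means — the standard choice for skewed positive data), and the filter
keeps `|log2 FC| >= 0.585`, i.e. at least a 1.5-fold change in either
direction, inclusive at the boundary. The filter compares cases to
controls only; it never sees the progression labels, which is what lets
the permutation stage hold it fixed.

### Bagged median-threshold accuracy

Each surviving protein is scored on the cases alone. For each of 100
bootstrap resamples (size 13, with replacement):

* the in-bag median RFU is the classification threshold (even-sized
  medians are the mean of the two central order statistics; values equal
  to the threshold count as "at/below");
* the classification *direction* is chosen on the in-bag sample: both
  "above-median predicts progressor" and its opposite are scored on the
  in-bag draws, and the better one is kept, ties going to above-median
  (because the two directions are complementary this reduces to a majority
  check). Choosing in-bag keeps the rule label-blind on the out-of-bag
  data while handling both risk markers and protective markers, which is
  necessary because both kinds appear among real candidates. A
  `direction = "fc_sign"` option instead fixes the direction a priori from
  the fold-change sign;
* accuracy is the fraction of correct out-of-bag predictions (2x2 table);
  resamples with an empty out-of-bag set are skipped.

The protein's score is the mean accuracy over retained resamples. Note a
structural subtlety: even a perfectly separated marker does not reach
accuracy exactly 1, because the in-bag median of an odd-sized resample is
always an actual data value, so out-of-bag subjects at the class boundary
can fall on the wrong side of it.

### Step-down maxT family-wise correction

Significance is assessed by permuting the progression labels across the
13 cases (the controls only enter the outcome-blind filter, which
therefore stays fixed) and recomputing every protein's bagged accuracy,
10,000 times by default. By default the bootstrap index sets are drawn
once and reused across permutations — a variance-reduction device that
also makes the permutation loop about two orders of magnitude cheaper;
`reuse_bootstrap = FALSE` redraws them per permutation. With proteins
ordered by observed accuracy, the adjusted p at rank *i* is

    p_i = (1 + #{ perms : max over ranks >= i of permuted accuracy >= observed_i }) / (P + 1)

followed by monotonicity enforcement (successive maximization) along the
ordering. The add-one estimator guarantees validity and `p > 0`; adjusted
p-values live in `[1/(P+1), 1]`. The inner loop (median thresholds,
direction choice, out-of-bag scoring across all permutations) is
implemented in C++, which is what makes 200-replicate FWER calibration
runs routine on one CPU.

The family-wise error property is checked two ways: exact agreement with
a brute-force Westfall-Young enumeration oracle on small cohorts, and an
empirical FWER simulation under the global null at the study's own scale
(13 cases / 7 progressors / 20 proteins / 100 resamples), which the
acceptance script recomputes from scratch.

## Stage 2: interval-censored validation

The validation pipeline per marker is: impute, transform, fit the
interval-censored proportional-hazards model, and — for markers passing
the Wald gate — dichotomize and compare strata.

* **Imputation** is k-nearest-neighbour with `k = 3`: each missing cell is
  the mean of its column over the 3 nearest rows by Euclidean distance on
  z-scored, mutually observed columns; only rows with the target column
  observed can donate, and ties break by row order.
* **Box-Cox transformation** brings each marker near normality before the
  hazard model: lambda maximizes the closed-form profile log-likelihood on
  `[-2, 2]`; non-positive inputs are shifted by `1e-6 - min(x)` first. The
  transformed marker is then standardized, so reported hazard ratios are
  per SD of the transformed marker and comparable across proteins.
* **IC-Cox fit.** The semiparametric proportional-hazards likelihood for
  interval-censored data places baseline mass on the Turnbull innermost
  intervals of the pooled sample. Rather than EM-profiling the baseline,
  the fit alternates *exact block maximization*: quasi-Newton (BFGS) over
  the softmax-parameterized baseline masses, then a Brent line search over
  beta on [-15, 15]. Each block step can only increase the likelihood, so
  monotone ascent holds by construction (and is asserted in tests).
  Convergence requires `|delta beta| < 1e-6` and baseline masses stable to
  `1e-6`, with a cap of 200 cycles (non-convergence warns, never silently
  returns). Wald inference uses the observed information from a
  central-difference Hessian of the full parameter vector; confidence
  intervals are Wald on the log-HR scale. Baseline dimension equals the
  innermost-interval count, which on a visit grid is at most
  `#visits + 1`, so the fit is fast even at n = 500.
* **Cutpoint estimation** follows Contal-O'Quigley: intervals are reduced
  to right-censored form (events at the interval midpoint by default —
  the least-assumption single-point summary, with `right_endpoint`
  exposed as the alternative; censoring at `L`), the logrank numerator is
  scanned over unique marker values between the 10th and 90th percentiles
  (trimming avoids degenerate strata), and the maximizing threshold is
  reported with the standardized supremum statistic and its
  Brownian-bridge p-value `2 * sum_k (-1)^(k+1) exp(-2 k^2 q^2)`. The
  search is monotone-invariant, so it runs on the original measurement
  scale and the threshold is reported in original units. The `direction`
  is read off the sign of the logrank numerator at the argmax: `high_risk`
  means the stratum at or above the threshold has the excess of deaths,
  hence the worse survival curve.
* **Turnbull curves** per stratum come from the self-consistency EM on the
  innermost intervals (mass tolerance 1e-8, cap 10,000 iterations);
  masses are nonnegative and sum to one, and the survival step function is
  reported at innermost-interval right endpoints (between which the NPMLE
  is uniquely defined). On exactly observed or right-censored data the
  estimate collapses to Kaplan-Meier, which is asserted against
  `survival::survfit`.
* **Generalized logrank test.** Strata are compared with a
  Finkelstein/Sun-type score test: per-subject scores
  `xi = (S(L) log S(L) - S(R) log S(R)) / (S(L) - S(R))` under the pooled
  NPMLE (with `S log S := 0` at 0 and the limit `log s + 1` for
  zero-probability intervals), statistic the centred score sum of one
  group. At n = 50 the chi-squared asymptotics are not trusted: the
  p-value is computed by permuting group labels (2000 by default, add-one
  estimator), or by exhaustive enumeration of all `choose(n, n1)`
  assignments whenever that count is at most 10,000 — which makes small
  examples exact. On purely right-censored data the scores reduce to
  classical logrank scores, and the test is checked against
  `survival::survdiff`. The method family is defined for interval-censored
  failure times, which is how it is implemented here; the right-censored
  case is covered as the reduction just described.
* **Multiplicity.** Validation-stage p-values are reported nominal, per
  protein, as is conventional for a small pre-selected panel taken forward
  from an error-controlled discovery stage; no further adjustment is
  applied by default.

A caution for interpreting the univariate fits: when several strong
markers act on the same hazard, each marginal (single-marker) HR is
attenuated toward 1 relative to its planted conditional value — hazard
models are not collapsible. The screen is deliberately univariate, like
the analysis it implements, so this attenuation is part of the estimand,
not a bug.

## Problem sizes used by the test suite

The suite exercises every operation at sizes chosen to make the checks
sharp while keeping a full run in the low minutes on one CPU: FWER
calibration on 200 replicate global-null cohorts at the discovery design's
own scale with 150 permutations per cohort; hazard-ratio recovery at
n = 500 over 50 seeds; end-to-end harmful/protective dichotomy recovery on
15 replicate 50-subject cohorts; exhaustive-enumeration oracles on 4-10
subject toys where exhaustion is exact. The acceptance script reruns the
FWER calibration from scratch with 250 permutations per cohort.

## Known limitations

* The generator's independence across proteins makes the discovery FWER
  calibration a test of the procedure under independence; maxT is valid
  under dependence too, but that regime is not exercised here.
* The IC-Cox implementation supports a single covariate — all the analyses
  it reproduces are univariate. Multi-covariate fits would need only a
  wider Newton block but are out of scope.
* The supremum p-value for the cutpoint assumes untied event times after
  the right-censored reduction; heavy ties (coarse visit grids with the
  `right_endpoint` reduction) make it approximate. The reported
  generalized-logrank permutation p for the dichotomized marker does not
  account for the cutpoint having been optimized; the same is true of the
  analysis this package reproduces.
* Validation-stage conclusions inherit the usual caveat of dichotomized
  markers: the cutpoint is a descriptive device, not a clinical threshold.
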