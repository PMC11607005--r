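---
title: "Methods: name-based MENA classification and doubly truncated Gompertz mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: name-based MENA classification and doubly truncated Gompertz mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the mortality
model and its assumptions, the name classifier, what the synthetic
generator does and does not emulate, and the numerical and design
choices made where the problem left them open.

## The mortality model

Adult mortality is modelled by a Gompertz proportional-hazard law
measured from an age origin (65 by default):

$$h_i(x) = a_0 \, e^{b_0 (x - 65)} \, e^{\beta Z_i},$$

where $a_0 > 0$ is the baseline hazard level at the origin (per year),
$b_0$ is the log-rate of increase of mortality with age (per year;
values around 0.10–0.15 are typical of over-65 human mortality), and
$\beta$ is a vector of log-hazard coefficients on record covariates
$Z_i$ — here principally a foreign-born indicator, so $e^\beta$ is the
nativity hazard ratio. Survival from the origin is
$S(x) = \exp\{-(a_0 e^{\beta Z}/b_0)(e^{b_0(x-65)} - 1)\}$, with the
exponential limit at $b_0 = 0$.

**Why a truncated likelihood.** Administrative death files have reliable
coverage only for deaths inside a calendar window (1988–2005 here) at
ages above a floor (65). A cohort born in 1935 can only be observed
dying at ages 65–70; a cohort born in 1900 only at ages 88–105. Both
tails of every cohort's death distribution are missing, and which tail
is missing depends on the birth year, so raw mean death ages and
ordinary regressions on death age confound mortality with cohort
composition. The package's estimator conditions each death on its
record-specific observable age window $[L_i, U_i]$:

$$\ell(\theta) = \sum_i w_i \left[\log h(x_i) + \log S(x_i)
  - \log\{S(L_i) - S(U_i)\}\right],$$

which is the exact likelihood of a death age given that the death was
observable, under the assumption that selection into the window depends
only on birth year (not on mortality conditional on it). Weights $w_i$
accommodate post-stratification person-weights, which the package
consumes as given and never constructs.

**Assumptions.** Gompertz hazards within each (group, sex, nativity)
cell above age 65; proportional nativity effects within a cell;
independence across records; birth year known to the year; no
emigration or record loss correlated with death age inside the window.

## From records to observations

Recorded death ages are completed integer years. The package treats
them as mid-year events, $x = \texttt{death\_age} + 0.5$, which is
unbiased under within-year uniformity of deaths. The observable window
is derived from the birth year as

$$L_i = \max(65,\ 1988 - \texttt{birth\_year} - 0.5), \qquad
  U_i = 2005 - \texttt{birth\_year} + 0.5,$$

where the half-year slack matches the continuity correction and absorbs
the one-year administrative rounding between death year, birth year and
death age. The calendar window is inclusive on both ends — [1988, 2005]
and ages ≥ 65 — chosen for determinism; records exactly on a boundary
are retained. `apply_truncation()` is a pure filter (no record is
modified), and `death_observations()` errors on any record outside its
own window rather than silently dropping it.

## Estimation and uncertainty

`fit_gompertz()` maximizes the truncated likelihood over
$(\log a_0, b_0, \beta)$ — the log-parameterization of $a_0$ makes the
search unconstrained — using BFGS with the analytic gradient, relative
tolerance `1e-12`, and up to three seeded jittered restarts on
non-convergence. The coefficient covariance is the inverse observed
information (numerical Hessian at the optimum); a singular information
matrix returns the fit with confidence intervals flagged unavailable
rather than failing.

Conditional life expectancy at 65 is
$e_{65} = 65 + \int_0^\infty S(65 + t)\,dt$, evaluated by adaptive
quadrature at relative tolerance `1e-8` over a finite horizon chosen
where the cumulative hazard reaches 40 (survival $\sim 10^{-18}$), which
keeps the integrator stable across the extreme parameter values visited
during calibration root-finding. At $b_0 = 0$ the closed form
$65 + 1/(a_0 e^{\beta Z})$ is used; $b_0 < 0$ leaves survival mass at
infinity and is an error.

Confidence intervals: Wald on coefficients and (exponentiated) hazard
ratios; for the nonlinear $e_{65}$ functional and the nativity gap
$\Delta e_{65}$ the default is a parametric bootstrap — 1,000
multivariate-normal draws from the coefficient covariance on the working
scale, seeded — because the delta method degrades for strongly nonlinear
functionals of $b_0$. Draws with $b_0 < 0$ (where $e_{65}$ is undefined)
are discarded; at the sample sizes the package targets they are
vanishingly rare.

Numerical guards: $(e^{b_0 t} - 1)/b_0$ and its $b_0$-derivative switch
to series expansions below $|b_0| < 10^{-8}$ so the likelihood is smooth
through $b_0 = 0$; the truncation denominator is evaluated as
$\log S(L) + \log(1 - e^{\log S(U) - \log S(L)})$ to avoid cancellation
when the window captures little mass, and a window with
$S(L) = S(U)$ to machine precision is an error naming the record.

**Stratification.** Following the analysis design the pipeline fits one
model per (ethno-racial group, sex) cell with a single foreign-born
indicator, so every group has its own $(a_0, b_0)$; nothing prevents
fitting a pooled model with additional covariate columns through the
same interface.

**Robustness companion.** `fe_linear_check()` runs (weighted) OLS of
death age on the covariates plus one indicator per birth year. Birth-year
fixed effects absorb cross-cohort differences in which part of the death
distribution is visible; this mitigates truncation bias but does not
model it, so the function is a sign-and-magnitude sanity check on the
MLE, never the primary estimator.

## The name classifier

Full names (given ⊕ `_` ⊕ surname) are normalized — lowercased,
accent-stripped to ASCII where the locale allows, digits removed,
hyphens and apostrophes kept because they carry naming-convention
signal — and tokenized by byte-pair encoding: starting from single
characters, the most frequent adjacent token pair is merged iteratively
until the inventory reaches `max_vocab` (default 512; name corpora
saturate quickly) or no pair occurs twice. Merge ties are broken
lexicographically on the (left, right) pair in C-locale order; the
source method for BPE leaves tie-breaking open, and a documented
deterministic rule is required for reproducible vocabularies.

The classifier is a single-layer gated recurrent unit (embedding 32,
hidden 64 by default) over the token sequence, ending in a sigmoid
probability. The contract calls for an LSTM-class gated recurrence; the
GRU shares the gated-memory mechanism with fewer parameters, trains in
minutes on a CPU at the corpus sizes involved, and is implemented
directly in vectorized R (backpropagation through time, Adam, batch 256,
10 epochs, learning rate 3e-3 by default) so that model state is plain
matrices, serializes as text, and is bit-reproducible from a seed. The
seed controls the stratified 80/20 train/test split, the weight
initialization, and batch order.

**Training-set construction** mirrors the administrative setting:
restrict to foreign-born records (U.S.-born records never enter,
whatever their names); label positive by birthplace in a configurable
MENA code set; exclude records whose last racial-identity report
predates 1981, when the coding system had only three categories; and
augment with parent names under the child's label — the father
contributes his surname, the mother her full name. Whether parent names
should be deduplicated against child names is not specified anywhere;
duplicates are retained, which weights common family names by their
actual frequency. The decision threshold is 0.5 by default (the
operating threshold of the source analysis is unstated) with
`threshold_sweep()` reporting the precision/recall trade-off; precision
with no positive predictions is reported as 0 with an explicit
`precision_defined = FALSE` flag.

Class imbalance handling (inverse-frequency loss weights) is available
but off by default: the synthetic corpora used for validation are
balanced, and the option exists for realistic imbalanced extracts.

`bigram_baseline()` — ridge logistic regression on boundary-marked
character bigram counts — is kept strictly as an independent yardstick:
the recurrent model must come within 0.05 F1 of it on separable data,
and both should collapse to chance on indistinguishable corpora.

**Group reassignment.** In the pipeline, every record is scored and a
record is assigned to the MENA group when the classifier calls it
positive *or* its birthplace is in the MENA code set; classified records
are carved out of their prior race coding (the shares of prior codes are
reported). Whether the source analysis classified all records or only
those not already birthplace-identified is not fully explicit; the union
rule is used because birthplace is the higher-precision signal and the
classifier exists precisely to recover records birthplace cannot label.
An intersect-with-prior-coding variant is a documented alternative.

## The synthetic generator

The generator produces person records with the statistical structure the
estimator assumes: six ethno-racial groups × two nativities × two sexes;
birth cohorts uniform on 1890–1940 by default (a configurable discrete
distribution can emulate cohort skew); names drawn from group-specific
order-2 character Markov chains with explicit start/stop symbols, built
from small synthetic seed lexicons so that groups differ in sub-word
statistics (the MENA chains put visible mass on clusters like "kh" and
"gh") — the cheapest process that gives a sequence classifier honest,
learnable signal; a spelling-perturbation rate (default 0.15) injecting
single-character substitutions and transpositions to emulate
transliteration variants; fathers sharing the child's surname with
probability 0.95; continuous Gompertz death ages from the window's age
floor, recorded as completed years with
`death_year = birth_year + floor(age) + Bernoulli(fraction)`; race codes
that fold MENA records mostly into "white" (85%) and "asian" (13%); and
last-race-report years spanning the 1981 coding change.

The default mortality regime is calibrated once, by
`calibrate_gompertz_e65()` (nested root-finding: $a_0$ pinned by the
U.S.-born $e_{65}$ target for each candidate $b_0$, then $b_0$ chosen to
hit the foreign-born target at the fixed hazard ratio), to per-(group,
sex) U.S.-born and foreign-born $e_{65}$ values representative of
over-65 mortality differentials among U.S. ethno-racial groups — e.g.
the MENA-male cell uses a U.S.-born $e_{65}$ of 82.26 years, a
foreign-born $e_{65}$ of 85.39 years, and a foreign-born hazard ratio of
0.64. Default group shares and foreign-born fractions (61% for MENA)
likewise reflect the over-65 composition of such files. These defaults
define the study conditions for all simulation-based validation and are
not adjusted per test.

**What the generator does not emulate** — and therefore what passing
tests do not establish about real data: real name inventories and their
cross-group overlap (real MENA/non-MENA name distributions overlap far
more than the synthetic chains, so real-data classifier metrics will be
materially worse than synthetic ones); non-Gompertz old-age mortality
deceleration; cohort trends in mortality within a cell; correlated
record errors (age misstatement, name transcription); realistic
post-stratification weights (all default to 1); and cause-of-death
structure. Tests on synthetic data validate the estimator's correctness
under its assumptions, not the assumptions themselves.

## Validation design and problem sizes

The test suite validates each layer against an independent route:
closed-form and quadrature oracles for the survival function, the
truncated likelihood (random small instances vs. brute-force
normalization), and the $e_{65}$ integral (dense trapezoid summation);
parameter recovery on untruncated samples of 100,000; calibrated
truncated designs at 20,000 records per nativity group (about 14,000
observed after truncation) for hazard-ratio and $e_{65}$-gap recovery
within Monte-Carlo tolerance; empirical 95% Wald coverage over 200
replicate truncated simulations; and classifier corpora of 5,000 names
per class for separability, with an identical-generator pair as the
no-signal control. These sizes were chosen so the full suite validates
every claim in minutes on a single CPU while keeping Monte-Carlo noise
well below the effect sizes being recovered; `scripts/acceptance.R`
re-runs the headline computations from scratch with a user-supplied
seed.

## Known limitations

- Observability windows are derived from birth *year*, not birth date;
  the half-year corrections make this exact only under within-year
  uniformity.
- The Wald/bootstrap intervals ignore uncertainty from classifier
  misclassification; the pipeline's ground-truth mode
  (`use_classifier = FALSE`) exists precisely to measure that
  attenuation by differencing the two runs.
- The recurrent classifier is binary (MENA vs. not); the source method's
  full multi-group taxonomy is out of scope.
- Exact reproducibility of trained models assumes the same BLAS;
  likelihood fits and all non-classifier results are
  BLAS-independent to their stated tolerances.
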