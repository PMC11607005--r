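# menamort

Demographic research on Middle Eastern and North African (MENA) Americans
runs into two structural data problems. First, U.S. federal race
classification folds MENA ancestry into the "white" category, so
administrative records carry no MENA identifier; the population has to be
recovered from what the records do contain — names. Second, large
administrative death files (social-security-style records) only have
reliable death coverage inside a calendar window and above an age floor,
so each birth cohort's death distribution is *doubly truncated*: both
early and late deaths are unobserved, and naive means or linear
regressions on age at death are biased.

`menamort` implements both halves of that analysis as a tested, reusable
R pipeline:

1. **Name classification.** A byte-pair-encoding (BPE) tokenizer learns
   variable-length character clusters from a name corpus (e.g. the "kh"
   cluster common to Arabic and Persian transliterations), and a gated
   recurrent sequence classifier (GRU, trained by backpropagation through
   time — implemented in the package, no deep-learning runtime needed)
   maps each tokenized full name to a probability of MENA origin.
   Training sets are built from foreign-born records labelled by
   birthplace, augmented with parent names, excluding records whose last
   racial-identity report predates the 1981 coding change.

2. **Truncated mortality estimation.** Age-specific mortality follows a
   Gompertz proportional-hazard model,

   *h<sub>i</sub>(x) = a₀ e^(b₀ x) e^(β Z<sub>i</sub>)*,

   with the hazard measured from age 65. Each record's death age is
   observable only inside its cohort-specific window [L<sub>i</sub>,
   U<sub>i</sub>] derived from the calendar window (deaths 1988–2005,
   ages 65+), and the likelihood conditions every death on that window:

   *ℓ = Σ w<sub>i</sub> [log h(x<sub>i</sub>) + log S(x<sub>i</sub>) −
   log(S(L<sub>i</sub>) − S(U<sub>i</sub>))]*.

   Maximum likelihood (BFGS with analytic gradient) yields hazard ratios,
   conditional life expectancy at 65 (e65, by adaptive quadrature of the
   survival function), and nativity effects on e65 with Wald or
   parametric-bootstrap confidence intervals. A linear regression on
   death age with birth-year fixed effects is provided as the standard
   robustness companion.

A synthetic person-record generator emulates the statistical structure of
such death files — six ethno-racial groups × two nativities, group-specific
character processes for names, per-group Gompertz mortality calibrated to
realistic over-65 differentials, administrative age rounding — so the
whole pipeline is testable end to end without downloading any data.

The package is aimed at demographers and epidemiologists working with
truncated administrative mortality data, and at anyone who needs a
self-contained, text-serializable name-ethnicity classifier.

## Worked example

Calibrate a Gompertz baseline so that U.S.-born e65 is 82.26 years and
foreign-born e65 is 85.39 years at a foreign-born hazard ratio of 0.64,
simulate a cohort, truncate it to the 1988–2005 / ages-65+ window, and
re-estimate the nativity effect:

```r
library(menamort)

cal <- calibrate_gompertz_e65(e65_native = 82.26, e65_foreign = 85.39, hr = 0.64)
# a0 = 0.0115, b0 = 0.118, beta_fb = log(0.64) = -0.446

cfg <- synthetic_config(
  n_records = 30000, seed = 101,
  group_proportions = c(mena = 0.5, white = 0.5),
  foreign_born_fraction_by_group = c(mena = 0.61, white = 0.064)
)
records <- generate_cohort(cfg)
deaths  <- apply_truncation(records, truncation_window())   # 10,607 records

mena_men <- deaths[deaths$group == "mena" & deaths$sex == "male", ]  # 2,665
fit <- fit_gompertz(death_observations(mena_men, truncation_window()))
fit
#> Doubly truncated Gompertz proportional-hazard fit
#>   n = 2665, origin = 65, loglik = -7144.891
#>   a0 = 0.011073, b0 = 0.12044
#>   Hazard ratios:
#>          term    beta      se     hr hr_lower hr_upper
#>  foreign_born -0.4545 0.06491 0.6348    0.559   0.7209

nativity_effect(fit, n_boot = 1000, seed = 101)
#>       hr hr_lower hr_upper e65_native e65_foreign delta_e65 delta_lower delta_upper
#>   0.6348    0.559   0.7209      82.29       85.43     3.145       2.292       4.027
```

At n ≈ 2,700 truncated deaths the estimator recovers the generating
hazard ratio (0.635, true 0.64) and the e65 gap (3.15 years, true 3.13):
the doubly truncated likelihood undoes the selection that makes the raw
mean death ages incomparable across cohorts.

The classifier side follows the same pattern:

```r
lab   <- build_training_set(records)        # foreign-born, birthplace-labelled,
                                            # parent-augmented, post-1981 only
model <- train_name_model(lab, max_vocab = 200, epochs = 5, seed = 1)
model$metrics                               # held-out precision/recall/F1
p     <- predict_name_proba(model, "khalil_khoury")
```

`run_pipeline(pipeline_config(...))` chains every stage — generation or
CSV input, classifier training, group reassignment (classified-MENA
records are carved out of their prior race coding), truncation,
descriptive statistics, per-(group, sex) mortality fits — and writes
`table1.csv` (descriptives), `table2.csv` (nativity hazard ratios and
effects on e65), `table3.csv` (e65 by nativity), `appendix_fe.csv`, the
classifier metrics, and the serialized model/vocabulary. A thin
command-line wrapper with `simulate` / `train-names` / `classify` /
`fit` / `run-all` subcommands lives at `inst/cli/menamort.R`.

## Package layout

- `R/gompertz.R`, `R/fit.R` — survival function, truncated likelihood
  (analytic gradient), MLE, e65 functional, calibration, nativity
  effects, fixed-effects check, descriptives.
- `R/bpe.R`, `R/gru.R`, `R/classifier.R` — tokenizer, recurrent network,
  training-set construction, metrics, bigram logistic baseline.
- `R/synthetic.R`, `R/names-generate.R` — record generator and per-group
  character Markov name processes.
- `R/pipeline.R`, `R/config-io.R`, `R/model-io.R` — orchestration, CSV
  and YAML interfaces, text model serialization.
- `vignettes/truncated-gompertz-mena.Rmd` — the methods vignette: model
  assumptions, parameter defaults, what the synthetic data do and do not
  emulate, numerical choices, and limitations.
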