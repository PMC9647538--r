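# psytraj

Data-driven modelling of the long-term course of psychotic disorders from
month-by-month symptom timelines.

After a first episode of psychosis, symptomatic course over the following
decade is highly variable. It is conventionally summarised by static
categories built on 6-month cut points — *episodic* (no episode ≥ 6
months), *continuous* (no remission ≥ 6 months), *neither* — which can
misclassify people with similar overall trajectories. `psytraj` implements
the data-driven alternative: aggregate each subject's monthly
presence/absence ratings into months-psychotic-per-year, `y_it ∈ [0, 12]`
for years `t = 1..10`, and fit growth mixture models

```
y_i | class k  ~  MVN( X β_k ,  Z Σ_b Zᵀ + σ² I )
```

— finite mixtures of polynomial latent growth curves with optional random
intercepts/slopes, estimated by multi-start EM under a missing-at-random
full-information likelihood. A model-selection ladder over class counts
and model forms applies the standard decision aids (BIC with a
10-point decisive difference, entropy, average posteriors, the
Lo–Mendell–Rubin test, a parametric bootstrapped likelihood ratio test,
and a 5% minimum-class-share rule). The package also provides the
classical course typology and a 2-year symptomatic recovery rule,
trajectory-by-outcome cross-tabulations, pairwise logistic odds ratios
for baseline covariates against a remitting reference, a random-intercept
logistic check of the MAR assumption, and a calibrated synthetic cohort
generator (no individual-level data of this kind are publicly deposited)
so the entire pipeline is testable end to end.

Who it is for: epidemiologists and biostatisticians analysing long-term
follow-up cohorts with Life-Chart-style symptom timelines, and anyone who
wants a transparent, tested reference implementation of GMM class
enumeration with LCGA/GMM ladders outside proprietary software.

## Worked example

```r
library(psytraj)

cfg <- generator_config(seed = 1)      # the calibrated default cohort
sim <- simulate_cohort(cfg)            # 326 subjects, 4 latent classes
Y   <- annual_matrix(sim$cohort)       # 326 x 10 months-per-year matrix

fit <- fit_gmm(Y, gmm_spec(K = 4, degree = 2,
                           random_effects = "intercept_slope",
                           n_starts = 50, seed = 8))
fit
#> <gmm_fit> K=4, degree=2, RE=intercept_slope | logLik -6256.827, BIC 12623.60, entropy 1.000
#>   class shares: 61.0% 28.5% 5.8% 4.6%

label_classes(fit)
#>            class_1            class_2            class_3            class_4
#>        "remitting"       "persistent"     "late_decline" "late_improvement"

round(fitted(fit)[c(1, 5, 10), ], 1)   # class mean curves, months/year
#>         class_1 class_2 class_3 class_4
#> year_1      4.3    10.7     1.2    11.9
#> year_5      1.9    10.6     5.1     6.7
#> year_10     0.9    10.0    11.4     1.5
```

The estimated shares (61.0 / 28.5 / 5.8 / 4.6) recover the generator's
58.5 / 30.6 / 5.6 / 5.4 split up to multinomial sampling error at
n = 326; entropy 1.000 means classification is essentially certain. The
four curves read as: remitting (moderate, falling to near zero),
persistent (high throughout), late decline (low, then rising after
mid-follow-up) and late improvement (high, then falling).

Cross-tabulating the modal classes against the classical 6-month
typology:

```r
course <- course_table(sim$cohort)
crosstab_class_by(modal_classes(fit),
                  setNames(course$course, course$subject_id))$counts
#>                   value
#> class              continuous episodic neither
#>   late_decline              0        0      19
#>   late_improvement          1        0      14
#>   persistent               89        0       4
#>   remitting                 0      171      28
```

Every episodic subject sits in the remitting class and almost every
continuous subject in the persistent class, while the "neither" category
scatters across all four trajectories — the typology's middle category
carries little trajectory information. Functional outcome differs
sharply by class:

```r
outcome_summaries(modal_classes(fit), sim$cohort$outcome)$by_class
#>              class   n     mean       sd
#> 1     late_decline  18 36.25000 16.90392
#> 2 late_improvement  10 51.44000 10.20405
#> 3       persistent  81 44.87531 12.17056
#> 4        remitting 170 63.56588 17.49167
# one-way F = 35.7 on (3, 275) df
```

(GAF-D disability, higher = better functioning; remitting subjects score
about 19 points above persistent ones.)

The full pipeline — simulate/read → aggregate → MAR check → model ladder
→ selection → labelling → course typology → cross-tabs → associations —
is one call:

```r
bundle <- run_pipeline(pipeline_config(generator = cfg, seed = 42,
                                       output_dir = "out/"))
cat(render_report(bundle), sep = "\n")
```

or from the shell via the installed CLI script:

```sh
inst/cli/psytraj simulate --out cohort/ --seed 1
inst/cli/psytraj run --out results/ --seed 42
```

## Package layout

- `R/cohort.R` — timeline/cohort types, CSV I/O, monthly→annual
  aggregation
- `R/simulate.R` — calibrated synthetic cohort generator
- `R/gmm.R` — growth mixture EM, BIC/entropy/posterior summaries,
  sandwich SEs
- `R/selection.R` — model ladder, LMR and bootstrap LRT, selection rules,
  class labelling
- `R/course.R` — run extraction, episodic/continuous/neither, recovery,
  cross-tabs
- `R/association.R` — odds ratios, MAR missingness check, outcome
  summaries
- `R/pipeline.R`, `R/cli.R` — orchestration, reporting, command line

The methods vignette (`vignettes/trajectory-modelling.Rmd`) documents the
model, the selection rules, every generator calibration constant and the
reasoning behind the numerical choices.
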