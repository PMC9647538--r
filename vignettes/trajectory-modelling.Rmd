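---
title: "Modelling long-term psychotic symptom trajectories with psytraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling long-term psychotic symptom trajectories with psytraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psytraj)
```

## The problem

After a first episode of psychosis, the long-term symptomatic course is
highly variable. Cohort studies traditionally compress month-by-month
symptom histories into a handful of static course types defined by fixed
cut points -- *episodic* (no symptomatic episode of 6 months or more),
*continuous* (no remission of 6 months or more) and *neither* (both a long
episode and a long remission occurred). Pre-specified cut points risk
misclassifying people whose overall trajectories are similar, which in turn
confounds the search for predictors of course.

`psytraj` implements the data-driven alternative: treat the number of
months psychotic per year, $y_{it}$ for subject $i$ in follow-up year
$t = 1,\dots,T$ (default $T = 10$), as repeated measures, and model the
population as a finite mixture of latent growth curves -- a growth mixture
model (GMM). Each latent class $k$ has mixing proportion $\pi_k$ and a
polynomial mean curve; subjects may additionally deviate from their class
curve through random intercepts and slopes:

$$
y_{it} \;=\; x_t^\top \beta_k \;+\; z_t^\top b_i \;+\; \varepsilon_{it},
\qquad b_i \sim N(0, \Sigma_b), \quad \varepsilon_{it} \sim N(0, \sigma^2),
$$

with $x_t = (1, t_c, t_c^2, \dots)$, $t_c$ the year centred at
$(T+1)/2$, and $z_t$ its first two components. Marginally, within class
$k$, $y_i \sim \mathrm{MVN}(X\beta_k,\; Z\Sigma_b Z^\top + \sigma^2 I)$.
Setting `random_effects = "none"` gives latent class growth analysis
(LCGA), the special case $\Sigma_b = 0$.

## Estimation

`fit_gmm()` maximises the observed-data likelihood by EM over class
membership, with the random effects integrated analytically (the
class-conditional marginal is multivariate normal, so no numerical
integration is needed):

* **E step.** Posterior class probabilities
  $p_{ik} \propto \pi_k \, \phi(y_i^{\mathrm{obs}}; (X\beta_k)^{\mathrm{obs}},
  V^{\mathrm{obs}})$, where the superscript restricts rows to each
  subject's observed years. This row-subsetting is the full-information
  treatment of missing data and is valid when missingness is MAR.
* **M step.** $\pi_k$ is the mean posterior; $\beta_k$ is a
  posterior-weighted generalised least-squares fit; $(\Sigma_b, \sigma^2)$
  are updated in closed form by treating the subject-level effects as
  additional latent data (their conditional moments are available
  analytically). Every component increases the EM minorant, so the
  log-likelihood is non-decreasing -- asserted on every test fit.

Mixture likelihoods are multimodal, so the fitter uses multi-start EM:
perturbed k-means initialisations, a short burn-in for every start, full
convergence for the most promising few, best log-likelihood kept. Classes
are reordered by descending $\pi_k$ so output is label-canonical.

Two numerical choices deserve a note:

* **Convergence.** The primary stop is an absolute log-likelihood gain
  below `tol` (default $10^{-6}$, `max_iter` 1000). Near-boundary variance
  components (a random-slope variance crawling toward zero) make plain EM
  crawl at $\sim 10^{-6}$ per iteration for thousands of iterations while
  every parameter is static to six decimals; the fitter therefore applies
  safeguarded SQUAREM-style extrapolation on an unconstrained parameter
  scale (log-Cholesky for $\Sigma_b$, log $\sigma^2$, multinomial logits
  for $\pi$), accepting an extrapolated step only when the log-likelihood
  does not decrease. Monotonicity is preserved; the crawl typically
  collapses from thousands of iterations to a few hundred.
* **Degenerate classes.** A start in which some $\pi_k$ falls below $1/n$
  is discarded and re-drawn (up to three times); if every start
  degenerates the fit aborts with advice to reduce `K`.

The outcome is bounded in $[0, 12]$ but modelled as Gaussian, exactly as
normal-theory GMM software does; truncation effects are accepted, not
modelled. A single residual variance is shared across classes and years,
and $\Sigma_b$ is shared across classes (the common software default);
class-specific covariances are out of scope.

Robust (sandwich) standard errors, `robust_standard_errors()`, use
$A^{-1} B A^{-\top}$ with $A$ the observed information (numerical Hessian)
and $B$ the outer product of per-subject scores obtained by central
differences -- the standard heteroscedasticity-robust variance for ML
estimators.

## Model selection

`run_model_ladder()` fits a grid over polynomial degree (linear,
quadratic; cubic is specifiable but routinely unidentified with ten
occasions -- such cells record their failure rather than aborting the
ladder), random-effect structure, and $K = 1..6$. Decision aids:

* **BIC** $= -2\ell + p\log n$; differences of 10 or more are treated as
  decisive.
* **Entropy** $E = 1 - \sum_{ik}(-p_{ik}\log p_{ik}) / (n\log K)$,
  1 = perfectly sharp classification.
* **Average posterior by modal class**, the per-class mean of $p_{ik}$
  among subjects assigned to $k$.
* **Lo-Mendell-Rubin test** (`lmr_test()`): the adjusted variant, i.e. the
  LR statistic deflated by $1 + 1/(d \log n)$ and referred to a
  $\chi^2_d$ reference. This is an approximation; implementations of the
  LMR reference differ by constants, which is tolerated here because the
  parametric bootstrap is the heavier-duty arbiter.
* **Bootstrapped LRT** (`bootstrap_lrt()`): simulate from the fitted
  $(k-1)$-class model (reproducing each subject's observed-year pattern),
  refit both models per draw, and use the add-one p-value
  $(1 + \#\{LR_b \ge LR_{\mathrm{obs}}\})/(B+1)$ -- never exactly zero, a
  deliberate convention since the paper-scale default is $B = 500$.
  Bootstrap refits default to 10 starts, a documented runtime trade-off.

`select_final_model()` encodes the published decision narrative as
explicit rules, applied in order among converged cells: drop cells with a
class below 5% of subjects; treat a BIC advantage of 10+ as decisive;
among the close survivors prefer higher entropy, then fewer classes. Every
firing is recorded in a trace. "Interpretability" beyond these rules is a
human judgement and is deliberately not encoded. If the class-size rule
eliminates everything, the best-BIC model is returned with a prominent
warning rather than silently.

`label_classes()` names the classes of a 4-class fit from their fitted
curves: the early mean (years 1-3) and late mean (years 8-10) are each
called *high* above 6 months/year, giving remitting (low/low), late
decline (low/high), late improvement (high/low) and persistent
(high/high).

## The synthetic cohort generator

Individual-level data of the kind this analysis was designed for are not
publicly deposited, so the package ships a generator
(`generator_config()`, `simulate_cohort()`) that emulates the assumed data
structure and makes every downstream stage testable. Its defaults are a
fixed "stated world":

* $n = 326$ subjects; class shares 58.5 / 5.6 / 5.4 / 30.6 percent
  (renormalised -- the printed values sum to 100.1%); follow-up length
  drawn per subject from $N(10.6, 1.1^2)$ years, clamped to 9.5-11 (the
  cohort design requires a completed timeline over roughly a decade).
* Quadratic class mean curves on the months-per-year scale, specified as
  anchor values at years 1, 5.5 and 10: remitting $(4.2, 1.6, 0.6)$, late
  decline $(1.2, 5.5, 11.8)$, late improvement $(11.3, 6.5, 1.0)$,
  persistent $(10.8, 10.5, 10.0)$. **These are calibration constants, not
  measurements**: no numeric curves are published, so the anchors were
  chosen to satisfy the verbal class descriptions with enough separation
  that a correctly specified 4-class fit reaches the published
  classification quality (entropy above 0.90, class-average posteriors
  above 0.98). The late-decline curve is deliberately convex -- low until
  mid follow-up, then rising steeply -- matching "initially remitting,
  more persistent over time".
* Monthly mechanism: month $m$ (fractional year $t$) is symptomatic with
  probability $p_m = \mathrm{clamp}\{(\beta_{0k} + \beta_{1k} t +
  \beta_{2k} t^2 + b_{0i} + b_{1i} t)/12,\, 0,\, 1\}$, except that with
  probability $\rho = 0.25$ the previous month's state simply carries
  forward (a two-state chain producing realistic episode runs). The
  expected symptomatic months per year track the class curve; the chain
  supplies the annual-level residual noise (about 1-2 months/year SD), so
  the extra year-level Gaussian knob `residual_sd` defaults to 0.
* Random effect SDs $(0.4, 0.04)$ months/year -- free constants
  (no variance components are published); the calibrated values keep
  within-class heterogeneity well below between-class separation.
* Missingness: whole years are blanked with probability 0.04, optionally
  shifted on the log-odds scale by observed baseline covariates. The
  masker reads covariates and the year index only -- never the symptom
  values -- so missingness is MAR **by construction** (a unit test blanks
  two cohorts that differ only in symptom values and asserts identical
  masks). Blanking whole years rather than single months matches the
  annual analysis grain.
* Covariates are generated class-conditionally (class first, covariates
  second), with prevalences chosen so that the implied
  persistent-vs-remitting odds ratios equal published adjusted estimates:
  male 1.89, black Caribbean 1.96, affective diagnosis 0.17. Duration of
  untreated psychosis uses gamma distributions with a shared shape and
  class-specific rates; with a shared shape the class log-density ratio is
  exactly linear in DUP, so the implied logistic coefficient is exactly
  $\log(1.05)$ per month. GAF-D disability scores are class-conditional
  normals with the published class means/SDs. The late-decline baseline
  profile mirrors the persistent one and late improvement mirrors
  remitting (with a shorter DUP), following the published qualitative
  reading.

What a green test on this world does establish: the estimators recover
the parameters of a correctly specified world of the published shape and
quality, the selection ladder prefers the true model form, and the
classical typology relates to the latent classes as reported. What it
does not establish: robustness to real-data features the generator
deliberately omits -- rating error, informative missingness, mortality
attrition, non-Gaussian within-class residual structure beyond the chain,
or the pre-presentation symptom period.

One stated-world tail is worth knowing about: a late-class subject can,
with probability about 0.002, show no 6-month episode in the observed
record (choppy high phase, possibly with the one long episode hidden in a
blanked year) and hence be classified *episodic* while belonging to a
small class. Averaged over cohorts this leaves episodic-to-largest-class
concordance at 99.9% rather than exactly 100%.

## Classical course typology

`extract_runs()` reduces a timeline to maximal presence/absence runs.
Missing gaps of at most 2 months flanked by the same state are bridged
(assigned that state); longer gaps and disagreeing flanks split the
sequence. The published analyses classified almost every subject despite
missing months, so *some* tolerance must have existed but none is stated;
the 2-month/matching-flanks rule is this package's explicit stand-in, and
conclusions that depend on it should be checked against the no-bridging
setting (`bridge = 0`).

`classify_course()` applies the 6-month typology with the doubly-negative
case (no long episode *and* no long remission) resolved as episodic --
"neither" is defined only by the conjunction of both long spells.
`assess_recovery()` implements symptomatic recovery as no symptomatic
month in the final 2 years, requiring at least 12 of those 24 months to be
rated (clear-information rule); shorter follow-ups are unclassifiable.

## Associations

`class_association_or()` fits pairwise binary logistic regressions (each
comparison class versus the remitting reference, matching how per-class
odds ratios are conventionally tabulated), ML-estimated with Wald 95%
intervals, adjusted for centre, sex, age and ethnicity except when the
covariate is itself one of these. Modal (hard) class assignment feeds the
regressions -- standard three-step practice; with entropy near 1 the
classification-error attenuation this ignores is negligible, and formal
three-step corrections are out of scope. `missingness_mar_check()` fits
random-intercept logistic regressions of the subject-year missingness
indicator on each baseline covariate (via `lme4`), the published check of
MAR plausibility. `outcome_summaries()` gives per-class outcome means/SDs
with a one-way ANOVA F.

## Reduced test scales

Null-calibration tests (LMR and bootstrap LRT rejection rates, MAR-check
type-I error) run at reduced scale -- 200 replicates of $n = 100$
subjects, $B = 50$ bootstrap draws, 1-2 EM starts, tolerance $10^{-4}$ --
chosen so the whole suite runs in minutes on one CPU. The LR statistics
involved are of order 1, so a $10^{-4}$ likelihood tolerance is far below
the resolution the tests need.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(seed = 1)
sim <- simulate_cohort(cfg)
Y <- annual_matrix(sim$cohort)

fit <- fit_gmm(Y, gmm_spec(K = 4, degree = 2,
                           random_effects = "intercept_slope",
                           n_starts = 50, seed = 8))
label_classes(fit)
plot(fit, labels = label_classes(fit))

course <- course_table(sim$cohort)
crosstab_class_by(modal_classes(fit),
                  setNames(course$course, course$subject_id))
```

The full pipeline -- simulate or read, aggregate, MAR check, ladder,
selection, labelling, course typology, cross-tabs, associations -- is
`run_pipeline(pipeline_config(...))`, also exposed as the `psytraj`
command line (`inst/cli/psytraj`).

## Known limitations

* The LMR reference distribution is an approximation; treat its p-values
  as advisory next to the bootstrap.
* A single shared $\sigma^2$ (not class- or year-specific) and a shared
  $\Sigma_b$; whether the original software run shared them is not
  stated.
* No MPlus-style MLR scaling corrections for LRT statistics; robust SEs
  use the plain sandwich.
* Real-data artefacts (see the generator section) are not emulated, and
  the published real-data odds ratios and outcome tables are therefore
  not reproduction targets -- only the generator's configured effects
  are.
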