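---
title: "Scoring pediatric adrenocortical neoplasms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pediatric adrenocortical neoplasms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acnscore)
```

## The diagnostic problem

Pediatric adrenocortical neoplasms (ACNs) frequently display atypical
morphology — brisk mitoses, necrosis, nuclear atypia — while behaving
indolently, so the adenoma/carcinoma distinction that works in adults
fails in children: no single histologic parameter is predictive on its
own, and adult systems over-call malignancy. The systems this package
implements attack the problem in three ways:

* **Wieneke criteria (WC).** Nine weighted-equally items — tumor
  weight >400 g, size >10.5 cm, extension into periadrenal soft
  tissue, vena cava invasion, venous invasion, capsular invasion,
  necrosis, >15 mitoses/20 HPF, atypical mitoses. The criterion count
  maps to a class: <3 benign, =3 indeterminate (uncertain malignant
  potential), >3 malignant.
* **Modified Wieneke criteria (mWC).** A two-step rule: step 1 counts
  the five *microscopic* items (necrosis, >15 mitoses/20 HPF, atypical
  mitoses, venous invasion, capsular invasion); step 2 resolves the
  intermediate band with the Ki67 proliferative index (cutoff 15%).
  The output is favorable vs unfavorable histology.
* **Reticulin algorithm (RA).** A gatekeeper design: malignancy
  requires disruption of the silver-staining reticulin framework
  (quantitative loss of fibers over extensive areas, qualitative
  fraying, or both), *plus* at least one of three malignancy criteria
  — necrosis, venous invasion, or a high mitotic rate. The adult
  variant (aRA) uses the Weiss-convention cutoff of >5 mitoses/50 HPF;
  the pediatric variant (pRA) uses the Wieneke-convention cutoff of
  >15 mitoses/20 HPF.

Because the pediatric cutoff is strictly harder to exceed while the
two variants share every other ingredient, pRA-malignant calls are a
subset of aRA-malignant calls whenever the two mitotic counts describe
the same underlying rate. This nesting is load-bearing: it is what
lets the joint pRA×aRA table — and hence Cohen's kappa between the two
variants — be reconstructed exactly from published marginal counts
(`reconstruct_nested_2x2()`).

## Decisions where the published record is open

**Mitotic denominators are never silently rescaled.** A count over 50
HPF and a count over 20 HPF come from different conventions (field
area, hot-spot selection), so each cutoff is compared only against the
count with its own denominator. `allow_mitotic_rescale` exists for
users who accept linear rescaling; it warns on every use.

**Adult cutoff.** Published descriptions of the algorithm circulate
with both ">50/50 HPF" and ">5/50 HPF"; the former is a typographical
corruption of the Weiss-convention threshold, and this package uses
>5/50 HPF throughout.

**Partial missingness resolves to a class when the verdict cannot
change.** A Wieneke case with four criteria already true is malignant
no matter what the missing items would have said; an intact reticulin
framework forces benign whatever else is unknown; three malignancy
criteria known false force RA-benign even without the stain. This
mirrors per-analysis deletion — each analysis keeps every case it can
decide — and explains why the four systems have different evaluable
Ns on the same cohort. The exact integer scores are reported only when
every item is evaluable.

**The mWC step-2 band is configuration.** The five microscopic items
and the 15% Ki67 cutoff are fixed by the system's description, but the
exact published trigger band is not restated in the sources this
package reproduces; the shipped default (score ≥3 unfavorable, ≤1
favorable, =2 resolved by Ki67) is therefore a documented
reconstruction, stored in `default_rules()` / `default_rules.cfg`
rather than hard-coded, and should be re-verified against the primary
description before clinical use.

**"Venous" vs "vascular" invasion.** The sources conflate the RA's
venous-invasion criterion with tabulated "vascular invasion"; the data
model keeps a single `vascular_invasion` field used for both and
documents the conflation.

**Qualitative-only alteration counts as disruption.** Published
cross-tabs contain RA-malignant cases whose only alteration is
qualitative, so any non-intact category satisfies the gatekeeper step.

## Agreement statistics

`cohen_kappa()` computes `kappa = (po - pe) / (1 - pe)` with the
large-sample standard error `sqrt(po(1-po)) / ((1-pe) sqrt(n))` and a
Wald 95% interval. The simpler variance was chosen over the
Fleiss–Cohen–Everitt expression deliberately: on the reconstructed
pRA×aRA table it reproduces the published interval (0.74–0.99) exactly
at two decimals, identifying it as the convention behind the published
numbers. `cramer_v()` uses the plain Pearson chi-square — no Yates
continuity correction, no bias correction — for the same reason (it
reproduces 0.68 / 0.69 / 0.57 exactly at two decimals). The
three-level Wieneke class is treated as nominal in V. Comparisons
against printed values round half away from zero
(`round_half_away()`), because base R's round-ties-to-even would turn
62.5% into 62%.

## Outcome models

Kaplan–Meier curves, the log-rank test and the Cox model are fitted
through the survival package (Breslow ties by default, matching the
default of the commercial software typically used for such analyses;
Efron available). The package owns the accounting around them: AIC is
`2k - 2 logPL`, the survival event defaults to death of disease with
AWD/CR censored at last follow-up (`event = "awd_or_dod"` switches to
the composite), and the logistic model's outcome defaults to the
composite unfavorable (AWD or DOD) — the coding most consistent with
published AUC magnitudes, though not exactly recoverable, which is why
published AUC and AIC *values* are treated as unverifiable
(`reproduce_all()`) and only the qualitative ordering — pRA best by
Cox AIC — is checked, by simulation. The ROC AUC is the midrank
Mann–Whitney statistic of fitted probabilities, hence invariant to any
strictly increasing transform. `compare_scores()` runs all systems on
the identical complete-case subset by default so AICs are comparable.
The indeterminate Wieneke class stays its own level rather than being
merged into malignant.

## The synthetic cohort generator

No per-case data for the modelled 92-tumor cohort were ever
published, so the package ships a generator
(`default_paper_spec()` + `generate_cohort()`) whose large-sample
expectations match the published marginals, making every pipeline
stage testable without access to the original specimens.

* **Latent mitotic rate.** One lognormal per-HPF rate per case
  generates both counts: the 50-HPF count is Poisson with exposure 50
  and the 20-HPF count is a binomial thinning of it (20 of the same 50
  fields). Thinning, rather than two independent Poissons, makes the
  count pair coherent, so the pRA ⊂ aRA nesting holds *case-wise with
  certainty* rather than with high probability. The lognormal
  parameters are solved at spec-construction time by quadrature so
  that P(>5/50 HPF) = 55/88 = 62.5% and P(>15/20 HPF) = 22/92 = 23.9%
  exactly.
* **Binary features.** Necrosis, invasions and atypical mitoses are
  Bernoulli with log-odds coupled to quantitative alteration and to a
  high latent mitotic rate, so malignant-pattern features co-occur;
  each feature's intercept is solved so its marginal prevalence hits
  the published count (e.g. necrosis 43/92). Couplings lean more on
  the mitotic rate than on the reticulin category because, in
  children, atypical features occur in framework-intact tumors too.
  The coupling magnitudes themselves are a modelling choice the
  published record cannot constrain; they live in the spec object,
  not in code.
* **Reticulin.** Categories drawn at the published mix (25 intact, 15
  qualitative, 49 quantitative, 3 both, of 92).
* **Outcome.** Survival is exponential per risk stratum, the
  high-risk stratum being exactly the condition the pRA calls
  malignant (disrupted framework plus ≥1 pediatric-cutoff criterion),
  with hazard ratio 9.5 over a base 0.0008/month and uniform
  administrative censoring on 6–112 months. These values were fixed
  so that the expected outcome mix per 59 outcome-known cases is
  ≈39 CR : 9 AWD : 11 DOD and median follow-up ≈48 months. Deaths
  before censoring become DOD; censored cases are AWD with a
  per-stratum probability, otherwise CR. Making the pRA condition the
  true hazard stratum is what gives the simulated analogue of the
  published AIC ordering: in repeated cohorts of 92, the pRA attains
  the lowest Cox AIC in roughly three-quarters of replicates, with the
  remainder mostly won by the closely correlated Wieneke class on
  11-event samples.
* **Missingness** is masked last, field by field, at the published
  missing-data rates (weight 47/92, Ki67 15/92, outcome 33/92, ...),
  so the generated truth — kept as the `"truth"` attribute — is
  unaffected.

What the generator does *not* emulate: observer disagreement, staining
artefacts, within-tumor heterogeneity, correlated missingness (missing
weight and missing size co-occur in practice), or any dependence of
censoring on risk. Passing tests on synthetic cohorts therefore
validate the statistical machinery and the classification logic, not
the clinical performance of any score on real material.

## The reconstructed 59-case cohort

`reconstruct_cohort59()` (shipped as `extdata/cohort59_synthetic.csv`)
is a deterministic, hand-constructed cohort realizing every margin the
published summary tables determine: the outcome mix, all four class
marginals, the Wieneke-by-system and reticulin-by-system cross-tabs,
the Ki67>15% split, and the sex/stage/laterality breakdowns per
system. Its continuous values (weights, ages, follow-up times) are
synthetic placeholders chosen only to trigger the intended criteria —
per-group medians and the feature-by-class rows that over-constrain
the joint distribution are deliberately not reproduced. The file
exists so the end-to-end pipeline (CSV → scoring → contingency →
statistics) can be exercised against known published totals.

## Numerical and testing choices

Degenerate inputs raise typed errors early: empty tables, zero
marginals (V undefined), chance agreement of 1 (kappa undefined), no
events (log-rank undefined), constant covariates. Monotone likelihood
in the Cox model is flagged (`converged = FALSE`) rather than raised,
since separation is an informative outcome on 11-event cohorts. All
agreement statistics are validated against brute-force oracles
(explicit cell/risk-set summation, grid-search likelihood
maximization) to 1e-10 on random instances of n ≤ 12, and the test
suite's simulation checks use 100 replicates at n = 600 (hazard-ratio
recovery, nominal 95% CI coverage required ≥90%) and 100 replicates
at n = 92 (AIC ordering, majority required) — sizes chosen to keep the
default suite under a minute while leaving the binomial noise on the
checked rates well inside their acceptance margins.
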