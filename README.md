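# acnscore

Diagnostic scoring and outcome comparison for **pediatric
adrenocortical neoplasms (ACNs)**.

Distinguishing adrenocortical adenoma from carcinoma in children is
notoriously unreliable on morphology alone: pediatric tumors often look
alarming and behave indolently, and adult systems over-call malignancy.
`acnscore` implements, as executable rules over per-case histopathology
records, the four classification systems used in this setting, plus the
statistical machinery for comparing them with each other and with
outcome. It is aimed at pathologists and biostatisticians validating
such scores on their own cohorts.

## The scoring systems

* **Wieneke criteria (WC)** — count of nine items (weight >400 g, size
  >10.5 cm, extra-adrenal extension, vena cava invasion, venous
  invasion, capsular invasion, necrosis, >15 mitoses/20 HPF, atypical
  mitoses); class `benign` (<3), `indeterminate` (=3), `malignant` (>3).
* **Modified Wieneke (mWC)** — five microscopic items, with the
  intermediate band resolved by the Ki67 proliferative index (≥15%);
  `favorable` vs `unfavorable` histology.
* **Reticulin algorithm, adult and pediatric (aRA / pRA)** — malignant
  iff the reticulin framework is disrupted (quantitative and/or
  qualitative alteration) **and** ≥1 of: necrosis, venous invasion, or
  mitoses above the cutoff — >5/50 HPF (aRA) or >15/20 HPF (pRA).

Around the rules: contingency tables, Cohen's kappa
(`kappa = (p_o − p_e)/(1 − p_e)`, SE `√(p_o(1−p_o))/((1−p_e)√n)`),
Cramér's V (`V = √(χ²/(n·min(r−1, c−1)))`, uncorrected Pearson χ²),
Kaplan–Meier / log-rank / Cox / logistic model comparison by AIC
(`2k − 2logL`), a calibrated synthetic-cohort generator, and a
reproduction module for the published summary statistics of the
92-tumor cohort the package models.

## Worked example

```r
library(acnscore)

case <- acn_case("T1", weight_g = 120, size_cm = 6.5,
                 mitoses_50hpf = 12, mitoses_20hpf = 5,
                 necrosis = TRUE, atypical_mitoses = TRUE,
                 vascular_invasion = FALSE, capsular_invasion = FALSE,
                 extra_adrenal_extension = FALSE, vena_cava_invasion = FALSE,
                 ki67_percent = 22, reticulin = "quantitative")
score_panel(case)[, c("wc_score", "wc_class", "mwc_score", "mwc_class",
                      "ara_class", "pra_class")]
#>   wc_score wc_class mwc_score   mwc_class ara_class pra_class
#> 1        2   benign         2 unfavorable malignant malignant
```

The tumor satisfies two of nine Wieneke criteria (necrosis, atypical
mitoses) — `benign` under the WC — but its microscopic score of 2 with
Ki67 = 22% triggers the mWC's Ki67 step (`unfavorable`), and the
disrupted reticulin framework plus necrosis makes it `malignant` under
both reticulin-algorithm variants, whose mitotic cutoffs (12/50 HPF
exceeds 5; 5/20 HPF does not exceed 15) would here disagree if necrosis
were absent.

Agreement between systems, from the shipped summary tables:

```r
fix <- load_fixture()
cramer_v(fix$wc_by_ara)
#> [1] 0.6786381

cohen_kappa(reconstruct_nested_2x2(fix$derived_marginals$ara,
                                   fix$derived_marginals$pra))
#> Cohen's kappa = 0.864 (95% CI 0.735-0.993), strong agreement; n = 59
```

The pRA×aRA joint table is not published anywhere — it is *forced* by
the marginals because the pediatric cutoff is strictly stricter
(`reconstruct_nested_2x2()`), which is what makes the kappa computable
at all.

Cohorts are plain CSVs (`read_cohort()` / `write_cohort()`, with
optional column-name mapping), and `compare_scores()` produces the
per-system Cox/logistic AIC ranking on a scored cohort. A thin CLI
wrapper for shell pipelines ships in `inst/cli/acn.R`.

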