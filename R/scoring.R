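# The four diagnostic classification rules. All functions are
# vectorized over the rows of a cohort and return NA where a class is
# not decidable from the non-missing fields.

.wc_class_levels  <- c("benign", "indeterminate", "malignant")
.mwc_class_levels <- c("favorable", "unfavorable")
.ra_class_levels  <- c("benign", "malignant")

# Strict-inequality mitotic criterion against the count with the
# matching denominator. Rescaling from the other denominator is
# refused unless rules$allow_mitotic_rescale is set, because HPF area
# and counting protocol differ between the 50-HPF and 20-HPF
# conventions.
.mitotic_exceeds <- function(cohort, cutoff, denominator, rules) {
  native <- if (denominator == 50) cohort$mitoses_50hpf else cohort$mitoses_20hpf
  other  <- if (denominator == 50) cohort$mitoses_20hpf else cohort$mitoses_50hpf
  other_den <- if (denominator == 50) 20 else 50
  res <- native > cutoff
  if (isTRUE(rules$allow_mitotic_rescale)) {
    use <- is.na(native) & !is.na(other)
    if (any(use)) {
      warning("rescaling ", sum(use), " mitotic count(s) from ",
              other_den, " to ", denominator,
              " HPF; conventions differ and counts are not strictly comparable",
              call. = FALSE)
      res[use] <- other[use] * denominator / other_den > cutoff
    }
  }
  res
}

# The nine Wieneke criteria as an n x 9 logical matrix (NA = not
# evaluable). Thresholds come from the rules config.
.wieneke_criteria <- function(cohort, rules = default_rules()) {
  cbind(
    weight          = cohort$weight_g > rules$wc$weight_g,
    size            = cohort$size_cm > rules$wc$size_cm,
    extra_adrenal   = cohort$extra_adrenal_extension,
    vena_cava       = cohort$vena_cava_invasion,
    vascular        = cohort$vascular_invasion,
    capsular        = cohort$capsular_invasion,
    necrosis        = cohort$necrosis,
    mitoses         = .mitotic_exceeds(cohort, rules$wc$mitoses_20hpf,
                                       20, rules),
    atypical        = cohort$atypical_mitoses
  )
}

#' Wieneke score (nine-item count)
#'
#' Counts how many of the nine Wieneke criteria a tumor satisfies:
#' weight >400 g, size >10.5 cm, extra-adrenal extension, vena cava
#' invasion, venous (vascular) invasion, capsular invasion, necrosis,
#' >15 mitoses/20 HPF, and atypical mitoses. The exact integer score
#' requires all nine criteria to be evaluable; with partial
#' missingness the score is `NA` but the *class* may still be
#' decidable -- see [wieneke_classify_cases()].
#'
#' @param cohort An `acn_cohort` data frame (or single case).
#' @param rules Scoring rules, see [default_rules()].
#' @return Integer vector in 0..9, `NA` where any criterion is
#'   unevaluable.
#' @export
wieneke_score <- function(cohort, rules = default_rules()) {
  crit <- .wieneke_criteria(as_cohort(cohort), rules)
  score <- as.integer(rowSums(crit))
  score
}

#' Classify a Wieneke score
#'
#' Fixed thresholds: score <3 benign, =3 indeterminate (uncertain
#' malignant potential), >3 malignant.
#'
#' @param score Integer vector of Wieneke scores (0..9); `NA` passes
#'   through.
#' @return Character vector: `"benign"`, `"indeterminate"` or
#'   `"malignant"`.
#' @export
wieneke_classify <- function(score) {
  ok <- is.na(score) | (score >= 0 & score <= 9 & score == round(score))
  if (!all(ok)) {
    stop("domain error: Wieneke score must be an integer in 0..9",
         call. = FALSE)
  }
  ifelse(is.na(score), NA_character_,
         ifelse(score < 3, "benign",
                ifelse(score == 3, "indeterminate", "malignant")))
}

#' Wieneke class with partial missingness
#'
#' Emits the class whenever it is decidable despite missing items:
#' with `t` criteria known true and `m` unknown, the score is bracketed
#' by \[t, t + m\], and the class is reported when both bounds fall in
#' the same band (e.g. four criteria already true forces
#' `"malignant"`). Otherwise `NA`. This mirrors per-analysis deletion:
#' cases stay usable whenever the verdict cannot change.
#'
#' @inheritParams wieneke_score
#' @return Character vector of classes, `NA` where undecidable.
#' @export
wieneke_classify_cases <- function(cohort, rules = default_rules()) {
  crit <- .wieneke_criteria(as_cohort(cohort), rules)
  lo <- as.integer(rowSums(crit, na.rm = TRUE))
  hi <- lo + as.integer(rowSums(is.na(crit)))
  cl_lo <- wieneke_classify(lo)
  cl_hi <- wieneke_classify(hi)
  ifelse(cl_lo == cl_hi, cl_lo, NA_character_)
}

#' Modified-Wieneke microscopic score (five items)
#'
#' Counts the satisfied items among: necrosis, >15 mitoses/20 HPF,
#' atypical mitoses, vascular invasion, capsular invasion. All five
#' items must be evaluable; otherwise the score is `NA`.
#'
#' @inheritParams wieneke_score
#' @return Integer vector in 0..5, `NA` where any item is missing.
#' @export
mwc_microscopic_score <- function(cohort, rules = default_rules()) {
  x <- as_cohort(cohort)
  items <- cbind(
    necrosis = x$necrosis,
    mitoses  = .mitotic_exceeds(x, rules$wc$mitoses_20hpf, 20, rules),
    atypical = x$atypical_mitoses,
    vascular = x$vascular_invasion,
    capsular = x$capsular_invasion
  )
  as.integer(rowSums(items))
}

#' Modified-Wieneke class (two-step rule)
#'
#' Step 1 is the five-item microscopic score; step 2 resolves the
#' intermediate band with the Ki67 proliferative index. Under the
#' default rule a score of `unfavorable_min` (3) or more is
#' unfavorable, `favorable_max` (1) or less favorable, and a score of
#' 2 is unfavorable iff Ki67 >= 15%. The band bounds and Ki67 cutoff
#' are configuration ([default_rules()]); the default band is a
#' reconstruction of the published two-step algorithm.
#'
#' @inheritParams wieneke_score
#' @return Character vector: `"favorable"`, `"unfavorable"`, or `NA`
#'   when the microscopic score (or a needed Ki67) is missing.
#' @export
mwc_classify <- function(cohort, rules = default_rules()) {
  x <- as_cohort(cohort)
  score <- mwc_microscopic_score(x, rules)
  out <- rep(NA_character_, nrow(x))
  out[!is.na(score) & score >= rules$mwc$unfavorable_min] <- "unfavorable"
  out[!is.na(score) & score <= rules$mwc$favorable_max] <- "favorable"
  band <- !is.na(score) & score > rules$mwc$favorable_max &
    score < rules$mwc$unfavorable_min
  out[band & !is.na(x$ki67_percent)] <-
    ifelse(x$ki67_percent[band & !is.na(x$ki67_percent)] >=
             rules$mwc$ki67_cutoff, "unfavorable", "favorable")
  out
}

#' Reticulin algorithm (adult or pediatric mitotic cutoff)
#'
#' Two-step rule: a tumor is malignant iff the reticulin framework is
#' disrupted (any non-intact category, quantitative or qualitative)
#' *and* at least one of three malignancy criteria is present:
#' necrosis, venous (vascular) invasion, or a mitotic rate above the
#' variant's cutoff -- >5/50 HPF for the adult variant (aRA), >15/20
#' HPF for the pediatric variant (pRA). Each cutoff is compared only
#' against the count with its own denominator.
#'
#' Partial missingness is resolved whenever the class is already
#' decided: an intact framework forces `"benign"` regardless of other
#' fields; a disrupted framework with any criterion known true forces
#' `"malignant"`; and all three criteria known false force `"benign"`
#' even when reticulin was not assessed.
#'
#' @inheritParams wieneke_score
#' @param variant `"adult"` or `"pediatric"`.
#' @return Character vector: `"benign"`, `"malignant"`, or `NA` when
#'   undecidable.
#' @export
ra_classify <- function(cohort, variant = c("adult", "pediatric"),
                        rules = default_rules()) {
  variant <- match.arg(variant)
  x <- as_cohort(cohort)
  altered <- reticulin_altered(x$reticulin)
  cutoff <- if (variant == "adult") rules$ra$adult_cutoff else rules$ra$pediatric_cutoff
  denom  <- if (variant == "adult") rules$ra$adult_denominator else rules$ra$pediatric_denominator
  crit <- cbind(
    necrosis = x$necrosis,
    vascular = x$vascular_invasion,
    mitoses  = .mitotic_exceeds(x, cutoff, denom, rules)
  )
  any_true  <- rowSums(crit, na.rm = TRUE) > 0
  all_false <- rowSums(!crit) == 3L  # NA-propagating: all known false
  all_false[is.na(all_false)] <- FALSE
  out <- rep(NA_character_, nrow(x))
  out[!is.na(altered) & !altered] <- "benign"
  out[all_false] <- "benign"
  out[!is.na(altered) & altered & any_true] <- "malignant"
  out
}

#' Score panel: all four classifications per case
#'
#' Applies the Wieneke criteria, the modified-Wieneke two-step rule
#' and both reticulin-algorithm variants to every case, appending the
#' raw scores and class labels as columns. Each sub-score is computed
#' whenever its inputs allow and `NA` otherwise, so a partially
#' documented case still contributes to the analyses it can support.
#'
#' @inheritParams wieneke_score
#' @return The cohort with columns `wc_score`, `wc_class`,
#'   `mwc_score`, `mwc_class`, `ara_class`, `pra_class` appended.
#' @examples
#' cs <- default_paper_spec(n = 10, seed = 1)
#' score_panel(generate_cohort(cs))[, c("case_id", "wc_class",
#'                                      "ara_class", "pra_class")]
#' @export
score_panel <- function(cohort, rules = default_rules()) {
  x <- as_cohort(cohort)
  x$wc_score  <- wieneke_score(x, rules)
  x$wc_class  <- wieneke_classify_cases(x, rules)
  x$mwc_score <- mwc_microscopic_score(x, rules)
  x$mwc_class <- mwc_classify(x, rules)
  x$ara_class <- ra_classify(x, "adult", rules)
  x$pra_class <- ra_classify(x, "pediatric", rules)
  x
}
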