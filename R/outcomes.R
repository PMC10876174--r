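# Outcome association: Kaplan-Meier, log-rank, Cox, logistic, and the
# AIC-based ranking of the scoring systems. Standard fits go through
# the survival package and stats::glm; this module owns the tidying,
# the AIC accounting, and the midrank AUC.

.check_surv <- function(time, event) {
  if (length(time) == 0L) {
    stop("insufficient data: no survival samples", call. = FALSE)
  }
  if (any(is.na(time)) || any(is.na(event))) {
    stop("time and event must be complete; filter incomplete cases first",
         call. = FALSE)
  }
  if (any(time <= 0)) {
    stop("survival times must be positive", call. = FALSE)
  }
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimate of the survival function, optionally per
#' group. Censored times reduce the risk set without introducing a
#' step.
#'
#' @param time Positive follow-up times (months).
#' @param event Logical, `TRUE` if the event occurred at `time`.
#' @param group Optional group labels (one curve per level).
#' @return `data.frame` of class `acn_km` with columns `group` (if
#'   supplied), `time`, `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(time, event, group = NULL) {
  .check_surv(time, event)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      survival = fit$surv)
  } else {
    g <- factor(group)
    fit <- survival::survfit(survival::Surv(time, event) ~ g)
    strata <- rep(names(fit$strata), fit$strata)
    out <- data.frame(group = sub("^g=", "", strata),
                      time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      survival = fit$surv)
  }
  class(out) <- c("acn_km", "data.frame")
  out
}

#' Log-rank test
#'
#' Standard (unweighted) log-rank comparison of survival across two or
#' more groups; the statistic is referred to a chi-square distribution
#' with `groups - 1` degrees of freedom.
#'
#' @inheritParams km_estimate
#' @param group Group labels, at least two non-empty levels.
#' @return List with `chisq`, `df`, `p`.
#' @export
log_rank_test <- function(time, event, group) {
  .check_surv(time, event)
  g <- factor(group)
  if (nlevels(droplevels(g)) < 2L) {
    stop("insufficient data: log-rank needs at least 2 groups",
         call. = FALSE)
  }
  if (!any(event)) {
    stop("undefined test: no events observed", call. = FALSE)
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ g)
  df <- length(fit$n) - 1L
  list(chisq = as.numeric(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit with AIC
#'
#' Maximum partial-likelihood fit of a single covariate (class label
#' or numeric), Breslow tie handling by default. The AIC is
#' `2 k - 2 logPL` with `k` the number of estimated coefficients.
#' Monotone likelihood (complete separation of the events) is flagged
#' through `converged = FALSE` rather than raised.
#'
#' @inheritParams km_estimate
#' @param covariate Class labels (factor/character, one-hot encoded
#'   against the first level) or a numeric covariate.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return List of class `acn_cox`: `coefficients`, `se`, `hr`,
#'   `loglik` (partial log-likelihood at the estimate), `loglik_null`,
#'   `aic`, `n`, `n_event`, `converged`.
#' @export
cox_fit <- function(time, event, covariate, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  .check_surv(time, event)
  if (!any(event)) {
    stop("insufficient data: no events observed", call. = FALSE)
  }
  x <- if (is.numeric(covariate)) covariate else droplevels(factor(covariate))
  if (length(unique(stats::na.omit(x))) < 2L) {
    stop("covariate is constant", call. = FALSE)
  }
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = ties),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  k <- sum(!is.na(stats::coef(fit)))
  logpl <- fit$loglik[2]
  cf <- stats::coef(fit)
  names(cf) <- sub("^x", "", names(cf))
  se <- sqrt(diag(fit$var))
  names(se) <- names(cf)
  structure(list(coefficients = cf, se = se, hr = exp(cf),
                 loglik = logpl, loglik_null = fit$loglik[1],
                 aic = 2 * k - 2 * logpl,
                 n = fit$n, n_event = fit$nevent,
                 converged = converged),
            class = "acn_cox")
}

# Midrank (Mann-Whitney) AUC of a score against a binary outcome.
.auc_midrank <- function(score, outcome) {
  outcome <- as.logical(outcome)
  r <- rank(score, ties.method = "average")
  n1 <- sum(outcome); n0 <- sum(!outcome)
  if (n1 == 0L || n0 == 0L) {
    stop("insufficient data: both outcome classes required",
         call. = FALSE)
  }
  (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Logistic regression fit with AIC and ROC AUC
#'
#' Maximum-likelihood logistic fit of a binary outcome on a single
#' predictor (class labels are one-hot encoded). The AUC is the
#' Mann-Whitney statistic of the fitted probabilities against the
#' outcome, with ties handled by midranks -- so it is invariant to any
#' strictly increasing transform of the fitted probabilities.
#' Separation is flagged through `converged = FALSE`.
#'
#' @param outcome Logical vector (`TRUE` = event/unfavorable).
#' @param predictor Class labels or numeric predictor.
#' @return List of class `acn_logistic`: `coefficients`, `loglik`,
#'   `aic`, `auc`, `n`, `converged`.
#' @export
logistic_fit <- function(outcome, predictor) {
  outcome <- as.logical(outcome)
  if (any(is.na(outcome)) || any(is.na(predictor))) {
    stop("outcome and predictor must be complete", call. = FALSE)
  }
  if (length(unique(outcome)) < 2L) {
    stop("insufficient data: outcome is constant", call. = FALSE)
  }
  x <- if (is.numeric(predictor)) predictor else droplevels(factor(predictor))
  form <- if (length(unique(x)) < 2L) outcome ~ 1 else outcome ~ x
  converged <- TRUE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge",
                conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  cf <- stats::coef(fit)
  names(cf) <- sub("^x", "", names(cf))
  structure(list(coefficients = cf,
                 loglik = as.numeric(stats::logLik(fit)),
                 aic = fit$aic,
                 auc = .auc_midrank(fit$fitted.values, outcome),
                 n = length(outcome),
                 converged = converged && fit$converged),
            class = "acn_logistic")
}

.system_columns <- c(wc = "wc_class", mwc = "mwc_class",
                     ara = "ara_class", pra = "pra_class")

#' Compare scoring systems by outcome models
#'
#' For each scoring system, fits (i) a Cox proportional-hazards model
#' of survival on the system's class and (ii) a logistic regression of
#' the binary unfavorable outcome on the class, and runs a log-rank
#' test across the classes. Systems are ranked by Cox AIC (ascending;
#' lowest = best). The survival event defaults to death of disease
#' (`"dod"`), with complete remission and alive-with-disease censored
#' at last follow-up; the logistic outcome defaults to the composite
#' unfavorable `"awd_or_dod"`.
#'
#' By default the comparison runs on the identical case subset: cases
#' with known outcome and follow-up on which *every* compared system
#' is evaluable (complete-case across systems).
#'
#' @param panel A scored cohort, as from [score_panel()], with
#'   `outcome` and `followup_months` filled where known.
#' @param systems Which systems to compare; subset of
#'   `c("wc", "mwc", "ara", "pra")`.
#' @param event Survival event definition: `"dod"` or `"awd_or_dod"`.
#' @param logistic_outcome Binary outcome for the logistic model:
#'   `"awd_or_dod"` (default) or `"dod"`.
#' @param complete_cases If `TRUE` (default), restrict to cases
#'   evaluable under every compared system.
#' @return `data.frame` of class `acn_model_comparison`, one row per
#'   system, ordered by `cox_aic`: columns `system`, `n`, `n_event`,
#'   `cox_aic`, `logistic_aic`, `logistic_auc`, `log_rank_p`, `rank`.
#' @export
compare_scores <- function(panel,
                           systems = c("wc", "mwc", "ara", "pra"),
                           event = c("dod", "awd_or_dod"),
                           logistic_outcome = c("awd_or_dod", "dod"),
                           complete_cases = TRUE) {
  event <- match.arg(event)
  logistic_outcome <- match.arg(logistic_outcome)
  systems <- match.arg(systems, several.ok = TRUE)
  cols <- .system_columns[systems]
  missing_cols <- setdiff(cols, names(panel))
  if (length(missing_cols)) {
    stop("panel lacks class columns: ",
         paste(missing_cols, collapse = ", "),
         "; run score_panel() first", call. = FALSE)
  }
  base_ok <- !is.na(panel$outcome) & !is.na(panel$followup_months) &
    panel$followup_months > 0
  evaluable <- vapply(cols, function(cl) !is.na(panel[[cl]]),
                      logical(nrow(panel)))
  evaluable <- matrix(evaluable, nrow = nrow(panel))
  common <- base_ok & rowSums(evaluable) == length(cols)
  rows <- lapply(seq_along(systems), function(i) {
    keep <- if (complete_cases) common else base_ok & evaluable[, i]
    d <- panel[keep, , drop = FALSE]
    if (nrow(d) == 0L) return(NULL)
    cl <- droplevels(factor(d[[cols[i]]]))
    if (nlevels(cl) < 2L) return(NULL)
    ev <- if (event == "dod") d$outcome == "DOD" else d$outcome %in% c("AWD", "DOD")
    lo <- if (logistic_outcome == "dod") d$outcome == "DOD" else d$outcome %in% c("AWD", "DOD")
    cox <- cox_fit(d$followup_months, ev, cl)
    lgt <- logistic_fit(lo, cl)
    lr <- log_rank_test(d$followup_months, ev, cl)
    data.frame(system = systems[i], n = nrow(d), n_event = sum(ev),
               cox_aic = cox$aic, logistic_aic = lgt$aic,
               logistic_auc = lgt$auc, log_rank_p = lr$p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    stop("insufficient data: no system is evaluable on a common subset",
         call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$cox_aic), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("acn_model_comparison", "data.frame")
  out
}
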