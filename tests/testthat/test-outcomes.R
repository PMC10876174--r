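# Survival and logistic machinery against closed forms and
# brute-force risk-set oracles.

test_that("Kaplan-Meier handles the closed-form cases", {
  all_cens <- km_estimate(c(3, 7, 12), c(FALSE, FALSE, FALSE))
  expect_true(all(all_cens$survival == 1))
  steps <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(steps$survival, c(2 / 3, 1 / 3, 0))
  expect_error(km_estimate(numeric(0), logical(0)), "insufficient")
  expect_error(km_estimate(c(0, 1), c(TRUE, TRUE)), "positive")
})

test_that("Kaplan-Meier equals the product over explicit risk sets", {
  set.seed(41)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    time <- sample(1:6, n, replace = TRUE)  # force ties
    event <- runif(n) < 0.7
    if (!any(event)) event[1] <- TRUE
    fit <- km_estimate(time, event)
    ora <- oracle_km(time, event)
    got <- fit$survival[fit$n_event > 0]
    expect_equal(got, ora$surv, tolerance = 1e-12)
  }
})

test_that("log-rank is zero for interleaved label copies and matches a hand example", {
  time <- rep(c(2, 5, 9, 14), 2)
  event <- rep(c(TRUE, TRUE, FALSE, TRUE), 2)
  g <- rep(c("a", "b"), each = 4)
  expect_lt(log_rank_test(time, event, g)$chisq, 1e-12)
  # four observations, all events, groups a = {1, 2}, b = {3, 4}
  hand <- log_rank_test(c(1, 2, 3, 4), rep(TRUE, 4),
                        c("a", "a", "b", "b"))
  expect_equal(hand$chisq,
               oracle_logrank(c(1, 2, 3, 4), rep(TRUE, 4),
                              c("a", "a", "b", "b")),
               tolerance = 1e-10)
  expect_identical(hand$df, 1L)
})

test_that("log-rank equals the brute-force statistic on random instances", {
  set.seed(43)
  done <- 0
  while (done < 30) {
    n <- sample(4:12, 1)
    k <- sample(2:3, 1)
    time <- sample(1:8, n, replace = TRUE)
    event <- runif(n) < 0.7
    g <- sample(letters[1:k], n, replace = TRUE)
    if (length(unique(g)) < k || !any(event)) next
    # every group must be represented among observations
    fit <- log_rank_test(time, event, g)
    expect_equal(fit$chisq, oracle_logrank(time, event, g),
                 tolerance = 1e-10)
    expect_equal(fit$p,
                 pchisq(fit$chisq, k - 1, lower.tail = FALSE))
    done <- done + 1
  }
  expect_error(log_rank_test(c(1, 2), c(FALSE, FALSE), c("a", "b")),
               "undefined test")
  expect_error(log_rank_test(c(1, 2), c(TRUE, TRUE), c("a", "a")),
               "at least 2 groups")
})

test_that("Cox fit maximizes the Breslow partial likelihood", {
  set.seed(47)
  for (i in 1:25) {
    n <- sample(6:12, 1)
    time <- sample(1:8, n, replace = TRUE)
    event <- runif(n) < 0.7
    x <- rbinom(n, 1, 0.5)
    if (!any(event) || length(unique(x)) < 2) next
    fit <- try(cox_fit(time, event, x), silent = TRUE)
    if (inherits(fit, "try-error") || !fit$converged) next
    beta <- unname(fit$coefficients)
    # reported log partial likelihood equals the brute-force value
    expect_equal(fit$loglik, oracle_cox_logpl(beta, time, event, x),
                 tolerance = 1e-10)
    expect_equal(fit$loglik_null,
                 oracle_cox_logpl(0, time, event, x),
                 tolerance = 1e-10)
    # and beta maximizes it (grid-search oracle)
    grid <- seq(beta - 2, beta + 2, length.out = 801)
    ll <- vapply(grid, oracle_cox_logpl, 0, time = time,
                 event = event, x = x)
    expect_lt(abs(grid[which.max(ll)] - beta), 0.01)
    expect_equal(fit$aic, 2 * 1 - 2 * fit$loglik)
  }
})

test_that("Cox separation is flagged, not raised", {
  # events only in one covariate arm, ordered: monotone likelihood
  time <- c(1, 2, 3, 10, 11, 12)
  event <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  x <- c(1, 1, 1, 0, 0, 0)
  fit <- cox_fit(time, event, x)
  expect_false(fit$converged)
  expect_error(cox_fit(time, event, rep(1, 6)), "constant")
})

test_that("logistic fit reports midrank AUC with its closed forms", {
  out <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  perfect <- logistic_fit(out, ifelse(out, "pos", "neg"))
  expect_equal(perfect$auc, 1)
  flat <- logistic_fit(out, rep(1, 6))
  expect_equal(flat$auc, 0.5)
  # binary predictor: AUC = (sensitivity + specificity) / 2
  set.seed(53)
  for (i in 1:20) {
    n <- 40
    o <- runif(n) < 0.4
    x <- ifelse(runif(n) < ifelse(o, 0.7, 0.3), "hit", "miss")
    if (length(unique(o)) < 2 || length(unique(x)) < 2) next
    fit <- logistic_fit(o, x)
    sens <- mean(x[o] == "hit"); spec <- mean(x[!o] == "miss")
    # the fitted probabilities follow the empirical association
    # direction, so the two-valued closed form is the larger of the
    # two orientations
    s <- (sens + spec) / 2
    expect_equal(fit$auc, max(s, 1 - s), tolerance = 1e-12)
    expect_equal(fit$auc, oracle_auc(fit$coefficients[1] +
                                       ifelse(x == "miss",
                                              fit$coefficients[2], 0), o),
                 tolerance = 1e-12)
  }
  expect_error(logistic_fit(rep(TRUE, 5), 1:5), "constant")
})

test_that("AUC is invariant to strictly increasing transforms", {
  set.seed(59)
  score <- runif(30)
  out <- runif(30) < plogis(3 * score - 1.5)
  if (length(unique(out)) == 2) {
    a1 <- oracle_auc(score, out)
    expect_equal(oracle_auc(exp(5 * score), out), a1)
    expect_equal(oracle_auc(rank(score), out), a1)
  }
})

test_that("an outcome-matched system wins the model comparison", {
  set.seed(61)
  n <- 80
  risk <- rep(c("benign", "malignant"), each = n / 2)
  time <- round(rexp(n, ifelse(risk == "malignant", 0.08, 0.005)), 1)
  time <- pmax(time, 0.5)
  dead <- time < 36
  panel <- data.frame(
    case_id = sprintf("c%02d", 1:n),
    outcome = ifelse(dead, "DOD", "CR"),
    followup_months = pmin(time, 36),
    ara_class = risk,                                  # informative
    pra_class = sample(risk),                          # shuffled: noise
    stringsAsFactors = FALSE)
  cmp <- compare_scores(panel, systems = c("ara", "pra"))
  expect_identical(cmp$system[1], "ara")
  expect_lt(cmp$cox_aic[1], cmp$cox_aic[2])
  expect_lt(cmp$logistic_aic[1], cmp$logistic_aic[2])
})

test_that("a single-system comparison is allowed and trivially ranked", {
  set.seed(67)
  n <- 40
  cl <- sample(c("benign", "malignant"), n, TRUE)
  panel <- data.frame(case_id = as.character(1:n),
                      outcome = sample(c("CR", "DOD"), n, TRUE,
                                       prob = c(0.7, 0.3)),
                      followup_months = round(runif(n, 1, 60), 1),
                      pra_class = cl, stringsAsFactors = FALSE)
  cmp <- compare_scores(panel, systems = "pra")
  expect_identical(nrow(cmp), 1L)
  expect_identical(cmp$rank, 1L)
})
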