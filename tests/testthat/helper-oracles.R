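# Independent brute-force oracles and random-instance generators used
# across the suite. The oracles share no code with the implementation:
# everything is computed by direct summation over cells / risk sets.

# --- agreement oracles ------------------------------------------------

oracle_kappa <- function(m) {
  n <- sum(m)
  po <- 0
  for (i in seq_len(nrow(m))) po <- po + m[i, i]
  po <- po / n
  pe <- 0
  for (i in seq_len(nrow(m))) {
    ri <- sum(m[i, ]); ci <- sum(m[, i])
    pe <- pe + (ri / n) * (ci / n)
  }
  (po - pe) / (1 - pe)
}

oracle_chisq <- function(m) {
  n <- sum(m)
  chi <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      e <- sum(m[i, ]) * sum(m[, j]) / n
      chi <- chi + (m[i, j] - e)^2 / e
    }
  }
  chi
}

oracle_cramer_v <- function(m) {
  sqrt(oracle_chisq(m) / (sum(m) * (min(dim(m)) - 1)))
}

# Random r x c count table with positive marginals.
random_table <- function(r, c, lambda = 8) {
  repeat {
    m <- matrix(rpois(r * c, lambda), r, c)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# --- survival oracles -------------------------------------------------

# Product-limit estimate by explicit risk-set bookkeeping; returns the
# survival value after each distinct event time.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event]))
  s <- 1
  out <- numeric(length(ts))
  for (k in seq_along(ts)) {
    n_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event)
    s <- s * (1 - d / n_risk)
    out[k] <- s
  }
  list(time = ts, surv = out)
}

# Multi-group log-rank chi-square via the full hypergeometric
# variance-covariance, inverting over the first g-1 groups.
oracle_logrank <- function(time, event, group) {
  g <- factor(group)
  lv <- levels(g)
  ts <- sort(unique(time[event]))
  O <- E <- rep(0, length(lv))
  V <- matrix(0, length(lv), length(lv))
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(time == t & event)
    for (a in seq_along(lv)) {
      na <- sum(at_risk & g == lv[a])
      O[a] <- O[a] + sum(time == t & event & g == lv[a])
      E[a] <- E[a] + d * na / n
      for (b in seq_along(lv)) {
        nb <- sum(at_risk & g == lv[b])
        if (n > 1) {
          V[a, b] <- V[a, b] +
            d * (n - d) / (n - 1) * (na / n) * ((a == b) - nb / n)
        }
      }
    }
  }
  k <- length(lv) - 1
  u <- (O - E)[seq_len(k)]
  drop(t(u) %*% solve(V[seq_len(k), seq_len(k), drop = FALSE]) %*% u)
}

# Breslow partial log-likelihood for a single numeric covariate.
oracle_cox_logpl <- function(beta, time, event, x) {
  lp <- beta * x
  ll <- 0
  for (t in sort(unique(time[event]))) {
    dead <- time == t & event
    risk <- time >= t
    ll <- ll + sum(lp[dead]) - sum(dead) * log(sum(exp(lp[risk])))
  }
  ll
}

# Midrank AUC by direct pairwise comparison.
oracle_auc <- function(score, outcome) {
  pos <- score[outcome]; neg <- score[!outcome]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# --- random case records ---------------------------------------------

# A random, structurally valid case; every optional field is missing
# with probability miss. Continuous values carry at most one decimal
# so the CSV round trip is exact.
random_case <- function(id, miss = 0.3) {
  mb <- function(x) if (runif(1) < miss) NA else x
  tri <- function() mb(runif(1) < 0.5)
  outcome <- mb(sample(c("CR", "AWD", "DOD"), 1))
  acn_case(
    case_id = id,
    age_months = mb(sample(1:216, 1)),
    sex = mb(sample(c("M", "F"), 1)),
    laterality = mb(sample(c("left", "right"), 1)),
    stage = mb(sample(c("I", "II", "III", "IV"), 1)),
    weight_g = mb(round(exp(runif(1, 2, 8)), 1)),
    size_cm = mb(round(runif(1, 0.5, 25), 1)),
    mitoses_50hpf = mb(rpois(1, 8)),
    mitoses_20hpf = mb(rpois(1, 4)),
    atypical_mitoses = tri(), necrosis = tri(),
    vascular_invasion = tri(), capsular_invasion = tri(),
    extra_adrenal_extension = tri(), vena_cava_invasion = tri(),
    ki67_percent = mb(round(runif(1, 0, 60), 1)),
    reticulin = mb(sample(c("intact", "quantitative", "qualitative",
                            "both"), 1)),
    outcome = outcome,
    followup_months = if (is.na(outcome)) NA else round(runif(1, 1, 120), 1)
  )
}

random_cohort <- function(n, miss = 0.3) {
  as_cohort(do.call(rbind, lapply(seq_len(n), function(i)
    random_case(sprintf("R%03d", i), miss))))
}

# A fully specified case with every binary feature set explicitly;
# used for exhaustive classification checks.
full_case <- function(id = "X", nec = FALSE, vasc = FALSE,
                      atyp = FALSE, caps = FALSE, extra = FALSE,
                      cava = FALSE, m50 = 2, m20 = 1,
                      weight = 50, size = 5, ki67 = 5,
                      reticulin = "intact") {
  acn_case(id, age_months = 60, sex = "F", laterality = "left",
           stage = "I", weight_g = weight, size_cm = size,
           mitoses_50hpf = m50, mitoses_20hpf = m20,
           atypical_mitoses = atyp, necrosis = nec,
           vascular_invasion = vasc, capsular_invasion = caps,
           extra_adrenal_extension = extra, vena_cava_invasion = cava,
           ki67_percent = ki67, reticulin = reticulin,
           outcome = "CR", followup_months = 24)
}
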