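# The four classification rules: worked examples, partial
# missingness, and the structural invariants of the rule family.

test_that("the Wieneke score counts satisfied criteria", {
  expect_identical(wieneke_score(full_case()), 0L)
  five <- full_case(nec = TRUE, atyp = TRUE, vasc = TRUE, caps = TRUE,
                    m20 = 20, m50 = 45)
  expect_identical(wieneke_score(five), 5L)
  maximal <- full_case(nec = TRUE, atyp = TRUE, vasc = TRUE,
                       caps = TRUE, extra = TRUE, cava = TRUE,
                       m20 = 20, m50 = 45, weight = 3750, size = 25)
  expect_identical(wieneke_score(maximal), 9L)
})

test_that("Wieneke scoring agrees with an independent criterion count", {
  set.seed(11)
  for (i in 1:50) {
    co <- random_case("w", miss = 0)
    # brute-force: enumerate the nine criteria independently
    expected <- sum(co$weight_g > 400, co$size_cm > 10.5,
                    co$extra_adrenal_extension, co$vena_cava_invasion,
                    co$vascular_invasion, co$capsular_invasion,
                    co$necrosis, co$mitoses_20hpf > 15,
                    co$atypical_mitoses)
    expect_identical(wieneke_score(co), as.integer(expected))
    expect_identical(wieneke_classify_cases(co),
                     c("benign", "indeterminate",
                       "malignant")[1 + (expected >= 3) + (expected > 3)])
  }
})

test_that("Wieneke class thresholds are <3 / =3 / >3", {
  expect_identical(wieneke_classify(c(0L, 2L, 3L, 4L, 9L)),
                   c("benign", "benign", "indeterminate", "malignant",
                     "malignant"))
  expect_error(wieneke_classify(10L), "domain error")
  expect_error(wieneke_classify(-1L), "domain error")
})

test_that("a decidable Wieneke class survives missing items", {
  four_true <- acn_case("p", necrosis = TRUE, atypical_mitoses = TRUE,
                        vascular_invasion = TRUE,
                        capsular_invasion = TRUE)
  expect_identical(wieneke_score(four_true), NA_integer_)
  expect_identical(wieneke_classify_cases(four_true), "malignant")
  all_false <- full_case()
  all_false$weight_g <- NA  # 0 known true, 1 unknown: still benign
  expect_identical(wieneke_classify_cases(all_false), "benign")
  two_true <- acn_case("q", necrosis = TRUE, vascular_invasion = TRUE)
  expect_identical(wieneke_classify_cases(two_true), NA_character_)
})

test_that("the five-item microscopic score requires all items", {
  expect_identical(mwc_microscopic_score(full_case()), 0L)
  expect_identical(
    mwc_microscopic_score(full_case(nec = TRUE, vasc = TRUE)), 2L)
  expect_identical(
    mwc_microscopic_score(full_case(nec = TRUE, vasc = TRUE,
                                    atyp = TRUE, caps = TRUE,
                                    m20 = 20, m50 = 45)), 5L)
  one_missing <- full_case(nec = TRUE)
  one_missing$capsular_invasion <- NA
  expect_identical(mwc_microscopic_score(one_missing), NA_integer_)
})

test_that("the two-step modified-Wieneke rule resolves the middle band by Ki67", {
  expect_identical(mwc_classify(full_case()), "favorable")
  expect_identical(
    mwc_classify(full_case(nec = TRUE, vasc = TRUE, atyp = TRUE,
                           caps = TRUE, m20 = 20, m50 = 45)),
    "unfavorable")
  expect_identical(
    mwc_classify(full_case(nec = TRUE, vasc = TRUE, ki67 = 20)),
    "unfavorable")
  expect_identical(
    mwc_classify(full_case(nec = TRUE, vasc = TRUE, ki67 = 14.9)),
    "favorable")
  in_band_no_ki67 <- full_case(nec = TRUE, vasc = TRUE)
  in_band_no_ki67$ki67_percent <- NA
  expect_identical(mwc_classify(in_band_no_ki67), NA_character_)
  # Ki67 irrelevant outside the band
  expect_identical(mwc_classify(full_case(ki67 = 90)), "favorable")
})

test_that("reticulin algorithm follows the two-step rule under both cutoffs", {
  # intact framework dominates everything
  intact <- full_case(nec = TRUE, m20 = 40, m50 = 90,
                      reticulin = "intact")
  expect_identical(ra_classify(intact, "adult"), "benign")
  expect_identical(ra_classify(intact, "pediatric"), "benign")
  # any alteration + necrosis is malignant under both variants
  quant <- full_case(nec = TRUE, reticulin = "quantitative")
  expect_identical(ra_classify(quant, "adult"), "malignant")
  expect_identical(ra_classify(quant, "pediatric"), "malignant")
  # the two cutoffs diverge between 5/50 and 15/20
  qual <- full_case(m50 = 10, m20 = 4, reticulin = "qualitative")
  expect_identical(ra_classify(qual, "adult"), "malignant")
  expect_identical(ra_classify(qual, "pediatric"), "benign")
  # altered but criterion-free stays benign
  low <- full_case(m50 = 2, m20 = 1, reticulin = "quantitative")
  expect_identical(ra_classify(low, "adult"), "benign")
})

test_that("reticulin algorithm resolves decidable partial cases", {
  # intact: benign even with criteria unassessed
  x <- acn_case("i", reticulin = "intact")
  expect_identical(ra_classify(x, "adult"), "benign")
  # altered + necrosis known true: malignant despite missing mitoses
  y <- acn_case("y", reticulin = "both", necrosis = TRUE,
                vascular_invasion = NA)
  expect_identical(ra_classify(y, "pediatric"), "malignant")
  # all criteria known false: benign even without the reticulin stain
  z <- full_case()
  z$reticulin <- NA
  expect_identical(ra_classify(z, "adult"), "benign")
  # genuinely undecidable: altered, criteria unassessed
  w <- acn_case("w", reticulin = "quantitative")
  expect_identical(ra_classify(w, "adult"), NA_character_)
})

test_that("mitotic rescaling is refused unless explicitly enabled", {
  x <- full_case(nec = FALSE, reticulin = "qualitative")
  x$mitoses_50hpf <- NA
  x$mitoses_20hpf <- 20L   # 50 per 50 HPF if rescaled
  expect_identical(ra_classify(x, "adult"), NA_character_)
  rules <- default_rules()
  rules$allow_mitotic_rescale <- TRUE
  expect_warning(cl <- ra_classify(x, "adult", rules), "rescaling")
  expect_identical(cl, "malignant")
})

test_that("an intact framework is benign for every feature combination", {
  grid <- expand.grid(nec = c(FALSE, TRUE), vasc = c(FALSE, TRUE),
                      atyp = c(FALSE, TRUE), caps = c(FALSE, TRUE),
                      extra = c(FALSE, TRUE), cava = c(FALSE, TRUE))
  for (m in list(c(2, 1), c(45, 20))) {
    for (i in seq_len(nrow(grid))) {
      case <- full_case(nec = grid$nec[i], vasc = grid$vasc[i],
                        atyp = grid$atyp[i], caps = grid$caps[i],
                        extra = grid$extra[i], cava = grid$cava[i],
                        m50 = m[1], m20 = m[2], reticulin = "intact")
      expect_identical(ra_classify(case, "adult"), "benign")
      expect_identical(ra_classify(case, "pediatric"), "benign")
    }
  }
})

test_that("raising the mitotic count never moves a class toward benign", {
  rank_wc <- function(x) match(x, c("benign", "indeterminate", "malignant"))
  rank_ra <- function(x) match(x, c("benign", "malignant"))
  rank_mwc <- function(x) match(x, c("favorable", "unfavorable"))
  set.seed(23)
  for (i in 1:40) {
    lo <- random_case("m", miss = 0)
    hi <- lo
    hi$mitoses_50hpf <- lo$mitoses_50hpf + sample(1:60, 1)
    hi$mitoses_20hpf <- lo$mitoses_20hpf + sample(1:30, 1)
    expect_gte(wieneke_score(hi), wieneke_score(lo))
    expect_gte(rank_wc(wieneke_classify_cases(hi)),
               rank_wc(wieneke_classify_cases(lo)))
    expect_gte(rank_mwc(mwc_classify(hi)), rank_mwc(mwc_classify(lo)))
    for (v in c("adult", "pediatric")) {
      expect_gte(rank_ra(ra_classify(hi, v)), rank_ra(ra_classify(lo, v)))
    }
  }
})

test_that("the panel evaluates each sub-score exactly when its inputs allow", {
  neg <- full_case()
  p <- score_panel(neg)
  expect_identical(p$wc_score, 0L)
  expect_identical(p$wc_class, "benign")
  expect_identical(p$mwc_class, "favorable")
  expect_identical(p$ara_class, "benign")
  expect_identical(p$pra_class, "benign")
  partial <- acn_case("r", reticulin = "quantitative", necrosis = TRUE,
                      vascular_invasion = FALSE, mitoses_50hpf = 8,
                      mitoses_20hpf = 3)
  pp <- score_panel(partial)
  expect_identical(pp$ara_class, "malignant")
  expect_identical(pp$pra_class, "malignant")
  expect_identical(pp$wc_score, NA_integer_)
  expect_identical(pp$mwc_score, NA_integer_)
})

test_that("pediatric-malignant implies adult-malignant on coherent cases", {
  co <- generate_cohort(default_paper_spec(n = 2000, seed = 31))
  p <- score_panel(co)
  both <- !is.na(p$ara_class) & !is.na(p$pra_class)
  expect_gt(sum(both & p$pra_class == "malignant"), 0)
  expect_false(any(p$pra_class[both] == "malignant" &
                     p$ara_class[both] == "benign"))
})

test_that("rules survive the config-file round trip and drive the scores", {
  rules <- default_rules()
  rules$wc$weight_g <- 200
  path <- withr::local_tempfile(fileext = ".cfg")
  write_rules(rules, path)
  back <- read_rules(path)
  expect_equal(back, rules)
  case <- full_case(weight = 300)
  expect_identical(wieneke_score(case), 0L)
  expect_identical(wieneke_score(case, back), 1L)
  shipped <- read_rules(system.file("extdata", "default_rules.cfg",
                                    package = "acnscore"))
  expect_equal(shipped, default_rules())
})
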