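# Concordance statistics between classification systems.

#' Round half away from zero
#'
#' Fixed-precision rounding in which ties go away from zero
#' (2.5 -> 3, -2.5 -> -3), the convention used when comparing computed
#' statistics against values printed at fixed decimals. Base R's
#' `round()` rounds ties to even and would turn 62.5% into 62%.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cross-tabulate two classification vectors
#'
#' Builds an r x c contingency table from paired class labels. Pairs
#' in which either label is missing are dropped and counted.
#'
#' @param a,b Equal-length vectors of class labels (character or
#'   factor); `NA` allowed.
#' @param row_labels,col_labels Optional orderings of the row (`a`)
#'   and column (`b`) labels; defaults to the sorted observed labels.
#' @return An object of class `acn_contingency`: list with elements
#'   `counts` (integer matrix with dimnames), `n` (total count) and
#'   `dropped` (number of incomplete pairs).
#' @export
contingency_table <- function(a, b, row_labels = NULL,
                              col_labels = NULL) {
  if (length(a) != length(b)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  keep <- !is.na(a) & !is.na(b)
  dropped <- sum(!keep)
  a <- as.character(a[keep]); b <- as.character(b[keep])
  if (length(a) < 2L) {
    stop("insufficient data: fewer than 2 complete label pairs",
         call. = FALSE)
  }
  if (is.null(row_labels)) row_labels <- sort(unique(a))
  if (is.null(col_labels)) col_labels <- sort(unique(b))
  counts <- table(factor(a, levels = row_labels),
                  factor(b, levels = col_labels))
  counts <- matrix(as.integer(counts), nrow = length(row_labels),
                   dimnames = list(row_labels, col_labels))
  new_contingency(counts, dropped = dropped)
}

#' Construct a contingency table from a count matrix
#'
#' @param counts Non-negative integer matrix, ideally with dimnames.
#' @param dropped Number of incomplete pairs excluded while building
#'   the table.
#' @return An `acn_contingency` object.
#' @export
new_contingency <- function(counts, dropped = 0L) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(list(counts = counts, n = sum(counts),
                 dropped = as.integer(dropped)),
            class = "acn_contingency")
}

#' @export
print.acn_contingency <- function(x, ...) {
  print(x$counts)
  cat("n =", x$n)
  if (x$dropped > 0) cat(" (", x$dropped, "incomplete pairs dropped )")
  cat("\n")
  invisible(x)
}

.as_counts <- function(table) {
  if (inherits(table, "acn_contingency")) table$counts else as.matrix(table)
}

#' Cohen's kappa with asymptotic confidence interval
#'
#' Chance-corrected agreement between two classifiers over the same
#' cases: `kappa = (po - pe) / (1 - pe)` with `po` the observed and
#' `pe` the chance agreement proportion. The standard error uses the
#' simple large-sample formula `sqrt(po (1 - po)) / ((1 - pe)
#' sqrt(n))` and the 95% interval is `kappa +/- 1.96 se` (truncated to
#' \[-1, 1\]). This simpler variance (rather than the full
#' Fleiss-Cohen-Everitt expression) is the package's convention for
#' published-value comparison.
#'
#' @param table Square `acn_contingency` (or count matrix) with the
#'   same label set on both axes.
#' @return List of class `acn_kappa`: `kappa`, `se`, `ci_low`,
#'   `ci_high`, `po`, `pe`, `n`, `band` (verbal agreement band).
#' @examples
#' cohen_kappa(matrix(c(25, 0, 4, 30), nrow = 2))
#' @export
cohen_kappa <- function(table) {
  m <- .as_counts(table)
  if (nrow(m) != ncol(m)) {
    stop("shape error: kappa requires a square table", call. = FALSE)
  }
  if (!is.null(rownames(m)) && !is.null(colnames(m))) {
    if (!setequal(rownames(m), colnames(m))) {
      stop("shape error: kappa requires the same label set on both axes",
           call. = FALSE)
    }
    m <- m[, rownames(m), drop = FALSE]  # align column order to rows
  }
  n <- sum(m)
  if (n == 0) stop("insufficient data: empty table", call. = FALSE)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (pe >= 1) {
    stop("degenerate table: chance agreement is 1", call. = FALSE)
  }
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po)) / ((1 - pe) * sqrt(n))
  structure(list(kappa = kappa, se = se,
                 ci_low = max(-1, kappa - 1.96 * se),
                 ci_high = min(1, kappa + 1.96 * se),
                 po = po, pe = pe, n = n,
                 band = interpret_kappa(max(-1, min(1, kappa)))),
            class = "acn_kappa")
}

#' @export
print.acn_kappa <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (95%% CI %.3f-%.3f), %s; n = %d\n",
              x$kappa, x$ci_low, x$ci_high, x$band, x$n))
  invisible(x)
}

#' Cramer's V
#'
#' Association strength for a nominal r x c table:
#' `V = sqrt(chi^2 / (n * min(r - 1, c - 1)))` with the plain
#' (uncorrected) Pearson chi-square statistic -- no Yates continuity
#' correction and no bias correction, which is the convention under
#' which the published concordance values are reproduced. Ordinal
#' classifications (such as the three-level Wieneke class) are treated
#' as nominal.
#'
#' @param table `acn_contingency` or count matrix, at least 2 x 2.
#' @return Scalar in \[0, 1\].
#' @examples
#' cramer_v(matrix(c(23, 1, 1, 8, 8, 18), nrow = 3))
#' @export
cramer_v <- function(table) {
  m <- .as_counts(table)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("shape error: V requires at least a 2 x 2 table",
         call. = FALSE)
  }
  n <- sum(m)
  if (n == 0) stop("insufficient data: empty table", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: zero row or column marginal",
         call. = FALSE)
  }
  chi2 <- suppressWarnings(
    stats::chisq.test(m, correct = FALSE)$statistic)
  as.numeric(sqrt(chi2 / (n * (min(dim(m)) - 1))))
}

#' Reconstruct a nested 2x2 joint table from its marginals
#'
#' When classifier `strict` can only call malignant where classifier
#' `lenient` also does (a nesting guaranteed, e.g., by a stricter
#' mitotic cutoff with all other criteria shared), the joint 2x2 table
#' of the two classifiers is fully determined by their marginal
#' benign/malignant counts: the (strict-malignant, lenient-benign)
#' cell is zero and the remaining cells are forced.
#'
#' @param lenient Named or ordered length-2 vector
#'   `(benign, malignant)` of the less strict classifier's marginals.
#' @param strict Same for the stricter classifier; must have
#'   `strict["malignant"] <= lenient["malignant"]` and the same total.
#' @param labels Length-2 class labels, default
#'   `c("benign", "malignant")`.
#' @return `acn_contingency` with rows = strict classes, columns =
#'   lenient classes.
#' @examples
#' # published marginals over 59 cases: aRA 25/34, pRA 29/30
#' reconstruct_nested_2x2(lenient = c(25, 34), strict = c(29, 30))
#' @export
reconstruct_nested_2x2 <- function(lenient, strict,
                                   labels = c("benign", "malignant")) {
  lenient <- as.numeric(lenient); strict <- as.numeric(strict)
  stopifnot(length(lenient) == 2L, length(strict) == 2L)
  if (sum(lenient) != sum(strict)) {
    stop("marginals disagree on the total count", call. = FALSE)
  }
  if (strict[2] > lenient[2]) {
    stop("infeasible: the strict classifier calls more malignant (",
         strict[2], ") than the lenient one (", lenient[2], ")",
         call. = FALSE)
  }
  counts <- matrix(c(lenient[1], lenient[2] - strict[2],
                     0,          strict[2]),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(strict = labels, lenient = labels))
  new_contingency(counts)
}

#' Verbal interpretation bands
#'
#' Maps a kappa or Cramer's V value to the verbal band used when
#' reporting agreement strength. Kappa bands (value rounded to 2
#' decimals first): 0-0.20 no agreement, 0.21-0.39 minimal, 0.40-0.59
#' weak, 0.60-0.79 moderate, 0.80-0.90 strong, 0.91-1.00 almost
#' perfect; negative values count as no agreement. V bands: below 0.3
#' weak, 0.3 to below 0.6 good, 0.6-1 strong association.
#'
#' @param kappa,v Scalar statistic value.
#' @return Character band label.
#' @export
interpret_kappa <- function(kappa) {
  if (!is.finite(kappa) || kappa < -1 || kappa > 1) {
    stop("domain error: kappa must lie in [-1, 1]", call. = FALSE)
  }
  k <- round_half_away(kappa, 2)
  if (k <= 0.20) "no agreement"
  else if (k <= 0.39) "minimal agreement"
  else if (k <= 0.59) "weak agreement"
  else if (k <= 0.79) "moderate agreement"
  else if (k <= 0.90) "strong agreement"
  else "almost perfect agreement"
}

#' @rdname interpret_kappa
#' @export
interpret_cramer_v <- function(v) {
  if (!is.finite(v) || v < 0 || v > 1) {
    stop("domain error: V must lie in [0, 1]", call. = FALSE)
  }
  if (v < 0.3) "weak association"
  else if (v < 0.6) "good association"
  else "strong association"
}
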