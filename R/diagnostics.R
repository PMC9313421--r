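#' Cross-tabulate predictions against truth
#'
#' @param predictions,truths equal-length character vectors over
#'   `c("malignant", "benign")` (`"malignant"` is the positive class).
#' @return Object of class `confusion_matrix`: list with counts `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
confusion_matrix <- function(predictions, truths) {
  if (length(predictions) != length(truths))
    stop("'predictions' and 'truths' differ in length")
  ok <- c("malignant", "benign")
  if (any(!predictions %in% ok) || any(!truths %in% ok))
    stop("labels must be 'malignant' or 'benign'")
  new_confusion(tp = sum(predictions == "malignant" & truths == "malignant"),
                fn = sum(predictions == "benign" & truths == "malignant"),
                fp = sum(predictions == "malignant" & truths == "benign"),
                tn = sum(predictions == "benign" & truths == "benign"))
}

new_confusion <- function(tp, fn, fp, tn) {
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn)),
            class = "confusion_matrix")
}

#' Reconstruct a confusion matrix from printed sensitivity and specificity
#'
#' Published diagnostic tables report SEN/SPEC as percentages at known class
#' sizes; because `tp = SEN * n_pos / 100` and `tn = SPEC * n_neg / 100` are
#' integers, the full matrix is recoverable by rounding (half away from
#' zero). A warning is raised when a printed rate is inconsistent with every
#' integer count (more than 0.05 points from the recovered one).
#'
#' @param sen_pct,spec_pct printed sensitivity and specificity, percent.
#' @param n_pos,n_neg class sizes (positives = malignant).
#' @return A `confusion_matrix`.
#' @examples
#' confusion_from_rates(83.3, 50.0, 30, 64)  # tp 25, fn 5, fp 32, tn 32
#' @export
confusion_from_rates <- function(sen_pct, spec_pct, n_pos, n_neg) {
  check_fraction(sen_pct, "sen_pct", 0, 100)
  check_fraction(spec_pct, "spec_pct", 0, 100)
  if (n_pos <= 0 || n_neg <= 0) stop("class sizes must be positive")
  tp <- round_half_out(sen_pct * n_pos / 100)
  tn <- round_half_out(spec_pct * n_neg / 100)
  if (abs(sen_pct - 100 * tp / n_pos) > 0.05)
    warning(sprintf("printed sensitivity %.1f inconsistent with tp=%d/%d (%.2f)",
                    sen_pct, tp, n_pos, 100 * tp / n_pos))
  if (abs(spec_pct - 100 * tn / n_neg) > 0.05)
    warning(sprintf("printed specificity %.1f inconsistent with tn=%d/%d (%.2f)",
                    spec_pct, tn, n_neg, 100 * tn / n_neg))
  new_confusion(tp = tp, fn = n_pos - tp, fp = n_neg - tn, tn = tn)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (positive = malignant)\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("malignant", "benign"),
                              truth = c("malignant", "benign")))
  print(m)
  invisible(x)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Computed from beta quantiles: the lower bound is the `alpha/2` quantile of
#' `Beta(x, n - x + 1)` (0 when `x = 0`) and the upper the `1 - alpha/2`
#' quantile of `Beta(x + 1, n - x)` (100 when `x = n`).
#'
#' @param successes,n counts, `0 <= successes <= n`, `n > 0`.
#' @param level confidence level in (0, 1), default 0.95.
#' @return Numeric `c(lower, upper)` in percent.
#' @examples
#' clopper_pearson(25, 30)  # c(65.3, 94.4) at 1 dp
#' @export
clopper_pearson <- function(successes, n, level = 0.95) {
  if (n <= 0 || successes < 0 || successes > n)
    stop("need 0 <= successes <= n with n > 0")
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  a <- 1 - level
  lo <- if (successes == 0) 0 else stats::qbeta(a / 2, successes, n - successes + 1)
  hi <- if (successes == n) 1 else stats::qbeta(1 - a / 2, successes + 1, n - successes)
  c(lower = 100 * lo, upper = 100 * hi)
}

# Hanley-McNeil standard error of an AUC estimate.
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Diagnostic performance of a binary classifier
#'
#' Computes SEN, SPEC, PPV, NPV, the false-negative and false-positive rates
#' (complements of SEN and SPEC), and the single-operating-point AUROC
#' `(SEN + SPEC) / 200` — the trapezoidal area under the two-segment ROC
#' polygon of a binary (single-threshold) test. Binomial quantities get exact
#' Clopper-Pearson intervals; the AUROC interval is normal-based with the
#' Hanley-McNeil standard error.
#'
#' @param cm a [confusion_matrix()].
#' @param ci_level confidence level, default 0.95.
#' @return Object of class `performance_report`: list of point estimates (in
#'   percent; AUROC as a fraction), CI pairs, and class sizes. PPV/NPV are
#'   `NA` when their denominator is zero.
#' @examples
#' performance(confusion_from_rates(83.3, 50.0, 30, 64))
#' @export
performance <- function(cm, ci_level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n_pos <- cm$tp + cm$fn
  n_neg <- cm$fp + cm$tn
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to evaluate performance")
  sen <- 100 * cm$tp / n_pos
  spec <- 100 * cm$tn / n_neg
  ppv <- if (cm$tp + cm$fp > 0) 100 * cm$tp / (cm$tp + cm$fp) else NA_real_
  npv <- if (cm$tn + cm$fn > 0) 100 * cm$tn / (cm$tn + cm$fn) else NA_real_
  auroc <- (sen / 100 + spec / 100) / 2
  se <- hanley_mcneil_se(auroc, n_pos, n_neg)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  rep <- list(
    sen = sen, sen_ci = clopper_pearson(cm$tp, n_pos, ci_level),
    spec = spec, spec_ci = clopper_pearson(cm$tn, n_neg, ci_level),
    ppv = ppv,
    ppv_ci = if (is.na(ppv)) c(lower = NA_real_, upper = NA_real_) else
      clopper_pearson(cm$tp, cm$tp + cm$fp, ci_level),
    npv = npv,
    npv_ci = if (is.na(npv)) c(lower = NA_real_, upper = NA_real_) else
      clopper_pearson(cm$tn, cm$tn + cm$fn, ci_level),
    fnr = 100 - sen, fpr = 100 - spec,
    auroc = auroc,
    auroc_ci = c(lower = max(0, auroc - z * se), upper = min(1, auroc + z * se)),
    n_pos = n_pos, n_neg = n_neg, ci_level = ci_level,
    cm = cm
  )
  structure(rep, class = "performance_report")
}

#' @export
print.performance_report <- function(x, digits = 1, ...) {
  fmt <- function(v, ci, d = digits) {
    if (is.na(v)) return("   (undefined)")
    sprintf("%5.*f (%.*f; %.*f)", d, round_half_out(v, d),
            d, round_half_out(ci[1], d), d, round_half_out(ci[2], d))
  }
  cat(sprintf("Diagnostic performance (n = %d malignant + %d benign, %.0f%% CI)\n",
              x$n_pos, x$n_neg, 100 * x$ci_level))
  cat("  SEN (%)  ", fmt(x$sen, x$sen_ci), "\n", sep = "")
  cat("  SPEC (%) ", fmt(x$spec, x$spec_ci), "\n", sep = "")
  cat("  PPV (%)  ", fmt(x$ppv, x$ppv_ci), "\n", sep = "")
  cat("  NPV (%)  ", fmt(x$npv, x$npv_ci), "\n", sep = "")
  cat(sprintf("  AUROC     %.2f (%.2f; %.2f)\n", round_half_out(x$auroc, 2),
              round_half_out(x$auroc_ci[1], 2), round_half_out(x$auroc_ci[2], 2)))
  invisible(x)
}

#' Summarise a performance report as a one-row data frame
#'
#' Values are rounded as in the printed tables: percents to 1 decimal, AUROC
#' to 2 decimals, half away from zero.
#'
#' @param object a `performance_report`.
#' @param ... unused.
#' @export
summary.performance_report <- function(object, ...) {
  data.frame(
    sen = round_half_out(object$sen, 1), spec = round_half_out(object$spec, 1),
    ppv = round_half_out(object$ppv, 1), npv = round_half_out(object$npv, 1),
    fnr = round_half_out(object$fnr, 1), fpr = round_half_out(object$fpr, 1),
    auroc = round_half_out(object$auroc, 2),
    n_pos = object$n_pos, n_neg = object$n_neg
  )
}

new_test_result <- function(statistic, df, p_value, method, note = NULL) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method, note = note),
            class = "vasc_test")
}

#' @export
print.vasc_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4g%s, p = %.4g\n", x$statistic,
              if (is.null(x$df) || is.na(x$df)) "" else sprintf(" (df = %g)", x$df),
              x$p_value))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' McNemar test for paired binary classifiers
#'
#' Compares two classifiers on the same subjects through the discordant-pair
#' counts `b` (first positive only) and `c` (second positive only). The exact
#' form uses the two-sided binomial tail `p = min(1, 2 P(X <= min(b, c)))`
#' with `X ~ Binomial(b + c, 1/2)`; the `chi2_cc` form is the
#' continuity-corrected chi-square `(|b - c| - 1)^2 / (b + c)` on 1 df,
#' dropping the correction under exact symmetry (`b = c`, statistic 0) as
#' [stats::mcnemar.test()] does. With no discordant pairs the test is
#' degenerate and `p = 1` is returned with a note.
#'
#' @param b_discordant,c_discordant discordant-pair counts.
#' @param method `"exact"` (default, suits small discordant counts) or
#'   `"chi2_cc"`.
#' @return A test-result object with `statistic`, `df`, `p_value`.
#' @export
mcnemar_test <- function(b_discordant, c_discordant,
                         method = c("exact", "chi2_cc")) {
  method <- match.arg(method)
  b <- b_discordant; cc <- c_discordant
  if (b < 0 || cc < 0) stop("discordant counts must be non-negative")
  if (b + cc == 0)
    return(new_test_result(NA_real_, NA_real_, 1,
                           "McNemar exact test", "no discordant pairs"))
  if (method == "exact") {
    p <- min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
    new_test_result(min(b, cc), NA_real_, p, "McNemar exact test")
  } else {
    # no correction under exact symmetry (b = c), matching stats::mcnemar.test
    stat <- if (b == cc) 0 else (abs(b - cc) - 1)^2 / (b + cc)
    new_test_result(stat, 1, stats::pchisq(stat, 1, lower.tail = FALSE),
                    "McNemar chi-squared test with continuity correction")
  }
}

# discordant counts of two logical vectors on the same subjects
discordant_counts <- function(a, b) {
  c(b = sum(a & !b), c = sum(!a & b))
}

#' Cochran's Q test for k correlated binary outcomes
#'
#' Tests equality of marginal proportions of `k >= 2` binary treatments
#' measured on the same subjects. `Q = (k - 1) (k * sum(C_j^2) - N^2) /
#' (k * N - sum(R_i^2))` with column totals `C_j`, row totals `R_i` and grand
#' total `N`, referred to chi-square on `k - 1` df. Rows with all-equal
#' outcomes contribute nothing; if every row is concordant `Q = 0` and
#' `p = 1`. For `k = 2`, Q equals the McNemar chi-square without continuity
#' correction.
#'
#' @param indicator_matrix subjects x k matrix of 0/1 (or logical) outcomes.
#' @return A test-result object.
#' @export
cochran_q <- function(indicator_matrix) {
  m <- as.matrix(indicator_matrix) * 1
  if (ncol(m) < 2L) stop("Cochran's Q needs at least two outcomes (k >= 2)")
  if (any(!m %in% c(0, 1))) stop("entries must be binary")
  k <- ncol(m)
  cj <- colSums(m)
  ri <- rowSums(m)
  n <- sum(m)
  denom <- k * n - sum(ri^2)
  if (denom == 0)
    return(new_test_result(0, k - 1, 1, "Cochran's Q test",
                           "all subjects concordant across outcomes"))
  q <- (k - 1) * (k * sum(cj^2) - n^2) / denom
  new_test_result(q, k - 1, stats::pchisq(q, k - 1, lower.tail = FALSE),
                  "Cochran's Q test")
}

#' z-test comparing two single-operating-point AUROCs
#'
#' Unpaired comparison `z = (A1 - A2) / sqrt(SE1^2 + SE2^2)` with
#' Hanley-McNeil standard errors, two-sided normal p-value. An AUROC of 1 has
#' a zero Hanley-McNeil SE; two unequal AUROCs with zero pooled SE are an
#' error, equal ones give `z = 0, p = 1`.
#'
#' @param auroc1,auroc2 AUROC estimates (fractions). Values below 0.5 warn.
#' @param n_pos1,n_neg1,n_pos2,n_neg2 class sizes behind each estimate.
#' @return A test-result object.
#' @export
auroc_z_test <- function(auroc1, n_pos1, n_neg1, auroc2, n_pos2, n_neg2) {
  check_fraction(c(auroc1, auroc2), "auroc", 0, 1)
  if (auroc1 < 0.5 || auroc2 < 0.5)
    warning("AUROC below 0.5: the Hanley-McNeil variance model assumes >= 0.5")
  if (min(n_pos1, n_neg1, n_pos2, n_neg2) <= 0) stop("class sizes must be positive")
  se <- sqrt(hanley_mcneil_se(auroc1, n_pos1, n_neg1)^2 +
               hanley_mcneil_se(auroc2, n_pos2, n_neg2)^2)
  if (se == 0) {
    if (auroc1 == auroc2)
      return(new_test_result(0, NA_real_, 1, "Unpaired z-test of two AUROCs"))
    stop("zero pooled standard error with unequal AUROCs")
  }
  z <- (auroc1 - auroc2) / se
  new_test_result(z, NA_real_, 2 * stats::pnorm(-abs(z)),
                  "Unpaired z-test of two AUROCs (Hanley-McNeil SE)")
}

#' Cohen's kappa and proportion agreement for two ratings
#'
#' Unweighted kappa `(p_o - p_e) / (1 - p_e)` with the observed agreement
#' `p_o` and the chance agreement `p_e` from the rating marginals; used for
#' intra-rater reliability of repeated qualitative vascularity grading.
#'
#' @param ratings_a,ratings_b equal-length vectors of ratings.
#' @param categories category levels; defaults to the union of observed
#'   values.
#' @return List with `kappa` (NA with a note when `p_e = 1`, i.e. both raters
#'   constant and equal), `agreement` (`p_o`), and `n`.
#' @export
cohens_kappa <- function(ratings_a, ratings_b,
                         categories = sort(unique(c(ratings_a, ratings_b)))) {
  if (length(ratings_a) != length(ratings_b)) stop("ratings differ in length")
  if (length(ratings_a) == 0L) stop("no ratings")
  bad <- !c(ratings_a, ratings_b) %in% categories
  if (any(bad)) stop("rating outside the stated categories")
  a <- factor(ratings_a, levels = categories)
  b <- factor(ratings_b, levels = categories)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1)
    return(list(kappa = NA_real_, agreement = p_o, n = n,
                note = "both raters constant and equal; kappa undefined"))
  list(kappa = (p_o - p_e) / (1 - p_e), agreement = p_o, n = n)
}

#' Paired-samples t-test
#'
#' Two-sided paired t-test of the mean difference `x - y` (first minus
#' second), as used to compare mean regional VIs between paired Doppler
#' modes. Identical vectors give `t = 0, p = 1`; constant nonzero differences
#' are degenerate and raise an error.
#'
#' @param x,y equal-length numeric vectors, `n >= 2`.
#' @return A test-result object.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' differ in length")
  if (length(x) < 2L) stop("need at least two pairs")
  d <- x - y
  tol <- 1e-10 * max(abs(d), 1)
  if (stats::sd(d) <= tol) {
    if (all(abs(d) <= tol))
      return(new_test_result(0, length(x) - 1, 1, "Paired t-test",
                             "all differences zero"))
    stop("differences are constant and nonzero: zero variance")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  new_test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
                  "Paired t-test")
}

#' Pearson chi-square tests for classification proportions
#'
#' `proportion_chi_square(table)` runs the Pearson chi-square test (no
#' continuity correction) on a contingency table, e.g. nodule classification
#' counts by truth. `proportion_chi_square_1s(k, n, p0)` is the one-sample
#' variant testing an observed proportion `k/n` against `p0` (default 0.5),
#' used for "RVI > 1 within benign nodules".
#'
#' @param counts contingency table (matrix) of non-negative counts.
#' @return A test-result object.
#' @export
proportion_chi_square <- function(counts) {
  m <- as.matrix(counts)
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero marginal in the contingency table")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  new_test_result(unname(ct$statistic), unname(ct$parameter), ct$p.value,
                  "Pearson chi-squared test")
}

#' @rdname proportion_chi_square
#' @param k,n successes and trials for the one-sample variant.
#' @param p0 null proportion, default 0.5.
#' @export
proportion_chi_square_1s <- function(k, n, p0 = 0.5) {
  if (k < 0 || n <= 0 || k > n) stop("need 0 <= k <= n with n > 0")
  check_fraction(p0, "p0", 0, 1)
  if (p0 == 0 || p0 == 1) stop("zero marginal: p0 must be in (0, 1)")
  ct <- suppressWarnings(
    stats::chisq.test(c(k, n - k), p = c(p0, 1 - p0), correct = FALSE))
  new_test_result(unname(ct$statistic), unname(ct$parameter), ct$p.value,
                  "One-sample Pearson chi-squared test of a proportion")
}
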