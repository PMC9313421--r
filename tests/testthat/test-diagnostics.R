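test_that("confusion matrices tally predictions against truth", {
  t10 <- c(rep("malignant", 10), rep("benign", 10))
  cm <- confusion_matrix(t10, t10)
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]),
               c(tp = 10L, fn = 0L, fp = 0L, tn = 10L))
  flip <- ifelse(t10 == "malignant", "benign", "malignant")
  cm2 <- confusion_matrix(flip, t10)
  expect_equal(cm2$tp + cm2$tn, 0L)
  expect_error(confusion_matrix("positive", "malignant"), "labels")
  # random draws match a hand tally
  set.seed(9)
  truth <- sample(c("malignant", "benign"), 200, TRUE)
  pred <- sample(c("malignant", "benign"), 200, TRUE)
  cm3 <- confusion_matrix(pred, truth)
  tab <- table(pred, truth)
  expect_equal(cm3$tp, unname(tab["malignant", "malignant"]))
  expect_equal(cm3$tn, unname(tab["benign", "benign"]))
})

test_that("confusion matrices reconstruct from printed rates with a consistency warning", {
  cm <- confusion_from_rates(83.3, 50.0, 30, 64)
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]),
               c(tp = 25L, fn = 5L, fp = 32L, tn = 32L))
  expect_equal(unlist(confusion_from_rates(100, 100, 9, 31)[c("tp", "tn")]),
               c(tp = 9L, tn = 31L))
  expect_equal(unlist(confusion_from_rates(66.7, 73.4, 30, 64)[c("tp", "tn")]),
               c(tp = 20L, tn = 47L))
  expect_warning(confusion_from_rates(58.1, 73.4, 30, 64), "inconsistent")
})

test_that("performance derives predictive values and single-point AUROC from the matrix", {
  p <- performance(make_cm(25, 5, 32, 32))
  expect_equal(round_1(p$ppv), 43.9)
  expect_equal(round_1(p$npv), 86.5)
  expect_equal(round_2(p$auroc), 0.67)
  p2 <- performance(make_cm(23, 7, 10, 54))
  expect_equal(round_1(p2$ppv), 69.7)
  expect_equal(round_1(p2$npv), 88.5)
  expect_equal(round_2(p2$auroc), 0.81)
  expect_error(performance(confusion_matrix(rep("malignant", 5),
                                            rep("malignant", 5))),
               "both classes")
})

test_that("report identities hold: fnr, fpr and auroc are determined by sen and spec", {
  set.seed(4)
  for (i in 1:25) {
    tp <- sample(0:30, 1); fn <- 30 - tp
    tn <- sample(0:64, 1); fp <- 64 - tn
    p <- performance(confusion_from_rates(100 * tp / 30, 100 * tn / 64, 30, 64))
    expect_equal(p$fnr, 100 - p$sen)
    expect_equal(p$fpr, 100 - p$spec)
    expect_equal(p$auroc, (p$sen + p$spec) / 200)
    expect_true(p$sen_ci[1] <= p$sen && p$sen <= p$sen_ci[2])
    expect_true(p$auroc_ci[1] <= p$auroc && p$auroc <= p$auroc_ci[2])
  }
  perfect <- performance(confusion_matrix(
    c(rep("malignant", 4), rep("benign", 6)),
    c(rep("malignant", 4), rep("benign", 6))))
  expect_equal(c(perfect$sen, perfect$spec, perfect$ppv, perfect$npv),
               c(100, 100, 100, 100))
  expect_equal(perfect$auroc, 1)
})

test_that("Clopper-Pearson intervals are exact beta-quantile bounds", {
  expect_equal(round_1(clopper_pearson(25, 30)), c(lower = 65.3, upper = 94.4))
  expect_equal(round_1(clopper_pearson(8, 9)), c(lower = 51.8, upper = 99.7))
  expect_equal(clopper_pearson(0, 20)[["lower"]], 0)
  expect_equal(clopper_pearson(20, 20)[["upper"]], 100)
  expect_error(clopper_pearson(5, 4), "successes")
  expect_error(clopper_pearson(1, 4, 1.2), "level")
})

test_that("Clopper-Pearson 95% coverage is at least nominal-conservative at n=30, p=0.8", {
  set.seed(2024)
  x <- rbinom(2000, 30, 0.8)
  lo <- ifelse(x == 0, 0, qbeta(0.025, x, 30 - x + 1))
  hi <- ifelse(x == 30, 1, qbeta(0.975, x + 1, 30 - x))
  # recompute through the package and compare to direct quantiles
  ours <- t(vapply(x, function(k) clopper_pearson(k, 30), numeric(2))) / 100
  expect_equal(ours[, 1], lo)
  expect_equal(ours[, 2], hi)
  coverage <- mean(ours[, 1] <= 0.8 & 0.8 <= ours[, 2])
  expect_gte(coverage, 0.93)
})

test_that("exact McNemar equals brute-force binomial enumeration for all b+c <= 20", {
  for (n in 0:20) for (b in 0:n) {
    cc <- n - b
    expect_equal(mcnemar_test(b, cc)$p_value, oracle_mcnemar_exact(b, cc),
                 info = sprintf("b=%d c=%d", b, cc))
  }
  expect_equal(mcnemar_test(5, 5)$p_value, 1)
  expect_equal(mcnemar_test(10, 2)$p_value, 2 * pbinom(2, 12, 0.5))
  deg <- mcnemar_test(0, 0)
  expect_equal(deg$p_value, 1)
  expect_match(deg$note, "no discordant")
})

test_that("continuity-corrected McNemar matches stats::mcnemar.test", {
  for (bc in list(c(10, 2), c(7, 7), c(1, 12))) {
    m <- matrix(c(20, bc[1], bc[2], 20), 2, 2)
    ours <- mcnemar_test(bc[1], bc[2], method = "chi2_cc")
    ref <- mcnemar.test(m)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value)
  }
})

test_that("Cochran Q matches its defining formula and known degenerate forms", {
  set.seed(31)
  m <- matrix(rbinom(18, 1, 0.5), 6, 3)
  q <- cochran_q(m)
  expect_equal(q$statistic, oracle_cochran_q(m))
  expect_equal(q$df, 2)
  same <- matrix(rep(c(1, 0, 1, 1, 0, 1), 3), 6, 3)
  expect_equal(cochran_q(same)$statistic, 0)
  expect_equal(cochran_q(same)$p_value, 1)
  # k = 2 reduces to the McNemar chi-square without continuity correction
  m2 <- matrix(rbinom(40, 1, 0.5), 20, 2)
  b <- sum(m2[, 1] & !m2[, 2]); cc <- sum(!m2[, 1] & m2[, 2])
  expect_equal(cochran_q(m2)$statistic, (b - cc)^2 / (b + cc))
  expect_error(cochran_q(m[, 1, drop = FALSE]), "k >= 2")
})

test_that("AUROC z-test uses Hanley-McNeil standard errors", {
  eq <- auroc_z_test(0.75, 30, 64, 0.75, 30, 64)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  z <- auroc_z_test(0.81, 30, 64, 0.67, 30, 64)
  se <- sqrt(oracle_hm_var(0.81, 30, 64) + oracle_hm_var(0.67, 30, 64))
  expect_equal(z$statistic, (0.81 - 0.67) / se)
  expect_equal(z$p_value, 2 * pnorm(-abs(z$statistic)))
  # an AUROC of 1 has zero Hanley-McNeil SE
  expect_error(auroc_z_test(1, 30, 64, 0.99999999, 9, 31), NA)
  expect_equal(auroc_z_test(1, 30, 64, 1, 9, 31)$p_value, 1)
  expect_warning(auroc_z_test(0.4, 10, 10, 0.8, 10, 10), "0.5")
})

test_that("Cohen's kappa and proportion agreement match the defining formula", {
  grades <- c("I", "II", "III", "IV")
  a <- rep(grades, times = c(10, 12, 9, 9))
  expect_equal(cohens_kappa(a, a, grades)$kappa, 1)
  expect_equal(cohens_kappa(a, a, grades)$agreement, 1)
  set.seed(8)
  b <- sample(a)
  k <- cohens_kappa(a, b, grades)
  tab <- table(factor(a, grades), factor(b, grades))
  po <- sum(diag(tab)) / 40
  pe <- sum(rowSums(tab) * colSums(tab)) / 40^2
  expect_equal(k$kappa, (po - pe) / (1 - pe))
  expect_equal(k$agreement, po)
  if (requireNamespace("e1071", quietly = TRUE)) {
    ref <- e1071::classAgreement(tab)
    expect_equal(k$kappa, ref$kappa)
    expect_equal(k$agreement, ref$diag)
  }
  const <- cohens_kappa(rep("I", 5), rep("I", 5), grades)
  expect_true(is.na(const$kappa))
  expect_equal(const$agreement, 1)
  expect_error(cohens_kappa(c("I", "V"), c("I", "II"), grades), "categories")
})

test_that("paired t-test matches the closed form and keeps the first-minus-second sign", {
  x <- c(3.1, 4.5, 2.2, 5.0, 3.3)
  y <- c(2.0, 4.9, 1.1, 4.0, 2.5)
  tt <- paired_t_test(x, y)
  d <- x - y
  expect_equal(tt$statistic, mean(d) / (sd(d) / sqrt(5)))
  expect_equal(tt$df, 4)
  same <- paired_t_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(paired_t_test(x, x + 2), "zero variance")
  # lower first-member VIs give a negative t, the convention of paired
  # mode comparisons (conventional mode minus its microvascular counterpart)
  set.seed(93)
  conventional <- pmin(pmax(rnorm(94, 45, 16), 0), 100)
  angio <- pmin(pmax(conventional + 10 + rnorm(94, 0, 10), 0), 100)
  t94 <- paired_t_test(conventional, angio)
  expect_lt(t94$statistic, -4)
  expect_equal(t94$df, 93)
  expect_lt(t94$p_value, 0.001)
})

test_that("chi-square tests follow the Pearson formula for tables and one-sample proportions", {
  even <- matrix(c(10, 10, 20, 20), 2, 2)
  expect_equal(proportion_chi_square(even)$statistic, 0)
  expect_equal(proportion_chi_square(even)$p_value, 1)
  m <- matrix(c(18, 12, 6, 24), 2, 2)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(proportion_chi_square(m)$statistic,
               sum((m - expected)^2 / expected))
  expect_error(proportion_chi_square(matrix(c(0, 0, 3, 4), 2, 2)), "marginal")
  # all RVI > 1 against p0 = 0.5 gives statistic n
  expect_equal(proportion_chi_square_1s(31, 31)$statistic, 31)
  expect_lt(proportion_chi_square_1s(25, 31)$p_value, 0.01)
})
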