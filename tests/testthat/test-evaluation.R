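test_that("AUROC equals the pairwise Mann-Whitney statistic", {
  set.seed(41)
  for (rep in 1:200) {
    n <- sample(6:20, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    ev <- roc_pr(scores, labels)
    expect_equal(ev$auroc, oracle_auroc_mw(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUROC/AUPRC behave at the extremes", {
  labels <- rep(c(1, 0), each = 20)
  perfect <- c(rnorm(20, 10), rnorm(20, -10))
  ev <- roc_pr(perfect, labels)
  expect_equal(ev$auroc, 1.0)
  expect_equal(ev$auprc, 1.0)

  set.seed(42)
  null_scores <- rnorm(20000)
  null_labels <- rep(0:1, 10000)
  expect_equal(roc_pr(null_scores, null_labels)$auroc, 0.5, tolerance = 0.02)

  expect_error(roc_pr(rnorm(5), rep(1, 5)), "both classes")
  expect_error(roc_pr(c(1, NA, 3), c(0, 1, 1)), "finite")
})

test_that("ROC curve spans (0,0) to (1,1) with monotone FPR", {
  set.seed(43)
  ev <- roc_pr(rnorm(100), sample(0:1, 100, replace = TRUE))
  expect_equal(ev$roc$fpr[1], 0)
  expect_equal(ev$roc$tpr[1], 0)
  expect_equal(ev$roc$fpr[nrow(ev$roc)], 1)
  expect_equal(ev$roc$tpr[nrow(ev$roc)], 1)
  expect_true(all(diff(ev$roc$fpr) >= 0))
  expect_true(all(diff(ev$roc$tpr) >= 0))
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(44)
  scores <- rnorm(200)
  labels <- as.integer(runif(200) < plogis(scores))
  labels[1:2] <- 0:1
  a0 <- roc_pr(scores, labels)$auroc
  for (f in list(function(x) 3 * x + 2, function(x) exp(x), plogis)) {
    expect_equal(roc_pr(f(scores), labels)$auroc, a0, tolerance = 1e-12)
  }
})

test_that("AUROC agrees with pROC on random instances", {
  skip_if_not_installed("pROC")
  set.seed(45)
  for (rep in 1:10) {
    scores <- rnorm(80)
    labels <- c(0, 1, sample(0:1, 78, replace = TRUE))
    want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<",
                                           levels = c(0, 1))))
    expect_equal(roc_pr(scores, labels)$auroc, want, tolerance = 1e-12)
  }
})

test_that("matched-specificity operating point equals a brute-force scan", {
  # hand-listed 10-point instance
  scores <- c(0.9, 0.8, 0.75, 0.6, 0.55, 0.5, 0.4, 0.3, 0.2, 0.1)
  labels <- c(1, 1, 0, 1, 0, 0, 1, 0, 0, 0)
  for (target in c(0.5, 2 / 3, 0.8, 0.99)) {
    got <- sensitivity_at_specificity(scores, labels, target)
    want <- oracle_operating_point(scores, labels, target)
    expect_equal(got[c("sensitivity", "specificity", "ppv", "npv")],
                 want[c("sensitivity", "specificity", "ppv", "npv")])
  }
  set.seed(46)
  for (rep in 1:50) {
    scores <- round(runif(30), 2)
    labels <- c(0, 1, sample(0:1, 28, replace = TRUE))
    target <- runif(1, 0.3, 0.95)
    got <- sensitivity_at_specificity(scores, labels, target)
    want <- oracle_operating_point(scores, labels, target)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_gte(got$specificity, target)
  }
})

test_that("matched-specificity behaves on degenerate and ordered cases", {
  labels <- c(rep(1, 5), rep(0, 20))
  scores <- as.numeric(labels)
  op <- sensitivity_at_specificity(scores, labels, 0.866)
  expect_equal(op$sensitivity, 1.0)
  expect_equal(op$specificity, 1.0)

  # lower target specificity can only raise sensitivity
  set.seed(47)
  labels <- sample(0:1, 200, replace = TRUE)
  scores <- rnorm(200) + 0.8 * labels
  lo <- sensitivity_at_specificity(scores, labels, 0.647)
  hi <- sensitivity_at_specificity(scores, labels, 0.866)
  expect_gte(lo$sensitivity, hi$sensitivity)

  expect_error(sensitivity_at_specificity(scores, labels, 1.2), "in \\(0, 1\\)")
  # all scores tied: no threshold reaches a high specificity
  expect_error(sensitivity_at_specificity(rep(0.5, 10), rep(0:1, 5), 0.9),
               "unattainable")
})

test_that("DeLong variance matches the structural-components oracle", {
  set.seed(48)
  labels <- c(rep(1, 5), rep(0, 7))   # n = 12 paired instance
  a <- rnorm(12)
  b <- 0.5 * a + rnorm(12, sd = 0.5)
  got <- delong_test(a, b, labels)
  ca <- oracle_delong_components(a, labels)
  cb <- oracle_delong_components(b, labels)
  expect_equal(got$auc_a, ca$auc, tolerance = 1e-12)
  expect_equal(got$auc_b, cb$auc, tolerance = 1e-12)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  want_var <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / 5 +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / 7
  expect_equal(got$var_diff, want_var, tolerance = 1e-12)
})

test_that("DeLong test is symmetric and degenerate on self-comparison", {
  set.seed(49)
  labels <- sample(0:1, 60, replace = TRUE)
  labels[1:2] <- 0:1
  a <- rnorm(60); b <- rnorm(60)
  self <- delong_test(a, a, labels)
  expect_equal(self$z, 0)
  expect_equal(self$p_value, 1)
  ab <- delong_test(a, b, labels)
  ba <- delong_test(b, a, labels)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_error(delong_test(a, b, rep(1, 60)), "both classes")
})

test_that("DeLong p-value agrees with pROC and with a paired bootstrap", {
  skip_if_not_installed("pROC")
  set.seed(50)
  labels <- c(rep(1, 40), rep(0, 160))
  base <- rnorm(200)
  a <- base + 0.9 * labels
  b <- 0.8 * base + rnorm(200, sd = 0.6) + 0.5 * labels
  got <- delong_test(a, b, labels)
  ra <- pROC::roc(labels, a, quiet = TRUE)
  rb <- pROC::roc(labels, b, quiet = TRUE)
  want <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(got$p_value, as.numeric(want$p.value), tolerance = 1e-9)

  # paired bootstrap of the AUC difference
  nboot <- 2000
  diffs <- numeric(nboot)
  for (i in seq_len(nboot)) {
    idx <- sample(200, replace = TRUE)
    if (length(unique(labels[idx])) < 2) { diffs[i] <- NA; next }
    diffs[i] <- roc_pr(a[idx], labels[idx])$auroc -
      roc_pr(b[idx], labels[idx])$auroc
  }
  boot_se <- stats::sd(diffs, na.rm = TRUE)
  boot_z <- (got$auc_a - got$auc_b) / boot_se
  boot_p <- 2 * stats::pnorm(-abs(boot_z))
  expect_equal(got$p_value, boot_p, tolerance = 0.02)
})

test_that("interpretation phrases follow the two labeling criteria", {
  expect_true(categorize_interpretation("ACUTE MI", 1))
  expect_true(categorize_interpretation("Possible inferior infarct, age undetermined", 1))
  expect_true(categorize_interpretation("marked ST elevation", 1))
  expect_false(categorize_interpretation("ST depression", 1))
  expect_true(categorize_interpretation("ST depression", 2))
  expect_true(categorize_interpretation("Nonspecific T wave abnormality", 2))
  expect_false(categorize_interpretation("Normal sinus rhythm", 1))
  expect_false(categorize_interpretation("Normal sinus rhythm", 2))
  expect_false(categorize_interpretation("", 1))
  expect_false(categorize_interpretation("", 2))
  expect_false(categorize_interpretation(NA_character_, 2))
  # case-insensitive, whitespace-normalized
  expect_true(categorize_interpretation("acute  mi suspected", 1))
  expect_true(categorize_interpretation("ST  ELEVATION", 1))
  expect_error(categorize_interpretation("x", 3), "criterion")
})

test_that("criterion-2 positives are a superset of criterion-1 positives", {
  corpus <- utils::read.csv(
    system.file("extdata", "interpretations_synthetic.csv",
                package = "asyncecg"),
    stringsAsFactors = FALSE
  )
  c1 <- categorize_interpretation(corpus$text, 1)
  c2 <- categorize_interpretation(corpus$text, 2)
  expect_true(all(c2[c1]))           # c1 positives all positive under c2
  expect_gt(sum(c2), sum(c1))        # and the corpus exercises the gap
  expect_identical(c1, corpus$criterion1 == 1)
  expect_identical(c2, corpus$criterion2 == 1)
})
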