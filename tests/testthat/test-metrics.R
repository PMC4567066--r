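test_that("sensitivity, specificity and agreement match hand counts", {
  ref <- c("walk", "walk", "sit", "sit")
  pred <- c("walk", "sit", "sit", "sit")
  expect_equal(sensitivity(ref, pred, "walk"), 50)
  expect_equal(specificity(ref, pred, "walk"), 100)
  expect_equal(overall_agreement(ref, pred), 75)

  expect_equal(sensitivity(ref, ref, "walk"), 100)
  expect_equal(specificity(ref, ref, "walk"), 100)
  expect_equal(overall_agreement(ref, ref), 100)

  expect_equal(specificity(ref, rep("walk", 4), "walk"), 0)
  expect_equal(overall_agreement(c("a", "b"), c("b", "a")), 0)
})

test_that("undefined metrics are not-applicable, never zero", {
  ref <- rep("sitting", 5)
  expect_true(is.na(sensitivity(ref, ref, "lying")))
  expect_true(is.na(specificity(ref, ref, "sitting")))
  expect_error(sensitivity(ref, rep("sitting", 4), "sitting"), "length")
})

test_that("agreement is symmetric and metrics match the confusion oracle", {
  set.seed(31)
  cats <- c("sitting", "standing", "walking", "lying")
  for (rep in 1:50) {
    n <- sample(20:80, 1)
    ref <- sample(cats, n, replace = TRUE)
    pred <- sample(cats, n, replace = TRUE)
    expect_equal(overall_agreement(ref, pred), overall_agreement(pred, ref))
    # independent oracle: full confusion matrix
    cm <- table(factor(ref, cats), factor(pred, cats))
    for (cat in cats[1:2]) {
      tp <- cm[cat, cat]
      fn <- sum(cm[cat, ]) - tp
      tn <- sum(cm[-match(cat, cats), -match(cat, cats)])
      fp <- sum(cm[, cat]) - tp
      if (tp + fn > 0) expect_equal(sensitivity(ref, pred, cat),
                                    100 * tp / (tp + fn))
      if (tn + fp > 0) expect_equal(specificity(ref, pred, cat),
                                    100 * tn / (tn + fp))
    }
    expect_equal(overall_agreement(ref, pred), 100 * sum(diag(cm)) / n)
  }
})

test_that("ToL metrics reduce both series with the shared membership rule", {
  ref <- c("standing", "walking", "sitting", "sitting")
  pred <- c("standing", "sitting", "sitting", "sitting")
  tm <- tol_metrics(ref, pred)
  expect_equal(tm$sensitivity, 50)
  expect_equal(tm$specificity, 100)
  expect_equal(tm$agreement, 75)

  perfect <- tol_metrics(ref, ref)
  expect_equal(unlist(perfect), c(sensitivity = 100, specificity = 100,
                                  agreement = 100))
  inverted <- tol_metrics(c("standing", "sitting"), c("sitting", "standing"))
  expect_equal(unlist(inverted), c(sensitivity = 0, specificity = 0,
                                   agreement = 0))
})

test_that("grades follow the right-closed cut-offs", {
  expect_equal(grade(31.8), "insufficient")
  expect_equal(grade(42.9), "moderate")
  expect_equal(grade(72.1), "good")
  expect_equal(grade(87.7), "excellent")
  expect_equal(grade(c(40, 60, 80)), c("insufficient", "moderate", "good"))
  expect_equal(grade(c(40.0001, 60.0001, 80.0001)),
               c("moderate", "good", "excellent"))
  expect_error(grade(101), "parameter error")
  expect_error(grade(-1), "parameter error")
})

test_that("ICC(2,k) matches the ANOVA oracle and its fixed points", {
  # duplicated raters on varying targets: perfect reliability
  m <- cbind(1:6, 1:6)
  expect_equal(icc_2k(m)$value, 1.0)
  expect_true(icc_2k(m)$pass)

  # independent oracle: ANOVA mean squares via aov() on the long layout
  mat <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  long <- data.frame(y = as.vector(mat),
                     target = factor(rep(1:4, 2)),
                     rater = factor(rep(1:2, each = 4)))
  av <- summary(aov(y ~ target + rater, data = long))[[1]]
  msr <- av["target", "Mean Sq"]
  msc <- av["rater", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  expected <- (msr - mse) / (msr + (msc - mse) / 4)
  got <- icc_2k(mat)
  expect_equal(got$value, expected, tolerance = 1e-9)
  expect_equal(c(got$msr, got$msc, got$mse), c(msr, msc, mse),
               tolerance = 1e-9)

  # independent raters: reliability near zero
  set.seed(99)
  noise <- cbind(rnorm(1000), rnorm(1000))
  expect_lt(abs(icc_2k(noise)$value), 0.1)

  expect_error(icc_2k(matrix(1, 4, 2)), "degenerate")
  expect_error(icc_2k(matrix(1:2, 1, 2)), "at least 2")

  # consistency form ignores the rater offset
  off <- cbind(1:6, (1:6) + 3)
  expect_equal(icc_2k(off, type = "consistency")$value, 1.0)
  expect_lt(icc_2k(off, type = "agreement")$value, 1.0)
})

test_that("group comparison handles the degenerate and clear-cut cases", {
  same <- group_compare(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(5)
  g0 <- rnorm(4, 0, 0.01); g1 <- rnorm(4, 1, 0.01)
  expect_lt(group_compare(g0, g1)$p, 0.01)

  expect_true(is.na(group_compare(1, c(1, 2))$t))

  # pooled-variance flag reproduces the classic t-test
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 6)
  expect_equal(group_compare(a, b, var_equal = TRUE)$t,
               unname(t.test(a, b, var.equal = TRUE)$statistic))
})

test_that("validation reports carry all five category rows and grades", {
  run <- standardized_run(12)
  rep1 <- validation_report(run$ref, run$cls$labels)
  expect_s3_class(rep1, "validation_report")
  expect_equal(rep1$table$category,
               c("TOL", "sitting", "standing", "walking", "lying"))
  expect_true(all(rep1$table$sensitivity >= 0 & rep1$table$sensitivity <= 100,
                  na.rm = TRUE))
  expect_true(all(rep1$table$sensitivity_grade[!is.na(rep1$table$sensitivity)]
                  %in% c("insufficient", "moderate", "good", "excellent")))

  # perfect prediction: every defined metric is 100 and graded excellent
  perf <- validation_report(run$ref, run$ref)
  defined <- !is.na(perf$table$sensitivity)
  expect_true(all(perf$table$sensitivity[defined] == 100))
  expect_true(all(perf$table$sensitivity_grade[defined] == "excellent"))
  expect_equal(perf$overall_agreement, 100)
})

test_that("session totals do the study arithmetic", {
  tot <- session_totals(rep(564.25, 20))
  expect_equal(tot$total_seconds, 11285)
  expect_equal(tot$mean_seconds, 564.25)
  expect_equal(round(tot$total_hours, 2), 3.13)
})
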