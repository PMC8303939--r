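test_that("ROC curve matches exhaustive threshold enumeration", {
  scores <- c(0.9, 0.8, 0.7, 0.6)
  labels <- c(TRUE, TRUE, FALSE, TRUE)
  r <- roc_curve(scores, labels)
  want <- oracle_roc_points(scores, labels)
  expect_equal(r$points$fpr, want$fpr)
  expect_equal(r$points$tpr, want$tpr)
  expect_equal(r$points$threshold, want$threshold)
  expect_equal(r$auc, oracle_auc_pairs(scores, labels))
  expect_equal(r$cutoff_opt, oracle_cutoff(r$points))
})

test_that("degenerate curves behave as documented", {
  # perfect separation passes through (0, 1) with AUC 1
  r <- roc_curve(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(any(r$points$fpr == 0 & r$points$tpr == 1))
  expect_equal(r$auc, 1)
  d <- sqrt(r$points$fpr^2 + (1 - r$points$tpr)^2)
  opt <- r$points[r$points$threshold == r$cutoff_opt, ]
  expect_equal(min(d), 0)
  expect_equal(opt$fpr^2 + (1 - opt$tpr)^2, 0)
  # identical scores collapse to the two corner points (with sentinels)
  r2 <- roc_curve(rep(1, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r2$auc, 0.5)
  expect_true(all(r2$points$fpr == r2$points$tpr))
  # single-class labels are rejected
  expect_error(roc_curve(1:4, rep(TRUE, 4)), "both classes")
})

test_that("trapezoidal AUC equals the Mann-Whitney concordance and
           the cut-off matches brute force on random instances", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(8:25, 1)
    scores <- round(stats::rnorm(n), sample(c(1, 2), 1)) # force some ties
    labels <- stats::runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    orientation <- sample(c("higher_is_positive", "lower_is_positive"), 1)
    r <- roc_curve(scores, labels, orientation)
    expect_equal(r$auc, oracle_auc_pairs(scores, labels, orientation),
                 tolerance = 1e-12)
    opt_d <- min(sqrt(r$points$fpr^2 + (1 - r$points$tpr)^2))
    pts <- r$points[is.finite(r$points$threshold), ]
    s <- if (orientation == "higher_is_positive") 1 else -1
    got <- pts[pts$threshold * s == r$cutoff_opt * s, ]
    expect_equal(sqrt(got$fpr^2 + (1 - got$tpr)^2), opt_d,
                 tolerance = 1e-12)
  }
})

test_that("label inversion maps AUC to its complement", {
  set.seed(5)
  scores <- stats::rnorm(20)
  labels <- stats::runif(20) < 0.4
  a <- roc_curve(scores, labels)$auc
  b <- roc_curve(scores, !labels)$auc
  expect_equal(a + b, 1, tolerance = 1e-12)
  # and flipping the orientation does the same
  c_ <- roc_curve(scores, labels, "lower_is_positive")$auc
  expect_equal(a + c_, 1, tolerance = 1e-12)
})

test_that("agreement with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:5) {
    scores <- stats::rnorm(30)
    labels <- stats::runif(30) < 0.5
    if (!any(labels) || all(labels)) next
    ours <- roc_curve(scores, labels)$auc
    theirs <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, direction = "<",
      quiet = TRUE)))
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("resampling inference separates signal from noise", {
  set.seed(1)
  # perfect separation at n = 20: permutation p below 1%
  scores <- c(stats::rnorm(10, 3), stats::rnorm(10, -3))
  labels <- rep(c(TRUE, FALSE), each = 10)
  inf <- auc_inference(scores, labels, n_boot = 500, n_perm = 2000,
                       seed = 2)
  expect_lt(inf$p_value, 0.01)
  expect_equal(inf$auc, 1)
  # identical scores: CI contains 0.5
  inf2 <- auc_inference(rep(1, 12), rep(c(TRUE, FALSE), 6), n_boot = 200,
                        n_perm = 200, seed = 3)
  expect_lte(inf2$ci_low, 0.5)
  expect_gte(inf2$ci_high, 0.5)
  # tiny classes flag a widened CI
  inf3 <- auc_inference(1:5, c(TRUE, TRUE, FALSE, FALSE, FALSE),
                        n_boot = 50, n_perm = 50, seed = 4)
  expect_true(inf3$widened)
  expect_equal(c(inf3$ci_low, inf3$ci_high), c(0, 1))
})

test_that("permutation p-values are roughly calibrated under the null", {
  set.seed(8)
  rejections <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    scores <- stats::rnorm(20)
    labels <- rep(c(TRUE, FALSE), each = 10)
    p <- auc_inference(scores, labels, n_boot = 0 + 10, n_perm = 199,
                       seed = i)$p_value
    if (p <= 0.05) rejections <- rejections + 1
  }
  rate <- rejections / n_rep
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)
})

test_that("session selection is inclusive and orientation-aware", {
  features <- tibble::tibble(session_id = 1:3,
                             jaccard = c(0.95, 0.91, 0.90),
                             air_volume_ml = c(50, 105.6, 300))
  expect_equal(select_sessions(features, 0.91), c(1L, 2L))
  expect_equal(select_sessions(features, 0), 1:3)
  expect_equal(select_sessions(features, 1.0,
                               feature = "jaccard"), integer(0))
  features2 <- tibble::tibble(session_id = 1:2, jaccard = c(1.0, 0.5))
  expect_equal(select_sessions(features2, 1.0), 1L)
  # air volume selects at or below its cut-off
  expect_equal(select_sessions(features, 105.6, feature = "air_volume_ml"),
               c(1L, 2L))
})

test_that("tidy and glance expose the curve and the summary", {
  r <- roc_curve(c(0.9, 0.8, 0.7, 0.6), c(TRUE, TRUE, FALSE, TRUE),
                 feature_name = "jaccard")
  td <- tidy(r)
  expect_named(td, c("threshold", "fpr", "tpr"))
  gl <- glance(r)
  expect_equal(gl$feature, "jaccard")
  expect_equal(gl$auc, r$auc)
  plt <- ggplot2::autoplot(r)
  expect_s3_class(plt, "ggplot")
})
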