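cohort_fixture <- function(tumor, normal, grade = NULL) {
  n <- length(tumor) + length(normal)
  data.frame(sample = sprintf("s%03d", seq_len(n)),
             group = rep(c("tumor", "normal"), c(length(tumor), length(normal))),
             nams = c(tumor, normal),
             grade = if (is.null(grade)) NA_integer_
                     else c(grade, rep(NA_integer_, length(normal))),
             stringsAsFactors = FALSE)
}

test_that("probe averaging is the arithmetic mean with a concordance rho", {
  tab <- data.frame(sample = c("a", "b"), group = c("tumor", "normal"),
                    probe_a = c(20, 10), probe_b = c(40, 10))
  res <- average_probes(tab)
  expect_equal(res$table$avg_score, c(30, 10))
  same <- average_probes(data.frame(probe_a = 1:5, probe_b = 1:5))
  expect_equal(same$rho, 1)
  expect_equal(same$table$avg_score, as.numeric(1:5))
  expect_error(average_probes(tab, c("probe_a", "probe_z")), "probe_z")
})

test_that("a latent-score probe pair recovers its planted correlation", {
  set.seed(41)
  coh <- simulate_cohort(n_tumor = 4000, n_normal = 400, seed = 41)
  res <- average_probes(coh$table)
  expect_lt(abs(res$rho - 0.7), 0.1)
})

test_that("NAMS normalization anchors endpoints and preserves ranks", {
  expect_equal(nams_normalize(c(10, 20, 30)), c(0, 50, 100))
  set.seed(42)
  x <- rnorm(50, 50, 20)
  for (mode in c("linear", "logistic")) {
    nams <- nams_normalize(x, mode = mode)
    expect_equal(min(nams), 0)
    expect_equal(max(nams), 100)
    expect_equal(order(nams), order(x))    # strictly rank-preserving
  }
  expect_error(nams_normalize(rep(5, 3)), "distinct")
})

test_that("logistic NAMS matches the closed-form squash", {
  x <- c(10, 20, 30, 40, 70)
  k <- 1.5
  l <- plogis((x - mean(x)) / (k * sd(x)))
  expect_equal(nams_normalize(x, "logistic", k = k),
               (l - min(l)) / (max(l) - min(l)) * 100, tolerance = 1e-12)
  # symmetric data put the midpoint at 50
  expect_equal(nams_normalize(c(10, 20, 30), "logistic")[2], 50)
})

test_that("per-dataset normalization is independent across datasets", {
  x <- c(1, 2, 3, 10, 30, 50)
  ds <- rep(c("d1", "d2"), each = 3)
  got <- nams_normalize(x, dataset = ds)
  expect_equal(got, c(nams_normalize(x[1:3]), nams_normalize(x[4:6])))
  expect_equal(got[c(3, 6)], c(100, 100))
})

test_that("hypermethylation calls use a strict margin against the normal mean", {
  normal <- rep(40, 10)
  tab <- cohort_fixture(c(40, 70, 70.01, 9.99, 10, 85), normal,
                        grade = c(1, 1, 2, 2, 3, 3))
  res <- call_methylation(tab, margin = 30)
  expect_equal(res$normal_mean, 40)
  expect_equal(res$calls$call,
               c("neutral", "neutral", "hyper", "hypo", "neutral", "hyper"))
  f <- res$frequencies
  expect_equal(f$hyper_n[f$stratum == "all"], 2)
  expect_equal(f$hyper_n[f$stratum == "grade_2"], 1)
  expect_equal(f$hyper_n[f$stratum == "grade_1"], 0)
  expect_true(all(f$hyper_n + f$hypo_n + f$neutral_n == f$n))
  expect_error(call_methylation(cohort_fixture(1:3, numeric(0))), "normal")
})

test_that("planted hypermethylation frequency is recovered exactly", {
  set.seed(43)
  normal <- rnorm(33, 40, 3)
  n_hyper <- 213
  tumor <- c(mean(normal) + 30 + runif(n_hyper, 0.5, 30),
             mean(normal) + runif(338 - n_hyper, -30, 29.5))
  tab <- cohort_fixture(tumor, normal)
  res <- call_methylation(tab)
  expect_equal(res$frequencies$hyper_n[1], 213)
  expect_equal(res$frequencies$hyper_pct[1], 213 / 338 * 100,
               tolerance = 1e-12)
})

test_that("above-max-normal summarises tumor/normal separation", {
  tab <- cohort_fixture(c(60, 70, 80, 90, 30), c(40, 50))
  res <- above_max_normal(tab)
  expect_equal(res$pct_above_normal_max, 80)
  expect_equal(res$normal_max, 50)
  expect_equal(res$mean_difference, mean(c(60, 70, 80, 90, 30)) - 45)
  expect_error(above_max_normal(cohort_fixture(numeric(0), c(1, 2))), "tumor")
})

test_that("ROC on the small fixture matches exhaustive pair counting", {
  tab <- cohort_fixture(c(70, 80, 90, 55), c(40, 45, 50))
  roc <- roc_discriminate(tab, n_boot = 0)
  expect_equal(roc$auc, auc_paircount(tab$nams, tab$group == "tumor"))
  expect_equal(roc$auc, 1)
  expect_equal(roc$operating$threshold, 52.5)
  expect_equal(roc$operating$sensitivity, 1)
  expect_equal(roc$operating$specificity, 1)
  # sensitivity non-increasing, specificity non-decreasing along thresholds
  expect_true(all(diff(roc$sensitivity) <= 0))
  expect_true(all(diff(roc$specificity) >= 0))
  expect_error(roc_discriminate(cohort_fixture(1:3, numeric(0)), n_boot = 0),
               "non-empty")
})

test_that("trapezoid AUC equals tie-adjusted U/(n1 n2) and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(44)
  for (k in 1:20) {
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    scores <- sample(1:15, n1 + n0, replace = TRUE)   # ties on purpose
    tum <- rep(c(TRUE, FALSE), c(n1, n0))
    roc <- roc_discriminate(scores = scores, is_tumor = tum, n_boot = 0)
    expect_equal(roc$auc, auc_paircount(scores, tum), tolerance = 1e-12)
    proc_auc <- as.numeric(pROC::auc(pROC::roc(tum, as.numeric(scores),
                                               quiet = TRUE,
                                               direction = "<")))
    expect_equal(roc$auc, proc_auc, tolerance = 1e-9)
  }
})

test_that("null and bootstrap behaviour of the ROC are sane", {
  set.seed(45)
  scores <- rnorm(400, 50, 10)
  tum <- rep(c(TRUE, FALSE), 200)
  roc <- roc_discriminate(scores = scores, is_tumor = tum, n_boot = 0)
  expect_lt(abs(roc$auc - 0.5), 0.08)
  coh <- cohort_fixture(c(70, 80, 90, 55), c(40, 45, 50))
  r1 <- roc_discriminate(coh, n_boot = 200, seed = 9)
  r2 <- roc_discriminate(coh, n_boot = 200, seed = 9)
  expect_equal(r1$auc_ci, r2$auc_ci)
  expect_true(r1$auc_ci[1] <= r1$auc && r1$auc <= r1$auc_ci[2] + 1e-12)
})
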