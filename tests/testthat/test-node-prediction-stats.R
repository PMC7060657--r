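test_that("group_compare selects and applies the right two-sample test", {
  # identical groups: rank test on fully tied data gives p = 1
  x <- c(1, 2, 3, 4, 5)
  res <- group_compare(c(x, x), rep(0:1, each = 5), test = "wilcoxon")
  expect_equal(res$p, 1)

  # exact rank-sum p for {1,2,3} vs {4,5,6} by enumerating all 20 labelings
  pool <- 1:6
  splits <- combn(6, 3)
  u_of <- function(idx) sum(rank(pool)[idx]) - 3 * 4 / 2
  u_all <- apply(splits, 2, u_of)
  u_obs <- u_of(1:3)                      # U = 0
  expect_equal(u_obs, 0)
  p_exact <- mean(abs(u_all - 4.5) >= abs(u_obs - 4.5))
  res <- group_compare(pool, c(0, 0, 0, 1, 1, 1), test = "wilcoxon")
  expect_equal(res$p, p_exact)            # 2/20 = 0.1
  expect_equal(res$p, 0.1)

  # large normal samples: auto picks t, p agrees with the closed-form
  # z approximation of the mean difference
  set.seed(61)
  a <- rnorm(200, 0, 1); b <- rnorm(200, 0.25, 1)
  res <- group_compare(c(a, b), rep(0:1, each = 200))
  expect_equal(res$test, "t")
  z <- (mean(a) - mean(b)) / sqrt(var(a) / 200 + var(b) / 200)
  expect_equal(res$p, 2 * pnorm(-abs(z)), tolerance = 2e-2)

  # constant feature in both groups is degenerate, not a p-value
  res <- group_compare(rep(2, 8), rep(0:1, each = 4))
  expect_true(res$degenerate)
  expect_true(is.na(res$p))
  expect_error(group_compare(1:4, rep(0, 4)), "non-empty")
})

test_that("chi-square of the node 2x2 tables reproduces the printed p-values", {
  mri <- contingency_2x2(tn = 61, fp = 17, fn = 8, tp = 9)
  res <- chi_square_2x2(mri)
  expect_equal(round(res$p, 3), 0.009)    # uncorrected Pearson
  pet <- contingency_2x2(tn = 69, fp = 9, fn = 7, tp = 10)
  expect_lt(chi_square_2x2(pet)$p, 0.001)
  # independence gives statistic 0, p = 1
  res0 <- chi_square_2x2(contingency_2x2(10, 10, 10, 10))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  # invariant under transposition / relabeling of the table
  expect_equal(chi_square_2x2(contingency_2x2(61, 8, 17, 9))$statistic,
               res$statistic)
  expect_equal(chi_square_2x2(contingency_2x2(9, 8, 17, 61))$statistic,
               res$statistic)
  expect_error(chi_square_2x2(contingency_2x2(5, 0, 7, 0)), "exact")
})

test_that("binary test diagnostics match the published node readings", {
  pet <- binary_test_diagnostics(contingency_2x2(tn = 69, fp = 9,
                                                 fn = 7, tp = 10))
  expect_equal(round(pet$sensitivity, 2), 58.82)
  expect_equal(round(pet$specificity, 2), 88.46)
  expect_equal(round(pet$auc, 3), 0.736)
  mri <- binary_test_diagnostics(contingency_2x2(tn = 61, fp = 17,
                                                 fn = 8, tp = 9))
  expect_equal(round(mri$specificity, 2), 78.21)
  expect_equal(round(mri$auc, 3), 0.656)
  perfect <- binary_test_diagnostics(contingency_2x2(50, 0, 0, 10))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$auc, 1)
  expect_error(binary_test_diagnostics(contingency_2x2(5, 5, 0, 0)),
               "both truth classes")
})

test_that("roc_continuous equals the brute-force pairwise AUC", {
  # toy set {neg: 1,2,3; pos: 2,4,5}: 9 pairs, one tie counted half
  marker <- c(1, 2, 3, 2, 4, 5)
  labels <- c(0, 0, 0, 1, 1, 1)
  r <- roc_continuous(marker, labels)
  expect_equal(r$auc, 7.5 / 9)
  expect_equal(r$auc, pairwise_auc(marker, labels))

  # random markers agree with brute force and (when present) pROC
  set.seed(77)
  for (i in 1:10) {
    m <- rnorm(40)
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    r <- roc_continuous(m, y, direction = "higher")
    expect_equal(r$auc, pairwise_auc(m, y))
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    m <- rnorm(60); y <- rep(0:1, 30)
    pr <- pROC::roc(y, m, direction = "<", quiet = TRUE)
    expect_equal(roc_continuous(m, y, "higher")$auc, as.numeric(pr$auc))
  }
})

test_that("roc_continuous handles separation, null markers and direction", {
  # perfectly separated marker: AUC 1, J = 1, cutoff between the classes
  r <- roc_continuous(c(1, 2, 3, 7, 8, 9), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$youden_j, 1)
  expect_equal(r$cutoff, 5)            # midpoint of 3 and 7
  # marker independent of labels: AUC near 1/2 (but always reported >= 1/2)
  set.seed(42)
  m <- rnorm(2000); y <- rep(0:1, 1000)
  expect_lt(abs(pairwise_auc(m, y) - 0.5), 0.03)
  expect_gte(roc_continuous(m, y)$auc, 0.5)
  # invariance under strictly monotone transforms
  m <- c(0.2, 1.5, 0.9, 2.8, 3.3, 1.1); y <- c(0, 0, 1, 1, 1, 0)
  expect_equal(roc_continuous(exp(m), y)$auc, roc_continuous(m, y)$auc)
  expect_equal(roc_continuous(qnorm(m / 4), y)$auc,
               roc_continuous(m, y)$auc)
  # flipping direction maps AUC to 1 - AUC
  a_hi <- roc_continuous(m, y, "higher")$auc
  expect_equal(roc_continuous(m, y, "lower")$auc, 1 - a_hi)
  # auto direction reports the protective orientation for inverse markers
  r <- roc_continuous(-m, y)
  expect_equal(r$direction, "lower")
  expect_equal(r$auc, a_hi)
  expect_error(roc_continuous(1:5, rep(1, 5)), "both classes")
  expect_error(roc_continuous(rep(1, 6), c(0, 0, 0, 1, 1, 1)), "distinct")
})

test_that("a binary call scored as a continuous marker gives the 2x2 AUC", {
  set.seed(8)
  y <- rbinom(60, 1, 0.3)
  call <- ifelse(runif(60) < 0.7, y, 1 - y)
  tab <- contingency_from_calls(y, call)
  expect_equal(roc_continuous(call, y)$auc,
               binary_test_diagnostics(tab)$auc)
})

test_that("the Youden cutoff maximizes J with ties broken to specificity", {
  marker <- c(1, 2, 3, 4, 10, 11, 12, 13)
  labels <- c(0, 0, 0, 0, 1, 1, 1, 1)
  r <- roc_continuous(marker, labels)
  expect_equal(r$cutoff, 7)             # midpoint of 4 and 10
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  # verify the reported J is the maximum over all operating points
  expect_equal(r$youden_j,
               max(r$curve$sensitivity + r$curve$specificity - 100) / 100)
})

test_that("delong_compare is calibrated and matches a bootstrap oracle", {
  # a curve against itself: zero difference, p = 1 with warning
  y <- rep(0:1, each = 10)
  m <- c(rnorm(10), rnorm(10, 1))
  r <- roc_continuous(m, y)
  expect_warning(self <- delong_compare(r, r), "degenerate")
  expect_equal(self$diff, 0)
  expect_equal(self$p, 1)

  # 10-patient toy: DeLong variance within 15% of a stratified bootstrap
  # (1e4 resamples) of the AUC difference
  yy <- rep(c(0, 1), each = 5)
  xa <- c(1.2, 2.3, 0.8, 3.1, 1.9, 2.8, 3.5, 1.7, 4.2, 2.9)
  xb <- c(0.5, 1.1, 2.0, 1.4, 0.9, 1.8, 2.6, 1.2, 3.0, 0.7)
  dl <- delong_compare(roc_continuous(xa, yy, "higher"),
                       roc_continuous(xb, yy, "higher"))
  v_delong <- (dl$diff / dl$z)^2
  set.seed(99)
  B <- 10000L
  d <- numeric(B)
  for (i in seq_len(B)) {
    i1 <- sample(6:10, 5, replace = TRUE)
    i0 <- sample(1:5, 5, replace = TRUE)
    d[i] <- pairwise_auc(c(xa[i0], xa[i1]), yy) -
            pairwise_auc(c(xb[i0], xb[i1]), yy)
  }
  expect_lt(abs(v_delong / var(d) - 1), 0.15)

  if (requireNamespace("pROC", quietly = TRUE)) {
    pr <- pROC::roc.test(pROC::roc(yy, xa, direction = "<", quiet = TRUE),
                         pROC::roc(yy, xb, direction = "<", quiet = TRUE),
                         method = "delong")
    expect_equal(dl$p, as.numeric(pr$p.value), tolerance = 1e-10)
  }
  expect_error(delong_compare(r, roc_continuous(m, rev(y))), "paired")
})

test_that("fit_logistic matches a brute-force likelihood grid", {
  set.seed(5)
  x <- rnorm(30)
  y <- rbinom(30, 1, plogis(-0.5 + 1.2 * x))
  d <- data.frame(y = y, x = x)
  m <- fit_logistic(d, "y", "x")
  # grid maximization of the log-likelihood around the MLE
  b0 <- seq(-3, 2, by = 1e-3)
  b1 <- seq(-1, 4, by = 1e-3)
  ll <- outer(b0, b1, Vectorize(function(a, b) logistic_loglik(a, b, x, y)))
  best <- arrayInd(which.max(ll), dim(ll))
  expect_equal(m$coefficients$coefficient[1], b0[best[1]], tolerance = 1e-3)
  expect_equal(m$coefficients$coefficient[2], b1[best[2]], tolerance = 1e-3)
  expect_gte(m$log_likelihood, max(ll))
  # optimum log-likelihood is at least the null model's
  expect_gte(m$log_likelihood, m$null_log_likelihood)
  # Wald is (coef/SE)^2 by construction
  expect_equal(m$coefficients$wald,
               (m$coefficients$coefficient / m$coefficients$std_error)^2)
})

test_that("fit_logistic recovers generating parameters at large n", {
  set.seed(12)
  x <- rnorm(2000)
  y <- rbinom(2000, 1, plogis(-1 + 2 * x))
  m <- fit_logistic(data.frame(y = y, x = x), "y", "x")
  expect_lt(abs(m$coefficients$coefficient[1] - (-1)), 0.15)
  expect_lt(abs(m$coefficients$coefficient[2] - 2), 0.15)
  expect_true(m$converged)
  expect_false(m$separation)
  expect_true(all(m$fitted > 0 & m$fitted < 1))
})

test_that("fit_logistic flags no-association, separation and collinearity", {
  # feature with identical values in both classes: coefficient 0, p = 1
  d <- data.frame(y = rep(0:1, each = 4), x = rep(c(1, 2, 3, 4), 2))
  m <- fit_logistic(d, "y", "x")
  expect_equal(m$coefficients$coefficient[2], 0, tolerance = 1e-8)
  expect_equal(m$coefficients$p[2], 1, tolerance = 1e-6)
  # complete separation is detected, not silently diverged
  sep <- data.frame(y = rep(0:1, each = 10), x = c(1:10, 21:30))
  expect_true(fit_logistic(sep, "y", "x")$separation)
  # collinear predictors raise an error naming a variable
  col <- data.frame(y = rep(0:1, 10), a = rnorm(20))
  col$b <- 2 * col$a
  expect_error(fit_logistic(col, "y", c("a", "b")), "collinear")
})

test_that("bonferroni_alpha reproduces the published correction levels", {
  expect_equal(bonferroni_alpha(0.05, 10), 0.005)
  expect_equal(round(bonferroni_alpha(0.05, 3), 4), 0.0167)
  expect_error(bonferroni_alpha(0.05, 0), "n_tests")
})

test_that("build_combined_model finds a planted single signal", {
  set.seed(17)
  n <- 200L
  y <- rbinom(n, 1, 0.3)
  co <- data.frame(pathology_positive = y)
  feats <- c("suv_max", "suv_mean", "mtv", "tlg", "adc_mean", "adc_min",
             "d_mean", "d_min", "d_star", "f")
  for (v in feats) co[[v]] <- rnorm(n)
  co$tlg <- y * 2 + rnorm(n)            # the only informative feature
  co$pet_node_positive <- rbinom(n, 1, 0.2)
  co$mri_node_positive <- rbinom(n, 1, 0.2)
  m <- build_combined_model(co)
  expect_identical(m$selected, "tlg")
  expect_equal(m$alpha_entry, 0.005)
  expect_gt(m$roc$auc, 0.8)
  expect_true(any(grepl("enter tlg", m$audit)))
})

test_that("build_combined_model falls back gracefully on pure noise", {
  set.seed(23)
  n <- 120L
  co <- data.frame(pathology_positive = rbinom(n, 1, 0.3))
  for (v in c("suv_max", "suv_mean", "mtv", "tlg", "adc_mean", "adc_min",
              "d_mean", "d_min", "d_star", "f"))
    co[[v]] <- rnorm(n)
  co$pet_node_positive <- rbinom(n, 1, 0.2)
  co$mri_node_positive <- rbinom(n, 1, 0.2)
  expect_warning(m <- build_combined_model(co), "best univariate")
  expect_length(m$selected, 1L)
  expect_s3_class(m$model, "logistic_model")
})

test_that("spearman_matrix matches rank arithmetic", {
  # monotone transform: perfect rank correlation
  x <- c(0.3, 1.2, 2.4, 3.3, 5.0)
  sp <- spearman_matrix(data.frame(x = x, y = exp(x)))
  expect_equal(sp$rho["x", "y"], 1)
  expect_equal(sp$p["x", "y"], 0)
  # hand computation via the sum-of-squared-rank-differences formula:
  # d^2 = (1,1,1,1,0), rho = 1 - 6*4/(5*24) = 0.8
  sp2 <- spearman_matrix(data.frame(x = 1:5, y = c(2, 1, 4, 3, 5)))
  expect_equal(sp2$rho["x", "y"], 0.8)
  # symmetry, unit diagonal, constant column undefined
  sp3 <- spearman_matrix(data.frame(a = rnorm(10), b = rnorm(10),
                                    c = rep(1, 10)))
  expect_equal(sp3$rho["a", "b"], sp3$rho["b", "a"])
  expect_equal(sp3$rho["a", "a"], 1)
  expect_true(is.na(sp3$rho["a", "c"]))
  expect_error(spearman_matrix(data.frame(x = 1:2, y = 2:3)), "3 patients")
})

test_that("SUVmax and SUVmean of phantoms are strongly rank-correlated", {
  set.seed(3)
  mets <- t(vapply(1:12, function(i) {
    spec <- small_phantom_spec(noise_sigma = 0.03, seed = i,
                               suv_peak = runif(1, 8, 25),
                               suv_background = 0.5)
    ph <- make_pet_phantom(spec)
    tm <- tumor_metrics(ph$suv, ph$mask)
    c(suv_max = tm$suv_max, suv_mean = tm$suv_mean)
  }, c(suv_max = 0, suv_mean = 0)))
  sp <- spearman_matrix(as.data.frame(mets))
  expect_gt(sp$rho["suv_max", "suv_mean"], 0.9)
})

test_that("ICC(2,1) rewards agreement and penalizes systematic bias", {
  x <- c(9.1, 10.4, 11.8, 13.2, 8.7, 12.5)
  perfect <- icc_two_rater(x, x)
  expect_equal(perfect$icc, 1)
  expect_equal(perfect$band, "high")

  # constant shift, 4 subjects: closed-form mean squares computed by hand
  subj <- c(2, 4, 6, 8)
  shift <- 0.5
  y <- cbind(subj, subj + shift)
  grand <- mean(y)
  msr <- 2 * sum((rowMeans(y) - grand)^2) / 3
  msc <- 4 * sum((colMeans(y) - grand)^2) / 1
  ss_err <- sum((y - grand)^2) - 2 * sum((rowMeans(y) - grand)^2) -
    4 * sum((colMeans(y) - grand)^2)
  mse <- ss_err / 3
  expected <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 4)
  res <- icc_two_rater(subj, subj + shift)
  expect_equal(res$icc, expected)
  expect_lt(res$icc, 1)                 # absolute agreement penalizes bias
  expect_gt(res$icc, 0.9)               # between-subject variance dominates

  # independent ratings: ICC near zero
  set.seed(20)
  r <- icc_two_rater(rnorm(500), rnorm(500))
  expect_lt(abs(r$icc), 0.15)
  # zero total variance: undefined, flagged
  flat <- icc_two_rater(rep(3, 5), rep(3, 5))
  expect_true(is.na(flat$icc))
  expect_equal(flat$band, "undefined")
})
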