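# Statistical machinery, checked against brute-force oracles and base-R
# reference implementations on small fixtures.

# exhaustive pair-counting AUC oracle (ties count 1/2)
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

test_that("AUROC equals exhaustive pair counting on toy sets", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- sample(1:5, n, TRUE)          # plenty of ties
    expect_equal(auroc(scores, labels)$auc, auc_oracle(scores, labels))
  }
  expect_equal(auroc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "both")
})

test_that("AUROC is invariant under strictly monotone transforms", {
  set.seed(7)
  s <- rnorm(60); y <- rbinom(60, 1, plogis(s))
  a <- auroc(s, y)$auc
  expect_equal(auroc(exp(s), y)$auc, a)
  expect_equal(auroc(qlogis(plogis(s)), y)$auc, a, tolerance = 1e-12)
})

test_that("null AUROC concentrates at one half", {
  set.seed(123)
  s <- rnorm(1000); y <- rbinom(1000, 1, 0.4)
  expect_lt(abs(auroc(s, y)$auc - 0.5), 0.05)
})

test_that("DeLong variance and CI behave on an informative predictor", {
  set.seed(11)
  s <- rnorm(200); y <- rbinom(200, 1, plogis(2 * s))
  r <- auroc(s, y)
  expect_gt(r$auc, 0.7)
  expect_true(r$ci[1] < r$auc && r$auc < r$ci[2])
  expect_gt(r$var, 0)
})

test_that("Youden threshold equals brute-force maximisation", {
  brute <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    cand <- sort(unique(c(scores - 1e-6, scores + 1e-6)))
    best <- -Inf
    for (t in cand) {
      j <- mean(pos >= t) + mean(neg < t) - 1
      if (j > best + 1e-12) best <- j
    }
    best
  }
  set.seed(17)
  for (rep in 1:15) {
    scores <- sample(seq(0, 3, by = 0.5), 6, TRUE)
    labels <- c(0, 1, sample(0:1, 4, TRUE))
    y <- youden_threshold(scores, labels)
    expect_equal(y$youden, brute(scores, labels), tolerance = 1e-9)
    expect_equal(y$youden, y$sensitivity + y$specificity - 1)
  }
  sep <- youden_threshold(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))
  expect_equal(sep$youden, 1)
  expect_true(sep$threshold > 3 && sep$threshold <= 10)
  flat <- youden_threshold(rep(2, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(flat$youden, 0)
})

test_that("DeLong test: identical and monotone-equivalent scores give z=0", {
  set.seed(3)
  s <- rnorm(40); y <- rbinom(40, 1, plogis(s))
  r1 <- delong_test(s, s, y)
  expect_equal(r1$z, 0)
  expect_equal(r1$p, 1)
  r2 <- delong_test(s, 5 * s - 2, y)          # same ranks, same AUC
  expect_equal(r2$z, 0)
  expect_equal(r2$p, 1)
})

test_that("DeLong test separates a strong from a noisy predictor", {
  set.seed(21)
  x <- rnorm(400); y <- rbinom(400, 1, plogis(3 * x))
  noisy <- x + rnorm(400, 0, 4)
  r <- delong_test(x, noisy, y)
  expect_gt(r$auc_a, r$auc_b)
  expect_lt(r$p, 0.01)
})

test_that("VIF: orthogonal, duplicated and near-duplicated predictors", {
  # zero-mean mutually orthogonal contrast columns: VIF exactly 1
  blk <- rbind(c(1, 1, 1), c(-1, 1, -1), c(1, -1, -1), c(-1, -1, 1))
  q <- blk[rep(1:4, 16), ]
  d <- data.frame(a = q[, 1], b = q[, 2], c = q[, 3])
  v <- collinearity_check(d, candidates = c("a", "b", "c"))
  expect_equal(v$vif, rep(1, 3), tolerance = 1e-8)
  expect_false(any(v$flagged))

  d$dup <- d$a
  v2 <- collinearity_check(d, candidates = c("a", "b", "c", "dup"))
  expect_true(all(v2$flagged[v2$predictor %in% c("a", "dup")]))
  expect_true(all(!is.finite(v2$vif[v2$predictor %in% c("a", "dup")]) |
                    v2$vif[v2$predictor %in% c("a", "dup")] > 1e6))

  d$konst <- 1
  v3 <- collinearity_check(d, candidates = c("a", "b", "konst"))
  expect_true(is.infinite(v3$vif[v3$predictor == "konst"]))

  set.seed(9)
  x1 <- rnorm(100)
  vifs <- sapply(c(1, 0.3, 0.05), function(sg) {
    dd <- data.frame(x1 = x1, x2 = x1 + rnorm(100, 0, sg))
    collinearity_check(dd, candidates = c("x1", "x2"))$vif[2]
  })
  expect_true(all(diff(vifs) > 0))          # VIF grows as noise shrinks
})

test_that("rank-sum test matches exact enumeration and the reference", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)                    # 2/20 partitions as extreme
  expect_match(r$method, "exact")
  # against the base-R exact test on tie-free small samples
  set.seed(13)
  for (rep in 1:10) {
    x <- sample(1:50, 4); y <- sample(51:100, 5) - 50 + runif(5)
    ours <- rank_sum_test(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
  # identical groups sit at the null centre
  same <- rank_sum_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$p, 1)
  expect_error(rank_sum_test(1, c(1, 2)), "at least 2")
})

test_that("large-sample rank-sum approximation tracks the reference", {
  set.seed(41)
  x <- round(rlnorm(40, log(5), 0.3))
  y <- round(rlnorm(45, log(6.5), 0.3))
  ours <- rank_sum_test(x, y, exact = FALSE)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-6)
})

test_that("Spearman correlation matches the reference t approximation", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  set.seed(19)
  x <- rnorm(60); y <- 0.4 * x + rnorm(60)
  ours <- spearman_cor(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(ours$rho, unname(ref$estimate))
  expect_lt(abs(ours$p - ref$p.value), 0.02)
})

test_that("stepwise AIC: a useless predictor is usually rejected", {
  # AIC admits a null term iff its LRT statistic exceeds 2, which happens
  # with asymptotic probability 1 - pchisq(2, 1) = 0.157; the retention
  # count over 100 replicates is Binomial(100, 0.843), whose 0.1% quantile
  # is 73 -- assert that derived bound
  keep_null <- 0L
  for (rep in 1:100) {
    set.seed(400 + rep)
    d <- data.frame(outcome = rbinom(200, 1, 0.3), x = rnorm(200))
    fit <- stepwise_logistic_aic(d, candidates = "x")
    if (length(fit$selected) == 0L) keep_null <- keep_null + 1L
  }
  expect_gte(keep_null, qbinom(0.001, 100, pchisq(2, 1)))
})

test_that("stepwise AIC recovers active terms among decoys", {
  set.seed(71)
  hits <- 0L
  for (rep in 1:10) {
    n <- 200
    log_flr <- log(100 * plogis(rnorm(n, 1.57, 1.0)))
    ct1 <- exp(rnorm(n, log(722.5), 0.12))
    decoys <- matrix(rnorm(n * 3), n, 3)
    eta <- 1.24 - 2.26 * log_flr + 0.013 * ct1
    d <- data.frame(outcome = rbinom(n, 1, plogis(eta)),
                    log_flr = log_flr, ct1 = ct1,
                    d1 = decoys[, 1], d2 = decoys[, 2], d3 = decoys[, 3])
    fit <- stepwise_logistic_aic(d, candidates = c("log_flr", "ct1",
                                                   "d1", "d2", "d3"))
    if (all(c("log_flr", "ct1") %in% fit$selected)) hits <- hits + 1L
    # AIC never worse than the intercept-only model
    null_aic <- stats::AIC(stats::glm(outcome ~ 1, stats::binomial(),
                                      data = d))
    expect_lte(fit$aic, null_aic + 1e-9)
  }
  expect_gte(hits, 6L)
})

test_that("stepwise AIC degenerate inputs error; separation is flagged", {
  d <- data.frame(outcome = c(0, 1), x = c(1, 2))
  expect_error(stepwise_logistic_aic(d, candidates = "x"), "each outcome")
  sep <- data.frame(outcome = rep(c(0, 1), each = 12),
                    x = c(rnorm(12, -8), rnorm(12, 8)))
  fit <- stepwise_logistic_aic(sep, candidates = "x")
  expect_true(fit$separation)
  expect_true(is.finite(fit$aic))
})

test_that("predictor_matrix builds candidates, eligibility and log FLR", {
  co <- synthetic_cohort(60, seed = 5)
  pre <- cohort_preop(co$cohort)
  X <- predictor_matrix(pre, co$truth$outcome_poor)
  expect_true(all(CANDIDATE_PREDICTORS %in% names(X)))
  expect_equal(X$log_flr, log(pre$flr_percent))
  expect_identical(X$eligible,
                   unname(resected_fraction(pre$flr_percent) >= 0.10))
  expect_true(all(X$outcome %in% 0:1))
})

test_that("cohort rank tests wire the eligibility filter and pairs", {
  co <- synthetic_cohort(400, seed = 12)
  pre <- cohort_preop(co$cohort)
  rt <- rank_tests(pre)
  expect_true(rt$wilcoxon_los$n <= nrow(pre))
  expect_true(rt$wilcoxon_los$p >= 0 && rt$wilcoxon_los$p <= 1)
  expect_gte(rt$wilcoxon_los$median_elevated, rt$wilcoxon_los$median_normal)
  expect_equal(nrow(rt$spearman), 3)
  expect_true(all(rt$spearman$rho > 0))     # generator links are positive
})
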