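test_that("empirical ROC handles separation, ties, and inversion", {
  # perfect separation reaches sens 1 at spec 1
  roc <- empirical_roc(c(1, 2, 3), c(0, 0, 1))
  expect_true(any(roc$sensitivity == 1 & roc$specificity == 1))
  expect_equal(roc$sensitivity[1], 0)
  expect_equal(roc$specificity[1], 1)

  # all-tied scores give the two-point diagonal
  roc <- empirical_roc(rep(2, 6), c(1, 0, 1, 0, 0, 1))
  expect_equal(nrow(roc), 2L)
  expect_equal(roc$sensitivity + (1 - roc$specificity),
               2 * roc$sensitivity)  # on the diagonal sens = 1 - spec

  # anti-perfect scores sit below the diagonal
  roc <- empirical_roc(c(3, 2, 1), c(0, 0, 1))
  expect_true(all(roc$sensitivity <= 1 - roc$specificity))

  expect_error(empirical_roc(1:4, c(1, 1, 1, 1)), "degenerate")
})

test_that("ROC curves are monotone with endpoints present", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(10:80, 1)
    score <- round(rnorm(n), sample(0:2, 1))  # induce ties sometimes
    y <- runif(n) < plogis(score)
    if (all(y) || !any(y)) next
    roc <- empirical_roc(score, y)
    expect_true(all(diff(roc$sensitivity) >= 0))
    expect_true(all(diff(roc$specificity) <= 0))
    expect_equal(c(roc$sensitivity[1], roc$specificity[1]), c(0, 1))
    expect_equal(c(roc$sensitivity[nrow(roc)], roc$specificity[nrow(roc)]),
                 c(1, 0))
  }
})

test_that("AUC equals the Mann-Whitney pair enumeration", {
  expect_equal(auc_delong(c(3, 1, 2, 0), c(1, 1, 0, 0))$auc, 0.75)
  # perfectly separated
  a <- auc_delong(c(5, 6, 1, 2), c(1, 1, 0, 0))
  expect_equal(a$auc, 1.0)
  expect_equal(a$se, 0)
  # constant score is uninformative
  expect_equal(auc_delong(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)

  set.seed(9)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    score <- round(rnorm(n), sample(0:1, 1))
    y <- runif(n) < 0.4
    if (all(y) || !any(y)) next
    expect_equal(auc_delong(score, y)$auc, brute_auc(score, y),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(13)
  for (i in 1:10) {
    score <- rnorm(40)
    y <- runif(40) < plogis(score)
    if (all(y) || !any(y)) next
    a <- auc_delong(score, y)$auc
    expect_identical(auc_delong(exp(score), y)$auc, a)
    expect_identical(auc_delong(qlogis(plogis(score)), y)$auc,
                     auc_delong(score, y)$auc)
  }
})

test_that("DeLong variance matches enumeration and pROC", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (i in 1:15) {
    n <- sample(20:100, 1)
    score <- rnorm(n)
    y <- runif(n) < 0.35
    if (sum(y) < 2 || sum(!y) < 2) next
    est <- auc_delong(score, y)
    expect_equal(est$se^2, brute_delong_var(score, y), tolerance = 1e-12)
    pr <- pROC::roc(y, score, quiet = TRUE, direction = "<")
    expect_equal(est$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    expect_equal(est$se^2, as.numeric(pROC::var(pr, method = "delong")),
                 tolerance = 1e-10)
  }
})

test_that("DeLong variance approaches Hanley-McNeil in the binormal limit", {
  # continuous scores, no ties: compare the average estimated variance with
  # the Hanley-McNeil closed form at the empirical AUC
  set.seed(19)
  m <- 60; n <- 140
  vars <- replicate(200, {
    score <- c(rnorm(m, 1.2), rnorm(n, 0))
    y <- rep(c(1, 0), c(m, n))
    est <- auc_delong(score, y)
    a <- est$auc
    q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
    hm <- (a * (1 - a) + (m - 1) * (q1 - a^2) + (n - 1) * (q2 - a^2)) /
      (m * n)
    c(est$se^2, hm)
  })
  expect_equal(mean(vars[1, ]), mean(vars[2, ]), tolerance = 0.10)
})

test_that("paired DeLong comparison: identity, rank-invariance, oracle z", {
  set.seed(23)
  score <- rnorm(30)
  y <- rep(c(1, 0), 15)
  cmp <- compare_auc_delong(score, score, y)
  expect_equal(cmp$z, 0)
  expect_equal(cmp$p, 1)

  cmp <- compare_auc_delong(score, exp(score) + 2, y)
  expect_equal(cmp$auc_a, cmp$auc_b)
  expect_equal(cmp$p, 1)

  # n = 10 fixture checked against brute-force structural components
  sa <- c(2.1, 3.5, 1.2, 4.4, 2.8, 0.5, 2.2, 1.9, 3.0, 0.9)
  sb <- c(1.0, 2.0, 3.0, 2.5, 1.5, 2.4, 0.7, 1.1, 2.6, 0.8)
  yy <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  cmp <- compare_auc_delong(sa, sb, yy)
  expect_equal(cmp$z, brute_delong_z(sa, sb, yy), tolerance = 1e-12)
  expect_equal(sign(cmp$z), sign(cmp$auc_a - cmp$auc_b))

  expect_error(compare_auc_delong(sa, sb[-1], yy), "length")
})

test_that("paired DeLong comparison agrees with pROC's paired test", {
  skip_if_not_installed("pROC")
  set.seed(29)
  for (i in 1:10) {
    n <- 80
    base <- rnorm(n)
    y <- runif(n) < plogis(base)
    if (sum(y) < 3 || sum(!y) < 3) next
    sa <- base + rnorm(n)
    sb <- base + rnorm(n)
    mine <- compare_auc_delong(sa, sb, y)
    ref <- pROC::roc.test(pROC::roc(y, sa, quiet = TRUE, direction = "<"),
                          pROC::roc(y, sb, quiet = TRUE, direction = "<"),
                          method = "delong", paired = TRUE)
    expect_equal(abs(mine$z), abs(as.numeric(ref$statistic)),
                 tolerance = 1e-8)
    expect_equal(mine$p, as.numeric(ref$p.value), tolerance = 1e-8)
  }
})

test_that("paired DeLong test holds its nominal 5% size under the null", {
  set.seed(31)
  n_sim <- 2000
  rejections <- 0L
  for (i in seq_len(n_sim)) {
    n <- 150
    y <- runif(n) < 0.3
    if (sum(y) < 5 || sum(!y) < 5) next
    shared <- rnorm(n) + y
    sa <- shared + rnorm(n)
    sb <- shared + rnorm(n)   # exchangeable with sa given the outcome
    if (compare_auc_delong(sa, sb, y)$p < 0.05) rejections <- rejections + 1L
  }
  expect_lt(abs(rejections / n_sim - 0.05), 0.015)
})

test_that("Youden cutoff maximizes J with ties toward the smallest cutoff", {
  # perfect classifier: J = 1 at the separating threshold
  roc <- empirical_roc(c(1, 2, 5, 6), c(0, 0, 1, 1))
  best <- optimal_cutoff_youden(roc)
  expect_equal(best$youden_j, 1)
  expect_equal(best$cutoff, 5)

  # diagonal curve: J = 0, smallest threshold returned
  roc <- empirical_roc(rep(3, 8), rep(c(0, 1), 4))
  best <- optimal_cutoff_youden(roc)
  expect_equal(best$youden_j, 0)
  expect_equal(best$cutoff, 3)

  # one mislabeled control at 3.5: optimum sits in (2, 3]
  roc <- empirical_roc(c(3, 4, 1, 2, 3.5), c(1, 1, 0, 0, 0))
  best <- optimal_cutoff_youden(roc)
  expect_gt(best$cutoff, 2)
  expect_lte(best$cutoff, 3)
  expect_equal(best$sensitivity, 1)
  expect_equal(best$specificity, 2 / 3)
})
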