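test_that("logistic fit recovers known parameters and rejects bad input", {
  set.seed(41)
  n <- 5000
  x <- rnorm(n, 0, 30)
  p <- plogis(-3 + 0.05 * x)
  y <- runif(n) < p
  fit <- fit_logistic(x, y)
  expect_true(fit$converged)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$intercept - (-3)), 3 * se[1])
  expect_lt(abs(fit$slope - 0.05), 3 * se[2])
  expect_equal(fit$predicted, plogis(fit$intercept + fit$slope * x))

  # constant score
  expect_error(fit_logistic(rep(1, 20), rep(c(0, 1), 10)), "constant")
  # perfect separation
  expect_error(fit_logistic(c(1:10, 21:30), rep(c(0, 1), each = 10)),
               "separation")
})

test_that("null slope is covered when score and outcome are independent", {
  set.seed(43)
  x <- rnorm(3000)
  y <- runif(3000) < 0.2
  fit <- fit_logistic(x, y)
  se <- sqrt(fit$vcov[2, 2])
  expect_lt(abs(fit$slope), 3 * se)
})

test_that("Hosmer-Lemeshow statistic behaves at its fixed points", {
  # predicted equals the within-bin event rate by construction -> chi2 = 0
  p_levels <- seq(0.05, 0.50, by = 0.05)
  predicted <- rep(p_levels, each = 20)
  label <- unlist(lapply(p_levels, function(p)
    rep(c(TRUE, FALSE), c(round(20 * p), 20 - round(20 * p)))))
  hl <- hosmer_lemeshow(predicted, label, g = 10)
  expect_equal(hl$chi2, 0, tolerance = 1e-12)
  expect_equal(hl$p, 1)
  expect_equal(hl$df, 8L)
  expect_equal(sum(hl$bins$n), length(label))

  # chi2 is invariant under relabeling patients within a bin
  set.seed(47)
  predicted2 <- runif(400, 0.05, 0.9)
  label2 <- runif(400) < predicted2
  hl_a <- hosmer_lemeshow(predicted2, label2, g = 10)
  bin_id <- rep(seq_len(nrow(hl_a$bins)), times = hl_a$bins$n)
  ord <- order(predicted2)
  perm <- ord
  for (b in unique(bin_id)) {
    ix <- ord[bin_id == b]
    perm[bin_id == b] <- sample(ix)
  }
  hl_b <- hosmer_lemeshow(predicted2[perm], label2[perm], g = 10)
  expect_equal(hl_a$chi2, hl_b$chi2, tolerance = 1e-12)

  expect_error(hosmer_lemeshow(runif(100), runif(100) < 0.5, g = 2), "g")
  expect_error(hosmer_lemeshow(c(0, runif(99)), runif(100) < 0.5),
               "strictly")
})

test_that("HL p-values are approximately uniform under the null", {
  # correctly specified logistic model: the test statistic should follow
  # its reference chi-square distribution
  set.seed(53)
  pvals <- replicate(300, {
    x <- rnorm(800)
    y <- runif(800) < plogis(-2 + 0.8 * x)
    if (sum(y) < 10) return(NA_real_)
    fit <- fit_logistic(x, y)
    hosmer_lemeshow(fit$predicted, y, g = 10)$p
  })
  pvals <- pvals[!is.na(pvals)]
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("continuous NRI matches its defining formula on small cases", {
  # identical predictions
  r <- continuous_nri(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3), c(1, 0, 1),
                      n_boot = 50, seed = 1)
  expect_equal(r$nri, 0)

  # both events up; one nonevent up, one down -> NRI = 1 + 0 = 1
  r <- continuous_nri(pred_old = c(0.2, 0.3, 0.2, 0.3),
                      pred_new = c(0.3, 0.4, 0.3, 0.2),
                      label = c(1, 1, 0, 0), n_boot = 50, seed = 1)
  expect_equal(r$nri, 1.0)
  expect_equal(r$event_nri, 1.0)
  expect_equal(r$nonevent_nri, 0.0)

  # constant shift moves everyone up: +1 for events, -1 for nonevents
  set.seed(59)
  po <- runif(40, 0.1, 0.5)
  y <- rep(c(1, 0), 20)
  r <- continuous_nri(po, po + 0.1, y, n_boot = 50, seed = 1)
  expect_equal(r$event_nri, 1)
  expect_equal(r$nonevent_nri, -1)
  expect_equal(r$nri, 0)
})

test_that("NRI components stay within their bounds", {
  set.seed(61)
  for (i in 1:20) {
    n <- 60
    po <- runif(n)
    pn <- runif(n)
    y <- runif(n) < 0.4
    if (all(y) || !any(y)) next
    r <- continuous_nri(po, pn, y, n_boot = 10, seed = i)
    expect_true(r$event_nri >= -1 && r$event_nri <= 1)
    expect_true(r$nonevent_nri >= -1 && r$nonevent_nri <= 1)
    expect_true(r$nri >= -2 && r$nri <= 2)
    expect_equal(r$nri, r$event_nri + r$nonevent_nri)
  }
})

test_that("IDI matches hand arithmetic and is antisymmetric in labels", {
  r <- idi(pred_old = c(0.2, 0.3, 0.1, 0.2),
           pred_new = c(0.4, 0.3, 0.05, 0.3),
           label = c(1, 1, 0, 0), n_boot = 50, seed = 1)
  expect_equal(r$idi, 0.10 - 0.025)

  r0 <- idi(c(0.1, 0.4), c(0.1, 0.4), c(1, 0), n_boot = 20, seed = 1)
  expect_equal(r0$idi, 0)

  set.seed(67)
  po <- runif(30); pn <- runif(30); y <- rep(c(1, 0), 15)
  expect_equal(idi(po, pn, y, n_boot = 10, seed = 2)$idi,
               -idi(po, pn, !y, n_boot = 10, seed = 2)$idi)
})

test_that("bootstrap confidence intervals reproduce bit-for-bit by seed", {
  set.seed(71)
  po <- runif(150, 0.05, 0.6)
  y <- runif(150) < po
  pn <- plogis(qlogis(po) + rnorm(150, 0.2, 0.3))
  a <- continuous_nri(po, pn, y, n_boot = 200, seed = 20100101)
  b <- continuous_nri(po, pn, y, n_boot = 200, seed = 20100101)
  expect_identical(a$nri_ci95, b$nri_ci95)
  ia <- idi(po, pn, y, n_boot = 200, seed = 20100101)
  ib <- idi(po, pn, y, n_boot = 200, seed = 20100101)
  expect_identical(ia$idi_ci95, ib$idi_ci95)
  # intervals contain the point estimate
  expect_true(a$nri >= a$nri_ci95[1] && a$nri <= a$nri_ci95[2])
  expect_true(ia$idi >= ia$idi_ci95[1] && ia$idi <= ia$idi_ci95[2])
  # different seed gives a (generically) different interval
  c2 <- continuous_nri(po, pn, y, n_boot = 200, seed = 4)
  expect_false(identical(a$nri_ci95, c2$nri_ci95))
})
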