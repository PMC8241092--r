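#' Univariate logistic risk model
#'
#' Maximum-likelihood logistic regression of a binary outcome on a single
#' score, used to map raw scores (SI, CCr, SIC) onto the probability scale
#' for calibration, reclassification, and decision-curve analysis. The fit
#' is by iteratively reweighted least squares and is accepted only when the
#' score equations are solved to a gradient norm below `1e-6`; perfect
#' separation and constant scores are rejected loudly rather than returning
#' divergent coefficients.
#'
#' @param score numeric predictor.
#' @param label binary outcome.
#' @return list of class `sic_logit` with `intercept`, `slope`, `vcov`,
#'   `predicted` (fitted probabilities), `converged`.
#' @export
fit_logistic <- function(score, label) {
  y <- .check_binary(label)
  if (length(score) != length(y)) stop("score and label lengths differ")
  if (any(!is.finite(score))) stop("scores must be finite")
  if (stats::sd(score) == 0) stop("constant score: slope is not identifiable")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ score, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  p <- as.numeric(stats::fitted(fit))
  grad <- c(sum(y - p), sum(score * (y - p)))
  grad_norm <- max(abs(grad)) / max(1, length(y))
  if (sep_warn && max(abs(stats::coef(fit))) > 50)
    stop("non-convergence: perfect (or quasi-perfect) separation detected")
  if (!fit$converged || grad_norm > 1e-6)
    stop("logistic fit did not converge (gradient norm ", signif(grad_norm, 3),
         ")")
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 vcov = stats::vcov(fit),
                 predicted = p,
                 converged = TRUE),
            class = "sic_logit")
}

#' Predicted probabilities from a univariate logistic fit
#' @param fit a `sic_logit` object.
#' @param score new score values.
#' @return probabilities in (0, 1).
#' @export
predict_logistic <- function(fit, score) {
  stats::plogis(fit$intercept + fit$slope * score)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Ranks patients by predicted probability, splits them into `g` near-equal
#' groups by quantile (tied probabilities stay in one bin; a bin that empties
#' is merged into its neighbour with a warning), and compares observed with
#' expected event counts:
#' \deqn{\chi^2 = \sum_g \frac{(O_g - E_g)^2}{E_g (1 - E_g/n_g)}}
#' referred to a chi-square distribution with g - 2 degrees of freedom.
#' The uncorrected denominator `sum (O-E)^2/E + (O-E)^2/(n-E)` form is
#' available via `correction = "simple"`.
#'
#' @param predicted probabilities in (0, 1).
#' @param label binary outcome.
#' @param g number of bins (default 10, so df = 8).
#' @param correction `"variance"` (default) or `"simple"` denominator.
#' @return list of class `sic_hl` with `chi2`, `df`, `p`, and a per-bin
#'   data frame `bins` (n, observed, expected, mean_predicted).
#' @export
hosmer_lemeshow <- function(predicted, label, g = 10,
                            correction = c("variance", "simple")) {
  correction <- match.arg(correction)
  y <- as.numeric(.check_binary(label))
  if (length(predicted) != length(y)) stop("length mismatch")
  if (any(predicted <= 0 | predicted >= 1))
    stop("predicted probabilities must lie strictly in (0, 1)")
  if (g < 3) stop("g must be at least 3")
  n <- length(y)
  if (n < 5 * g)
    warning("fewer than 5 patients per bin on average; HL test unreliable")
  # Quantile bin edges; ties.method keeps equal probabilities together.
  qs <- stats::quantile(predicted, probs = seq_len(g - 1) / g, type = 2)
  bin <- findInterval(predicted, unique(qs), left.open = TRUE) + 1L
  tab <- split(seq_len(n), bin)
  if (length(tab) < g)
    warning("tied predicted probabilities reduced the bin count to ",
            length(tab))
  bins <- do.call(rbind, lapply(tab, function(ix) {
    data.frame(n = length(ix), observed = sum(y[ix]),
               expected = sum(predicted[ix]),
               mean_predicted = mean(predicted[ix]))
  }))
  rownames(bins) <- NULL
  # Merge bins whose expected count is numerically empty.
  while (any(bins$expected < 1e-10) && nrow(bins) > 3) {
    i <- which(bins$expected < 1e-10)[1]
    j <- if (i == 1) 2L else i - 1L
    bins[j, c("n", "observed", "expected")] <-
      bins[j, c("n", "observed", "expected")] +
      bins[i, c("n", "observed", "expected")]
    bins$mean_predicted[j] <- bins$expected[j] / bins$n[j]
    bins <- bins[-i, , drop = FALSE]
    warning("merged an empty-expected bin")
  }
  chi2 <- if (correction == "variance") {
    sum((bins$observed - bins$expected)^2 /
          (bins$expected * (1 - bins$expected / bins$n)))
  } else {
    sum((bins$observed - bins$expected)^2 / bins$expected +
          (bins$observed - bins$expected)^2 / (bins$n - bins$expected))
  }
  df <- nrow(bins) - 2L
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 bins = bins),
            class = "sic_hl")
}

# Shared bootstrap machinery for NRI/IDI percentile intervals. statistic
# takes (pred_old, pred_new, y) and returns a scalar.
.boot_ci <- function(statistic, pred_old, pred_new, y, n_boot, seed,
                     conf_level = 0.95) {
  est <- statistic(pred_old, pred_new, y)
  n <- length(y)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    ix <- sample.int(n, n, replace = TRUE)
    if (all(y[ix]) || !any(y[ix])) return(NA_real_)
    statistic(pred_old[ix], pred_new[ix], y[ix])
  }, numeric(1))
  reps <- reps[!is.na(reps)]
  alpha <- 1 - conf_level
  ci <- unname(stats::quantile(reps, c(alpha / 2, 1 - alpha / 2), type = 7))
  list(estimate = est, ci95 = ci, n_boot = n_boot, seed = seed)
}

.nri_stat <- function(pred_old, pred_new, y) {
  up <- pred_new > pred_old
  down <- pred_new < pred_old
  ev <- y
  (mean(up[ev]) - mean(down[ev])) + (mean(down[!ev]) - mean(up[!ev]))
}

.idi_stat <- function(pred_old, pred_new, y) {
  mean(pred_new[y] - pred_old[y]) - mean(pred_new[!y] - pred_old[!y])
}

#' Continuous (category-free) net reclassification improvement
#'
#' Measures whether a new risk model moves predicted probabilities in the
#' right direction relative to an old model:
#' \deqn{NRI = [P(\uparrow|event) - P(\downarrow|event)] +
#'   [P(\downarrow|nonevent) - P(\uparrow|nonevent)]}
#' where up/down means a strict increase/decrease of the predicted
#' probability; ties count to neither side. Confidence intervals are seeded
#' nonparametric percentile bootstrap.
#'
#' @param pred_old,pred_new aligned probability vectors for the two models.
#' @param label binary outcome.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed bootstrap seed (default 20100101).
#' @return list of class `sic_nri` with `nri`, `nri_ci95`, `event_nri`,
#'   `nonevent_nri`, `n_boot`, `seed`.
#' @export
continuous_nri <- function(pred_old, pred_new, label, n_boot = 1000,
                           seed = 20100101) {
  y <- .check_binary(label)
  if (length(pred_old) != length(pred_new) || length(pred_old) != length(y))
    stop("pred_old, pred_new, and label must have equal lengths")
  up <- pred_new > pred_old
  down <- pred_new < pred_old
  boot <- .boot_ci(.nri_stat, pred_old, pred_new, y, n_boot, seed)
  structure(list(nri = boot$estimate, nri_ci95 = boot$ci95,
                 event_nri = mean(up[y]) - mean(down[y]),
                 nonevent_nri = mean(down[!y]) - mean(up[!y]),
                 n_boot = n_boot, seed = seed),
            class = "sic_nri")
}

#' Integrated discrimination improvement
#'
#' The change in discrimination slope between two risk models:
#' \deqn{IDI = (\bar p^{new}_{event} - \bar p^{old}_{event}) -
#'             (\bar p^{new}_{nonevent} - \bar p^{old}_{nonevent})}
#' with a seeded percentile-bootstrap confidence interval.
#'
#' @inheritParams continuous_nri
#' @return list of class `sic_idi` with `idi`, `idi_ci95`, `n_boot`, `seed`.
#' @export
idi <- function(pred_old, pred_new, label, n_boot = 1000, seed = 20100101) {
  y <- .check_binary(label)
  if (length(pred_old) != length(pred_new) || length(pred_old) != length(y))
    stop("pred_old, pred_new, and label must have equal lengths")
  boot <- .boot_ci(.idi_stat, pred_old, pred_new, y, n_boot, seed)
  structure(list(idi = boot$estimate, idi_ci95 = boot$ci95,
                 n_boot = n_boot, seed = seed),
            class = "sic_idi")
}
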