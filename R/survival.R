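.check_survival_input <- function(time, event) {
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (anyNA(time) || anyNA(event)) stop("time/event contain missing values")
  if (any(time < 0)) stop("validation error: negative follow-up time")
  as.numeric(as.logical(event))
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] to return the product-limit survival curve.
#' Censored observations reduce the risk set without producing a drop; with
#' no censoring the curve equals one minus the empirical CDF of event times.
#'
#' @param time follow-up in days, >= 0.
#' @param event event indicator (1 = death).
#' @return list of class `sic_km` with `time` (ascending unique follow-up
#'   times), `survival`, `at_risk`, `n_event`.
#' @export
kaplan_meier <- function(time, event) {
  ev <- .check_survival_input(time, event)
  fit <- survival::survfit(survival::Surv(time, ev) ~ 1, conf.type = "none")
  structure(list(time = fit$time, survival = fit$surv,
                 at_risk = fit$n.risk, n_event = fit$n.event),
            class = "sic_km")
}

#' Log-rank test across strata
#'
#' Standard log-rank comparison of survival across two or more groups via
#' [survival::survdiff()], with df = groups - 1.
#'
#' @param time follow-up in days.
#' @param event event indicator.
#' @param group stratum label per patient (e.g. SIC tertile or binary
#'   stratum).
#' @return list of class `sic_logrank` with `chi2`, `df`, `p`, and the
#'   per-group observed/expected table.
#' @export
log_rank <- function(time, event, group) {
  ev <- .check_survival_input(time, event)
  g <- droplevels(as.factor(group))
  if (nlevels(g) < 2) stop("log-rank requires at least two non-empty groups")
  if (length(g) != length(time)) stop("group length mismatch")
  fit <- survival::survdiff(survival::Surv(time, ev) ~ g)
  df <- nlevels(g) - 1L
  structure(list(chi2 = fit$chisq, df = df,
                 p = stats::pchisq(fit$chisq, df, lower.tail = FALSE),
                 observed = fit$obs, expected = fit$exp),
            class = "sic_logrank")
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood estimation via [survival::coxph()], Efron tie handling
#' by default (admission-day resolution creates tied event times; Breslow is
#' available via `ties`). Reports hazard ratios with Wald confidence
#' intervals and p-values. Constant covariates and monotone likelihoods
#' (complete separation) are rejected.
#'
#' @param time follow-up in days.
#' @param event event indicator.
#' @param covariates data frame (or named list) of numeric/factor adjustment
#'   terms; the covariate set is the caller's choice.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return list of class `sic_cox` with `coef`, `hr`, `se`, `ci95` (matrix),
#'   `p`, `converged`, and the underlying `fit`.
#' @export
cox_ph <- function(time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  ev <- .check_survival_input(time, event)
  if (sum(ev) == 0) stop("no events: Cox model is not estimable")
  x <- as.data.frame(covariates)
  if (nrow(x) != length(time)) stop("covariate length mismatch")
  const <- vapply(x, function(v) length(unique(v)) < 2L, logical(1))
  if (any(const))
    stop("constant covariate(s): ", paste(names(x)[const], collapse = ", "))
  dat <- cbind(data.frame(.time = time, .event = ev), x)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(x), collapse = " + ")))
  warned_inf <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties,
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("coefficient may be infinite|did not converge",
                conditionMessage(w)))
        warned_inf <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (warned_inf || any(abs(stats::coef(fit)) > 20))
    stop("non-convergence: monotone partial likelihood ",
         "(complete separation in a covariate)")
  sm <- summary(fit)
  ci <- cbind(lower = sm$conf.int[, "lower .95"],
              upper = sm$conf.int[, "upper .95"])
  rownames(ci) <- names(stats::coef(fit))
  structure(list(coef = stats::coef(fit),
                 hr = exp(stats::coef(fit)),
                 se = sm$coefficients[, "se(coef)"],
                 ci95 = ci,
                 p = sm$coefficients[, "Pr(>|z|)"],
                 score_test = unname(sm$sctest["test"]),
                 converged = TRUE,
                 fit = fit),
            class = "sic_cox")
}
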