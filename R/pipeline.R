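#' Round half away from zero
#'
#' Clinical tables report one-decimal percentages rounded half-up; base
#' `round()` rounds half-even, so 3.75 would print as 3.8 vs 3.8 but 0.65
#' as 0.6. This helper implements the table convention.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

.known_outcomes <- c("death", "stroke", "acute_heart_failure", "dialysis",
                     "tvr", "mace", "ci_aki", "bleeding", "death_1y")

.outcome_vector <- function(cohort, outcome) {
  if (outcome == "mace") return(derive_mace(cohort))
  if (!outcome %in% names(cohort))
    stop("unknown outcome name: ", outcome)
  as.logical(cohort[[outcome]])
}

# Chi-square (no continuity correction) when all expected counts >= 5,
# Fisher's exact test otherwise.
.two_group_test <- function(flag, group) {
  tab <- table(group, factor(flag, levels = c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0)) return(list(method = "none", p = NA_real_))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(colSums(tab) > 0) && all(expected >= 5)) {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(method = "chi-square", statistic = unname(ct$statistic),
         p = unname(ct$p.value))
  } else if (any(colSums(tab) == 0)) {
    # No events (or all events) in either group: groups indistinguishable.
    list(method = "degenerate", statistic = 0, p = 1)
  } else {
    ft <- stats::fisher.test(tab)
    list(method = "fisher", statistic = NA_real_, p = unname(ft$p.value))
  }
}

#' Event-rate summary table
#'
#' Counts and one-decimal percentages per in-hospital outcome, overall and
#' (optionally) per group, with two-group comparisons by chi-square when all
#' expected cell counts are at least 5 and by Fisher's exact test otherwise.
#' The MACE composite is derived on the fly from its component flags.
#'
#' @param cohort cohort data frame.
#' @param outcomes outcome names (default: all in-hospital outcomes present).
#' @param by optional name of a two-level grouping column
#'   (e.g. `"cohort_label"`).
#' @return data frame of class `sic_event_table`: one row per outcome with
#'   `count`, `percent`, per-group counts/percents, and the comparison `p`.
#' @export
event_rate_summary <- function(cohort, outcomes = NULL, by = NULL) {
  validate_cohort(cohort)
  if (is.null(outcomes)) {
    outcomes <- intersect(.known_outcomes, c(names(cohort), "mace"))
    outcomes <- setdiff(outcomes, "death_1y")
    if (!all(c("stroke", "dialysis", "acute_heart_failure", "tvr") %in%
             names(cohort)))
      outcomes <- setdiff(outcomes, "mace")
  }
  n <- nrow(cohort)
  grp <- NULL
  if (!is.null(by)) {
    if (!by %in% names(cohort)) stop("grouping column not found: ", by)
    grp <- factor(cohort[[by]])
    if (nlevels(grp) != 2) stop("grouping must have exactly 2 levels")
  }
  rows <- lapply(outcomes, function(o) {
    flag <- .outcome_vector(cohort, o)
    row <- data.frame(outcome = o, n = n, count = sum(flag),
                      percent = round_half_up(100 * mean(flag), 1))
    if (!is.null(grp)) {
      for (lv in levels(grp)) {
        f <- flag[grp == lv]
        row[[paste0("count_", lv)]] <- sum(f)
        row[[paste0("percent_", lv)]] <- round_half_up(100 * mean(f), 1)
      }
      tst <- .two_group_test(flag, grp)
      row$test <- tst$method
      row$p <- tst$p
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sic_event_table", "data.frame")
  out
}

#' Two-group baseline comparison table
#'
#' Compares baseline variables between two groups the way clinical Table 1s
#' are built: normally-distributed continuous variables by two-sample t test
#' (mean +/- sd), skewed continuous variables by Wilcoxon rank-sum
#' (median and IQR), and categorical variables by chi-square.
#'
#' @param cohort cohort data frame.
#' @param group name of a two-level grouping column.
#' @param normal_vars continuous variables summarized as mean +/- sd.
#' @param skewed_vars continuous variables summarized as median (IQR).
#' @param categorical_vars binary/categorical variables.
#' @return data frame: one row per variable with per-group summaries,
#'   test name, and p-value.
#' @export
baseline_table <- function(cohort, group,
                           normal_vars = character(),
                           skewed_vars = character(),
                           categorical_vars = character()) {
  g <- factor(cohort[[group]])
  if (nlevels(g) != 2) stop("grouping must have exactly 2 levels")
  lv <- levels(g)
  fmt_mean <- function(v) sprintf("%.1f ± %.1f", mean(v), stats::sd(v))
  fmt_med <- function(v) sprintf("%.1f (%.1f, %.1f)", stats::median(v),
                                 stats::quantile(v, 0.25),
                                 stats::quantile(v, 0.75))
  rows <- list()
  for (v in normal_vars) {
    x <- cohort[[v]]
    tt <- stats::t.test(x[g == lv[1]], x[g == lv[2]], var.equal = FALSE)
    rows[[v]] <- data.frame(variable = v, test = "t",
                            group1 = fmt_mean(x[g == lv[1]]),
                            group2 = fmt_mean(x[g == lv[2]]),
                            p = tt$p.value)
  }
  for (v in skewed_vars) {
    x <- cohort[[v]]
    wt <- suppressWarnings(stats::wilcox.test(x[g == lv[1]], x[g == lv[2]]))
    rows[[v]] <- data.frame(variable = v, test = "wilcoxon",
                            group1 = fmt_med(x[g == lv[1]]),
                            group2 = fmt_med(x[g == lv[2]]),
                            p = wt$p.value)
  }
  for (v in categorical_vars) {
    x <- factor(cohort[[v]])
    tab <- table(g, x)
    identical_props <- all(abs(prop.table(tab, 1)[1, ] -
                                 prop.table(tab, 1)[2, ]) < 1e-12)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    p <- if (identical_props) 1 else unname(ct$p.value)
    pct <- function(i) sprintf("%d (%.1f)", tab[i, ncol(tab)],
                               100 * tab[i, ncol(tab)] / sum(tab[i, ]))
    rows[[v]] <- data.frame(variable = v, test = "chi-square",
                            group1 = pct(1), group2 = pct(2), p = p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Univariate screen with multivariable follow-up
#'
#' Fits a univariate logistic model of the outcome on each candidate column,
#' keeps candidates with Wald p < `alpha`, then fits one multivariable
#' logistic model on the selected set and reports adjusted odds ratios.
#'
#' @param cohort data frame.
#' @param candidates candidate column names (numeric or binary).
#' @param outcome outcome name (see [event_rate_summary()]).
#' @param alpha selection threshold (default 0.05).
#' @return list with `univariate` (per-candidate OR, CI, p), `selected`
#'   (names), and `multivariable` (adjusted ORs, or NULL when nothing was
#'   selected).
#' @export
univariate_screen <- function(cohort, candidates, outcome, alpha = 0.05) {
  y <- .check_binary(.outcome_vector(cohort, outcome))
  uni <- do.call(rbind, lapply(candidates, function(v) {
    x <- as.numeric(cohort[[v]])
    fit <- fit_logistic(x, y)
    se <- sqrt(fit$vcov[2, 2])
    data.frame(variable = v, or = exp(fit$slope),
               or_low = exp(fit$slope - 1.96 * se),
               or_high = exp(fit$slope + 1.96 * se),
               p = 2 * stats::pnorm(-abs(fit$slope / se)))
  }))
  selected <- uni$variable[uni$p < alpha]
  multi <- NULL
  if (length(selected)) {
    dat <- cohort[, selected, drop = FALSE]
    dat <- as.data.frame(lapply(dat, as.numeric))
    dat$.y <- as.numeric(y)
    fit <- withCallingHandlers(
      stats::glm(.y ~ ., data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w)))
          stop("non-convergence: separation in the multivariable model")
        invokeRestart("muffleWarning")
      })
    cf <- summary(fit)$coefficients[-1, , drop = FALSE]
    multi <- data.frame(variable = rownames(cf),
                        or = exp(cf[, "Estimate"]),
                        or_low = exp(cf[, "Estimate"] -
                                       1.96 * cf[, "Std. Error"]),
                        or_high = exp(cf[, "Estimate"] +
                                        1.96 * cf[, "Std. Error"]),
                        p = cf[, "Pr(>|z|)"])
    rownames(multi) <- NULL
  }
  list(univariate = uni, selected = as.character(selected),
       multivariable = multi)
}

#' Evaluate scores against an outcome
#'
#' For one outcome, computes per-score AUC (DeLong), the univariate logistic
#' probability mapping, Hosmer-Lemeshow calibration, and for each comparator
#' the paired DeLong comparison plus continuous NRI and IDI against the
#' primary score.
#'
#' @param scored scored cohort (from [score_cohort()]).
#' @param outcome outcome name.
#' @param score primary score column (default `"sic"`).
#' @param compare comparator score columns (default `c("si100", "ccr")`).
#' @param hl_bins Hosmer-Lemeshow bin count.
#' @param n_boot,seed bootstrap settings for NRI/IDI.
#' @return nested list: `auc` per score, `hl` for the primary score,
#'   `comparisons` per comparator (`delong`, `nri`, `idi`), plus the
#'   Youden-optimal cutoff of the primary score.
#' @export
evaluate_scores <- function(scored, outcome, score = "sic",
                            compare = c("si100", "ccr"),
                            hl_bins = 10, n_boot = 1000, seed = 20100101) {
  y <- .check_binary(.outcome_vector(scored, outcome))
  cols <- c(score, compare)
  miss <- setdiff(cols, names(scored))
  if (length(miss)) stop("score column(s) missing: ",
                         paste(miss, collapse = ", "))
  # CCr protects (higher = lower risk); orient every score so that higher
  # predicts the event before ROC analysis, as SPSS-style ROC tools do.
  oriented <- lapply(cols, function(cl) {
    x <- scored[[cl]]
    fit <- fit_logistic(x, y)
    if (fit$slope < 0) -x else x
  })
  names(oriented) <- cols
  aucs <- lapply(oriented, function(x) auc_delong(x, y))
  fits <- lapply(cols, function(cl) fit_logistic(scored[[cl]], y))
  names(fits) <- cols
  hl <- hosmer_lemeshow(fits[[score]]$predicted, y, g = hl_bins)
  roc <- empirical_roc(oriented[[score]], y)
  cutoff <- optimal_cutoff_youden(roc)
  comparisons <- lapply(compare, function(cl) {
    list(delong = compare_auc_delong(oriented[[score]], oriented[[cl]], y),
         nri = continuous_nri(fits[[cl]]$predicted, fits[[score]]$predicted,
                              y, n_boot = n_boot, seed = seed),
         idi = idi(fits[[cl]]$predicted, fits[[score]]$predicted, y,
                   n_boot = n_boot, seed = seed))
  })
  names(comparisons) <- compare
  list(outcome = outcome, auc = aucs, hl = hl, youden = cutoff,
       comparisons = comparisons,
       predicted = lapply(fits, function(f) f$predicted))
}

#' Run the full analysis pipeline
#'
#' Scores a cohort, tabulates event rates, evaluates discrimination /
#' calibration / reclassification per outcome, runs decision-curve analysis
#' for in-hospital death, and -- when follow-up columns are present -- the
#' survival stage (KM by stratum, log-rank, Cox on the binary stratum).
#' Writes the scored cohort, delimited tables, and a JSON report into
#' `output_dir`; re-running with the same inputs reproduces the bundle.
#'
#' @param cohort cohort data frame (e.g. from [generate_cohort()] or
#'   [read_cohort()]).
#' @param output_dir output directory (created if needed); `NULL` skips
#'   writing and just returns the bundle.
#' @param outcomes outcomes to evaluate (default death, MACE, CI-AKI,
#'   bleeding).
#' @param ccr_variant,cutoff,cutpoints scoring settings, see
#'   [score_cohort()].
#' @param hl_bins,n_boot,seed evaluation settings.
#' @param dca_thresholds decision-curve threshold grid.
#' @return invisibly, a list with `scored`, `event_rates`, `evaluation`,
#'   `dca`, `survival`.
#' @export
run_pipeline <- function(cohort, output_dir = NULL,
                         outcomes = c("death", "mace", "ci_aki", "bleeding"),
                         ccr_variant = "as_printed", cutoff = 10,
                         cutpoints = c(-30, -5), hl_bins = 10,
                         n_boot = 1000, seed = 20100101,
                         dca_thresholds = seq(0.01, 0.50, by = 0.01)) {
  scored <- score_cohort(cohort, ccr_variant = ccr_variant, cutoff = cutoff,
                         cutpoints = cutpoints)
  by <- if ("cohort_label" %in% names(scored) &&
            length(unique(scored$cohort_label)) == 2) "cohort_label" else NULL
  event_rates <- event_rate_summary(scored, by = by)
  evaluation <- lapply(outcomes, function(o)
    evaluate_scores(scored, o, hl_bins = hl_bins, n_boot = n_boot,
                    seed = seed))
  names(evaluation) <- outcomes
  dca <- NULL
  if ("death" %in% outcomes) {
    preds <- evaluation$death$predicted
    dca <- decision_curve_table(preds, .outcome_vector(scored, "death"),
                                thresholds = dca_thresholds)
  }
  surv_out <- NULL
  if (all(c("followup_days", "death_1y") %in% names(scored)) &&
      !anyNA(scored$followup_days)) {
    km <- lapply(split(seq_len(nrow(scored)), scored$tertile), function(ix)
      kaplan_meier(scored$followup_days[ix], scored$death_1y[ix]))
    lr <- log_rank(scored$followup_days, scored$death_1y, scored$tertile)
    cox <- cox_ph(scored$followup_days, scored$death_1y,
                  data.frame(high_risk = as.numeric(scored$high_risk)))
    surv_out <- list(km_by_tertile = km, log_rank = lr, cox_high_risk = cox)
  } else {
    warning("follow-up columns absent or incomplete; survival stage skipped")
  }
  bundle <- list(scored = scored, event_rates = event_rates,
                 evaluation = evaluation, dca = dca, survival = surv_out)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(scored[, setdiff(names(scored), "tertile")],
                 file.path(output_dir, "scored_cohort.csv"))
    utils::write.csv(event_rates, file.path(output_dir, "event_rates.csv"),
                     row.names = FALSE)
    if (!is.null(dca))
      utils::write.csv(dca, file.path(output_dir, "decision_curve.csv"),
                       row.names = FALSE)
    report <- lapply(evaluation, function(ev) list(
      auc = lapply(ev$auc, function(a) list(auc = a$auc, se = a$se,
                                            ci95 = a$ci95)),
      hl = list(chi2 = ev$hl$chi2, df = ev$hl$df, p = ev$hl$p),
      youden = ev$youden,
      comparisons = lapply(ev$comparisons, function(cmp) list(
        auc_a = cmp$delong$auc_a, auc_b = cmp$delong$auc_b,
        z = cmp$delong$z, p = cmp$delong$p,
        nri = cmp$nri$nri, nri_ci = cmp$nri$nri_ci95,
        idi = cmp$idi$idi, idi_ci = cmp$idi$idi_ci95,
        n_boot = n_boot, seed = seed))))
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(bundle)
}
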