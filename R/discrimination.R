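# Coerce an outcome to logical and require both classes.
.check_binary <- function(label) {
  y <- as.logical(label)
  if (anyNA(y)) stop("outcome labels contain missing values")
  if (all(y) || !any(y))
    stop("degenerate input: both outcome classes must be present")
  y
}

#' Empirical ROC curve
#'
#' Computes the empirical receiver operating characteristic over the unique
#' observed score values, with ties grouped at one threshold. The
#' classification rule at threshold t is positive iff score >= t, so the
#' curve always contains the endpoints (sens 0, spec 1) at +Inf and
#' (sens 1, spec 0) at the minimum score.
#'
#' @param score numeric score, higher = more likely positive.
#' @param label binary outcome (logical or 0/1).
#' @return a data frame of class `sic_roc` with columns `threshold`
#'   (descending), `sensitivity`, `specificity`.
#' @export
empirical_roc <- function(score, label) {
  y <- .check_binary(label)
  if (any(!is.finite(score))) stop("scores must be finite")
  if (length(score) != length(y)) stop("score and label lengths differ")
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  n_case <- sum(y)
  n_ctrl <- sum(!y)
  sens <- vapply(thr, function(t) sum(score[y] >= t) / n_case, numeric(1))
  spec <- vapply(thr, function(t) sum(score[!y] < t) / n_ctrl, numeric(1))
  out <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  class(out) <- c("sic_roc", "data.frame")
  out
}

# Midranks (average ranks for ties), the kernel of the fast DeLong algorithm.
.midrank <- function(x) rank(x, ties.method = "average")

# DeLong structural components. Returns list(auc, v10 (per case),
# v01 (per control)). Ties in scores contribute 1/2 to the Mann-Whitney
# kernel, the standard convention.
.delong_components <- function(score, y) {
  x_case <- score[y]
  x_ctrl <- score[!y]
  m <- length(x_case)
  n <- length(x_ctrl)
  tz <- .midrank(c(x_case, x_ctrl))
  tx <- .midrank(x_case)
  ty <- .midrank(x_ctrl)
  v10 <- (tz[seq_len(m)] - tx) / n
  v01 <- 1 - (tz[m + seq_len(n)] - ty) / m
  auc <- (sum(tz[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' AUC with DeLong standard error
#'
#' The area under the empirical ROC curve equals the Mann-Whitney estimator:
#' the mean over all case-control pairs of the kernel that scores 1 when the
#' case outranks the control and 1/2 at ties. The standard error comes from
#' the DeLong structural-component variance
#' \deqn{\widehat{var} = S_{10}/m + S_{01}/n}
#' with m cases and n controls.
#'
#' @param score numeric score vector.
#' @param label binary outcome.
#' @param conf_level confidence level for the (normal, clipped) interval.
#' @return list of class `sic_auc` with `auc`, `se`, `ci95`, `n_case`,
#'   `n_control`.
#' @export
auc_delong <- function(score, label, conf_level = 0.95) {
  y <- .check_binary(label)
  if (length(score) != length(y)) stop("score and label lengths differ")
  if (any(!is.finite(score))) stop("scores must be finite")
  cmp <- .delong_components(score, y)
  s10 <- if (cmp$m > 1) stats::var(cmp$v10) else 0
  s01 <- if (cmp$n > 1) stats::var(cmp$v01) else 0
  se <- sqrt(s10 / cmp$m + s01 / cmp$n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, cmp$auc + c(-1, 1) * z * se))
  structure(list(auc = cmp$auc, se = se, ci95 = ci,
                 n_case = cmp$m, n_control = cmp$n),
            class = "sic_auc")
}

#' Paired DeLong comparison of two AUCs
#'
#' Compares the AUCs of two scores measured on the same patients using the
#' DeLong covariance of their structural components:
#' \deqn{z = (AUC_a - AUC_b)/\sqrt{var_a + var_b - 2\,cov_{ab}}}
#' with a two-sided normal p-value. When the two scores induce identical
#' rankings the variance of the difference is zero and z = 0, p = 1.
#'
#' @param score_a,score_b score vectors on the same patients.
#' @param label binary outcome.
#' @return list of class `sic_auc_cmp` with `auc_a`, `auc_b`, `var_a`,
#'   `var_b`, `cov`, `z`, `p`.
#' @export
compare_auc_delong <- function(score_a, score_b, label) {
  y <- .check_binary(label)
  if (length(score_a) != length(score_b) || length(score_a) != length(y))
    stop("score_a, score_b, and label must have equal lengths")
  ca <- .delong_components(score_a, y)
  cb <- .delong_components(score_b, y)
  m <- ca$m; n <- ca$n
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  smat <- s10 / m + s01 / n
  var_diff <- smat[1, 1] + smat[2, 2] - 2 * smat[1, 2]
  d <- ca$auc - cb$auc
  if (var_diff <= .Machine$double.eps^0.5 && abs(d) < 1e-12) {
    z <- 0; p <- 1
  } else if (var_diff <= 0) {
    z <- sign(d) * Inf; p <- 0
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = ca$auc, auc_b = cb$auc,
                 var_a = smat[1, 1], var_b = smat[2, 2], cov = smat[1, 2],
                 z = z, p = p),
            class = "sic_auc_cmp")
}

#' Youden-optimal cutoff
#'
#' Returns the threshold on the ROC curve maximizing Youden's J =
#' sensitivity + specificity - 1. Ties are broken toward the smallest
#' cutoff (the more sensitive rule).
#'
#' @param roc a `sic_roc` curve from [empirical_roc()].
#' @return list with `cutoff`, `sensitivity`, `specificity`, `youden_j`.
#' @export
optimal_cutoff_youden <- function(roc) {
  if (!inherits(roc, "sic_roc") || nrow(roc) < 2L)
    stop("degenerate ROC curve")
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.min(roc$threshold[best])]
  list(cutoff = roc$threshold[pick],
       sensitivity = roc$sensitivity[pick],
       specificity = roc$specificity[pick],
       youden_j = j[pick])
}
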