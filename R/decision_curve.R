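#' Decision-curve analysis: net benefit across threshold probabilities
#'
#' At each threshold probability t, patients with predicted probability
#' >= t (inclusive at ties) are treated as positive and the net benefit is
#' \deqn{NB(t) = TP/n - (FP/n)\, t/(1-t).}
#' The treat-all reference is `prevalence - (1 - prevalence) t/(1-t)` and
#' treat-none is identically zero. Net benefit can never exceed the event
#' prevalence; the bound is attained only by a perfect predictor.
#'
#' @param predicted probabilities in (0, 1).
#' @param label binary outcome.
#' @param thresholds probability grid, strictly inside (0, 1); default
#'   0.01 to 0.50 in steps of 0.01, the clinically relevant range for
#'   in-hospital mortality decisions.
#' @return data frame of class `sic_dca` with columns `threshold`,
#'   `nb_model`, `nb_all`, `nb_none`; attribute `prevalence`.
#' @export
net_benefit <- function(predicted, label,
                        thresholds = seq(0.01, 0.50, by = 0.01)) {
  y <- .check_binary(label)
  if (length(predicted) != length(y)) stop("length mismatch")
  if (any(predicted <= 0 | predicted >= 1))
    stop("predicted probabilities must lie strictly in (0, 1)")
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly in (0, 1)")
  n <- length(y)
  prev <- mean(y)
  w <- thresholds / (1 - thresholds)
  nb_model <- vapply(seq_along(thresholds), function(i) {
    t <- thresholds[i]
    pos <- predicted >= t
    sum(pos & y) / n - (sum(pos & !y) / n) * w[i]
  }, numeric(1))
  out <- data.frame(threshold = thresholds,
                    nb_model = nb_model,
                    nb_all = prev - (1 - prev) * w,
                    nb_none = 0)
  attr(out, "prevalence") <- prev
  class(out) <- c("sic_dca", "data.frame")
  out
}

#' Tidy multi-model decision-curve table
#'
#' Runs [net_benefit()] for several prediction models on the same outcome and
#' stacks the curves into one long table suitable for plotting or export.
#'
#' @param predictions named list of probability vectors.
#' @param label binary outcome.
#' @param thresholds threshold grid, see [net_benefit()].
#' @return data frame with columns `model_name`, `threshold`, `nb_model`,
#'   `nb_all`, `nb_none`.
#' @export
decision_curve_table <- function(predictions, label,
                                 thresholds = seq(0.01, 0.50, by = 0.01)) {
  stopifnot(is.list(predictions), length(names(predictions)) ==
              length(predictions))
  do.call(rbind, lapply(names(predictions), function(nm) {
    nb <- net_benefit(predictions[[nm]], label, thresholds)
    cbind(model_name = nm, as.data.frame(nb))
  }))
}
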