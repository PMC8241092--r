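#' Shock index
#'
#' Heart rate (bpm) divided by systolic blood pressure (mmHg). Higher values
#' indicate hemodynamic compromise.
#'
#' @param heart_rate beats per minute, > 0.
#' @param sbp systolic blood pressure in mmHg, > 0.
#' @return numeric ratio, same length as the inputs.
#' @export
shock_index <- function(heart_rate, sbp) {
  if (any(!is.finite(heart_rate)) || any(!is.finite(sbp)))
    stop("heart_rate and sbp must be finite")
  if (any(sbp <= 0)) stop("sbp must be > 0")
  if (any(heart_rate <= 0)) stop("heart_rate must be > 0")
  heart_rate / sbp
}

#' Estimated creatinine clearance (Cockcroft-Gault family)
#'
#' Two variants are provided. `"as_printed"` (the default) is the
#' weight-free abbreviation used to build the SIC score:
#' \deqn{CCr = (140 - age)/Scr \times (0.85\ \mathrm{if\ female})}
#' `"full_cockcroft_gault"` is the standard equation
#' \deqn{CCr = (140 - age) \times weight / (72 \times Scr) \times (0.85\ \mathrm{if\ female})}
#' The two coincide exactly at weight = 72 kg.
#'
#' @param age years, in [18, 140).
#' @param sex `"male"` or `"female"`.
#' @param scr serum creatinine, mg/dL, > 0.
#' @param weight kg; required for the full variant.
#' @param variant `"as_printed"` or `"full_cockcroft_gault"`.
#' @return estimated creatinine clearance in mL/min.
#' @export
creatinine_clearance <- function(age, sex, scr, weight = NULL,
                                 variant = c("as_printed",
                                             "full_cockcroft_gault")) {
  variant <- match.arg(variant)
  if (any(!sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (any(age >= 140)) stop("age >= 140: formula nonpositive")
  if (any(age < 18)) stop("age must be >= 18")
  if (any(scr <= 0)) stop("scr must be > 0")
  base <- (140 - age) / scr
  if (variant == "full_cockcroft_gault") {
    if (is.null(weight) || anyNA(weight))
      stop("weight required for the full Cockcroft-Gault variant")
    if (any(weight <= 0)) stop("weight must be > 0")
    base <- base * weight / 72
  }
  ifelse(sex == "female", base * 0.85, base)
}

#' SIC tertile assignment
#'
#' Partitions the SIC scale at the cutpoints used for clinical stratification:
#' T1 for SIC < -30, T2 for -30 <= SIC < -5, T3 for SIC >= -5. Boundary
#' values fall in the upper stratum (left-closed T2 and T3).
#'
#' @param sic finite numeric SIC values.
#' @param cutpoints increasing length-2 numeric, defaults `c(-30, -5)`.
#' @return factor with levels `T1`, `T2`, `T3`.
#' @export
sic_tertile <- function(sic, cutpoints = c(-30, -5)) {
  if (any(!is.finite(sic))) stop("sic must be finite")
  if (length(cutpoints) != 2L || diff(cutpoints) <= 0)
    stop("cutpoints must be two increasing values")
  cut(sic, breaks = c(-Inf, cutpoints, Inf), right = FALSE,
      labels = c("T1", "T2", "T3"))
}

#' Binary high-risk stratum
#'
#' High risk iff SIC strictly exceeds the cutoff; patients at exactly the
#' cutoff fall in the low-risk group.
#'
#' @param sic finite numeric SIC values.
#' @param cutoff score cutoff, default 10.
#' @return logical vector.
#' @export
sic_binary <- function(sic, cutoff = 10) {
  if (any(!is.finite(sic))) stop("sic must be finite")
  sic > cutoff
}

#' Score a cohort with SI, CCr, and SIC
#'
#' Computes, per patient, the shock index (SI), SI x 100, estimated
#' creatinine clearance (CCr), and the Shock Index-C
#' \deqn{SIC = SI \times 100 - CCr,}
#' then attaches the tertile and binary high-risk stratum. No rounding is
#' applied anywhere; stratification uses full-precision values.
#'
#' @param cohort validated cohort data frame.
#' @param ccr_variant creatinine-clearance variant, see
#'   [creatinine_clearance()].
#' @param cutoff binary stratification cutoff (default 10).
#' @param cutpoints tertile cutpoints (default `c(-30, -5)`).
#' @return the cohort with columns `si`, `si100`, `ccr`, `sic`, `tertile`,
#'   `high_risk` appended; class `sic_scored`.
#' @export
score_cohort <- function(cohort, ccr_variant = c("as_printed",
                                                 "full_cockcroft_gault"),
                         cutoff = 10, cutpoints = c(-30, -5)) {
  ccr_variant <- match.arg(ccr_variant)
  validate_cohort(cohort)
  out <- cohort
  out$si <- shock_index(cohort$heart_rate, cohort$sbp)
  out$si100 <- out$si * 100
  out$ccr <- creatinine_clearance(cohort$age, cohort$sex, cohort$scr,
                                  weight = cohort$weight,
                                  variant = ccr_variant)
  out$sic <- out$si100 - out$ccr
  out$tertile <- sic_tertile(out$sic, cutpoints)
  out$high_risk <- sic_binary(out$sic, cutoff)
  attr(out, "ccr_variant") <- ccr_variant
  attr(out, "sic_cutoff") <- cutoff
  attr(out, "sic_cutpoints") <- cutpoints
  class(out) <- unique(c("sic_scored", class(out)))
  out
}
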