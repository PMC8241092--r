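# Independent brute-force oracles used to check the fast implementations.

# Mann-Whitney AUC by exhaustive pair enumeration (ties count 1/2).
brute_auc <- function(score, label) {
  y <- as.logical(label)
  cases <- score[y]
  ctrl <- score[!y]
  k <- outer(cases, ctrl, ">") + 0.5 * outer(cases, ctrl, "==")
  mean(k)
}

# DeLong structural components by direct enumeration.
brute_delong <- function(score, label) {
  y <- as.logical(label)
  cases <- score[y]
  ctrl <- score[!y]
  k <- outer(cases, ctrl, ">") + 0.5 * outer(cases, ctrl, "==")
  list(auc = mean(k), v10 = rowMeans(k), v01 = colMeans(k),
       m = length(cases), n = length(ctrl))
}

brute_delong_var <- function(score, label) {
  cmp <- brute_delong(score, label)
  stats::var(cmp$v10) / cmp$m + stats::var(cmp$v01) / cmp$n
}

# Paired DeLong z statistic by enumeration of both kernels.
brute_delong_z <- function(score_a, score_b, label) {
  ca <- brute_delong(score_a, label)
  cb <- brute_delong(score_b, label)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  smat <- s10 / ca$m + s01 / ca$n
  (ca$auc - cb$auc) / sqrt(smat[1, 1] + smat[2, 2] - 2 * smat[1, 2])
}

# A tiny fully-specified cohort for I/O and scoring tests.
tiny_cohort <- function() {
  data.frame(
    patient_id = c("A1", "A2", "A3"),
    age = c(60, 75, 40),
    sex = c("male", "male", "female"),
    weight = c(72, NA, 60),
    heart_rate = c(80, 110, 95),
    sbp = c(120, 90, 130),
    scr = c(1.0, 1.5, 0.9),
    death = c(FALSE, TRUE, FALSE),
    stroke = c(FALSE, FALSE, FALSE),
    acute_heart_failure = c(FALSE, TRUE, FALSE),
    dialysis = c(FALSE, FALSE, FALSE),
    tvr = c(FALSE, FALSE, FALSE),
    ci_aki = c(FALSE, TRUE, FALSE),
    bleeding = c(FALSE, FALSE, TRUE),
    followup_days = c(365, 12.5, 365),
    death_1y = c(FALSE, TRUE, FALSE),
    cohort_label = c("derivation", "derivation", "validation"),
    stringsAsFactors = FALSE
  )
}

# Random valid cohort for round-trip property checks.
random_cohort <- function(n, seed) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("R%04d", seq_len(n)),
    age = runif(n, 20, 95),
    sex = sample(c("male", "female"), n, replace = TRUE),
    weight = ifelse(runif(n) < 0.9, runif(n, 40, 110), NA),
    heart_rate = runif(n, 40, 160),
    sbp = runif(n, 70, 200),
    scr = exp(rnorm(n, 0, 0.3)),
    death = runif(n) < 0.1,
    stroke = runif(n) < 0.05,
    acute_heart_failure = runif(n) < 0.1,
    dialysis = runif(n) < 0.05,
    tvr = runif(n) < 0.02,
    ci_aki = runif(n) < 0.1,
    bleeding = runif(n) < 0.1,
    followup_days = runif(n, 0, 365),
    death_1y = runif(n) < 0.1,
    cohort_label = "unspecified",
    stringsAsFactors = FALSE
  )
}

# A cohort whose flags reproduce fixed per-group event counts, used to check
# the event-rate accounting against known totals. counts is a named list of
# c(derivation, validation) event counts.
counted_cohort <- function(n_der, n_val, counts) {
  n <- n_der + n_val
  out <- data.frame(
    patient_id = sprintf("C%05d", seq_len(n)),
    age = 60, sex = "male", heart_rate = 80, sbp = 120, scr = 1.0,
    cohort_label = rep(c("derivation", "validation"), c(n_der, n_val)),
    stringsAsFactors = FALSE
  )
  for (nm in names(counts)) {
    k <- counts[[nm]]
    flag <- logical(n)
    flag[seq_len(k[1])] <- TRUE                 # first k1 derivation rows
    flag[n_der + seq_len(k[2])] <- TRUE         # first k2 validation rows
    out[[nm]] <- flag
  }
  out
}

# Cohort whose flags reproduce the published per-group in-hospital event
# counts, with the four MACE component flags arranged so their union equals
# the published composite count in each group (derivation: AHF rows 1-68,
# dialysis rows 68-101, stroke 1-13, TVR 1-6 -> union 101; validation: AHF
# 1-50, dialysis 42-77, stroke 1-10, TVR 1-6 -> union 77).
printed_cohort <- function() {
  n_der <- 1145; n_val <- 706
  n <- n_der + n_val
  out <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = 60, sex = "male", heart_rate = 80, sbp = 120, scr = 1.0,
    cohort_label = rep(c("derivation", "validation"), c(n_der, n_val)),
    stringsAsFactors = FALSE
  )
  span <- function(der_rows, val_rows) {
    flag <- logical(n)
    flag[der_rows] <- TRUE
    flag[n_der + val_rows] <- TRUE
    flag
  }
  out$acute_heart_failure <- span(1:68, 1:50)
  out$dialysis <- span(68:101, 42:77)
  out$stroke <- span(1:13, 1:10)
  out$tvr <- span(1:6, 1:6)
  out$death <- span(1:40, 1:28)
  out$ci_aki <- span(1:115, 1:70)
  out$bleeding <- span(1:126, 1:67)
  out
}
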