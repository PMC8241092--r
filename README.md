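# sicstrat

Risk stratification for STEMI patients undergoing PCI with the **Shock
Index-C (SIC)** score, plus the complete statistical toolkit used to
validate clinical risk scores.

## The problem and the score

In-hospital mortality after primary PCI for ST-segment elevation
myocardial infarction remains 3–4%, and bleeding, contrast-induced kidney
injury (CI-AKI), and other major adverse events are common. Established
scores (GRACE, TIMI, Mehran, CRUSADE) each target one endpoint and need
many inputs. SIC condenses three admission measurements into one number:

```
SI  = heart rate (bpm) / systolic BP (mmHg)
CCr = (140 − age) / Scr          [× 0.85 if female]
SIC = 100·SI − CCr
```

Higher SIC (tachycardia, hypotension, renal dysfunction) means higher
risk. Patients are stratified into tertiles at −30 and −5, or into a
binary high-risk group at SIC > 10. The standard weight-based
Cockcroft-Gault clearance is available as a variant.

The package is aimed at clinical-prediction researchers: it provides the
score itself, delimited-file cohort I/O with strict validation, and
implementations of the full validation battery — empirical ROC with
DeLong variance, paired DeLong AUC comparison, Youden-optimal cutoffs,
Hosmer-Lemeshow calibration, continuous NRI and IDI with seeded bootstrap
intervals, decision-curve analysis, Kaplan-Meier / log-rank / Cox survival
(via the survival package), event-rate and baseline tables, and a seeded
synthetic cohort generator so that the entire pipeline is testable without
access to patient data.

## Worked example

```r
library(sicstrat)

co <- generate_cohort(generator_config(n = 1851, seed = 7))
sc <- score_cohort(co)                 # adds si, si100, ccr, sic, tertile, high_risk
table(sc$tertile)
#>  T1  T2  T3
#> 510 502 839

ev <- evaluate_scores(sc, "death")     # discrimination + calibration vs si100, ccr
lr <- log_rank(sc$followup_days, sc$death_1y, sc$tertile)
cx <- cox_ph(sc$followup_days, sc$death_1y,
             data.frame(high_risk = as.numeric(sc$high_risk)))
```

which prints (this exact seed):

```
AUC(SIC) = 0.858 (95% CI 0.816-0.900)
AUC(SI)  = 0.772 ; DeLong p = 9.7e-05
HL chi2 = 7.01, df = 8, p = 0.535
NRI vs SI = 0.821 (0.608-1.026); IDI = 0.068
Youden cutoff = 13.1 (sens 76.1%, spec 79.5%)
log-rank chi2 = 92.11, p = 1e-20
SIC>10 HR for 1-y death = 5.47 (95% CI 3.83-7.83)
```

Reading: on this synthetic cohort SIC discriminates in-hospital death
well (AUC 0.86) and significantly better than the shock index alone
(paired DeLong p < 0.001, large positive NRI/IDI); the Hosmer-Lemeshow
test finds no miscalibration of the logistic mapping (p = 0.54); and the
high-SIC stratum carries a five-fold 1-year mortality hazard. The
generator draws outcomes from a logistic link on SIC calibrated to an AUC
of 0.87 at 3.7% prevalence, so numbers near these are expected by design.

A thin command-line wrapper covers the same stages
(`simulate | score | evaluate | survival | run`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli/sicstrat.R", package="sicstrat"))') \
    simulate --n 1851 --seed 7 --out synth.csv
```

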