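# bmiprofiles

Probabilistic subclassification of obesity phenotypes from
BMI–biomarker discordance.

Two people with the same BMI can have very different metabolic health.
`bmiprofiles` quantifies, for each individual, how far ten routine
cardiometabolic biomarkers — fasting glucose, HDL, LDL, triglycerides,
systolic/diastolic blood pressure, serum creatinine, ALT, CRP and
waist-to-hip ratio — depart from the values expected for their BMI
(age- and smoking-adjusted, sex-stratified), and partitions those
departures into reproducible *discordance profiles* with per-individual
membership probabilities. It then estimates each profile's
epidemiology and its added value for predicting cardiovascular events
and type 2 diabetes.

## The method in brief

1. **Discordance.** Per biomarker \(y\): residualize \(y\) on age and
   smoking, then on BMI; center and scale to unit SD. The standardized
   residual vector \(\delta_i \in \mathbb{R}^{10}\) measures
   discordance. Its squared Mahalanobis distance is \(\chi^2_{10}\)
   under multivariate normality, giving a per-individual p-value and a
   cohort-level excess-discordance test.
2. **Profiles.** A binary kNN graph on the \(\delta_i\)
   (\(nn = \max(10, 10 + 15(\log_{10}N - 4))\)) is partitioned by
   leading-eigenvector seeding plus restarted Leiden; communities become
   Gaussian components via eigenvector-centrality-weighted moments; a
   concordant component \(\mathcal N(0, I)\) is always included.
   Moments stay fixed and only mixture weights are fitted by EM, giving
   allocation probabilities \(p_{ik}\) with \(\sum_k p_{ik} = 1\).
3. **Replication.** Profiles must re-identify (median cross-cohort
   allocation probability > 0.8 among confidently allocated discovery
   individuals) in *every* validation cohort, or they are absorbed back
   into the concordant profile.
4. **Epidemiology & prediction.** Probability-weighted summaries,
   slopes, prevalences/incidences and OR/RRs (BH-adjusted, meta-analyzed
   across cohorts); nested Cox models with compositional log-contrast
   terms \(z_{ik} = \ln(p_{ik}/p_{i,\mathrm{conc}})\) — likelihood-ratio
   tests, added explained variation, ΔC — plus Lasso checks, decision
   curves (net benefit and per-10,000 deltas) and
   probability-shift hazard ratios mapped back to biomarker units.

## Worked example

Restricted-access cohort data cannot ship with the package, so the
example runs on synthetic cohorts with planted structure (three
discordant profiles at weights 0.08/0.07/0.05 and a ln 2 hazard effect
on the first profile's log-ratio):

```r
library(bmiprofiles)

cfg <- default_config("survival", n_individuals = 20000, seed = 42)
cohorts <- generate_multicohort(cfg, 4, c(20000, 4000, 4000, 4000))
fits <- lapply(cohorts, function(g) {
  qc  <- remove_outliers(g$cohort)$cohort
  res <- residualize(qc)
  list(qc = qc, res = res, fit = fit_profiles(res, n_iter = 50, seed = 1))
})
disc <- fits[[1]]

excess_discordance_test(mahalanobis_discordance(disc$res))
#> flagged: 8.3% (5% expected), binomial p << 0.001

rep <- replication_test(disc$fit$alloc, disc$fit$mixture,
                        lapply(fits[-1], function(f) f$fit$mixture), disc$res)
fin <- finalize_model(disc$fit$mixture, rep$replicated, disc$res)
fin$mixture
#> mixture_model: 4 profiles (concordant concordant)
#>        label weight
#> 1  d_tg_high 0.0723
#> 2  d_fg_high 0.0594
#> 3 d_dbp_high 0.0441
#> 4 concordant 0.8242
separation_index(fin$alloc)
#> 0.973
```

The three replicated profiles are the planted ones (high triglycerides,
hyperglycemic, hypertensive); spurious central communities from the
discovery cohort fail replication and fold back into the concordant
profile, whose fitted weight (0.824) sits close to the planted 0.8. A
separation index of 0.97 means allocations are nearly one-hot.

```r
z    <- log_contrast(fin$alloc)
base <- fit_cox(as.data.frame(disc$res$values),
                disc$qc$fu_years_mace, disc$qc$mace_event)
full <- fit_cox(cbind(as.data.frame(disc$res$values), as.data.frame(z)),
                disc$qc$fu_years_mace, disc$qc$mace_event)
compare_nested(base, full)
#> LRT = 475.4 (df 3), p = 1e-102; added variance = 3.1%; C: 0.977 -> 0.991

shift_risk(full, fin$mixture, target = "d_tg_high", disc$res$fit_params)
#> 10%-shift toward d_tg_high: HR = 1.65 (95% CI 1.61-1.69)

shift_biomarkers(fin$mixture, "d_tg_high", 0.8, disc$res$fit_params)$biomarkers
#>     fg    hdl    ldl     tg    sbp    dbp    scr    alt    crp    whr
#>   4.85   0.56   4.81   3.45 134.12  74.47  71.93  26.42   3.17   0.88
```

The log-ratio terms add predictive signal beyond the biomarkers
themselves (the planted hazard acts through the profile membership), and
the back-mapping shows what an 80%-probability
high-triglyceride-profile individual looks like in raw units at age 55,
BMI 30: TG 3.45 mmol/l and HDL 0.56 mmol/l against BMI-expected values
of roughly 1.7 and 1.3.

See `vignettes/methods.Rmd` for the full model description, parameter
choices and limitations.

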