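# meadowsem

Does cattle grazing reduce amphibian occupancy of montane meadows, or do
the two species simply use different parts of the landscape? `meadowsem`
implements a complete analysis pipeline for that question, built around
the study design of a multi-year cattle/toad monitoring program in Sierra
Nevada grazing allotments: 24 meadows nested in 3 allotments, five
monitoring sites per meadow (120 sites), three grazing seasons
(early/mid/late) per year, with meadow-scale breeding-occupancy surveys.
It is aimed at quantitative ecologists who want a tested, reproducible
reference implementation of this model family — and a synthetic-data
generator with known truth, so every stage can be validated without any
field data.

## The model

Site wetness is scored on an ordinal 0 (dry) – 6 (continuously flooded)
scale; the meadow-scale hydrologic rank is the rounded mean of its site
scores. On standardized variables, the hierarchical Bayesian structural
equation model (SEM) is

```
quality:       Q_i  = gamma_WQ * W_i + u_i + zeta_Q,i      (latent)
productivity:  P_i  = gamma_WP * W_i + u_i + zeta_P,i
                      corr(zeta_Q, zeta_P) = rho_QP
indicators:    CP_i = 1      * Q_i + e_i    (loading fixed: sets Q's scale)
               TP_i = lam_TP * Q_i + e_i
               ADF_i= lam_ADF* Q_i + e_i    (expected negative)
utilization:   U_i  = beta_QU * Q_i + beta_PU * P_i + u_i + eps_i
occupancy:     O_i ~ Bernoulli( logit^-1(alpha + beta_WO * W_i
                                          + beta_UO * U_i + u_i) )
```

where `u_i` denotes meadow-in-allotment and year random intercepts
(independent per equation, SDs shared across equations). Priors are
Normal(0, 10²) on coefficients and loadings, half-Normal(0, 1) on SDs,
Uniform(−1, 1) on `rho_QP`. The model is fitted by a Metropolis-within-
Gibbs sampler with conjugate updates for Gaussian blocks, partially
collapsed (latent-quality-integrated) updates for variance parameters,
and a dedicated latent-scale jump move (see the methods vignette).
Exploratory stages use fractional logistic regression (quasi-likelihood
logit for proportion responses, sandwich SEs), linear/quadratic fits with
Box-Cox remediation and AIC selection; model assessment uses the
Brooks-Gelman R-hat, DIC, and leave-one-out ROC/AUC for occupancy.

## Worked example

```r
library(meadowsem)

design <- make_design(list(years = c(2007, 2008)))
truth  <- true_params()                 # beta_UO = 0: no grazing effect
sim    <- simulate_study(design, truth, seed = 42)

composite_meadow_rank(c(6, 6, 6, 0, 0))
#> Composite hydrologic rank: 4 (mean score 3.6 over 5 sites)

sdat <- prepare_sem_data(sim$meadow_years, season = "mid")
fit  <- sample_posterior(sem_spec("mid"), sdat,
                         n_chains = 3, n_iter = 6000, burn_in = 2000,
                         seed = 7)
posterior_summary(fit, c("gamma_wq", "lambda_tp", "beta_wo", "beta_uo"))
#>    parameter       mean        sd      lower      upper     rhat      ess flag
#> 1   gamma_wq -0.6481992 0.1257613 -0.8936352 -0.4011978 1.000436 3564.660   **
#> 2  lambda_tp  0.8243928 0.1227108  0.5957992  1.0858962 1.000509 3157.139   **
#> 3    beta_wo  1.2382636 0.4685011  0.3844234  2.2381192 1.000687 2464.858   **
#> 4    beta_uo -0.3036111 0.3784294 -1.0681825  0.4498510 1.000275 5006.002   NS
```

Read: forage quality declines with wetness (`gamma_wq` < 0, the
generating value was −0.6), total phosphorus loads positively on the
latent quality factor (truth 0.8), wetness drives occupancy (`beta_wo`
significant at the 95% credible level, truth 1.8), and the
utilization→occupancy path — generated as exactly zero — is correctly
flagged not significant (`NS`). Held-out predictive skill:

```r
loo <- loo_cv_occupancy(sem_spec("mid"), sdat, samples = fit, seed = 5)
roc_auc(loo$prob, loo$occupancy)
#> ROC: AUC = 0.713 (27 positive, 21 negative)
```

The whole pipeline (simulate → rank → bivariate → three seasonal SEM
fits → diagnostics → validation → JSON report) runs via

```r
report <- run_pipeline(list(seed = 1, design = list(years = c(2007, 2008)),
                            out_dir = "out"))
```

or from the command line with subcommands
`simulate | rank | bivariate | sem | validate | all`:

```sh
Rscript -e 'meadowsem::cli_main()' all --seed 1 --out out
```

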