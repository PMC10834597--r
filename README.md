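# snbsurv

Individual treatment effects for right-censored survival data with a
self-normalizing balanced survival network (SNB).

## The problem

Observational cohorts — registry extracts, electronic health records —
record which treatment each patient actually received, never the outcome
under the alternative. When the choice of treatment depends on prognosis
(sicker patients are operated on less often), naive arm comparisons are
confounded, and the *average* effect may hide substantial heterogeneity:
surgery that benefits most patients can still harm an identifiable
minority. `snbsurv` estimates, for every patient, counterfactual survival
curves under both treatment options and turns them into an individual
treatment recommendation, then evaluates how much following those
recommendations would have been worth.

## The model

The SNB couples three pieces:

- a **shared representation network** Φ(x): a five-layer self-normalizing
  MLP (SELU activations, alpha-dropout, LeCun-normal initialization),
- two **arm-specific risk networks** h₀(Φ), h₁(Φ): four-layer SNNs with a
  linear log-hazard output, trained only on their own arm's subjects with
  the Cox partial likelihood (Breslow ties),
- a **balancing penalty**: the debiased Sinkhorn (entropic p-Wasserstein)
  divergence between {Φ(xᵢ) : Tᵢ=0} and {Φ(xᵢ) : Tᵢ=1}, which discourages
  the representation from encoding treatment assignment and thereby
  reduces confounding bias in the counterfactual predictions.

The joint loss is

    L = CoxPL₀ + CoxPL₁ + α · S_ε(Φ(X₀), Φ(X₁))

minimized by mini-batch Adam with early stopping (training stops when the
validation loss has not decreased for `patience` = 1000 steps). After
training, per-arm Breslow baseline cumulative hazards H₀⁽ᵃ⁾(t) complete
the individual survival distribution

    S(t | x, T=a) = exp(−H₀⁽ᵃ⁾(t) · exp(h_a(Φ(x)))).

The **time at risk** TaR⁽ᵃ⁾(x) is the earliest time at which
S(t | x, a) falls to 10% (90% mortality), the individual treatment effect
is ITE(x) = TaR⁽¹⁾ − TaR⁽⁰⁾ in months, and treatment is recommended
exactly when ITE > 0.

Recommendation quality is assessed by splitting patients into **Consis.**
(actual treatment equals the recommendation) and **Inconsis.** groups and
contrasting their survival with the multivariate Cox hazard ratio (HR),
the risk difference (RD, percentage points) and the restricted mean
survival time difference (dRMST, months) at a 10-year horizon, each also
in an IPTW-adjusted version (inverse probability weights from a logistic
propensity of consistency-group membership), plus arm-specific IPCW
integrated Brier scores (IBS) of the factual predictions.

Because real registry data cannot be redistributed, the package ships a
**simulator** with a Weibull proportional-hazards ground truth,
confounded ~80/20 treatment assignment, and a covariate-dependent effect
whose closed-form TaR and ITE provide an exact oracle for every
downstream stage.

## Worked example

```r
library(snbsurv)

# a confounded cohort of 5000 patients with known true effects
ch <- simulate_cohort(sim_config(n_subjects = 5000, seed = 11))
ch$data
#> survival_dataset: 5000 subjects, 10 covariates
#>   treated: 3954 (79.1%), events: 4230 (84.6%)

train <- subset_dataset(ch$data, 1:4000)
test  <- subset_dataset(ch$data, 4001:5000)

fit <- snb_fit(train, snb_config(seed = 5))
rec <- recommend_batch(fit, test)
head(rec[, c("tar0", "tar1", "ite", "recommendation")], 3)
#>       tar0     tar1        ite recommendation
#> 1  91.6130 225.5021  133.88912              1
#> 2 145.0924 108.7860  -36.30645              0
#> 3 210.3435 108.7860 -101.55752              0

# how often does the recommended sign match the simulator's truth?
mean(rec$recommendation == (ch$truth$ite[4001:5000] > 0))
#> [1] 0.844

# would following the advice have helped?
evaluate_recommendations(test, rec, model = fit, horizon = 120,
                         bootstrap = 200)
#> Recommendation effect report (horizon 120 months)
#>   n = 1000 (consis 629 / inconsis 371)
#>   HR   : 0.715 (0.608-0.840)
#>   RD   : 7.818 (1.512-14.365) percentage points
#>   dRMST: 9.153 (3.279-14.723) months
#>   log-rank p = 9.221e-05
#>   IPTW-adjusted:
#>     HR   : 0.656 (0.552-0.780)
#>     RD   : 11.586 (4.704-18.530)
#>     dRMST: 13.770 (7.185-20.716)
#>     log-rank p = 6.69e-08
#>   IBS (arm 0): 0.190 (0.171-0.208)
#>   IBS (arm 1): 0.198 (0.190-0.207)
```

The first patient gains an estimated 134 months of time-at-risk from
treatment; the second and third are predicted to do better without it.

A hazard ratio well below 1 says patients whose actual treatment agreed
with the model's recommendation died at a substantially lower rate over
the 10-year horizon; the IPTW-adjusted row repeats the contrast after
reweighting away the measured covariate imbalance between the two groups.

A command-line interface wrapping the same functions is installed at
`inst/cli/snb` (subcommands `simulate`, `fit`, `predict`, `evaluate`).

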