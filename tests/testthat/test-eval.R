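test_that("consistency labels are elementwise equality", {
  expect_true(all(label_consistency(c(1, 0, 1), c(1, 0, 1)) == "consis"))
  expect_true(all(label_consistency(c(1, 0), c(0, 1)) == "inconsis"))
  expect_identical(as.character(label_consistency(c(1, 0, 1), c(1, 1, 1))),
                   c("consis", "inconsis", "consis"))
  expect_error(label_consistency(c(1, 0), c(1, 0, 1)), "length")
})

test_that("IPTW weights are near one without confounding", {
  set.seed(81)
  n <- 20000   # large n so propensity estimation noise is negligible
  X <- matrix(rnorm(n * 3), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  g <- rbinom(n, 1, 0.5)
  w <- iptw_weights(X, g)
  expect_true(all(abs(w$weights - 1) < 0.1))
})

test_that("constant covariate columns are dropped with a warning", {
  set.seed(82)
  X <- cbind(const = 1, z = rnorm(500))
  g <- rbinom(500, 1, plogis(X[, "z"]))
  expect_warning(w <- iptw_weights(X, g), "const")
  expect_true(all(is.finite(w$weights)))
})

test_that("IPTW restores covariate balance on a confounded cohort", {
  ch <- simulate_cohort(sim_config(n_subjects = 5000, seed = 7))
  d <- ch$data
  smd_raw <- standardized_mean_diff(d$X, d$treatment)
  expect_gt(max(smd_raw), 0.1)
  w <- iptw_weights(d$X, d$treatment)
  smd_w <- standardized_mean_diff(d$X, d$treatment, w$weights)
  expect_lt(max(smd_w), 0.1)
})

test_that("weighted Kaplan-Meier matches hand computation and invariances", {
  # deaths at 1,2,3,4, no censoring: S(2) = 3/4 * 2/3 = 1/2
  km <- kaplan_meier(1:4, rep(1, 4))
  expect_equal(snbsurv:::eval_curve(km, 2), 0.5, tolerance = 1e-12)
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0), tolerance = 1e-12)
  # all censored: S = 1 everywhere
  km2 <- kaplan_meier(1:5, rep(0, 5))
  expect_true(all(km2$surv == 1))
  # doubling all weights leaves the curve unchanged
  set.seed(83)
  tt <- rexp(50); ee <- rbinom(50, 1, 0.7)
  kmA <- kaplan_meier(tt, ee, rep(1, 50))
  kmB <- kaplan_meier(tt, ee, rep(2, 50))
  expect_equal(kmA$surv, kmB$surv, tolerance = 1e-12)
  # textbook reference on a small censored dataset
  tt2 <- c(1, 2, 2, 3, 5, 8); ee2 <- c(1, 1, 0, 1, 0, 1)
  km3 <- kaplan_meier(tt2, ee2)
  ref <- km_reference(tt2, ee2)
  expect_equal(km3$surv[km3$time %in% ref$time], ref$surv,
               tolerance = 1e-12)
})

test_that("log-rank test matches survdiff and degenerates correctly", {
  set.seed(84)
  tt <- rexp(80); ee <- rbinom(80, 1, 0.8); gg <- rep(0:1, 40)
  lr <- logrank_test(tt, ee, gg)
  ref <- survival::survdiff(survival::Surv(tt, ee) ~ gg)
  expect_equal(lr$statistic, ref$chisq, tolerance = 1e-9)
  expect_equal(lr$p_value, stats::pchisq(ref$chisq, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  # identical groups duplicated: statistic 0, p 1
  lr0 <- logrank_test(c(tt, tt), c(ee, ee), rep(0:1, each = 80))
  expect_equal(lr0$statistic, 0, tolerance = 1e-9)
  expect_equal(lr0$p_value, 1, tolerance = 1e-9)
  expect_error(logrank_test(tt, rep(0, 80) * ee, gg), "no events")
})

test_that("strong separation is detected with high power", {
  set.seed(85)
  n <- 1000
  g <- rep(0:1, n / 2)
  tt <- rexp(n, 0.05 * ifelse(g == 1, 3, 1))
  lr <- logrank_test(tt, rep(1, n), g)
  expect_lt(lr$p_value, 0.001)
})

test_that("cox_hr recovers a known hazard ratio and covers the null", {
  set.seed(86)
  n <- 2000
  g <- rep(0:1, n / 2)
  tt <- rexp(n, 0.05 * exp(log(0.5) * g))
  fit <- cox_hr(tt, rep(1, n), g)
  expect_gt(fit$hr, 0.42); expect_lt(fit$hr, 0.60)
  expect_true(fit$ci[1] < fit$hr && fit$hr < fit$ci[2])
  # orthogonal indicator: CI covers 1
  g2 <- rbinom(n, 1, 0.5)
  fit2 <- cox_hr(tt, rep(1, n), g2, covariates = cbind(z = rnorm(n)))
  expect_true(fit2$ci[1] < 1 && 1 < fit2$ci[2])
})

test_that("cox_hr agrees with brute-force partial likelihood maximization", {
  # n = 5, single binary covariate: maximize the Breslow partial
  # likelihood on a fine grid as an independent oracle
  tt <- c(2, 4, 3, 1, 5); ee <- c(1, 1, 1, 1, 0); g <- c(1, 0, 1, 0, 1)
  grid <- seq(-4, 4, by = 1e-4)
  pl <- vapply(grid, function(b)
    -coxpl_reference(b * g, tt, ee), numeric(1))
  b_hat <- grid[which.max(pl)]
  fit <- cox_hr(tt, ee, g)
  expect_equal(fit$coef, b_hat, tolerance = 1e-3)
})

test_that("RMST matches closed forms and dRMST conventions", {
  # S = 1 up to tau: RMST = tau
  expect_equal(rmst(survival_curve(1e6, 1), 120), 120, tolerance = 1e-12)
  # exponential on a fine grid: (1 - exp(-lambda tau))/lambda
  tt <- seq(0, 500, by = 0.001)
  cv <- survival_curve(tt, exp(-0.01 * tt))
  expect_equal(rmst(cv, 120), (1 - exp(-0.01 * 120)) / 0.01,
               tolerance = 0.01)
  expect_equal(drmst(cv, cv, 120), 0, tolerance = 1e-12)
  # hand-worked step curve: S=0.8 on [10,20), 0.5 on [20,+)
  sc <- survival_curve(c(10, 20), c(0.8, 0.5))
  expect_equal(rmst(sc, 30), 10 * 1 + 10 * 0.8 + 10 * 0.5,
               tolerance = 1e-12)
})

test_that("risk difference arithmetic and antisymmetry", {
  a <- survival_curve(c(50, 100), c(0.95, 0.9))
  b <- survival_curve(c(50, 100), c(0.9, 0.8))
  expect_equal(risk_difference(a, b, 120), 10, tolerance = 1e-12)
  expect_equal(risk_difference(b, a, 120), -10, tolerance = 1e-12)
  expect_equal(risk_difference(a, a, 120), 0, tolerance = 1e-12)
})

test_that("integrated Brier score reproduces its closed-form cases", {
  set.seed(87)
  n <- 40
  tt <- rexp(n, 0.02); ee <- rep(1, n)
  horizon <- quantile(tt, 0.8)
  # oracle step predictions: S_i = 1 before subject's own death, 0 after
  oracle <- lapply(seq_len(n), function(i)
    survival_curve(c(0, tt[i]), c(1, 0)))
  expect_lt(integrated_brier(oracle, tt, ee, horizon), 1e-10)
  # constant 1/2 prediction, no censoring: BS(t) = 1/4 at every t
  flat <- lapply(seq_len(n), function(i) survival_curve(0, 0.5))
  expect_equal(integrated_brier(flat, tt, ee, horizon), 0.25,
               tolerance = 1e-12)
})

test_that("informative predictions beat permuted predictions on IBS", {
  cfg <- sim_config(n_subjects = 1500, seed = 19)
  ch <- simulate_cohort(cfg)
  tr <- subset_dataset(ch$data, 1:1000)
  te <- subset_dataset(ch$data, 1001:1500)
  fit <- snb_fit(tr, snb_config(shared_widths = c(16, 8),
                                risk_widths = c(8, 1), seed = 2,
                                max_iterations = 400, patience = 400))
  horizon <- 120
  grid <- unique(c(0, sort(unique(te$time[te$event == 1 &
                                            te$time <= horizon])), horizon))
  S <- snbsurv:::factual_survival_matrix(fit, te, grid)
  ibs_fit <- integrated_brier(S, te$time, te$event, horizon, grid = grid)
  set.seed(3)
  perm <- sample(nrow(S))
  ibs_perm <- integrated_brier(S[perm, ], te$time, te$event, horizon,
                               grid = grid)
  expect_lt(ibs_fit, ibs_perm)
})

test_that("T-learner Cox recovers effect signs without confounding", {
  cfg <- sim_config(n_subjects = 5000, propensity_coefs = rep(0, 11),
                    seed = 23)
  ch <- simulate_cohort(cfg)
  tr <- subset_dataset(ch$data, 1:4000)
  te <- subset_dataset(ch$data, 4001:5000)
  tl <- tlearner_cph(tr, te)
  acc <- mean(tl$recommendations$recommendation ==
                as.integer(ch$truth$ite[4001:5000] > 0))
  expect_gte(acc, 0.85)
  # determinism
  tl2 <- tlearner_cph(tr, te)
  expect_identical(tl$recommendations, tl2$recommendations)
})

test_that("T-learner under a null effect recommends near 50/50 on average", {
  # With no true effect, a single training realization still carries a
  # cohort-wide ITE offset (between-arm sampling noise in the baseline
  # hazards shifts every subject together), so the 50/50 behaviour is a
  # property of the average over training realizations.
  fracs <- vapply(1:6, function(r) {
    cfg <- sim_config(n_subjects = 3000, propensity_coefs = rep(0, 11),
                      effect_coefs = rep(0, 10), seed = 29 + r)
    ch <- simulate_cohort(cfg)
    tr <- subset_dataset(ch$data, 1:2000)
    te <- subset_dataset(ch$data, 2001:3000)
    tl <- tlearner_cph(tr, te)
    # median |ITE| stays small relative to the overall TaR scale
    expect_lt(median(abs(tl$recommendations$ite)),
              0.2 * median(tl$recommendations$tar0))
    mean(tl$recommendations$recommendation)
  }, numeric(1))
  expect_gt(mean(fracs), 0.3); expect_lt(mean(fracs), 0.7)
})

test_that("rule recommender applies first-match semantics", {
  X <- matrix(c(-1, 2, 0.5, 1, 1, 1), ncol = 2,
              dimnames = list(NULL, c("x1", "x2")))
  expect_identical(rule_recommender(list(list(when = "TRUE", treat = 1)), X),
                   c(1L, 1L, 1L))
  rec <- rule_recommender(list(list(when = "x1 > 0", treat = 1),
                               list(when = "x1 <= 0", treat = 0)), X)
  expect_identical(rec, c(0L, 1L, 1L))
  expect_error(rule_recommender(list(list(when = "x1 > 10", treat = 1)), X),
               "no rule matched")
})

test_that("unit weights reproduce the unadjusted metrics exactly", {
  ch <- simulate_cohort(sim_config(n_subjects = 800, seed = 31))
  d <- ch$data
  rec <- as.integer(ch$truth$ite > 0)
  rep_w1 <- evaluate_recommendations(d, rec, weights = rep(1, 800),
                                     bootstrap = 0)
  expect_equal(rep_w1$hr_iptw, rep_w1$hr, tolerance = 1e-9)
  expect_equal(rep_w1$rd_iptw, rep_w1$rd, tolerance = 1e-12)
  expect_equal(rep_w1$drmst_iptw, rep_w1$drmst, tolerance = 1e-12)
  expect_equal(rep_w1$logrank_p_iptw, rep_w1$logrank_p, tolerance = 1e-12)
})

test_that("bootstrap intervals bracket the point estimates", {
  ch <- simulate_cohort(sim_config(n_subjects = 600, seed = 37))
  d <- ch$data
  rec <- as.integer(ch$truth$ite > 0)
  rp <- evaluate_recommendations(d, rec, bootstrap = 60, seed = 5)
  expect_true(rp$rd_ci[1] <= rp$rd && rp$rd <= rp$rd_ci[2])
  expect_true(rp$drmst_ci[1] <= rp$drmst && rp$drmst <= rp$drmst_ci[2])
  expect_true(rp$hr_ci[1] < rp$hr && rp$hr < rp$hr_ci[2])
})

test_that("evaluation is invariant to subject ordering", {
  ch <- simulate_cohort(sim_config(n_subjects = 500, seed = 41))
  d <- ch$data
  rec <- as.integer(ch$truth$ite > 0)
  r1 <- evaluate_recommendations(d, rec, bootstrap = 0)
  set.seed(9); perm <- sample(500)
  d2 <- subset_dataset(d, perm)
  r2 <- evaluate_recommendations(d2, rec[perm], bootstrap = 0)
  for (field in c("hr", "rd", "drmst", "logrank_p", "rd_iptw",
                  "drmst_iptw")) {
    expect_equal(r1[[field]], r2[[field]], tolerance = 1e-6, label = field)
  }
})

test_that("feature ablation: empty group is a no-op, signal beats noise", {
  cfg <- sim_config(n_subjects = 900, n_continuous = 3, n_categorical = 0,
                    propensity_coefs = c(1.2, 0.4, 0, 0),
                    main_coefs = c(1.2, 0, 0), effect_coefs = c(-0.5, 0, 0),
                    seed = 43)
  ch <- simulate_cohort(cfg)
  tr <- subset_dataset(ch$data, 1:600)
  te <- subset_dataset(ch$data, 601:900)
  mcfg <- snb_config(shared_widths = c(8, 4), risk_widths = c(4, 1),
                     max_iterations = 150, patience = 150, seed = 6)
  tab <- feature_ablation(tr, te, mcfg,
                          list(none = character(),
                               noise = "x3",
                               signal = "x1"))
  expect_equal(tab$delta_ibs[tab$group == "none"], 0, tolerance = 1e-12)
  expect_lt(abs(tab$delta_ibs[tab$group == "noise"]), 0.01)
  expect_gt(tab$delta_ibs[tab$group == "signal"], 0)
  expect_gt(tab$delta_ibs[tab$group == "signal"],
            tab$delta_ibs[tab$group == "noise"])
  expect_error(feature_ablation(tr, te, mcfg, list(bad = "nope")),
               "unknown columns")
})
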