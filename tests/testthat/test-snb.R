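test_that("early stopping fires exactly `patience` steps after the last improvement", {
  # strictly improving: runs to the end of the trace
  tr <- rev(seq_len(5000)) / 1000
  es <- early_stop_iteration(tr, patience = 1000)
  expect_identical(es$stop_iteration, 5000L)
  expect_identical(es$best_iteration, 5000L)
  # constant from iteration k: stops at k + patience
  k <- 37
  tr2 <- c(rev(seq_len(k)), rep(1, 3000))
  es2 <- early_stop_iteration(tr2, patience = 1000)
  expect_identical(es2$stop_iteration, as.integer(k + 1000))
  expect_identical(es2$best_iteration, as.integer(k))
  # a late improvement resets the counter
  tr3 <- c(5, 4, 3, rep(3, 10), 2.9, rep(3, 50))
  es3 <- early_stop_iteration(tr3, patience = 20)
  expect_identical(es3$stop_iteration, es3$best_iteration + 20L)
})

test_that("snb_fit's training loop obeys the stopping rule", {
  d <- tiny_dataset(n = 80, seed = 31)
  cfg <- tiny_config(max_iterations = 40, patience = 10, seed = 3)
  fit <- snb_fit(d, cfg)
  expect_true(fit$log$stopped_at <= 40)
  if (fit$log$stopped_at < 40) {
    expect_identical(fit$log$stopped_at - fit$log$best_iteration,
                     cfg$patience)
  }
  # the trace is finite everywhere
  expect_true(all(is.finite(fit$log$trace$train_loss)))
  expect_true(all(is.finite(fit$log$trace$val_loss)))
})

test_that("with zero balance weight the loss is the sum of arm-wise Cox losses", {
  set.seed(32)
  d <- tiny_dataset(n = 50, seed = 32, p = 3)
  cfg <- snb_config(shared_widths = c(5, 4), risk_widths = c(3, 1),
                    balance_weight = 0, dropout_rate = 0)
  model <- snbsurv:::init_snb_params(3, cfg)
  X <- d$X
  total <- snb_loss(model, X, d$treatment, d$time, d$event, cfg)
  Z <- mlp_forward(model$shared, X)
  manual <- 0
  for (arm in 0:1) {
    idx <- which(d$treatment == arm)
    s <- drop(mlp_forward(model[[paste0("risk", arm)]],
                          Z[idx, , drop = FALSE]))
    manual <- manual + cox_partial_loglik(s, d$time[idx], d$event[idx])
  }
  expect_equal(total, manual, tolerance = 1e-12)
})

test_that("an arm without events contributes zero with a warning", {
  d <- tiny_dataset(n = 40, seed = 33)
  d$event[d$treatment == 1] <- 0
  cfg <- snb_config(shared_widths = c(4), risk_widths = c(1),
                    balance_weight = 0, dropout_rate = 0)
  model <- snbsurv:::init_snb_params(2, cfg)
  expect_warning(
    v <- snb_loss(model, d$X, d$treatment, d$time, d$event, cfg),
    "no events")
  idx <- which(d$treatment == 0)
  Z <- mlp_forward(model$shared, d$X)
  s <- drop(mlp_forward(model$risk0, Z[idx, , drop = FALSE]))
  expect_equal(v, cox_partial_loglik(s, d$time[idx], d$event[idx]),
               tolerance = 1e-12)
})

test_that("a single-arm batch skips the balancing term with a warning", {
  d <- tiny_dataset(n = 40, seed = 34)
  idx <- which(d$treatment == 0)
  d1 <- subset_dataset(d, idx)
  cfg <- snb_config(shared_widths = c(4), risk_widths = c(1),
                    balance_weight = 1, dropout_rate = 0)
  model <- snbsurv:::init_snb_params(2, cfg)
  expect_warning(
    snb_loss(model, d1$X, d1$treatment, d1$time, d1$event, cfg),
    "single-arm")
})

test_that("full loss gradients match numerical differentiation", {
  set.seed(35)
  n <- 25; p <- 3
  X <- matrix(rnorm(n * p), n, p)
  trt <- rep(0:1, length.out = n)
  tm <- rexp(n); ev <- rbinom(n, 1, 0.8); ev[1:2] <- 1
  cfg <- snb_config(shared_widths = c(4, 3), risk_widths = c(3, 1),
                    dropout_rate = 0, balance_weight = 0.5,
                    sinkhorn_epsilon = 0.5)
  model <- snbsurv:::init_snb_params(p, cfg)
  lg <- snb_loss(model, X, trt, tm, ev, cfg, gradient = TRUE, warn = FALSE)
  params <- snbsurv:::collect_params(model)
  for (nm in names(params)) {
    k <- 1  # first element of every tensor
    h <- 1e-6
    p2 <- params; p2[[nm]][k] <- p2[[nm]][k] + h
    m2 <- snbsurv:::apply_params(model, p2)
    num <- (snb_loss(m2, X, trt, tm, ev, cfg, warn = FALSE) - lg$value) / h
    expect_equal(lg$grads[[nm]][k], num, tolerance = 1e-3,
                 label = paste("grad", nm))
  }
})

test_that("a linear single-layer model recovers Cox coefficients", {
  cfg <- sim_config(n_subjects = 2000, n_continuous = 3, n_categorical = 0,
                    propensity_coefs = c(0, 0, 0, 0),
                    main_coefs = c(0.5, -0.4, 0.3),
                    effect_coefs = c(0, 0, 0), censor_rate = 0,
                    admin_horizon = 1e6, seed = 7)
  ch <- simulate_cohort(cfg)
  scfg <- snb_config(shared_widths = integer(0), risk_widths = 1,
                     dropout_rate = 0, balance_weight = 0,
                     learning_rate = 0.05, batch_size = Inf,
                     max_iterations = 2000, patience = 500, seed = 2)
  fit <- snb_fit(ch$data, scfg)
  for (arm in 0:1) {
    idx <- ch$data$treatment == arm
    ref <- survival::coxph(
      survival::Surv(ch$data$time[idx], ch$data$event[idx]) ~
        ch$data$X[idx, ], ties = "breslow")
    W <- drop(fit[[paste0("risk", arm)]]$layers[[1]]$W) /
      fit$standardizer$scale
    expect_lt(max(abs(W - coef(ref))), 0.1)
  }
})

test_that("fitting is deterministic given the seed", {
  d <- tiny_dataset(n = 70, seed = 36, p = 3)
  cfg <- tiny_config(seed = 9, max_iterations = 30, patience = 30)
  f1 <- snb_fit(d, cfg)
  f2 <- snb_fit(d, cfg)
  expect_identical(snbsurv:::collect_params(f1),
                   snbsurv:::collect_params(f2))
  expect_identical(f1$baseline0, f2$baseline0)
})

test_that("tuning returns the grid argmin with first-wins tie-break", {
  d <- tiny_dataset(n = 80, seed = 37, p = 3)
  base <- tiny_config(seed = 4, max_iterations = 15, patience = 15,
                      cv_folds = 2)
  # one grid point: returned as-is
  g1 <- snb_tune(d, list(list(learning_rate = 0.02)), base)
  expect_equal(g1$learning_rate, 0.02)
  # two identical points: the first wins
  g2 <- snb_tune(d, list(list(learning_rate = 0.02),
                         list(learning_rate = 0.02)), base)
  losses <- attr(g2, "cv_losses")
  expect_equal(losses[1], losses[2], tolerance = 1e-10)
  expect_equal(g2$learning_rate, 0.02)
  expect_error(snb_tune(d, list(), base), "empty")
})

test_that("non-finite losses abort with a learning-rate hint", {
  d <- tiny_dataset(n = 60, seed = 38)
  cfg <- tiny_config(learning_rate = 1e6, max_iterations = 200,
                     patience = 200, seed = 1)
  expect_error(snb_fit(d, cfg), "learning_rate")
})
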