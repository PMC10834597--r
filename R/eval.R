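#' Recommendation-effect evaluation
#'
#' Machinery for the consistency analysis: patients are split into the
#' recommended ("consis") and anti-recommended ("inconsis") groups
#' according to whether their actual treatment matches the model's
#' recommendation, and the two groups are contrasted with Kaplan-Meier
#' curves, weighted log-rank tests, multivariate Cox hazard ratios, risk
#' differences and restricted-mean-survival-time differences at a fixed
#' horizon (default 10 years), both unadjusted and reweighted by inverse
#' probability of treatment weighting. Arm-specific IPCW integrated Brier
#' scores measure calibration of the factual predictions.
#'
#' @name recommendation-eval
NULL

#' Label recommendation consistency
#'
#' @param actual Binary vector of treatments actually received.
#' @param recommended Binary vector of recommended treatments.
#' @return Factor with levels `consis`, `inconsis`.
#' @export
label_consistency <- function(actual, recommended) {
  if (length(actual) != length(recommended)) {
    stop("actual and recommended treatment vectors differ in length")
  }
  factor(ifelse(actual == recommended, "consis", "inconsis"),
         levels = c("consis", "inconsis"))
}

#' Inverse probability of treatment weights
#'
#' Logistic-regression propensity of group membership given covariates;
#' the weight is `g/e(x) + (1-g)/(1-e(x))`, optionally stabilized by the
#' marginal group probabilities and truncated at the stated weight
#' quantiles (a guard against positivity violations). Constant covariate
#' columns are dropped with a warning.
#'
#' @param X Covariate matrix.
#' @param group Binary group vector (both groups non-empty).
#' @param stabilize Multiply by marginal group probabilities.
#' @param truncate Length-2 quantile pair for weight truncation, or
#'   `NULL` for none.
#' @return An `iptw_weights` object: list with `weights`, `propensity`,
#'   `stabilized`, `truncation`.
#' @export
iptw_weights <- function(X, group, stabilize = TRUE,
                         truncate = c(0.01, 0.99)) {
  X <- as.matrix(X)
  group <- as.numeric(group)
  if (length(unique(group)) < 2) stop("both groups must be non-empty")
  keep <- apply(X, 2, function(v) stats::var(v) > 0)
  if (any(!keep)) {
    warning("dropping constant covariate columns: ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  df <- data.frame(group = group, X)
  fit <- suppressWarnings(
    stats::glm(group ~ ., data = df, family = stats::binomial())
  )
  e <- stats::fitted(fit)
  if (any(e < 1e-10) || any(e > 1 - 1e-10)) {
    stop("propensity model separates the groups (fitted probabilities of ",
         "0 or 1); IPTW weights are not identifiable")
  }
  w <- group / e + (1 - group) / (1 - e)
  if (stabilize) {
    pg <- mean(group)
    w <- w * ifelse(group == 1, pg, 1 - pg)
  }
  if (!is.null(truncate)) {
    qs <- stats::quantile(w, truncate)
    w <- pmin(pmax(w, qs[1]), qs[2])
  }
  structure(list(weights = unname(w), propensity = unname(e),
                 stabilized = stabilize, truncation = truncate),
            class = "iptw_weights")
}

#' Weighted Kaplan-Meier estimator
#'
#' Weighted product-limit estimator of the survival function (computed
#' via [survival::survfit()]); with unit weights this is the usual
#' Kaplan-Meier curve. Invariant to rescaling all weights by a constant.
#'
#' @param time Follow-up times.
#' @param event Event indicators.
#' @param weights Optional nonnegative weights (default all 1).
#' @return A [survival_curve()].
#' @export
kaplan_meier <- function(time, event, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(time))
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (sum(weights) == 0) stop("all weights are zero")
  df <- data.frame(time = time, event = event, w = weights)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df,
                           weights = w)
  survival_curve(fit$time, fit$surv)
}

#' Weighted log-rank test
#'
#' Two-group (1 df) log-rank test; with weights the at-risk and event
#' counts are replaced by their weighted versions, the standard plug-in
#' used for IPTW-adjusted survival comparisons. Both groups must contain
#' events.
#'
#' @param time Follow-up times.
#' @param event Event indicators.
#' @param group Binary group membership.
#' @param weights Optional nonnegative weights.
#' @return List with `statistic` (chi-square, 1 df) and `p_value`.
#' @export
logrank_test <- function(time, event, group, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(time))
  group <- as.numeric(group)
  for (g in c(0, 1)) {
    if (sum(event[group == g]) == 0) {
      stop(sprintf("group %d has no events: log-rank p is undefined", g))
    }
  }
  ev_times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ev_times) {
    at <- time >= t
    Y <- sum(weights[at])
    Y1 <- sum(weights[at & group == 1])
    dt <- weights * event * (time == t)
    d <- sum(dt)
    d1 <- sum(dt[group == 1])
    if (Y <= 0 || d == 0) next
    O1 <- O1 + d1
    E1 <- E1 + d * Y1 / Y
    if (Y > 1) {
      V <- V + d * (Y1 / Y) * (1 - Y1 / Y) * (Y - d) / (Y - 1)
    }
  }
  if (V <= 0) {
    return(list(statistic = 0, p_value = 1))
  }
  chi <- (O1 - E1)^2 / V
  list(statistic = chi, p_value = stats::pchisq(chi, df = 1,
                                                lower.tail = FALSE))
}

#' Multivariate Cox hazard ratio for a group indicator
#'
#' Weighted Cox regression (Breslow ties) of survival on the group
#' indicator plus adjustment covariates, via [survival::coxph()]. The
#' reported hazard ratio is `exp` of the group coefficient; with
#' non-unit weights the confidence interval uses the robust (sandwich)
#' variance.
#'
#' @param time Follow-up times.
#' @param event Event indicators.
#' @param group Binary indicator whose hazard ratio is reported.
#' @param covariates Optional adjustment covariate matrix.
#' @param weights Optional nonnegative weights.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `hr`, `ci` (length 2), `coef`, `se`, `p_value`.
#' @export
cox_hr <- function(time, event, group, covariates = NULL, weights = NULL,
                   conf_level = 0.95) {
  df <- data.frame(time = time, event = event, group = as.numeric(group))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- apply(covariates, 2, function(v) stats::var(v) > 0)
    df <- cbind(df, as.data.frame(covariates[, keep, drop = FALSE]))
  }
  robust <- !is.null(weights) && any(weights != 1)
  if (is.null(weights)) weights <- rep(1, nrow(df))
  df$.w <- weights
  covnames <- setdiff(names(df), c("time", "event", ".w"))
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covnames, collapse = " + ")))
  fit <- suppressWarnings(
    survival::coxph(fml, data = df, weights = .w, ties = "breslow",
                    robust = robust,
                    control = survival::coxph.control(iter.max = 100)))
  if (any(is.na(stats::coef(fit)["group"]))) {
    stop("Cox fit failed for the group indicator")
  }
  co <- stats::coef(fit)["group"]
  # fit$var is the robust (sandwich) variance when robust = TRUE
  gi <- which(names(stats::coef(fit)) == "group")
  se <- sqrt(diag(as.matrix(fit$var)))[gi]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(hr = unname(exp(co)),
       ci = unname(exp(co + c(-1, 1) * z * se)),
       coef = unname(co), se = unname(se),
       p_value = unname(2 * stats::pnorm(-abs(co / se))))
}

#' Restricted mean survival time of a step curve
#'
#' Area under the right-continuous survival step function on `[0, tau]`,
#' with survival 1 before the curve's first time and the last value
#' carried forward beyond its final time.
#'
#' @param curve A [survival_curve()].
#' @param tau Horizon in months (> 0).
#' @return Months.
#' @export
rmst <- function(curve, tau) {
  stopifnot(tau > 0)
  tt <- c(0, curve$time[curve$time < tau], tau)
  ss <- c(1, curve$surv[curve$time < tau])
  sum(ss * diff(tt))
}

#' Difference in restricted mean survival time
#'
#' `rmst(curve_a, tau) - rmst(curve_b, tau)`; by convention `curve_a` is
#' the consistency (recommended) group, so positive values mean the
#' recommended group lives longer on average over the horizon.
#'
#' @param curve_a,curve_b [survival_curve()] objects.
#' @param tau Horizon in months.
#' @return Months.
#' @export
drmst <- function(curve_a, curve_b, tau) {
  rmst(curve_a, tau) - rmst(curve_b, tau)
}

#' Risk difference at a horizon
#'
#' `100 * [(1 - S_b(h)) - (1 - S_a(h))]` in percentage points; positive
#' values mean lower mortality in group A (the recommended group, by
#' convention). Curves are evaluated by the right-continuous step rule,
#' carrying the last value beyond the final step.
#'
#' @param curve_a,curve_b [survival_curve()] objects.
#' @param horizon Months.
#' @return Percentage points.
#' @export
risk_difference <- function(curve_a, curve_b, horizon) {
  100 * (eval_curve(curve_a, horizon) - eval_curve(curve_b, horizon))
}

#' IPCW integrated Brier score
#'
#' Inverse-probability-of-censoring-weighted Brier score
#' `BS(t)`, integrated over `[0, horizon]` by the trapezoidal rule and
#' normalized by the horizon. The censoring survival distribution `G` is
#' the Kaplan-Meier estimator of the censoring times; event terms are
#' weighted by `1/G(T_i-)` and at-risk terms by `1/G(t)`.
#'
#' @param curves List of per-subject predicted [survival_curve()]s, or a
#'   matrix of survival probabilities (subjects x grid times).
#' @param time Observed follow-up times.
#' @param event Event indicators.
#' @param horizon Integration horizon (months); must not exceed the time
#'   at which the censoring distribution vanishes.
#' @param grid Evaluation grid when `curves` is a matrix (defaults to the
#'   observed event times up to the horizon).
#' @return The integrated Brier score in `[0, 1]`.
#' @export
integrated_brier <- function(curves, time, event, horizon, grid = NULL) {
  n <- length(time)
  horizon <- unname(horizon)
  if (is.null(grid)) {
    grid <- sort(unique(c(time[event == 1 & time <= horizon], horizon)))
    grid <- grid[grid <= horizon]
    if (length(grid) == 0 || max(grid) < horizon) grid <- c(grid, horizon)
    grid <- unique(c(0, grid))
  }
  S <- if (is.matrix(curves)) {
    if (ncol(curves) != length(grid)) {
      stop("prediction matrix must have one column per grid time")
    }
    curves
  } else {
    t(vapply(curves, function(cv) eval_curve(cv, grid),
             numeric(length(grid))))
  }
  stopifnot(nrow(S) == n)

  # censoring KM (left limit for event terms)
  cens_fit <- kaplan_meier(time, 1 - event)
  G_at <- function(t) eval_curve(cens_fit, t)
  G_minus <- function(t) {
    idx <- findInterval(t - 1e-9, cens_fit$time)
    c(1, cens_fit$surv)[idx + 1]
  }
  Gt <- G_at(grid)
  Gi_minus <- G_minus(time)
  if (any(Gt[grid < horizon] <= 0) || G_at(horizon) <= 0) {
    stop("censoring distribution reaches 0 before the horizon; ",
         "use a smaller horizon")
  }
  died <- event == 1
  if (any(died & time <= horizon & Gi_minus <= 0)) {
    stop("censoring distribution vanishes before an event time; ",
         "use a smaller horizon")
  }

  bs <- vapply(seq_along(grid), function(k) {
    t <- grid[k]
    s <- S[, k]
    w_event <- as.numeric(died & time <= t) / ifelse(Gi_minus > 0, Gi_minus, 1)
    w_alive <- as.numeric(time > t) / Gt[k]
    mean(w_event * s^2 + w_alive * (1 - s)^2)
  }, numeric(1))
  sum((bs[-1] + bs[-length(bs)]) / 2 * diff(grid)) / horizon
}

# Factual predicted survival matrix for a dataset on a fixed grid.
factual_survival_matrix <- function(model, data, grid) {
  S <- matrix(NA_real_, nrow(data$X), length(grid))
  for (arm in c(0, 1)) {
    idx <- which(data$treatment == arm)
    if (length(idx) == 0) next
    s <- snb_scores_generic(model, data$X[idx, , drop = FALSE], arm)
    bh <- baseline_of(model, arm)
    H <- eval_baseline(bh, grid)
    S[idx, ] <- exp(-outer(exp(s), H))
  }
  S
}

# Dispatch helpers shared by the SNB and T-learner comparators.
snb_scores_generic <- function(model, X, arm) {
  if (inherits(model, "snb")) {
    snb_scores(model, X, arm)
  } else if (inherits(model, "tlearner_cph")) {
    drop(X[, names(model$coefs[[arm + 1]]), drop = FALSE] %*%
           model$coefs[[arm + 1]])
  } else {
    stop("unsupported model class")
  }
}

baseline_of <- function(model, arm) {
  if (inherits(model, "snb")) {
    if (arm == 0) model$baseline0 else model$baseline1
  } else {
    model$baselines[[arm + 1]]
  }
}

#' T-learner Cox proportional-hazards comparator
#'
#' Fits one (linear) Cox model per treatment arm on the training data,
#' estimates each arm's Breslow baseline hazard, and then derives
#' counterfactual survival curves, times-at-risk, ITEs and
#' recommendations through exactly the same machinery as the SNB. Fully
#' deterministic.
#'
#' @param train Training [survival_dataset()]; both arms need events.
#' @param test Dataset (or covariate matrix) to score.
#' @param mortality_threshold Mortality fraction defining TaR.
#' @return A list with `fit` (class `tlearner_cph`) and `recommendations`
#'   (the [recommend_batch()]-style table for `test`).
#' @export
tlearner_cph <- function(train, test, mortality_threshold = 0.90) {
  coefs <- list()
  baselines <- list()
  for (arm in c(0, 1)) {
    idx <- which(train$treatment == arm)
    if (sum(train$event[idx]) == 0) {
      stop(sprintf("arm %d has no events in the training data", arm))
    }
    X <- train$X[idx, , drop = FALSE]
    keep <- apply(X, 2, function(v) stats::var(v) > 0)
    df <- data.frame(X[, keep, drop = FALSE])
    df$time <- train$time[idx]
    df$event <- train$event[idx]
    cfit <- survival::coxph(survival::Surv(time, event) ~ . , data = df,
                            ties = "breslow")
    beta <- stats::coef(cfit)
    beta[is.na(beta)] <- 0
    scores <- drop(as.matrix(df[, names(beta), drop = FALSE]) %*% beta)
    coefs[[arm + 1]] <- beta
    baselines[[arm + 1]] <- breslow_baseline(scores, train$time[idx],
                                             train$event[idx])
  }
  fit <- structure(list(coefs = coefs, baselines = baselines),
                   class = "tlearner_cph")
  X_test <- if (inherits(test, "survival_dataset")) test$X else as.matrix(test)
  target_h <- log(1 / (1 - mortality_threshold))
  out <- list()
  for (arm in c(0, 1)) {
    s <- snb_scores_generic(fit, X_test, arm)
    bh <- baselines[[arm + 1]]
    need <- target_h * exp(-s)
    pos <- findInterval(need - 1e-12, bh$hazard) + 1
    capped <- pos > length(bh$time)
    tar <- ifelse(capped, bh$time[length(bh$time)],
                  bh$time[pmin(pos, length(bh$time))])
    out[[arm + 1]] <- list(tar = tar, capped = capped)
  }
  ite <- out[[2]]$tar - out[[1]]$tar
  rec <- data.frame(id = seq_len(nrow(X_test)),
                    tar0 = out[[1]]$tar, tar1 = out[[2]]$tar, ite = ite,
                    capped0 = out[[1]]$capped, capped1 = out[[2]]$capped,
                    recommendation = as.integer(ite > 0))
  list(fit = fit, recommendations = rec)
}

#' Rule-based recommender (guideline comparator interface)
#'
#' Applies a declarative list of rules, each a covariate predicate (an R
#' expression over the covariate columns) with a recommended treatment;
#' the first matching rule wins. Enables guideline-versus-model
#' comparisons through the same evaluation pipeline.
#'
#' @param rules List of `list(when = "<expression>", treat = 0 or 1)`.
#' @param X Covariate matrix (columns referenced by the predicates).
#' @return Integer vector of recommendations.
#' @export
rule_recommender <- function(rules, X) {
  df <- as.data.frame(X)
  n <- nrow(df)
  rec <- rep(NA_integer_, n)
  for (rule in rules) {
    hit <- eval(parse(text = rule$when), envir = df)
    hit <- rep_len(as.logical(hit), n)
    apply_to <- is.na(rec) & hit & !is.na(hit)
    rec[apply_to] <- as.integer(rule$treat)
  }
  if (anyNA(rec)) {
    stop("no rule matched subjects: ",
         paste(utils::head(which(is.na(rec)), 20), collapse = ", "))
  }
  rec
}

#' Evaluate treatment recommendations
#'
#' Assembles the full recommendation-effect report for a dataset and a
#' vector of recommendations: consistency labelling, unadjusted and
#' IPTW-adjusted Kaplan-Meier contrasts (hazard ratio, risk difference,
#' restricted-mean-survival-time difference, log-rank), and, when a model
#' is supplied, arm-specific IPCW integrated Brier scores of its factual
#' predictions. Percentile-bootstrap confidence intervals (resampling
#' subjects) are attached to RD, dRMST and IBS; the hazard-ratio interval
#' is model-based (robust sandwich when weighted).
#'
#' @param data A [survival_dataset()].
#' @param recommendations Binary vector, or a [recommend_batch()] table.
#' @param model Optional fitted `snb` or `tlearner_cph` object (enables
#'   the IBS block).
#' @param horizon Evaluation horizon in months (default 120, i.e. 10
#'   years).
#' @param iptw Compute IPTW-adjusted versions (propensity of consistency
#'   given covariates).
#' @param weights Optional explicit weights to use instead of estimated
#'   IPTW weights.
#' @param bootstrap Number of bootstrap replicates for the percentile
#'   intervals (0 disables).
#' @param conf_level Confidence level.
#' @param seed Seed for the bootstrap resampling.
#' @return A `recommendation_report` list.
#' @export
evaluate_recommendations <- function(data, recommendations, model = NULL,
                                     horizon = 120, iptw = TRUE,
                                     weights = NULL, bootstrap = 200,
                                     conf_level = 0.95, seed = 1L) {
  stopifnot(inherits(data, "survival_dataset"), horizon > 0)
  if (is.data.frame(recommendations)) {
    recommendations <- recommendations$recommendation
  }
  n <- nrow(data$X)
  stopifnot(length(recommendations) == n)
  consis <- as.integer(data$treatment == recommendations)
  if (length(unique(consis)) < 2) {
    stop("all subjects fall in a single consistency group")
  }

  w <- NULL
  if (iptw) {
    w <- if (!is.null(weights)) weights else
      iptw_weights(data$X, consis)$weights
  }

  point <- function(idx, use_w) {
    ww <- if (is.null(use_w)) NULL else use_w[idx]
    g <- consis[idx]
    km_c <- kaplan_meier(data$time[idx][g == 1], data$event[idx][g == 1],
                         if (is.null(ww)) NULL else ww[g == 1])
    km_i <- kaplan_meier(data$time[idx][g == 0], data$event[idx][g == 0],
                         if (is.null(ww)) NULL else ww[g == 0])
    c(rd = risk_difference(km_c, km_i, horizon),
      drmst = drmst(km_c, km_i, horizon))
  }

  full_idx <- seq_len(n)
  est <- point(full_idx, NULL)
  hr_fit <- cox_hr(data$time, data$event, consis, covariates = data$X)
  lr <- logrank_test(data$time, data$event, consis)

  report <- list(
    horizon = horizon,
    n = n,
    n_consis = sum(consis), n_inconsis = sum(1 - consis),
    hr = hr_fit$hr, hr_ci = hr_fit$ci,
    rd = unname(est["rd"]), drmst = unname(est["drmst"]),
    logrank_p = lr$p_value
  )

  if (iptw) {
    est_w <- point(full_idx, w)
    hr_w <- cox_hr(data$time, data$event, consis, covariates = data$X,
                   weights = w)
    lr_w <- logrank_test(data$time, data$event, consis, weights = w)
    report$hr_iptw <- hr_w$hr
    report$hr_iptw_ci <- hr_w$ci
    report$rd_iptw <- unname(est_w["rd"])
    report$drmst_iptw <- unname(est_w["drmst"])
    report$logrank_p_iptw <- lr_w$p_value
    report$weights <- w
  }

  # arm-specific IPCW integrated Brier scores of factual predictions
  grid <- unique(c(0, sort(unique(
    data$time[data$event == 1 & data$time <= horizon])), horizon))
  S <- NULL
  if (!is.null(model)) {
    S <- factual_survival_matrix(model, data, grid)
    for (arm in c(0, 1)) {
      idx <- which(data$treatment == arm)
      if (length(idx) == 0) next
      report[[paste0("ibs_arm", arm)]] <-
        integrated_brier(S[idx, , drop = FALSE], data$time[idx],
                         data$event[idx], horizon, grid = grid)
    }
  }

  if (bootstrap > 0) {
    old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
    on.exit(restore_seed(old_seed), add = TRUE)
    set.seed(seed)
    boots <- replicate(bootstrap, {
      idx <- sample.int(n, n, replace = TRUE)
      out <- point(idx, NULL)
      if (iptw) {
        # weights are re-estimated inside each bootstrap replicate
        wb <- tryCatch(
          if (!is.null(weights)) weights[idx] else
            iptw_weights(data$X[idx, , drop = FALSE], consis[idx])$weights,
          error = function(e) NULL)
        out <- c(out, if (is.null(wb)) {
          c(rd_iptw = NA_real_, drmst_iptw = NA_real_)
        } else {
          g <- consis[idx]
          km_c <- kaplan_meier(data$time[idx][g == 1],
                               data$event[idx][g == 1], wb[g == 1])
          km_i <- kaplan_meier(data$time[idx][g == 0],
                               data$event[idx][g == 0], wb[g == 0])
          c(rd_iptw = risk_difference(km_c, km_i, horizon),
            drmst_iptw = drmst(km_c, km_i, horizon))
        })
      }
      if (!is.null(S)) {
        for (arm in c(0, 1)) {
          sub <- idx[data$treatment[idx] == arm]
          out[paste0("ibs_arm", arm)] <- if (length(sub) > 1 &&
                                             sum(data$event[sub]) > 0) {
            tryCatch(integrated_brier(S[sub, , drop = FALSE],
                                      data$time[sub], data$event[sub],
                                      horizon, grid = grid),
                     error = function(e) NA_real_)
          } else NA_real_
        }
      }
      out
    })
    alpha <- (1 - conf_level) / 2
    cis <- apply(boots, 1, stats::quantile, probs = c(alpha, 1 - alpha),
                 na.rm = TRUE)
    for (nm in rownames(boots)) {
      report[[paste0(nm, "_ci")]] <- unname(cis[, nm])
    }
  }

  structure(report, class = "recommendation_report")
}

#' @export
print.recommendation_report <- function(x, ...) {
  fmt_ci <- function(v, ci) {
    if (is.null(ci)) sprintf("%.3f", v) else
      sprintf("%.3f (%.3f-%.3f)", v, ci[1], ci[2])
  }
  cat(sprintf("Recommendation effect report (horizon %g months)\n",
              x$horizon))
  cat(sprintf("  n = %d (consis %d / inconsis %d)\n", x$n, x$n_consis,
              x$n_inconsis))
  cat("  HR   : ", fmt_ci(x$hr, x$hr_ci), "\n", sep = "")
  cat("  RD   : ", fmt_ci(x$rd, x$rd_ci), " percentage points\n", sep = "")
  cat("  dRMST: ", fmt_ci(x$drmst, x$drmst_ci), " months\n", sep = "")
  cat(sprintf("  log-rank p = %.4g\n", x$logrank_p))
  if (!is.null(x$hr_iptw)) {
    cat("  IPTW-adjusted:\n")
    cat("    HR   : ", fmt_ci(x$hr_iptw, x$hr_iptw_ci), "\n", sep = "")
    cat("    RD   : ", fmt_ci(x$rd_iptw, x$rd_iptw_ci), "\n", sep = "")
    cat("    dRMST: ", fmt_ci(x$drmst_iptw, x$drmst_iptw_ci), "\n", sep = "")
    cat(sprintf("    log-rank p = %.4g\n", x$logrank_p_iptw))
  }
  if (!is.null(x$ibs_arm0)) {
    cat("  IBS (arm 0): ", fmt_ci(x$ibs_arm0, x$ibs_arm0_ci), "\n", sep = "")
  }
  if (!is.null(x$ibs_arm1)) {
    cat("  IBS (arm 1): ", fmt_ci(x$ibs_arm1, x$ibs_arm1_ci), "\n", sep = "")
  }
  invisible(x)
}

#' Feature-ablation change in integrated Brier score
#'
#' Retrains the SNB without each named feature group (same seed and
#' config) and reports the change in the IPCW integrated Brier score on
#' the test set relative to the full model: overall and per treatment
#' arm. Positive deltas mean the ablated model predicts worse.
#'
#' @param train Training [survival_dataset()].
#' @param test Test [survival_dataset()].
#' @param config [snb_config()] used for every (re)fit.
#' @param feature_groups Named list of character vectors of column names.
#' @param horizon IBS horizon in months.
#' @return data.frame with columns `group`, `delta_ibs`, `delta_ibs_arm0`,
#'   `delta_ibs_arm1`.
#' @export
feature_ablation <- function(train, test, config, feature_groups,
                             horizon = 120) {
  all_cols <- colnames(train$X)
  for (nm in names(feature_groups)) {
    unknown <- setdiff(feature_groups[[nm]], all_cols)
    if (length(unknown) > 0) {
      stop("unknown columns in feature group '", nm, "': ",
           paste(unknown, collapse = ", "))
    }
  }
  ibs_of <- function(drop_cols) {
    keep <- setdiff(all_cols, drop_cols)
    tr <- survival_dataset(train$X[, keep, drop = FALSE], train$treatment,
                           train$time, train$event)
    te <- survival_dataset(test$X[, keep, drop = FALSE], test$treatment,
                           test$time, test$event)
    fit <- snb_fit(tr, config)
    grid <- unique(c(0, sort(unique(
      te$time[te$event == 1 & te$time <= horizon])), horizon))
    S <- factual_survival_matrix(fit, te, grid)
    out <- c(overall = integrated_brier(S, te$time, te$event, horizon,
                                        grid = grid))
    for (arm in c(0, 1)) {
      idx <- which(te$treatment == arm)
      out[paste0("arm", arm)] <-
        integrated_brier(S[idx, , drop = FALSE], te$time[idx],
                         te$event[idx], horizon, grid = grid)
    }
    out
  }
  full <- ibs_of(character())
  rows <- lapply(names(feature_groups), function(nm) {
    abl <- ibs_of(feature_groups[[nm]])
    data.frame(group = nm,
               delta_ibs = abl["overall"] - full["overall"],
               delta_ibs_arm0 = abl["arm0"] - full["arm0"],
               delta_ibs_arm1 = abl["arm1"] - full["arm1"],
               row.names = NULL)
  })
  do.call(rbind, rows)
}
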