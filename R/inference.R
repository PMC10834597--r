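#' Counterfactual survival inference
#'
#' A fitted SNB predicts, for any patient, a survival curve under either
#' treatment arm: the covariates are routed through the shared network and
#' the chosen arm's risk network (evaluation mode) to a log-hazard score
#' `s`, and the curve is `S(t) = exp(-H0_arm(t) * exp(s))` with the arm's
#' Breslow baseline cumulative hazard. The time-at-risk (TaR) is the
#' earliest time at which predicted survival reaches 10% (90% mortality);
#' the individual treatment effect is `ITE = TaR(arm 1) - TaR(arm 0)` and
#' treatment is recommended exactly when the ITE is greater than zero.
#'
#' @name counterfactual
NULL

#' Construct a survival curve step function
#'
#' Right-continuous step convention: `surv[i]` applies on
#' `[time[i], time[i+1])`, and survival is 1 before `time[1]`.
#'
#' @param time Sorted, nonnegative time grid (months).
#' @param surv Survival probabilities in `[0, 1]`, nonincreasing.
#' @return A `survival_curve` object.
#' @export
survival_curve <- function(time, surv) {
  stopifnot(length(time) == length(surv))
  if (length(time) == 0) stop("empty survival curve")
  if (is.unsorted(time)) stop("curve times must be sorted")
  if (any(surv < -1e-12) || any(surv > 1 + 1e-12)) {
    stop("survival probabilities must lie in [0, 1]")
  }
  if (any(diff(surv) > 1e-12)) stop("survival must be nonincreasing")
  structure(list(time = as.numeric(time),
                 surv = pmin(pmax(as.numeric(surv), 0), 1)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("survival_curve: %d steps on [%g, %g], final S = %.3f\n",
              length(x$time), min(x$time), max(x$time),
              x$surv[length(x$surv)]))
  invisible(x)
}

# Evaluate a right-continuous survival step curve at times t (S = 1
# before the first step; last value carried beyond the final step).
eval_curve <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  c(1, curve$surv)[idx + 1]
}

#' Predict a counterfactual survival curve
#'
#' @param model A fitted `snb` object.
#' @param x A single covariate row (vector or 1-row matrix) on the
#'   training schema, or a matrix of rows.
#' @param arm Counterfactual arm, 0 (control) or 1 (treated).
#' @return A [survival_curve()] for a single row; a list of curves for a
#'   matrix input.
#' @export
predict_survival <- function(model, x, arm) {
  stopifnot(inherits(model, "snb"), arm %in% c(0, 1))
  single <- is.null(dim(x)) || nrow(x) == 1
  s <- snb_scores(model, x, arm)
  bh <- if (arm == 0) model$baseline0 else model$baseline1
  curves <- lapply(s, function(si) {
    survival_curve(bh$time, exp(-bh$hazard * exp(si)))
  })
  if (single) curves[[1]] else curves
}

# Log-hazard scores for arm `arm`, evaluation mode.
snb_scores <- function(model, x, arm) {
  if (is.null(dim(x))) {
    x <- matrix(x, nrow = 1,
                dimnames = list(NULL, model$standardizer$columns))
  }
  Xs <- apply_standardizer(model$standardizer, x)
  Z <- mlp_forward(model$shared, Xs, training = FALSE)
  drop(mlp_forward(model[[paste0("risk", arm)]], Z, training = FALSE))
}

#' Time at risk of a survival curve
#'
#' The smallest time at which the curve's survival probability falls to
#' `1 - mortality_threshold` or below (first crossing on the
#' right-continuous step function). If the curve never reaches it, the
#' curve's last time is returned with `capped = TRUE`.
#'
#' @param curve A [survival_curve()].
#' @param mortality_threshold Mortality fraction defining the event
#'   (default 0.90, i.e. survival 10%).
#' @return List with `time` (months) and `capped` (logical).
#' @export
time_at_risk <- function(curve, mortality_threshold = 0.90) {
  stopifnot(inherits(curve, "survival_curve"),
            mortality_threshold > 0, mortality_threshold < 1)
  target <- 1 - mortality_threshold
  hit <- which(curve$surv <= target + 1e-12)
  if (length(hit) == 0) {
    list(time = curve$time[length(curve$time)], capped = TRUE)
  } else {
    list(time = curve$time[hit[1]], capped = FALSE)
  }
}

#' Individual treatment effect for one patient
#'
#' Computes both counterfactual survival curves, the time-at-risk under
#' each arm, their difference (the ITE, in months), and the treatment
#' recommendation (`"treated"` exactly when ITE > 0, else `"control"`).
#' Capped-TaR flags are propagated.
#'
#' @param model A fitted `snb` object.
#' @param x A single covariate row on the training schema.
#' @param mortality_threshold Mortality fraction defining TaR.
#' @return List with `tar0`, `tar1`, `ite`, `tar0_capped`, `tar1_capped`,
#'   `recommendation`.
#' @export
individual_treatment_effect <- function(model, x,
                                        mortality_threshold = 0.90) {
  c0 <- predict_survival(model, x, arm = 0)
  c1 <- predict_survival(model, x, arm = 1)
  t0 <- time_at_risk(c0, mortality_threshold)
  t1 <- time_at_risk(c1, mortality_threshold)
  ite <- t1$time - t0$time
  list(tar0 = t0$time, tar1 = t1$time, ite = ite,
       tar0_capped = t0$capped, tar1_capped = t1$capped,
       recommendation = if (ite > 0) "treated" else "control")
}

#' Batch counterfactual recommendations
#'
#' Vectorized [individual_treatment_effect()] over a dataset or covariate
#' matrix. Deterministic (evaluation mode).
#'
#' @param model A fitted `snb` object.
#' @param data A [survival_dataset()] or a covariate matrix.
#' @param mortality_threshold Mortality fraction defining TaR.
#' @return A data.frame with columns `id`, `tar0`, `tar1`, `ite`,
#'   `capped0`, `capped1`, `recommendation` (0/1).
#' @export
recommend_batch <- function(model, data, mortality_threshold = 0.90) {
  X <- if (inherits(data, "survival_dataset")) data$X else as.matrix(data)
  n <- nrow(X)
  if (n == 0) {
    return(data.frame(id = integer(), tar0 = numeric(), tar1 = numeric(),
                      ite = numeric(), capped0 = logical(),
                      capped1 = logical(), recommendation = integer()))
  }
  target_h <- log(1 / (1 - mortality_threshold))
  out <- list()
  for (arm in c(0, 1)) {
    s <- snb_scores(model, X, arm)
    bh <- if (arm == 0) model$baseline0 else model$baseline1
    # S(t) <= 1 - thr  <=>  H(t) >= log(1/(1-thr)) * exp(-s)
    need <- target_h * exp(-s)
    pos <- findInterval(need - 1e-12, bh$hazard) + 1
    capped <- pos > length(bh$time)
    tar <- ifelse(capped, bh$time[length(bh$time)], bh$time[pmin(pos, length(bh$time))])
    out[[arm + 1]] <- list(tar = tar, capped = capped)
  }
  ite <- out[[2]]$tar - out[[1]]$tar
  data.frame(id = seq_len(n),
             tar0 = out[[1]]$tar, tar1 = out[[2]]$tar, ite = ite,
             capped0 = out[[1]]$capped, capped1 = out[[2]]$capped,
             recommendation = as.integer(ite > 0))
}

#' @export
predict.snb <- function(object, newdata, type = c("recommendation", "score"),
                        mortality_threshold = 0.90, ...) {
  type <- match.arg(type)
  if (type == "recommendation") {
    recommend_batch(object, newdata, mortality_threshold)
  } else {
    X <- if (inherits(newdata, "survival_dataset")) newdata$X else as.matrix(newdata)
    data.frame(score0 = snb_scores(object, X, 0),
               score1 = snb_scores(object, X, 1))
  }
}
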