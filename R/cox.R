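#' Cox partial log-likelihood for neural risk scores
#'
#' Mean negative Cox partial log-likelihood of a vector of per-subject
#' log-hazard-ratio scores, the loss attached to each risk network. Ties
#' are handled by Breslow's method by default (Efron available). The value
#' is invariant to adding a constant to every score.
#'
#' @param scores Per-subject log hazard ratios (finite).
#' @param time Follow-up times.
#' @param event Event indicators (0/1); at least one event required.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param gradient If `TRUE`, also return the gradient with respect to
#'   `scores`.
#' @return The mean negative log partial likelihood (a scalar), or a list
#'   `list(value, gradient)` when `gradient = TRUE`.
#' @export
cox_partial_loglik <- function(scores, time, event,
                               ties = c("breslow", "efron"),
                               gradient = FALSE) {
  ties <- match.arg(ties)
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  if (any(!is.finite(scores))) stop("scores must be finite")
  D <- sum(event)
  if (D == 0) stop("at least one event is required for the Cox loss")

  ord <- order(time)
  s <- scores[ord]
  t_s <- time[ord]
  e_s <- event[ord]

  smax <- max(s)
  es <- exp(s - smax)
  # risk-set sums: reverse cumulative sum; tied times share the sum taken
  # at the first index of their tie group
  rev_cum <- rev(cumsum(rev(es)))
  first_of_tie <- match(t_s, t_s)       # first index with this time
  risk_sum <- rev_cum[first_of_tie]

  # group events by tied event time
  ev_idx <- which(e_s == 1)
  ev_times <- t_s[ev_idx]
  grp <- match(ev_times, ev_times)      # first event index per tie group
  groups <- split(ev_idx, t_s[ev_idx])

  loglik <- 0
  dgrad <- if (gradient) numeric(n)

  if (ties == "breslow") {
    # loglik = sum_k [ sum_{i in D_k} s_i - d_k log R_k ]
    for (g in groups) {
      Rk <- risk_sum[g[1]]
      dk <- length(g)
      loglik <- loglik + sum(s[g] - smax) - dk * log(Rk)
    }
    if (gradient) {
      # dL/ds_j = -(1/D)[ e_j - es_j * sum_{event groups k with t_k <= t_j}
      #                           d_k / R_k ]
      inc <- numeric(n)
      for (g in groups) {
        inc[g[1]] <- length(g) / risk_sum[g[1]]
      }
      # cumulative over positions; subjects at tied times are all in the
      # risk set of that time, so accumulate through the end of each tie
      # group before applying
      cum_inc <- cumsum(inc)
      # value applicable to subject j is the cumulative sum over event
      # times <= t_j; inc sits at the first index of each tie group, and
      # all members of a tie group (and later subjects) are at risk there.
      last_of_tie <- n + 1 - match(t_s, rev(t_s)) # last index of tie group
      appl <- cum_inc[last_of_tie]
      dgrad <- -(e_s - es * appl) / D
    }
  } else {
    for (g in groups) {
      Rk <- risk_sum[g[1]]
      dk <- length(g)
      tie_sum <- sum(es[g])
      l_seq <- seq_len(dk) - 1
      denoms <- Rk - (l_seq / dk) * tie_sum
      loglik <- loglik + sum(s[g] - smax) - sum(log(denoms))
    }
    if (gradient) {
      # accumulate per-subject gradient directly (O(n * #groups) worst
      # case but groups are typically small)
      grad_s <- numeric(n)
      for (g in groups) {
        Rk <- risk_sum[g[1]]
        dk <- length(g)
        tie_sum <- sum(es[g])
        l_seq <- seq_len(dk) - 1
        denoms <- Rk - (l_seq / dk) * tie_sum
        at_risk <- which(t_s >= t_s[g[1]])
        in_tie <- logical(n); in_tie[g] <- TRUE
        inv_sum <- sum(1 / denoms)
        tie_adj <- sum((l_seq / dk) / denoms)
        grad_s[at_risk] <- grad_s[at_risk] + es[at_risk] * inv_sum
        grad_s[g] <- grad_s[g] - es[g] * tie_adj
      }
      grad_s[e_s == 1] <- grad_s[e_s == 1] - 1
      dgrad <- grad_s / D
    }
  }

  value <- -loglik / D
  if (!gradient) return(value)
  out_grad <- numeric(n)
  out_grad[ord] <- dgrad
  list(value = value, gradient = out_grad)
}

#' Breslow cumulative baseline hazard
#'
#' Nonparametric cumulative baseline hazard for one treatment arm given
#' fitted log-hazard scores:
#' `H0(t) = sum over event times t_k <= t of d_k / sum_{j at risk} exp(s_j)`.
#' With all scores zero this is the Nelson-Aalen estimator. The step
#' function is 0 before the first event time.
#'
#' @param scores Training log hazard ratios for the arm.
#' @param time Follow-up times.
#' @param event Event indicators; at least one event required.
#' @return A `baseline_hazard` object: list with sorted unique event
#'   `time`s and the nondecreasing cumulative `hazard` at those times.
#' @export
breslow_baseline <- function(scores, time, event) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  if (sum(event) == 0) stop("no events: cannot estimate a baseline hazard")
  ord <- order(time)
  s <- scores[ord]
  t_s <- time[ord]
  e_s <- event[ord]
  es <- exp(s)
  rev_cum <- rev(cumsum(rev(es)))
  first_of_tie <- match(t_s, t_s)
  risk_sum <- rev_cum[first_of_tie]

  ev <- which(e_s == 1)
  ev_time <- t_s[ev]
  uniq <- !duplicated(ev_time)
  d_k <- as.numeric(table(factor(ev_time, levels = ev_time[uniq])))
  R_k <- risk_sum[ev[uniq]]
  structure(list(time = ev_time[uniq], hazard = cumsum(d_k / R_k)),
            class = "baseline_hazard")
}

# Evaluate a cumulative baseline hazard step function at times t
# (right-continuous; 0 before the first event time).
eval_baseline <- function(bh, t) {
  idx <- findInterval(t, bh$time)
  c(0, bh$hazard)[idx + 1]
}
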