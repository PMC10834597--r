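# Shared fixtures: all data are generated in code at test time.

# A tiny uncounfounded two-arm dataset with guaranteed events in each arm.
tiny_dataset <- function(n = 60, seed = 42, p = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  treatment <- rep(c(0, 1), length.out = n)
  time <- rexp(n, 0.05)
  event <- rbinom(n, 1, 0.8)
  event[1:2] <- 1  # one event per arm guaranteed
  survival_dataset(X, treatment, time, event)
}

# Small SNB config for fast smoke-level fits; any field can be overridden.
tiny_config <- function(...) {
  defaults <- list(shared_widths = c(8, 4), risk_widths = c(4, 1),
                   max_iterations = 60, patience = 60, batch_size = Inf,
                   learning_rate = 0.01)
  do.call(snb_config, utils::modifyList(defaults, list(...)))
}

# Independent textbook Kaplan-Meier (product-limit), unweighted.
km_reference <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(tt))
  for (i in seq_along(tt)) {
    d <- sum(time == tt[i] & event == 1)
    y <- sum(time >= tt[i])
    s <- s * (1 - d / y)
    surv[i] <- s
  }
  list(time = tt, surv = surv)
}

# Independent brute-force Breslow partial log-likelihood (mean negative),
# computed directly from the definition by looping over event times.
coxpl_reference <- function(scores, time, event) {
  total <- 0
  for (i in which(event == 1)) {
    rs <- which(time >= time[i])
    total <- total + scores[i] - log(sum(exp(scores[rs])))
  }
  -total / sum(event)
}
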