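#' SNB model configuration
#'
#' The estimator couples a shared self-normalizing representation network
#' (five SELU layers by default, 10% alpha-dropout) with two identical
#' four-layer risk networks, one per treatment arm, trained jointly on the
#' sum of the two arm-wise Cox partial likelihoods plus a balancing
#' penalty: the debiased Sinkhorn p-Wasserstein divergence between the
#' latent representations of the two arms, weighted by `balance_weight`.
#'
#' Layer counts follow the published architecture; widths are
#' hyperparameters (defaults: shared 64-64-32-32-16, risk 32-32-16-1 with
#' a linear output). Early stopping monitors the validation Cox loss and
#' halts after `patience` optimizer steps without improvement.
#'
#' @param shared_widths Widths of the shared SELU layers.
#' @param risk_widths Widths of the risk-network layers; the final layer
#'   is the linear log-hazard output and must have width 1.
#' @param dropout_rate Alpha-dropout rate for SELU layers.
#' @param balance_weight Nonnegative multiplier on the IPM (Sinkhorn)
#'   balancing term.
#' @param wasserstein_p Order of the Wasserstein cost, 1 or 2.
#' @param sinkhorn_epsilon Entropic blur of the Sinkhorn divergence.
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size; use `Inf` for full-batch training.
#' @param max_iterations Maximum optimizer steps.
#' @param patience Early-stopping patience in optimizer steps (default
#'   1000: training stops when the validation loss has not decreased in
#'   that many iterations).
#' @param cv_folds Folds for [snb_tune()] cross-validation.
#' @param ties Tie handling for the Cox loss, `"breslow"` or `"efron"`.
#' @param val_fraction Fraction of training data held out for early
#'   stopping when no validation set is supplied (stratified by arm and
#'   event status).
#' @param seed Integer seed; fans out to weight initialization, fold and
#'   validation-split assignment, batching and dropout.
#' @return An `snb_config` list.
#' @export
snb_config <- function(shared_widths = c(64, 64, 32, 32, 16),
                       risk_widths = c(32, 32, 16, 1),
                       dropout_rate = 0.10,
                       balance_weight = 0.1,
                       wasserstein_p = 2,
                       sinkhorn_epsilon = 1.0,
                       learning_rate = 0.003,
                       batch_size = 256,
                       max_iterations = 4000,
                       patience = 1000,
                       cv_folds = 5,
                       ties = c("breslow", "efron"),
                       val_fraction = 0.2,
                       seed = 1L) {
  ties <- match.arg(ties)
  stopifnot(patience >= 1, cv_folds >= 2, balance_weight >= 0,
            sinkhorn_epsilon > 0, learning_rate > 0, max_iterations >= 1,
            dropout_rate >= 0, dropout_rate < 1,
            val_fraction > 0, val_fraction < 1)
  if (length(risk_widths) < 1 || risk_widths[length(risk_widths)] != 1) {
    stop("the last risk-network layer must have width 1 (log-hazard output)")
  }
  structure(list(
    shared_widths = shared_widths, risk_widths = risk_widths,
    dropout_rate = dropout_rate, balance_weight = balance_weight,
    wasserstein_p = wasserstein_p, sinkhorn_epsilon = sinkhorn_epsilon,
    learning_rate = learning_rate, batch_size = batch_size,
    max_iterations = as.integer(max_iterations),
    patience = as.integer(patience), cv_folds = as.integer(cv_folds),
    ties = ties, val_fraction = val_fraction, seed = as.integer(seed)
  ), class = "snb_config")
}

# Modify a config with named overrides (used by the tuning grid).
modify_config <- function(config, overrides) {
  fields <- unclass(config)
  bad <- setdiff(names(overrides), names(fields))
  if (length(bad) > 0) {
    stop("unknown config fields: ", paste(bad, collapse = ", "))
  }
  for (nm in names(overrides)) fields[[nm]] <- overrides[[nm]]
  do.call(snb_config, fields)
}

# ---- parameter plumbing -------------------------------------------------

init_snb_params <- function(d_in, config) {
  shared <- if (length(config$shared_widths) > 0) {
    mlp_init(d_in, config$shared_widths, dropout_rate = config$dropout_rate)
  } else {
    structure(list(layers = list(), d_in = d_in), class = "mlp")
  }
  d_latent <- if (length(config$shared_widths) > 0) {
    config$shared_widths[length(config$shared_widths)]
  } else {
    d_in
  }
  risk0 <- mlp_init(d_latent, config$risk_widths,
                    dropout_rate = config$dropout_rate, linear_out = TRUE)
  risk1 <- mlp_init(d_latent, config$risk_widths,
                    dropout_rate = config$dropout_rate, linear_out = TRUE)
  list(shared = shared, risk0 = risk0, risk1 = risk1)
}

# Flatten nets into a list of tensors for the optimizer.
collect_params <- function(model) {
  out <- list()
  for (net in c("shared", "risk0", "risk1")) {
    for (i in seq_along(model[[net]]$layers)) {
      out[[paste0(net, ".W", i)]] <- model[[net]]$layers[[i]]$W
      out[[paste0(net, ".b", i)]] <- model[[net]]$layers[[i]]$b
    }
  }
  out
}

apply_params <- function(model, params) {
  for (net in c("shared", "risk0", "risk1")) {
    for (i in seq_along(model[[net]]$layers)) {
      model[[net]]$layers[[i]]$W <- params[[paste0(net, ".W", i)]]
      model[[net]]$layers[[i]]$b <- params[[paste0(net, ".b", i)]]
    }
  }
  model
}

# ---- loss ---------------------------------------------------------------

#' SNB joint loss on a batch
#'
#' Sum of the two arm-wise mean negative Cox partial log-likelihoods (each
#' arm routed through its own risk network on top of the shared
#' representation) plus `balance_weight` times the Sinkhorn divergence
#' between the arms' latent representations. With `balance_weight = 0`
#' this reduces exactly to a T-learner with a shared trunk. A batch
#' containing a single arm skips the balancing term with a warning; an
#' arm with zero events contributes zero Cox loss with a warning.
#'
#' @param model List with `shared`, `risk0`, `risk1` networks (as built
#'   internally by [snb_fit()]).
#' @param X Standardized covariate matrix for the batch.
#' @param treatment,time,event Batch outcome columns.
#' @param config An [snb_config()].
#' @param training Logical; enables dropout (and gradients internally).
#' @param gradient If `TRUE`, return `list(value, grads)`.
#' @param warn Emit warnings for single-arm / zero-event degeneracies.
#' @return Scalar loss, or a list when `gradient = TRUE`.
#' @export
snb_loss <- function(model, X, treatment, time, event, config,
                     training = FALSE, gradient = FALSE, warn = TRUE) {
  i0 <- which(treatment == 0)
  i1 <- which(treatment == 1)
  fs <- mlp_forward(model$shared, X, training = training, cache = gradient)
  Z <- if (gradient) fs$out else fs
  d_Z <- if (gradient) matrix(0, nrow(Z), ncol(Z))

  loss <- 0
  risk_grads <- list(risk0 = NULL, risk1 = NULL)
  notes <- character()
  for (arm in c(0, 1)) {
    idx <- if (arm == 0) i0 else i1
    net_name <- paste0("risk", arm)
    if (length(idx) == 0) next
    if (sum(event[idx]) == 0) {
      notes <- c(notes, sprintf("arm %d has no events in batch; Cox term skipped", arm))
      next
    }
    fr <- mlp_forward(model[[net_name]], Z[idx, , drop = FALSE],
                      training = training, cache = gradient)
    s <- drop(if (gradient) fr$out else fr)
    cl <- cox_partial_loglik(s, time[idx], event[idx], ties = config$ties,
                             gradient = gradient)
    if (gradient) {
      loss <- loss + cl$value
      bk <- mlp_backward(model[[net_name]], fr$cache,
                         matrix(cl$gradient, ncol = 1))
      risk_grads[[net_name]] <- bk$grads
      d_Z[idx, ] <- d_Z[idx, ] + bk$d_input
    } else {
      loss <- loss + cl
    }
  }

  ipm <- 0
  if (config$balance_weight > 0) {
    if (length(i0) > 0 && length(i1) > 0) {
      # The divergence is computed on per-dimension batch-standardized
      # latents: this makes the penalty scale-invariant, so collapsing
      # the representation to a constant (the degenerate minimum of a
      # raw transport cost) does not reduce it.
      mu <- colMeans(Z)
      sdv <- sqrt(colMeans(Z^2) - mu^2 + 1e-8)
      # the cost is measured per latent dimension (coordinates scaled by
      # 1/sqrt(d)) so the blur epsilon has the same meaning whatever the
      # representation width
      root_d <- sqrt(ncol(Z))
      Zn <- sweep(sweep(Z, 2, mu, "-"), 2, sdv * root_d, "/")
      # cap the per-arm sample entering the transport problem; a random
      # subsample of the batch is an unbiased estimate of the divergence
      cap <- if (training) 128L else .Machine$integer.max
      s0 <- if (length(i0) > cap) sample(i0, cap) else i0
      s1 <- if (length(i1) > cap) sample(i1, cap) else i1
      # looser Sinkhorn convergence during training: the envelope
      # gradient at tol 1e-6 is ample for stochastic optimization
      sd_ <- sinkhorn_divergence(Zn[s0, , drop = FALSE],
                                 Zn[s1, , drop = FALSE],
                                 p = config$wasserstein_p,
                                 epsilon = config$sinkhorn_epsilon,
                                 max_iter = if (training) 50 else 1000,
                                 tol = if (training) 1e-6 else 1e-9,
                                 gradient = gradient)
      if (gradient) {
        ipm <- sd_$value
        G <- matrix(0, nrow(Z), ncol(Z))
        G[s0, ] <- sd_$grad_x
        G[s1, ] <- sd_$grad_y
        # chain rule through the batch z-score (columnwise), with u the
        # unit-variance score: dL/dz = (g - mean(g) - u mean(g u)) /
        # (sd * sqrt(d))
        U <- Zn * root_d
        gm <- colMeans(G)
        gu <- colMeans(G * U)
        dZn <- sweep(G, 2, gm, "-") - sweep(U, 2, gu, "*")
        d_Z <- d_Z + config$balance_weight *
          sweep(dZn, 2, sdv * root_d, "/")
      } else {
        ipm <- sd_
      }
    } else {
      notes <- c(notes, "single-arm batch: balancing term skipped")
    }
  }
  loss <- loss + config$balance_weight * ipm
  if (warn && length(notes) > 0) {
    for (msg in notes) warning(msg, call. = FALSE)
  }

  if (!gradient) return(loss)

  grads <- list()
  if (length(model$shared$layers) > 0) {
    bs <- mlp_backward(model$shared, fs$cache, d_Z)
    for (i in seq_along(bs$grads)) {
      grads[[paste0("shared.W", i)]] <- bs$grads[[i]]$W
      grads[[paste0("shared.b", i)]] <- bs$grads[[i]]$b
    }
  }
  for (net_name in c("risk0", "risk1")) {
    rg <- risk_grads[[net_name]]
    for (i in seq_along(model[[net_name]]$layers)) {
      if (is.null(rg)) {
        grads[[paste0(net_name, ".W", i)]] <-
          model[[net_name]]$layers[[i]]$W * 0
        grads[[paste0(net_name, ".b", i)]] <-
          model[[net_name]]$layers[[i]]$b * 0
      } else {
        grads[[paste0(net_name, ".W", i)]] <- rg[[i]]$W
        grads[[paste0(net_name, ".b", i)]] <- rg[[i]]$b
      }
    }
  }
  list(value = loss, grads = grads, notes = notes)
}

# ---- early stopping -----------------------------------------------------

#' Early-stopping rule on a validation-loss trace
#'
#' Returns the iteration at which training stops for a given loss trace:
#' the first iteration lying `patience` steps after the last strict
#' improvement of the running best validation loss, or `length(trace)` if
#' that never happens (training runs to the end of the trace). Also
#' returns the index of the best iteration whose weights are restored.
#'
#' @param trace Numeric vector of validation losses, one per iteration.
#' @param patience Number of iterations without improvement that triggers
#'   termination.
#' @return List with `stop_iteration` and `best_iteration`.
#' @export
early_stop_iteration <- function(trace, patience) {
  stopifnot(patience >= 1)
  best <- Inf
  best_i <- 0L
  for (i in seq_along(trace)) {
    if (trace[i] < best) {
      best <- trace[i]
      best_i <- i
    } else if (i - best_i >= patience) {
      return(list(stop_iteration = i, best_iteration = best_i))
    }
  }
  list(stop_iteration = length(trace), best_iteration = best_i)
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- standardization ----------------------------------------------------

fit_standardizer <- function(X) {
  is_binary <- apply(X, 2, function(v) all(v %in% c(0, 1)))
  center <- ifelse(is_binary, 0, colMeans(X))
  scale <- ifelse(is_binary, 1, apply(X, 2, stats::sd))
  scale[scale == 0 | !is.finite(scale)] <- 1
  list(center = center, scale = scale, columns = colnames(X))
}

apply_standardizer <- function(std, X) {
  if (!is.null(std$columns)) {
    missing_cols <- setdiff(std$columns, colnames(X))
    if (length(missing_cols) > 0) {
      stop("input is missing training columns: ",
           paste(missing_cols, collapse = ", "))
    }
    X <- X[, std$columns, drop = FALSE]
  }
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

# ---- fitting ------------------------------------------------------------

#' Fit the SNB model
#'
#' Mini-batch Adam minimization of [snb_loss()] with early stopping on a
#' validation set: training halts when the validation Cox loss has not
#' decreased for `patience` optimizer steps (or at `max_iterations`), and
#' the best-validation weights are restored. Afterwards the two
#' treatment-specific Breslow baseline cumulative hazards are estimated on
#' the training set. Deterministic given `config$seed`.
#'
#' @param train A [survival_dataset()]; both arms must contain events.
#' @param config An [snb_config()].
#' @param val Optional validation [survival_dataset()]; if omitted, a
#'   fraction `config$val_fraction` of `train` is held out, stratified by
#'   arm and event status.
#' @return An object of class `snb`: networks, per-arm baseline hazards,
#'   standardization parameters, resolved config, and a training log.
#' @export
snb_fit <- function(train, config = snb_config(), val = NULL) {
  stopifnot(inherits(train, "survival_dataset"))
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)

  if (is.null(val)) {
    strata <- interaction(train$treatment, train$event)
    val_idx <- unlist(lapply(split(seq_along(strata), strata), function(ix) {
      if (length(ix) == 0) return(integer())
      k <- max(1, round(length(ix) * config$val_fraction))
      sample(ix, min(k, length(ix)))
    }))
    val <- subset_dataset(train, val_idx)
    train <- subset_dataset(train, setdiff(seq_len(nrow(train$X)), val_idx))
  }
  for (arm in c(0, 1)) {
    if (sum(train$event[train$treatment == arm]) == 0) {
      stop(sprintf("training data: arm %d has no events", arm))
    }
    if (sum(train$treatment == arm) == 0) {
      stop(sprintf("training data: arm %d is empty", arm))
    }
  }

  std <- fit_standardizer(train$X)
  Xs <- apply_standardizer(std, train$X)
  Xv <- apply_standardizer(std, val$X)

  model <- init_snb_params(ncol(Xs), config)
  params <- collect_params(model)
  opt <- adam_init(params)

  n <- nrow(Xs)
  i0 <- which(train$treatment == 0)
  i1 <- which(train$treatment == 1)
  bsz <- min(config$batch_size, n)
  full_batch <- bsz >= n

  best_val <- Inf
  best_params <- params
  best_iter <- 0L
  train_log <- data.frame(iteration = integer(), train_loss = numeric(),
                          val_loss = numeric())
  skipped_ipm <- 0L
  skipped_cox <- 0L

  val_cox_loss <- function(params) {
    m <- apply_params(model, params)
    snb_loss_cox_only(m, Xv, val$treatment, val$time, val$event, config)
  }

  iter <- 0L
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    if (full_batch) {
      idx <- seq_len(n)
    } else {
      # stratified mini-batch: sample each arm proportionally, >= 2 each
      k1 <- max(2, round(bsz * length(i1) / n))
      k0 <- max(2, bsz - k1)
      idx <- c(sample(i0, min(k0, length(i0))),
               sample(i1, min(k1, length(i1))))
    }
    m <- apply_params(model, params)
    lg <- snb_loss(m, Xs[idx, , drop = FALSE], train$treatment[idx],
                   train$time[idx], train$event[idx], config,
                   training = TRUE, gradient = TRUE, warn = FALSE)
    if (!is.finite(lg$value)) {
      stop(sprintf(paste0("non-finite training loss at iteration %d; ",
                          "try a smaller learning_rate (current %g)"),
                   iter, config$learning_rate))
    }
    skipped_ipm <- skipped_ipm +
      any(grepl("single-arm", lg$notes))
    skipped_cox <- skipped_cox +
      any(grepl("no events", lg$notes))
    st <- adam_step(params, lg$grads, opt, config$learning_rate)
    params <- st$params
    opt <- st$state

    vl <- val_cox_loss(params)
    train_log <- rbind(train_log,
                       data.frame(iteration = iter, train_loss = lg$value,
                                  val_loss = vl))
    if (vl < best_val) {
      best_val <- vl
      best_params <- params
      best_iter <- iter
    } else if (iter - best_iter >= config$patience) {
      break
    }
  }

  model <- apply_params(model, best_params)

  # Breslow baselines per arm from final (evaluation-mode) training scores
  Z <- mlp_forward(model$shared, Xs, training = FALSE)
  baselines <- list()
  for (arm in c(0, 1)) {
    idx <- if (arm == 0) i0 else i1
    s <- drop(mlp_forward(model[[paste0("risk", arm)]],
                          Z[idx, , drop = FALSE], training = FALSE))
    baselines[[arm + 1]] <- breslow_baseline(s, train$time[idx],
                                             train$event[idx])
  }

  structure(list(
    shared = model$shared, risk0 = model$risk0, risk1 = model$risk1,
    baseline0 = baselines[[1]], baseline1 = baselines[[2]],
    standardizer = std, config = config,
    log = list(trace = train_log, best_iteration = best_iter,
               stopped_at = iter, best_val_loss = best_val,
               skipped_ipm_batches = skipped_ipm,
               skipped_cox_terms = skipped_cox)
  ), class = "snb")
}

# Validation loss: Cox terms only, evaluation mode (used for early
# stopping and CV model selection; excludes the balancing penalty).
snb_loss_cox_only <- function(model, X, treatment, time, event, config) {
  cfg <- config
  cfg$balance_weight <- 0
  snb_loss(model, X, treatment, time, event, cfg,
           training = FALSE, gradient = FALSE, warn = FALSE)
}

#' @export
print.snb <- function(x, ...) {
  widths <- function(net) {
    if (length(net$layers) == 0) return("identity")
    paste(vapply(net$layers, function(l) l$spec$width, numeric(1)),
          collapse = "-")
  }
  cat("Self-normalizing balanced survival network (SNB)\n")
  cat(sprintf("  shared net: %s; risk nets: %s (x2)\n",
              widths(x$shared), widths(x$risk0)))
  cat(sprintf("  balance weight: %g (p=%d Wasserstein, epsilon=%g)\n",
              x$config$balance_weight, x$config$wasserstein_p,
              x$config$sinkhorn_epsilon))
  cat(sprintf("  trained %d iterations (best at %d, val loss %.4f)\n",
              x$log$stopped_at, x$log$best_iteration, x$log$best_val_loss))
  invisible(x)
}

#' Shared-network latent representations
#'
#' Evaluation-mode forward pass of standardized covariates through the
#' fitted shared network; used for balance diagnostics.
#'
#' @param model A fitted `snb` object.
#' @param X Covariate matrix on the training schema.
#' @return Latent representation matrix.
#' @export
snb_latent <- function(model, X) {
  mlp_forward(model$shared, apply_standardizer(model$standardizer, X),
              training = FALSE)
}

# ---- tuning -------------------------------------------------------------

#' Tune SNB hyperparameters by k-fold cross-validation
#'
#' For each grid point, fits the model on `cv_folds - 1` folds with the
#' held-out fold as the early-stopping validation set and records the best
#' validation Cox loss; returns the config whose mean CV loss is smallest.
#' Fold assignment is deterministic given `config$seed`; ties are broken
#' by grid order (first minimum wins).
#'
#' @param train A [survival_dataset()].
#' @param grid A list of named lists of `snb_config` field overrides.
#' @param config Base [snb_config()].
#' @return The selected `snb_config`, with attributes `cv_losses` (mean
#'   loss per grid point) and `grid`.
#' @export
snb_tune <- function(train, grid, config = snb_config()) {
  if (length(grid) == 0) stop("hyperparameter grid is empty")
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)
  n <- nrow(train$X)
  folds <- sample(rep(seq_len(config$cv_folds), length.out = n))

  cv_losses <- vapply(seq_along(grid), function(gi) {
    cfg <- modify_config(config, grid[[gi]])
    fold_losses <- vapply(seq_len(config$cv_folds), function(k) {
      tr <- subset_dataset(train, which(folds != k))
      va <- subset_dataset(train, which(folds == k))
      fit <- snb_fit(tr, cfg, val = va)
      fit$log$best_val_loss
    }, numeric(1))
    mean(fold_losses)
  }, numeric(1))

  best <- which.min(cv_losses)  # first minimum under ties
  out <- modify_config(config, grid[[best]])
  attr(out, "cv_losses") <- cv_losses
  attr(out, "grid") <- grid
  out
}
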