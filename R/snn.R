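#' Self-normalizing network primitives
#'
#' Building blocks for self-normalizing feed-forward networks: the SELU
#' activation, alpha-dropout, LeCun-normal weight initialization, and a
#' plain multilayer perceptron with manual forward/backward passes. These
#' are used by both the shared representation network and the two
#' arm-specific risk networks of the SNB model, but are exported because
#' they are useful on their own for testing self-normalization behaviour.
#'
#' @name snn
NULL

# Canonical SELU constants (full double precision).
SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772
# Negative saturation value -lambda*alpha, the value alpha-dropout inserts.
SELU_SAT <- -SELU_LAMBDA * SELU_ALPHA

#' Scaled exponential linear unit
#'
#' `selu(x)` equals `lambda * x` for `x > 0` and
#' `lambda * alpha * (exp(x) - 1)` for `x <= 0`, with the canonical
#' constants `lambda = 1.0507009873554805`, `alpha = 1.6732632423543772`.
#' The activation's fixed point drives activations toward zero mean and
#' unit variance when weights follow the LeCun-normal contract.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape as `x`.
#' @examples
#' selu(0)          # 0
#' selu(1)          # 1.0507...
#' selu(-1e6)       # approaches -lambda*alpha = -1.7580993...
#' @export
selu <- function(x) {
  ifelse(x > 0, SELU_LAMBDA * x, SELU_LAMBDA * SELU_ALPHA * (exp(x) - 1))
}

# Derivative of selu, used by backprop.
selu_grad <- function(x) {
  ifelse(x > 0, SELU_LAMBDA, SELU_LAMBDA * SELU_ALPHA * exp(x))
}

#' Alpha-dropout
#'
#' Dropout variant that preserves the self-normalizing property: dropped
#' units are set to the SELU negative saturation value `-lambda*alpha`
#' (not zero), and an affine correction restores zero mean and unit
#' variance in expectation for standardized inputs.
#'
#' @param x Numeric vector or matrix of activations.
#' @param rate Drop probability in `[0, 1)`.
#' @param training Logical; in evaluation mode (`FALSE`) the input is
#'   returned unchanged.
#' @return Activations of the same shape as `x`. When called with
#'   `return_mask = TRUE` (internal use) a list with elements `out`,
#'   `mask` and `scale` for backpropagation.
#' @param return_mask Internal; also return the keep mask and affine scale.
#' @export
alpha_dropout <- function(x, rate, training = TRUE, return_mask = FALSE) {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1) {
    stop("dropout `rate` must be a single number in [0, 1)")
  }
  if (!training || rate == 0) {
    if (return_mask) {
      return(list(out = x, mask = NULL, scale = 1))
    }
    return(x)
  }
  q <- 1 - rate
  a <- (q + SELU_SAT^2 * q * rate)^(-0.5)
  b <- -a * rate * SELU_SAT
  keep <- stats::runif(length(x)) < q
  if (!is.null(dim(x))) dim(keep) <- dim(x)
  out <- a * (x * keep + SELU_SAT * (1 - keep)) + b
  if (return_mask) {
    return(list(out = out, mask = keep, scale = a))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Layer specification
#'
#' @param width Number of units (>= 1).
#' @param activation `"selu"` or `"linear"` (linear is used for the final
#'   log-hazard output of a risk network).
#' @param dropout_rate Alpha-dropout rate in `[0, 1)`.
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(width, activation = c("selu", "linear"),
                       dropout_rate = 0) {
  activation <- match.arg(activation)
  if (!is.numeric(width) || length(width) != 1L || width < 1) {
    stop("`width` must be a single integer >= 1")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("`dropout_rate` must be in [0, 1)")
  }
  structure(list(width = as.integer(width), activation = activation,
                 dropout_rate = dropout_rate),
            class = "layer_spec")
}

#' Initialize an MLP with LeCun-normal weights
#'
#' Weights are drawn N(0, 1/fan_in) as self-normalization requires;
#' biases start at zero. Uses the current RNG state, so wrap in
#' `set.seed()` for reproducibility.
#'
#' @param d_in Input dimension.
#' @param specs List of [layer_spec()] objects (or a bare integer vector of
#'   widths, all-SELU with shared dropout rate).
#' @param dropout_rate Dropout rate applied when `specs` is an integer
#'   vector.
#' @param linear_out If `TRUE` and `specs` is an integer vector, the last
#'   layer is linear with no dropout (risk-network head convention).
#' @return An `mlp` object: list of layers with weight matrix `W`
#'   (fan_in x width), bias `b`, and the layer spec.
#' @export
mlp_init <- function(d_in, specs, dropout_rate = 0, linear_out = FALSE) {
  if (is.numeric(specs)) {
    n <- length(specs)
    specs <- lapply(seq_len(n), function(i) {
      if (linear_out && i == n) {
        layer_spec(specs[i], "linear", 0)
      } else {
        layer_spec(specs[i], "selu", dropout_rate)
      }
    })
  }
  layers <- vector("list", length(specs))
  fan_in <- d_in
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    layers[[i]] <- list(
      W = matrix(stats::rnorm(fan_in * sp$width, sd = 1 / sqrt(fan_in)),
                 nrow = fan_in, ncol = sp$width),
      b = rep(0, sp$width),
      spec = sp
    )
    fan_in <- sp$width
  }
  structure(list(layers = layers, d_in = d_in), class = "mlp")
}

#' Forward pass through an MLP
#'
#' Per layer: affine transform, activation, then alpha-dropout (training
#' mode only). Deterministic in evaluation mode. An empty network (zero
#' layers) is the identity map.
#'
#' @param net An `mlp` object from [mlp_init()].
#' @param x Input matrix (n x d_in) or vector (coerced to a single row).
#' @param training Logical; enables alpha-dropout.
#' @param cache Internal; keep intermediates for [mlp_backward()].
#' @return Output activation matrix, or (with `cache = TRUE`) a list with
#'   `out` and `cache`.
#' @export
mlp_forward <- function(net, x, training = FALSE, cache = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != net$d_in) {
    stop(sprintf("input has %d columns but network expects %d",
                 ncol(x), net$d_in))
  }
  caches <- if (cache) vector("list", length(net$layers))
  h <- x
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ncol(h) != nrow(ly$W)) {
      stop(sprintf("shape mismatch at layer %d: input %d vs fan-in %d",
                   i, ncol(h), nrow(ly$W)))
    }
    a <- sweep(h %*% ly$W, 2, ly$b, "+")
    act <- switch(ly$spec$activation, selu = selu(a), linear = a)
    dp <- alpha_dropout(act, ly$spec$dropout_rate, training = training,
                        return_mask = TRUE)
    if (cache) {
      caches[[i]] <- list(input = h, pre = a, mask = dp$mask,
                          scale = dp$scale)
    }
    h <- dp$out
  }
  if (cache) list(out = h, cache = caches) else h
}

# Backward pass: given upstream gradient d_out (n x width_last), returns
# per-layer weight/bias gradients and the gradient w.r.t. the input.
mlp_backward <- function(net, cache, d_out) {
  grads <- vector("list", length(net$layers))
  dh <- d_out
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    cc <- cache[[i]]
    # through dropout
    if (!is.null(cc$mask)) {
      dh <- dh * cc$scale * cc$mask
    }
    # through activation
    da <- switch(ly$spec$activation,
                 selu = dh * selu_grad(cc$pre),
                 linear = dh)
    grads[[i]] <- list(W = crossprod(cc$input, da), b = colSums(da))
    dh <- tcrossprod(da, ly$W)
  }
  list(grads = grads, d_input = dh)
}
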