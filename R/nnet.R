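#' Dense feed-forward network specification
#'
#' Describes a fully connected multilayer perceptron by its input width, the
#' ordered widths of its dense layers, the hidden activation, the output
#' activation, and an optional per-layer dropout rate applied after a layer's
#' activation. The specification is purely structural: it carries no
#' parameters and is consumed by [mlp_init()] and [count_parameters()].
#'
#' @param input_dim integer, number of input features (>= 1).
#' @param layer_widths integer vector, output width of each dense layer in
#'   order; the last entry is the network's output width.
#' @param hidden_activation activation for all layers but the last;
#'   only `"relu"` is supported.
#' @param output_activation one of `"linear"`, `"sigmoid"`, `"softmax"`.
#' @param dropout numeric vector of per-layer dropout rates in `[0, 1)`,
#'   recycled to `length(layer_widths)`; rate `d > 0` after layer `l` drops
#'   each of that layer's outputs with probability `d` during training
#'   (inverted scaling), and is a no-op at inference.
#' @return an object of class `"mlp_spec"`.
#' @seealso [mlp_init()], [count_parameters()]
#' @export
mlp_spec <- function(input_dim, layer_widths,
                     hidden_activation = "relu",
                     output_activation = c("linear", "sigmoid", "softmax"),
                     dropout = 0) {
  output_activation <- match.arg(output_activation)
  input_dim <- as.integer(input_dim)
  layer_widths <- as.integer(layer_widths)
  if (length(input_dim) != 1L || is.na(input_dim) || input_dim < 1L)
    stop("'input_dim' must be a single integer >= 1")
  if (length(layer_widths) < 1L || anyNA(layer_widths) || any(layer_widths < 1L))
    stop("'layer_widths' must be a non-empty vector of integers >= 1")
  if (!identical(hidden_activation, "relu"))
    stop("only 'relu' hidden activation is supported")
  dropout <- rep_len(as.numeric(dropout), length(layer_widths))
  if (anyNA(dropout) || any(dropout < 0) || any(dropout >= 1))
    stop("dropout rates must lie in [0, 1)")
  structure(
    list(input_dim = input_dim, layer_widths = layer_widths,
         hidden_activation = hidden_activation,
         output_activation = output_activation, dropout = dropout),
    class = "mlp_spec")
}

#' Count trainable parameters of a dense network
#'
#' Closed-form count for a fully connected network: for consecutive widths
#' `w_in -> w_out` each dense layer contributes `(w_in + 1) * w_out`
#' parameters (weights plus biases). Works on an `"mlp_spec"` or on an
#' initialized/trained `"fog_network"`, where it simply enumerates the stored
#' arrays; both routes agree by construction and are cross-checked in the
#' test suite.
#'
#' @param x an `"mlp_spec"` or `"fog_network"`.
#' @return integer parameter count.
#' @examples
#' count_parameters(mlp_spec(2, 3))  # (2 + 1) * 3 = 9
#' @export
count_parameters <- function(x) {
  if (inherits(x, "fog_network")) {
    return(as.integer(sum(vapply(x$W, length, numeric(1))) +
                        sum(vapply(x$b, length, numeric(1)))))
  }
  if (!inherits(x, "mlp_spec")) stop("'x' must be an 'mlp_spec' or 'fog_network'")
  widths <- c(x$input_dim, x$layer_widths)
  as.integer(sum((widths[-length(widths)] + 1) * widths[-1]))
}

#' Per-layer parameter counts of a dense network spec
#'
#' @param spec an `"mlp_spec"`.
#' @return integer vector, one `(w_in + 1) * w_out` count per dense layer.
#' @export
layer_parameter_counts <- function(spec) {
  stopifnot(inherits(spec, "mlp_spec"))
  widths <- c(spec$input_dim, spec$layer_widths)
  as.integer((widths[-length(widths)] + 1) * widths[-1])
}

#' Initialize network parameters for a spec
#'
#' He-normal weights (`sd = sqrt(2 / fan_in)`) suited to rectifier hidden
#' units; biases start at zero. Seeding is the caller's responsibility (the
#' training front-ends set the RNG once per run).
#'
#' @param spec an `"mlp_spec"`.
#' @return an object of class `"fog_network"`: the spec plus weight matrices
#'   `W` (fan-in x fan-out) and bias vectors `b`.
#' @export
mlp_init <- function(spec) {
  stopifnot(inherits(spec, "mlp_spec"))
  widths <- c(spec$input_dim, spec$layer_widths)
  n_layers <- length(spec$layer_widths)
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- widths[l]
    W[[l]] <- matrix(stats::rnorm(fan_in * widths[l + 1L], sd = sqrt(2 / fan_in)),
                     nrow = fan_in, ncol = widths[l + 1L])
    b[[l]] <- numeric(widths[l + 1L])
  }
  structure(list(spec = spec, W = W, b = b), class = "fog_network")
}

# Numerically safe logistic; clamps the output away from {0, 1} so that
# log(p) and log(1 - p) stay finite in the adversarial losses.
sigmoid <- function(z, eps = 1e-7) {
  p <- 1 / (1 + exp(-z))
  pmin(pmax(p, eps), 1 - eps)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass through a dense network
#'
#' @param net a `"fog_network"`.
#' @param X numeric matrix, rows are samples, `ncol(X)` must equal the
#'   spec's `input_dim`.
#' @param training logical; `TRUE` applies dropout (consuming RNG draws),
#'   `FALSE` (inference) is deterministic.
#' @return numeric matrix of outputs, one row per input row.
#' @export
mlp_forward <- function(net, X, training = FALSE) {
  mlp_forward_cache(net, X, training = training)$out
}

# Forward pass keeping what backprop needs: the post-activation (and
# post-dropout) output of every layer, and the elementwise derivative factor
# of that output w.r.t. its pre-activation (relu gate times dropout scale).
mlp_forward_cache <- function(net, X, training = FALSE) {
  spec <- net$spec
  if (!is.matrix(X)) X <- matrix(X, ncol = spec$input_dim)
  if (ncol(X) != spec$input_dim)
    stop(sprintf("input has %d columns; network expects %d", ncol(X), spec$input_dim))
  n_layers <- length(spec$layer_widths)
  h <- vector("list", n_layers + 1L)  # h[[1]] is the input
  dfac <- vector("list", n_layers)
  h[[1L]] <- X
  for (l in seq_len(n_layers)) {
    z <- h[[l]] %*% net$W[[l]]
    z <- sweep(z, 2L, net$b[[l]], "+")
    last <- l == n_layers
    if (!last) {
      a <- z * (z > 0)
      d <- (z > 0) * 1
    } else {
      a <- switch(spec$output_activation,
                  linear = z,
                  sigmoid = sigmoid(z),
                  softmax = softmax_rows(z))
      d <- NULL  # output-layer gradient is supplied pre-activation
    }
    rate <- spec$dropout[l]
    if (training && rate > 0) {
      keep <- 1 - rate
      mask <- matrix(stats::runif(length(a)) < keep, nrow = nrow(a)) / keep
      a <- a * mask
      if (!last) d <- d * mask
    }
    h[[l + 1L]] <- a
    dfac[[l]] <- d
  }
  list(out = h[[n_layers + 1L]], h = h, dfac = dfac)
}

# Backpropagate a pre-activation output gradient `delta` (n x out_width)
# through the cached forward pass. Returns per-layer weight/bias gradients
# and, when `input_grad = TRUE`, the gradient w.r.t. the input rows (used to
# push the generator through a frozen discriminator).
mlp_backprop <- function(net, cache, delta, input_grad = FALSE) {
  n_layers <- length(net$spec$layer_widths)
  gW <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  for (l in seq.int(n_layers, 1L)) {
    gW[[l]] <- crossprod(cache$h[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- tcrossprod(delta, net$W[[l]]) * cache$dfac[[l - 1L]]
    } else if (input_grad) {
      delta <- tcrossprod(delta, net$W[[1L]])
    }
  }
  list(W = gW, b = gb, input = if (input_grad) delta)
}

# Adam optimizer state for a network's parameters.
adam_new <- function(net) {
  zeros_like <- function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  }
  list(mW = lapply(net$W, zeros_like), vW = lapply(net$W, zeros_like),
       mb = lapply(net$b, zeros_like), vb = lapply(net$b, zeros_like),
       t = 0L)
}

# One Adam update; returns list(net, opt). Standard bias-corrected moments.
adam_step <- function(net, grads, opt, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (l in seq_along(net$W)) {
    opt$mW[[l]] <- beta1 * opt$mW[[l]] + (1 - beta1) * grads$W[[l]]
    opt$vW[[l]] <- beta2 * opt$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (opt$mW[[l]] / c1) / (sqrt(opt$vW[[l]] / c2) + eps)
    opt$mb[[l]] <- beta1 * opt$mb[[l]] + (1 - beta1) * grads$b[[l]]
    opt$vb[[l]] <- beta2 * opt$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (opt$mb[[l]] / c1) / (sqrt(opt$vb[[l]] / c2) + eps)
  }
  list(net = net, opt = opt)
}

#' @export
print.fog_network <- function(x, ...) {
  s <- x$spec
  cat("Dense network:", s$input_dim, "->",
      paste(s$layer_widths, collapse = " -> "),
      sprintf("(%s hidden, %s output)\n", s$hidden_activation, s$output_activation))
  if (any(s$dropout > 0))
    cat("Dropout:", paste(s$dropout, collapse = ", "), "\n")
  cat("Trainable parameters:", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}
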