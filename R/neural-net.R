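#' Configuration of the calibration network
#'
#' A shallow fully connected network mapping `q` observed state frames
#' (flattened to `input_dim` numbers) to `p` nonnegative parameter
#' estimates. The default architecture is a single hidden layer of 20
#' neurons with the modulus `x -> |x|` as activation on both the hidden and
#' the output layer; the modulus on the output guarantees nonnegative
#' parameter estimates by construction. Outputs are multiplied by
#' per-parameter `output_scales` so the whole prior box is reachable with
#' pre-activations of order one.
#'
#' @param input_dim Number of inputs (`q` frames times state dimension).
#' @param param_names Character vector naming the `p` calibrated parameters.
#' @param hidden Width(s) of the hidden layer(s); default a single layer of
#'   20 neurons.
#' @param activation `"abs"` (default) or `"tanh"`; the hidden-layer
#'   activation.
#' @param final_activation `"abs"` (default) maps the output through the
#'   modulus, guaranteeing nonnegative estimates of unbounded magnitude;
#'   `"sigmoid"` maps each output into `(0, output_scale)`, confining the
#'   estimates to the prior box. The bounded variant encodes the a-priori
#'   knowledge that the parameters live in a known range and keeps the
#'   training dynamics out of numerically dangerous regions, which matters
#'   when the training data are dominated by noise.
#' @param prior_ranges `p x 2` matrix of finite `[lower, upper]` prior
#'   intervals, one row per parameter; the net is initialised so its first
#'   prediction is uniform over this box.
#' @param output_scales Positive per-parameter output multipliers; default
#'   the prior upper bounds (or 1 where the upper bound is 0).
#' @return An object of class `net_config`.
#' @export
net_config <- function(input_dim, param_names, hidden = 20L,
                       activation = c("abs", "tanh"),
                       final_activation = c("abs", "sigmoid"),
                       prior_ranges, output_scales = NULL) {
  activation <- match.arg(activation)
  final_activation <- match.arg(final_activation)
  p <- length(param_names)
  prior_ranges <- matrix(as.numeric(prior_ranges), ncol = 2L)
  stopifnot(nrow(prior_ranges) == p, all(is.finite(prior_ranges)),
            all(prior_ranges[, 2L] >= prior_ranges[, 1L]),
            all(prior_ranges[, 1L] >= 0))
  if (is.null(output_scales)) {
    output_scales <- pmax(prior_ranges[, 2L], 1e-8)
  }
  stopifnot(length(output_scales) == p, all(output_scales > 0))
  structure(
    list(input_dim = as.integer(input_dim), param_names = param_names,
         hidden = as.integer(hidden), activation = activation,
         final_activation = final_activation,
         prior_ranges = prior_ranges, output_scales = output_scales),
    class = "net_config"
  )
}

.act <- function(x, kind) if (kind == "abs") abs(x) else tanh(x)
# derivative of the activation; sign(0) = 0 realises the minimum-norm
# subgradient of |x| at the kink
.act_grad <- function(x, kind) if (kind == "abs") sign(x) else 1 - tanh(x)^2

#' Create a calibration network
#'
#' Draws the weights from small zero-mean Gaussians (standard deviation
#' `1/sqrt(fan-in)`). Use [initialize_uniform_prior()] afterwards to pin the
#' initial prediction to a uniform draw over the prior box.
#'
#' @param config A [net_config()].
#' @param seed Optional integer seed.
#' @return An object of class `neural_net`.
#' @export
neural_net <- function(config, seed = NULL) {
  stopifnot(inherits(config, "net_config"))
  if (!is.null(seed)) set.seed(seed)
  d <- config$input_dim
  h <- config$hidden[1L]
  p <- nrow(config$prior_ranges)
  net <- list(
    W1 = matrix(stats::rnorm(h * d, sd = 1 / sqrt(d)), h, d),
    b1 = stats::rnorm(h, sd = 0.1),
    W2 = matrix(stats::rnorm(p * h, sd = 1 / sqrt(h)), p, h),
    b2 = numeric(p),
    config = config
  )
  class(net) <- "neural_net"
  net
}

#' Pin the network's initial prediction to a uniform prior draw
#'
#' Draws one point uniformly from the prior box and shifts the output-layer
#' bias so that the network's prediction on the reference input equals that
#' point exactly. Across repeated initialisations the distribution of the
#' initial parameter estimate is therefore exactly uniform over the prior
#' ranges, which makes the implied prior of the loss-potential posterior a
#' uniform density.
#'
#' @param net A [neural_net()].
#' @param x_ref Reference input (the first training frame).
#' @return The adjusted `neural_net`, with the drawn initial estimate
#'   attached as attribute `"lambda0"`.
#' @export
initialize_uniform_prior <- function(net, x_ref) {
  cfg <- net$config
  stopifnot(length(x_ref) == cfg$input_dim)
  pr <- cfg$prior_ranges
  lambda0 <- stats::runif(nrow(pr), pr[, 1L], pr[, 2L])
  h <- .act(as.vector(net$W1 %*% x_ref + net$b1), cfg$activation)
  target <- if (identical(cfg$final_activation, "sigmoid")) {
    # invert the sigmoid within the open box
    frac <- pmin(pmax(lambda0 / cfg$output_scales, 1e-6), 1 - 1e-6)
    log(frac / (1 - frac))
  } else {
    # the target pre-activation is nonnegative, where the modulus is the
    # identity, so the match is exact
    lambda0 / cfg$output_scales
  }
  net$b2 <- target - as.vector(net$W2 %*% h)
  attr(net, "lambda0") <- lambda0
  net
}

#' Network forward pass
#'
#' @param net A [neural_net()].
#' @param x Numeric input of length `input_dim` (one or more observed
#'   frames, flattened).
#' @return Named numeric vector of `p` nonnegative parameter estimates.
#' @export
net_forward <- function(net, x) {
  out <- .net_forward_cache(net, x)$lambda
  stats::setNames(out, net$config$param_names)
}

.net_forward_cache <- function(net, x) {
  cfg <- net$config
  if (length(x) != cfg$input_dim) {
    stop(sprintf("input has length %d but the net expects %d.",
                 length(x), cfg$input_dim), call. = FALSE)
  }
  z1 <- as.vector(net$W1 %*% x + net$b1)
  h <- .act(z1, cfg$activation)
  z2 <- as.vector(net$W2 %*% h + net$b2)
  fact <- cfg$final_activation %||% "abs"
  lambda <- if (fact == "sigmoid") {
    cfg$output_scales / (1 + exp(-z2))
  } else {
    .act(z2, cfg$activation) * cfg$output_scales
  }
  list(x = x, z1 = z1, h = h, z2 = z2, lambda = lambda)
}

# Backpropagate dJ/dlambda through the net; returns gradients for each
# weight array.
.net_backward <- function(net, cache, dlambda) {
  cfg <- net$config
  fact <- cfg$final_activation %||% "abs"
  dz2 <- if (fact == "sigmoid") {
    sg <- 1 / (1 + exp(-cache$z2))
    dlambda * cfg$output_scales * sg * (1 - sg)
  } else {
    dlambda * cfg$output_scales * .act_grad(cache$z2, cfg$activation)
  }
  dh <- as.vector(crossprod(net$W2, dz2))
  dz1 <- dh * .act_grad(cache$z1, cfg$activation)
  list(W1 = tcrossprod(dz1, cache$x), b1 = dz1,
       W2 = tcrossprod(dz2, cache$h), b2 = dz2)
}

# Adam optimizer state and update ---------------------------------------------

.adam_init <- function(net) {
  zeros <- lapply(net[c("W1", "b1", "W2", "b2")], function(w) w * 0)
  list(m = zeros, v = zeros, t = 0L)
}

.adam_step <- function(net, opt, grads, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in c("W1", "b1", "W2", "b2")) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    net[[nm]] <- net[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(net = net, opt = opt)
}

#' Batch-averaged squared-error loss
#'
#' The training loss `J = (1/B) sum_j ||phihat_j - phi_j||^2` between a
#' predicted and an observed trajectory segment; zero exactly when they
#' coincide, and homogeneous of degree two in the residuals.
#'
#' @param pred,obs Numeric matrices of matching dimension, one state vector
#'   per row (vectors are treated as single rows).
#' @return A single nonnegative number.
#' @examples
#' batch_loss(c(0.1, -0.1, 0), c(0, 0, 0)) # 0.02
#' @export
batch_loss <- function(pred, obs) {
  if (is.null(dim(pred))) pred <- matrix(pred, nrow = 1L)
  if (is.null(dim(obs))) obs <- matrix(obs, nrow = 1L)
  if (nrow(pred) == 0L) stop("empty batch.", call. = FALSE)
  if (!identical(dim(pred), dim(obs))) {
    stop("`pred` and `obs` must have identical dimensions.", call. = FALSE)
  }
  mean(rowSums((pred - obs)^2))
}
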