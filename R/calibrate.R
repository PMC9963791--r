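#' Training configuration for neural calibration
#'
#' @param epochs Number of passes over the dataset per initialisation.
#' @param batch_size Number of solver steps `B` per optimizer update: the
#'   loss is accumulated over `B` predicted frames before the weights move.
#'   With `B` equal to the usable series length this is batch gradient
#'   descent; with `B = 1` it is stochastic gradient descent.
#' @param learning_rate Adam learning rate (default 0.002).
#' @param n_init Number of independent network initialisations; pooling
#'   their training samples increases the volume of parameter space
#'   explored, which is how nonconvex loss landscapes (several minima) are
#'   covered.
#' @param solver_noise `"none"` to run the forward solver without noise,
#'   `"learned"` to treat the noise amplitude as an additional network
#'   output (SIR only), or a fixed nonnegative number.
#' @param dt Solver time step; defaults to 1 for the SIR surrogate (one
#'   step per observation frame) and 0.01 for Harris--Wilson.
#' @param seed Master seed; per-initialisation seeds are derived from it.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs, batch_size, learning_rate = 0.002,
                         n_init = 20L, solver_noise = "none", dt = NULL,
                         seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, n_init >= 1)
  if (is.numeric(solver_noise)) {
    stopifnot(solver_noise >= 0)
  } else {
    solver_noise <- match.arg(solver_noise, c("none", "learned"))
  }
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, n_init = as.integer(n_init),
         solver_noise = solver_noise, dt = dt, seed = as.integer(seed)),
    class = "train_config"
  )
}

# deterministic derivation of child seeds from a master seed
.child_seed <- function(master, offset) {
  as.integer((as.numeric(master) %% 65536 * 31013 + offset * 9973 + 1) %%
               2147483647)
}

# problem abstraction: observations plus a gradient-returning rollout ---------

.make_problem <- function(data, model, network, cfg) {
  if (model == "sir") {
    need <- c("S", "I", "R")
    if (!all(need %in% names(data))) {
      stop("SIR data needs columns S, I, R.", call. = FALSE)
    }
    obs <- as.matrix(data[, need])
    dt <- if (is.null(cfg$dt)) 1 else cfg$dt
    learned <- identical(cfg$solver_noise, "learned")
    sigma_fixed <- if (is.numeric(cfg$solver_noise)) cfg$solver_noise else 0
    param_names <- if (learned) c("beta", "tau", "sigma") else c("beta", "tau")
    rollout <- function(lambda, k, B) {
      beta <- lambda[[1L]]
      tau_hat <- lambda[[2L]]
      tau <- max(tau_hat, dt) # stability floor for the explicit scheme
      sigma <- if (learned) lambda[[3L]] else sigma_fixed
      dw <- if (sigma > 0) stats::rnorm(B, sd = sqrt(dt)) else numeric(B)
      path <- .sir_path(obs[k, ], beta, tau, sigma, B, dt, dw, sens = TRUE)
      resid <- path$states[-1L, , drop = FALSE] -
        obs[(k + 1L):(k + B), , drop = FALSE]
      J <- mean(rowSums(resid^2))
      dl <- numeric(3L)
      for (t in seq_len(B)) {
        dl <- dl + as.vector(resid[t, ] %*% path$sens[[t + 1L]])
      }
      dl <- 2 * dl / B
      if (tau_hat < tau) dl[2L] <- 0 # clamped: minimum-norm subgradient
      list(loss = J, grad = dl[seq_along(param_names)])
    }
    list(obs = obs, dt = dt, param_names = param_names,
         input_dim = ncol(obs), rollout = rollout,
         default_priors = rbind(beta = c(0, 1), tau = c(1, 30),
                                sigma = c(0, 0.5))[seq_along(param_names), ,
                                                   drop = FALSE])
  } else {
    if (is.null(network)) {
      stop("Harris-Wilson calibration needs a `network`.", call. = FALSE)
    }
    wcols <- grep("^W[0-9]+$", names(data), value = TRUE)
    if (length(wcols) == 0L) {
      stop("Harris-Wilson data needs columns W1..WM.", call. = FALSE)
    }
    obs <- as.matrix(data[, wcols])
    dt <- if (is.null(cfg$dt)) 0.01 else cfg$dt
    if (identical(cfg$solver_noise, "learned")) {
      stop("learned solver noise is only supported for the SIR model.",
           call. = FALSE)
    }
    sigma_fixed <- if (is.numeric(cfg$solver_noise)) cfg$solver_noise else 0
    param_names <- c("alpha", "beta", "kappa")
    net_cache <- .hw_cache(network)
    rollout <- function(lambda, k, B) {
      params <- list(alpha = lambda[[1L]], beta = lambda[[2L]],
                     kappa = max(lambda[[3L]], 1e-6), epsilon = 1,
                     sigma = sigma_fixed)
      dw <- if (sigma_fixed > 0) {
        matrix(stats::rnorm(B * ncol(obs), sd = sqrt(dt)), B, ncol(obs))
      } else {
        NULL
      }
      path <- .hw_path(obs[k, ], network, params, B, dt, dw = dw,
                       sens = TRUE, cache = net_cache)
      # steady-state data of length one: the target is the input frame
      # itself (self-consistency); otherwise the next B observed frames
      target <- if (nrow(obs) == 1L) {
        obs[rep(1L, B), , drop = FALSE]
      } else {
        obs[(k + 1L):(k + B), , drop = FALSE]
      }
      resid <- path$states[-1L, , drop = FALSE] - target
      J <- mean(rowSums(resid^2))
      dl <- numeric(3L)
      for (t in seq_len(B)) {
        dl <- dl + as.vector(resid[t, ] %*% path$sens[[t + 1L]])
      }
      list(loss = J, grad = 2 * dl / B)
    }
    list(obs = obs, dt = dt, param_names = param_names,
         input_dim = ncol(obs), rollout = rollout,
         default_priors = rbind(alpha = c(0, 2), beta = c(0, 6),
                                kappa = c(0, 5)))
  }
}

# Batch start indices for a series of L frames with q = 1 input frame.
# Only full batches are used (leftover frames shorter than B are not made
# into a trailing batch: near an absorbed end state they would contribute
# loss values of exactly zero for any parameters, flooding the posterior
# with maximum-weight samples at arbitrary locations). If the series is
# shorter than B, a single short batch covers it; steady-state data of
# length one yields a single self-consistency batch.
.batch_plan <- function(L, B) {
  if (L <= 1L) {
    return(list(starts = 1L, sizes = min(B, 1L)))
  }
  n_full <- (L - 1L) %/% B
  if (n_full >= 1L) {
    starts <- 1L + B * (seq_len(n_full) - 1L)
    list(starts = starts, sizes = rep(B, n_full))
  } else {
    list(starts = 1L, sizes = L - 1L)
  }
}

#' One training epoch
#'
#' Processes the dataset once in batches. For each batch the network reads
#' the observed frame at the batch start, emits a parameter estimate, the
#' solver is run for `B` steps from that frame (teacher forcing), the
#' batch-averaged squared-error loss and its gradient are computed through
#' the solver, and Adam takes one step. One `(lambda, J)` sample is recorded
#' per optimizer step; a non-finite loss is recorded with `J = Inf` and the
#' step is skipped.
#'
#' @param state A calibration state as produced by [calibrate()]'s
#'   internals: a list with elements `net`, `opt`, `problem`, `cfg`.
#' @param epoch Integer epoch index stored with the samples.
#' @return The updated state, with a `samples` data frame of this epoch's
#'   visited `(lambda, J)` points.
#' @export
train_epoch <- function(state, epoch = 1L) {
  problem <- state$problem
  cfg <- state$cfg
  plan <- .batch_plan(nrow(problem$obs), cfg$batch_size)
  nb <- length(plan$starts)
  p <- length(problem$param_names)
  lam_rec <- matrix(NA_real_, nb, p)
  loss_rec <- numeric(nb)
  for (b in seq_len(nb)) {
    step <- .train_batch(state$net, state$opt, problem, cfg,
                         plan$starts[b], plan$sizes[b])
    state$net <- step$net
    state$opt <- step$opt
    lam_rec[b, ] <- step$lambda
    loss_rec[b] <- step$loss
  }
  samples <- as.data.frame(lam_rec)
  names(samples) <- problem$param_names
  samples$loss <- loss_rec
  samples$epoch <- epoch
  samples$batch <- seq_len(nb)
  state$samples <- samples
  state
}

# One optimizer step: forward, rollout, backprop, Adam update. The
# estimate entering the solver is clamped to the training box (twice the
# prior range) with a pass-through gradient: an excursion beyond the box
# still feels the restoring gradient at the box edge instead of wandering
# onto flat far-field plateaus of the loss, which is how the net is kept
# out of the numerically dangerous parameter regions.
.train_batch <- function(net, opt, problem, cfg, k, B) {
  cache <- .net_forward_cache(net, problem$obs[k, ])
  lam <- pmin(cache$lambda, problem$clamp_hi %||% Inf)
  out <- tryCatch(problem$rollout(lam, k, B),
                  error = function(e) list(loss = Inf, grad = NULL))
  if (is.finite(out$loss) && all(is.finite(out$grad))) {
    grads <- .net_backward(net, cache, out$grad)
    upd <- .adam_step(net, opt, grads, cfg$learning_rate)
    net <- upd$net
    opt <- upd$opt
  }
  list(net = net, opt = opt, lambda = lam, loss = out$loss)
}

.train_one_init <- function(problem, ncfg, cfg, init_seed, init_id) {
  set.seed(init_seed)
  net <- neural_net(ncfg)
  net <- initialize_uniform_prior(net, problem$obs[1L, ])
  opt <- .adam_init(net)
  plan <- .batch_plan(nrow(problem$obs), cfg$batch_size)
  nb <- length(plan$starts)
  p <- length(problem$param_names)
  total <- cfg$epochs * nb
  lam_rec <- matrix(NA_real_, total, p)
  loss_rec <- numeric(total)
  row <- 0L
  for (e in seq_len(cfg$epochs)) {
    for (b in seq_len(nb)) {
      step <- .train_batch(net, opt, problem, cfg, plan$starts[b],
                           plan$sizes[b])
      net <- step$net
      opt <- step$opt
      row <- row + 1L
      lam_rec[row, ] <- step$lambda
      loss_rec[row] <- step$loss
    }
  }
  samples <- as.data.frame(lam_rec)
  names(samples) <- problem$param_names
  samples$loss <- loss_rec
  samples$epoch <- rep(seq_len(cfg$epochs), each = nb)
  samples$batch <- rep(seq_len(nb), times = cfg$epochs)
  samples$init_id <- init_id
  final_lambda <- net_forward(net, problem$obs[1L, ])
  list(samples = samples, final = final_lambda, net = net)
}

#' Calibrate model parameters with a neural network
#'
#' The core procedure: a shallow neural network maps an observed state
#' frame to a parameter estimate; a differentiable solver turns the
#' estimate into a predicted trajectory segment; the batch-averaged squared
#' error between prediction and observation trains the network. Every
#' parameter estimate visited during training is recorded together with its
#' loss value, tracing out a potential over parameter space from which
#' posterior marginals are later estimated (see [marginal()]). Training is
#' repeated from `n_init` independent uniform-prior initialisations and the
#' samples pooled, so that distinct minima of a nonconvex loss are all
#' visited.
#'
#' @param data A data frame of observations: columns `S`, `I`, `R` for the
#'   SIR surrogate, or `W1..WM` for Harris--Wilson (a single row is treated
#'   as steady-state data whose target is itself).
#' @param model `"sir"` or `"harris_wilson"`.
#' @param train_cfg A [train_config()].
#' @param network An [hw_network()]; required for `model = "harris_wilson"`.
#' @param net_cfg Optional [net_config()]; a default with one hidden layer
#'   of 20 modulus-activated neurons and model-appropriate prior ranges is
#'   built when omitted.
#' @return An object of class `calibration_fit` with elements `samples`
#'   (tibble: `init_id`, `epoch`, `batch`, one column per parameter,
#'   `loss`), `final` (per-initialisation final parameter estimates),
#'   `model`, `net_cfg`, `train_cfg`.
#' @examples
#' traj <- integrate_sir(c(0.99, 0.01, 0), sir_params(0.3, 10), 40)
#' fit <- calibrate(traj, "sir",
#'                  train_config(epochs = 5, batch_size = 40, n_init = 2))
#' dplyr::glimpse(fit$samples)
#' @export
calibrate <- function(data, model = c("sir", "harris_wilson"), train_cfg,
                      network = NULL, net_cfg = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(train_cfg, "train_config"))
  problem <- .make_problem(data, model, network, train_cfg)
  if (is.null(net_cfg)) {
    net_cfg <- net_config(input_dim = problem$input_dim,
                          param_names = problem$param_names,
                          prior_ranges = problem$default_priors)
  }
  stopifnot(identical(net_cfg$param_names, problem$param_names))
  problem$clamp_hi <- 2 * pmax(net_cfg$prior_ranges[, 2L], 1e-6)

  runs <- vector("list", train_cfg$n_init)
  errors <- character(0)
  for (i in seq_len(train_cfg$n_init)) {
    runs[[i]] <- tryCatch(
      .train_one_init(problem, net_cfg, train_cfg,
                      .child_seed(train_cfg$seed, i), i),
      error = function(e) e
    )
    if (inherits(runs[[i]], "error")) {
      errors <- c(errors, sprintf("init %d: %s", i,
                                  conditionMessage(runs[[i]])))
    }
  }
  ok <- !vapply(runs, inherits, logical(1L), "error")
  if (!any(ok)) {
    stop("all initialisations failed:\n", paste(errors, collapse = "\n"),
         call. = FALSE)
  }
  samples <- dplyr::bind_rows(lapply(runs[ok], `[[`, "samples"))
  samples <- tibble::as_tibble(
    samples[, c("init_id", "epoch", "batch", problem$param_names, "loss")]
  )
  final <- dplyr::bind_rows(lapply(which(ok), function(i) {
    tibble::as_tibble(c(list(init_id = i), as.list(runs[[i]]$final),
                        list(loss = NA_real_)))
  }))
  # final loss per init: minimum loss over its last epoch
  last <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(samples, .data$epoch == max(.data$epoch)),
                    .data$init_id),
    loss = min(.data$loss), .groups = "drop"
  )
  final$loss <- last$loss[match(final$init_id, last$init_id)]
  structure(
    list(samples = samples, final = final, model = model,
         net_cfg = net_cfg, train_cfg = train_cfg,
         failed = errors),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> model: %s | %d initialisations | %d samples | min loss %.4g\n",
    x$model, x$train_cfg$n_init, nrow(x$samples),
    min(x$samples$loss, na.rm = TRUE)
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration fit
#'
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @return The pooled sample table: one row per optimizer step with
#'   `init_id`, `epoch`, `batch`, the visited parameter estimate and its
#'   loss.
#' @method tidy calibration_fit
#' @export
tidy.calibration_fit <- function(x, ...) x$samples

#' One-row summary of a calibration fit
#'
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @return A one-row tibble with sample counts and the best visited loss.
#' @method glance calibration_fit
#' @export
glance.calibration_fit <- function(x, ...) {
  best <- x$samples[which.min(x$samples$loss), ]
  out <- tibble::tibble(
    model = x$model,
    n_init = x$train_cfg$n_init,
    epochs = x$train_cfg$epochs,
    n_samples = nrow(x$samples),
    min_loss = best$loss
  )
  pars <- x$net_cfg$param_names
  for (p in pars) out[[paste0("best_", p)]] <- best[[p]]
  out
}
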