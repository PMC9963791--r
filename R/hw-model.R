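#' Parameters of the Harris--Wilson network model
#'
#' Destination-zone sizes `W_j` on a complete bipartite origin--destination
#' network evolve by `M` coupled logistic SDEs
#' \deqn{dW_j = \epsilon W_j (D_j - \kappa W_j)\,dt + \sigma W_j \circ dB_j,}
#' where the demands `D_j` aggregate the flows from every origin zone.
#'
#' @param alpha Relative importance of destination size (nonnegative).
#' @param beta Relative importance of travel convenience (nonnegative).
#' @param kappa Cost per unit floor space (positive).
#' @param epsilon Responsiveness: the rate at which zones adapt to demand
#'   (positive). The noiseless steady state does not depend on it.
#' @param sigma Multiplicative noise amplitude (nonnegative).
#' @return An object of class `hw_params`.
#' @export
hw_params <- function(alpha, beta, kappa, epsilon = 1, sigma = 0) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0) {
    stop("`kappa` must be a single positive number.", call. = FALSE)
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("`epsilon` must be a single positive number.", call. = FALSE)
  }
  stopifnot(is.numeric(alpha), alpha >= 0, is.numeric(beta), beta >= 0,
            is.numeric(sigma), sigma >= 0)
  structure(list(alpha = alpha, beta = beta, kappa = kappa,
                 epsilon = epsilon, sigma = sigma),
            class = "hw_params")
}

#' An origin--destination network for the Harris--Wilson model
#'
#' @param origin_sizes Vector of `N` positive origin-zone sizes `O_i`
#'   (fixed demands).
#' @param cost_matrix `N x M` nonnegative convenience matrix `c_ij`; no row
#'   may be all zero (every origin must reach some destination).
#' @param initial_sizes Vector of `M` positive initial destination sizes
#'   `W_{j,0}`.
#' @return An object of class `hw_network`.
#' @export
hw_network <- function(origin_sizes, cost_matrix, initial_sizes) {
  cost_matrix <- as.matrix(cost_matrix)
  origin_sizes <- as.numeric(origin_sizes)
  initial_sizes <- as.numeric(initial_sizes)
  stopifnot(nrow(cost_matrix) == length(origin_sizes),
            ncol(cost_matrix) == length(initial_sizes))
  if (any(origin_sizes <= 0)) {
    stop("all origin sizes must be positive.", call. = FALSE)
  }
  if (any(initial_sizes <= 0)) {
    stop("all initial destination sizes must be positive.", call. = FALSE)
  }
  if (any(cost_matrix < 0)) {
    stop("the cost matrix must be nonnegative.", call. = FALSE)
  }
  if (any(rowSums(cost_matrix) == 0)) {
    stop("the cost matrix has an all-zero row: that origin reaches no destination.",
         call. = FALSE)
  }
  structure(list(origin_sizes = origin_sizes,
                 cost_matrix = cost_matrix,
                 initial_sizes = initial_sizes),
            class = "hw_network")
}

#' Demand flows on the Harris--Wilson network
#'
#' Computes the origin-to-destination flow matrix
#' `T_ij = O_i W_j^alpha c_ij^beta / sum_k W_k^alpha c_ik^beta` and the
#' resulting demands `D_j = sum_i T_ij`. Each origin's demand is fully
#' distributed: the rows of `T` sum to `O_i`, so `sum_j D_j = sum_i O_i`.
#'
#' @param w Vector of `M` positive destination sizes.
#' @param network An [hw_network()].
#' @param alpha,beta Size and convenience exponents.
#' @return A list with elements `flows` (`N x M` matrix) and `demand`
#'   (length-`M` vector).
#' @export
hw_flows <- function(w, network, alpha, beta) {
  stopifnot(inherits(network, "hw_network"))
  if (any(w <= 0)) stop("destination sizes must be positive.", call. = FALSE)
  A <- .hw_attraction(w, network$cost_matrix, alpha, beta)
  Z <- rowSums(A)
  if (any(Z == 0)) {
    stop("degenerate origin row: zero attraction to every destination (all-zero costs with beta > 0).",
         call. = FALSE)
  }
  flows <- A * (network$origin_sizes / Z)
  list(flows = flows, demand = colSums(flows))
}

# A_ij = W_j^alpha c_ij^beta. Note 0^0 = 1 in R, so beta = 0 neutralises the
# cost kernel even at c_ij = 0, as required.
.hw_attraction <- function(w, costs, alpha, beta) {
  cb <- if (beta == 0) array(1, dim(costs)) else costs^beta
  wa <- w^alpha
  cb * rep(wa, each = nrow(costs))
}

# precomputable per-network quantities for the hot path; entries with
# c_ij = 0 get log = -Inf, and exp(beta * -Inf) = 0 reproduces 0^beta
.hw_cache <- function(net) {
  lnC <- log(net$cost_matrix)
  lnC[net$cost_matrix == 0] <- log(.Machine$double.xmin)
  list(lnC = lnC, O = net$origin_sizes, N = nrow(net$cost_matrix))
}

# Drift f_j = eps * W_j * (D_j - kappa W_j) and, if jac, its Jacobians with
# respect to the state (M x M) and to (alpha, beta, kappa) (M x 3).
# `cb` = costs^beta may be supplied to share the power between the Heun
# predictor and corrector stages.
.hw_drift <- function(w, net, alpha, beta, kappa, eps, jac = FALSE,
                      cache = NULL, cb = NULL) {
  if (is.null(cache)) cache <- .hw_cache(net)
  O <- cache$O
  M <- length(w)
  if (is.null(cb)) cb <- exp(beta * cache$lnC)
  A <- cb * rep(w^alpha, each = cache$N)
  Z <- rowSums(A)
  Tm <- A * (O / Z)
  D <- colSums(Tm)
  f <- eps * w * (D - kappa * w)
  if (!jac) return(list(f = f, demand = D))

  lnW <- log(w)
  lnC <- cache$lnC
  # d D_j / d alpha
  s_a <- as.vector(Tm %*% lnW) / O
  dDa <- lnW * D - as.vector(crossprod(Tm, s_a))
  # d D_j / d beta
  TlnC <- Tm * lnC
  s_b <- rowSums(TlnC) / O
  dDb <- colSums(TlnC) - as.vector(crossprod(Tm, s_b))
  # d D_j / d W_m = alpha * (delta_jm D_j / w_j - G_jm / w_m),
  # G_jm = sum_i T_ij T_im / O_i
  G <- crossprod(Tm, Tm / O)
  dDW <- G * rep(-alpha / w, each = M)
  diag(dDW) <- diag(dDW) + alpha * D / w
  Jw <- eps * (w * dDW)
  diag(Jw) <- diag(Jw) + eps * (D - 2 * kappa * w)
  Jp <- cbind(eps * w * dDa, eps * w * dDb, -eps * w^2)
  list(f = f, demand = D, Jw = Jw, Jp = Jp)
}

# One Heun step of the Harris--Wilson SDE with multiplicative Stratonovich
# noise g_j = sigma W_j and optional sensitivities w.r.t. (alpha, beta,
# kappa). `dw` is the length-M vector of Wiener increments. Sizes are floored
# at `floor` to keep training excursions out of the unstable region; floored
# components get zero sensitivity (minimum-norm subgradient of the clamp).
.hw_heun_step <- function(w, net, alpha, beta, kappa, eps, sigma, dt, dw,
                          Smat = NULL, floor = 1e-8, cache = NULL,
                          cb = NULL) {
  jac <- !is.null(Smat)
  if (is.null(cache)) cache <- .hw_cache(net)
  if (is.null(cb)) cb <- exp(beta * cache$lnC)
  e1 <- .hw_drift(w, net, alpha, beta, kappa, eps, jac = jac,
                  cache = cache, cb = cb)
  pred <- w + e1$f * dt + sigma * w * dw
  pred <- pmax(pred, floor)
  e2 <- .hw_drift(pred, net, alpha, beta, kappa, eps, jac = jac,
                  cache = cache, cb = cb)
  w_new <- w + 0.5 * dt * (e1$f + e2$f) + 0.5 * sigma * (w + pred) * dw
  clamped <- !is.na(w_new) & w_new < floor
  w_new <- pmax(w_new, floor)
  if (!jac) return(list(w = w_new, Smat = NULL))
  S_pred <- Smat + dt * (e1$Jw %*% Smat + e1$Jp) + sigma * dw * Smat
  S_new <- Smat +
    0.5 * dt * (e1$Jw %*% Smat + e1$Jp + e2$Jw %*% S_pred + e2$Jp) +
    0.5 * sigma * dw * (Smat + S_pred)
  if (any(clamped)) S_new[clamped, ] <- 0
  list(w = w_new, Smat = S_new)
}

.hw_path <- function(w0, net, params, n_steps, dt, dw = NULL,
                     sens = FALSE, keep_every = 1L, cache = NULL) {
  M <- length(w0)
  if (is.null(dw)) dw <- matrix(0, n_steps, M)
  keep_idx <- seq(0L, n_steps, by = keep_every)
  states <- matrix(0, length(keep_idx), M)
  states[1L, ] <- w0
  w <- w0
  if (is.null(cache)) cache <- .hw_cache(net)
  cb <- exp(params$beta * cache$lnC)
  Smat <- if (sens) matrix(0, M, 3L) else NULL
  sens_list <- if (sens) vector("list", n_steps + 1L) else NULL
  if (sens) sens_list[[1L]] <- Smat
  row <- 1L
  for (t in seq_len(n_steps)) {
    st <- .hw_heun_step(w, net, params$alpha, params$beta, params$kappa,
                        params$epsilon, params$sigma, dt, dw[t, ], Smat,
                        cache = cache, cb = cb)
    w <- st$w
    if (any(!is.finite(w))) {
      stop(sprintf("numerical instability in the Harris-Wilson integrator at step %d", t),
           call. = FALSE)
    }
    if (sens) {
      Smat <- st$Smat
      sens_list[[t + 1L]] <- Smat
    }
    if (t %% keep_every == 0L) {
      row <- row + 1L
      states[row, ] <- w
    }
  }
  list(states = states, times = keep_idx * dt, sens = sens_list, w = w)
}

#' Integrate the Harris--Wilson SDE
#'
#' Heun (predictor--corrector) integration of the `M` coupled logistic
#' equations with multiplicative Stratonovich noise. Sizes are kept positive
#' by the scheme plus a small positivity floor.
#'
#' @param network An [hw_network()].
#' @param params An [hw_params()].
#' @param n_steps Number of integration steps.
#' @param dt Time step (default 0.01).
#' @param seed Optional seed for the Wiener increments.
#' @param keep_every Record every `keep_every`-th step (plus the initial
#'   state).
#' @return A tibble with a `time` column and one `W<j>` column per
#'   destination zone.
#' @export
integrate_hw <- function(network, params, n_steps, dt = 0.01, seed = NULL,
                         keep_every = 1L) {
  stopifnot(inherits(network, "hw_network"), dt > 0, n_steps >= 1)
  if (!inherits(params, "hw_params")) params <- do.call(hw_params, params)
  M <- length(network$initial_sizes)
  if (params$sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    dw <- matrix(stats::rnorm(n_steps * M, sd = sqrt(dt)), n_steps, M)
  } else {
    dw <- NULL
  }
  path <- .hw_path(network$initial_sizes, network, params, n_steps, dt,
                   dw = dw, keep_every = keep_every)
  out <- tibble::as_tibble(
    stats::setNames(as.data.frame(path$states),
                    paste0("W", seq_len(M)))
  )
  out <- dplyr::bind_cols(tibble::tibble(time = path$times), out)
  attr(out, "model_tag") <- "harris_wilson"
  out
}

#' Noiseless steady state of the Harris--Wilson model
#'
#' Iterates the noiseless dynamics until the per-step change satisfies
#' `sup_j |dW_j| < tol`. At the fixed point the balance `D = kappa W`
#' holds, equivalently
#' `sum_i c_ij^beta O_i / sum_k W_k^alpha c_ik^beta = kappa W_j^(1-alpha)`.
#'
#' @param network An [hw_network()].
#' @param params An [hw_params()] with `sigma = 0`.
#' @param tol Convergence tolerance on the per-step change of the
#'   integration phase.
#' @param dt Time step.
#' @param max_steps Maximum number of steps before a convergence failure is
#'   raised.
#' @param polish After the integrator has converged, refine the fixed point
#'   with damped self-consistency iterations `w <- (1-g) w + g D(w)/kappa`
#'   until the relative balance residual falls below `resid_tol`. Small
#'   zones equilibrate very slowly under plain forward integration (their
#'   relaxation rate is proportional to their own size), and the polishing
#'   phase removes that residual at negligible cost.
#' @param resid_tol Target maximum relative balance residual for the
#'   polishing phase.
#' @return Numeric vector of `M` steady-state sizes, with attributes
#'   `steps` and `residual` (the maximum relative balance residual).
#' @export
hw_steady_state <- function(network, params, tol = 1e-6, dt = 0.01,
                            max_steps = 1e5, polish = TRUE,
                            resid_tol = 1e-9) {
  stopifnot(inherits(network, "hw_network"))
  if (!inherits(params, "hw_params")) params <- do.call(hw_params, params)
  if (params$sigma > 0) {
    stop("`hw_steady_state()` requires sigma = 0; use `integrate_hw()` and a late-time window for the noisy dynamics.",
         call. = FALSE)
  }
  w <- network$initial_sizes
  sup_dw <- Inf
  steps <- NA_integer_
  for (t in seq_len(max_steps)) {
    st <- .hw_heun_step(w, network, params$alpha, params$beta, params$kappa,
                        params$epsilon, 0, dt, numeric(length(w)))
    sup_dw <- max(abs(st$w - w))
    w <- st$w
    if (any(!is.finite(w))) {
      stop(sprintf("numerical instability in the Harris-Wilson integrator at step %d", t),
           call. = FALSE)
    }
    if (sup_dw < tol) {
      steps <- t
      break
    }
  }
  if (is.na(steps)) {
    stop(sprintf("steady state not reached within %d steps (sup_j |dW_j| = %.3g).",
                 as.integer(max_steps), sup_dw), call. = FALSE)
  }
  resid <- .hw_scale_residual(w, network, params)
  if (polish) {
    gamma <- 0.7
    for (it in seq_len(5000L)) {
      if (resid < resid_tol) break
      D <- hw_flows(w, network, params$alpha, params$beta)$demand
      w_new <- (1 - gamma) * w + gamma * D / params$kappa
      resid_new <- .hw_scale_residual(w_new, network, params)
      if (!is.finite(resid_new) || resid_new > resid) {
        gamma <- gamma / 2 # safeguard: damp harder if the map overshoots
        if (gamma < 1e-4) break
      } else {
        w <- w_new
        resid <- resid_new
      }
    }
  }
  attr(w, "steps") <- steps
  attr(w, "residual") <- resid
  w
}

# Balance residual normalised by the dominant cost scale kappa * max(w):
# zones that die out under a strong size preference approach w = 0, where
# the per-zone relative residual tends to -1 but the absolute imbalance
# D - kappa*w vanishes; the scale-relative form is the one a fixed point
# can actually satisfy.
.hw_scale_residual <- function(w, network, params) {
  D <- hw_flows(w, network, params$alpha, params$beta)$demand
  max(abs(D - params$kappa * w)) / (params$kappa * max(w))
}

#' Relative steady-state balance residual
#'
#' Relative residual of the fixed-point condition `D_j = kappa W_j` (the
#' steady-state balance of demand against maintenance cost), evaluated at a
#' candidate size vector.
#'
#' @param w Vector of `M` positive sizes.
#' @param network An [hw_network()].
#' @param params An [hw_params()].
#' @return Length-`M` vector of relative residuals
#'   `(D_j - kappa W_j) / (kappa W_j)`.
#' @export
hw_balance_residual <- function(w, network, params) {
  if (!inherits(params, "hw_params")) params <- do.call(hw_params, params)
  D <- hw_flows(w, network, params$alpha, params$beta)$demand
  (D - params$kappa * w) / (params$kappa * w)
}
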