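#' Parameters of the SIR density SDE
#'
#' The surrogate model fitted to the agent-based densities is
#' \deqn{dS = -\beta S I\,dt - \sigma I \circ dW,\quad
#'       dI = (\beta S - \tau^{-1}) I\,dt + \sigma I \circ dW,\quad
#'       dR = \tau^{-1} I\,dt,}
#' with a single shared Wiener process `W` and Stratonovich integration, so
#' the noise terms cancel pairwise and `S + I + R` is conserved pathwise.
#'
#' @param beta Transmission rate (nonnegative).
#' @param tau Recovery time (positive); enters the drift as `1/tau`.
#' @param sigma Noise amplitude (nonnegative).
#' @return An object of class `sir_params`.
#' @export
sir_params <- function(beta, tau, sigma = 0) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("`tau` must be a single positive number.", call. = FALSE)
  }
  stopifnot(is.numeric(beta), beta >= 0, is.numeric(sigma), sigma >= 0)
  structure(list(beta = beta, tau = tau, sigma = sigma),
            class = "sir_params")
}

#' Drift of the SIR density SDE
#'
#' Deterministic part of the surrogate equations, per unit time. Its
#' components sum to zero: the drift conserves total mass.
#'
#' @param state Numeric length-3 state `(S, I, R)`.
#' @param params A [sir_params()].
#' @return Named numeric vector `(dS, dI, dR)`.
#' @export
sir_drift <- function(state, params) {
  if (!inherits(params, "sir_params")) params <- do.call(sir_params, params)
  S <- state[[1L]]; I <- state[[2L]]
  b <- params$beta; tau <- params$tau
  c(dS = -b * S * I, dI = (b * S - 1 / tau) * I, dR = I / tau)
}

# One Heun (predictor-corrector) step of the SIR SDE with optional forward
# sensitivities d(state)/d(beta, tau, sigma). The Heun scheme converges to
# the Stratonovich solution for the multiplicative noise term. `dw` is the
# Wiener increment for this step (a constant w.r.t. the parameters).
.sir_fjac <- function(phi, b, tau) {
  S <- phi[1L]; I <- phi[2L]
  f <- c(-b * S * I, (b * S - 1 / tau) * I, I / tau)
  Jf <- matrix(c(-b * I, -b * S, 0,
                 b * I, b * S - 1 / tau, 0,
                 0, 1 / tau, 0),
               nrow = 3L, byrow = TRUE)
  Pf <- matrix(c(-S * I, 0, 0,
                 S * I, I / tau^2, 0,
                 0, -I / tau^2, 0),
               nrow = 3L, byrow = TRUE)
  list(f = f, Jf = Jf, Pf = Pf)
}

.sir_heun_step <- function(phi, b, tau, sigma, dt, dw, Smat = NULL) {
  e1 <- .sir_fjac(phi, b, tau)
  gdir <- c(-1, 1, 0)
  g0 <- sigma * phi[2L] * gdir
  pred <- phi + e1$f * dt + g0 * dw
  e2 <- .sir_fjac(pred, b, tau)
  g1 <- sigma * pred[2L] * gdir
  phi_new <- phi + 0.5 * dt * (e1$f + e2$f) + 0.5 * dw * (g0 + g1)
  if (is.null(Smat)) return(list(phi = phi_new, Smat = NULL))
  # sensitivity propagation (3 states x 3 params, columns beta, tau, sigma)
  Jg <- matrix(0, 3L, 3L); Jg[, 2L] <- sigma * gdir
  Pg0 <- matrix(0, 3L, 3L); Pg0[, 3L] <- phi[2L] * gdir
  S_pred <- Smat + dt * (e1$Jf %*% Smat + e1$Pf) + dw * (Jg %*% Smat + Pg0)
  Pg1 <- matrix(0, 3L, 3L); Pg1[, 3L] <- pred[2L] * gdir
  S_new <- Smat +
    0.5 * dt * (e1$Jf %*% Smat + e1$Pf + e2$Jf %*% S_pred + e2$Pf) +
    0.5 * dw * (Jg %*% Smat + Pg0 + Jg %*% S_pred + Pg1)
  list(phi = phi_new, Smat = S_new)
}

# Internal path engine. Returns states ((n_steps+1) x 3) and, if sens, the
# per-step sensitivity matrices as a list (entry t+1 = d phi_t / d lambda).
.sir_path <- function(init, beta, tau, sigma, n_steps, dt, dw,
                      sens = FALSE) {
  states <- matrix(0, n_steps + 1L, 3L)
  states[1L, ] <- init
  phi <- init
  Smat <- if (sens) matrix(0, 3L, 3L) else NULL
  sens_list <- if (sens) vector("list", n_steps + 1L) else NULL
  if (sens) sens_list[[1L]] <- Smat
  for (t in seq_len(n_steps)) {
    st <- .sir_heun_step(phi, beta, tau, sigma, dt, dw[t], Smat)
    phi <- st$phi
    if (any(!is.finite(phi))) {
      stop(sprintf("numerical instability in the SIR integrator at step %d", t),
           call. = FALSE)
    }
    states[t + 1L, ] <- phi
    if (sens) {
      Smat <- st$Smat
      sens_list[[t + 1L]] <- Smat
    }
  }
  list(states = states, sens = sens_list)
}

#' Integrate the SIR density SDE
#'
#' Heun (predictor--corrector) integration of the surrogate equations under
#' the Stratonovich convention, with one shared Wiener increment per step
#' feeding the `-sigma I dW` and `+sigma I dW` terms, so that `S + I + R`
#' is conserved along every path.
#'
#' @param init Length-3 initial state `(S, I, R)` on the simplex.
#' @param params A [sir_params()].
#' @param n_steps Number of integration steps.
#' @param dt Time step (default 1: one solver step per observation frame).
#' @param seed Optional seed for the Wiener increments.
#' @param increments Optional numeric vector of `n_steps` Wiener increments
#'   (overrides `seed`); useful for common-random-number experiments.
#' @return A tibble with columns `time`, `S`, `I`, `R`.
#' @examples
#' integrate_sir(c(0.99, 0.01, 0), sir_params(0.3, 14), n_steps = 50)
#' @export
integrate_sir <- function(init, params, n_steps, dt = 1, seed = NULL,
                          increments = NULL) {
  stopifnot(length(init) == 3L, dt > 0, n_steps >= 1)
  if (!inherits(params, "sir_params")) params <- do.call(sir_params, params)
  if (is.null(increments)) {
    if (!is.null(seed)) set.seed(seed)
    increments <- if (params$sigma > 0) {
      stats::rnorm(n_steps, sd = sqrt(dt))
    } else {
      numeric(n_steps)
    }
  }
  stopifnot(length(increments) == n_steps)
  path <- .sir_path(init, params$beta, params$tau, params$sigma,
                    n_steps, dt, increments)
  out <- tibble::tibble(
    time = seq(0, by = dt, length.out = n_steps + 1L),
    S = path$states[, 1L],
    I = path$states[, 2L],
    R = path$states[, 3L]
  )
  attr(out, "model_tag") <- "sir_sde"
  out
}
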