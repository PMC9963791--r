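#' Configuration for the diffusive SIR agent-based model
#'
#' `N` agents move by Brownian steps on a square periodic domain `[0, L)^2`.
#' A susceptible agent within the infection radius `r` of at least one
#' infected agent is infected with probability `p` (one Bernoulli trial per
#' susceptible per step, however many infected neighbours it has). Infected
#' agents recover permanently once their time since infection reaches the
#' recovery time `tau`.
#'
#' @param n_agents Number of agents `N`.
#' @param domain_size Side length `L` of the periodic domain.
#' @param infection_radius Contact radius `r`; must satisfy `r < L / 2`.
#' @param infection_probability Per-step infection probability `p` in `[0, 1]`.
#' @param recovery_time Recovery time `tau` in steps (positive).
#' @param diffusivity Length-3 vector of per-compartment diffusivities
#'   `(sigma_S, sigma_I, sigma_R)`: the standard deviation of the Gaussian
#'   displacement per unit step. The default `(0.15, 0.02, 0.15)` lets an
#'   epidemic started from a single agent percolate the default `L = 10`
#'   domain within the default 100 steps, while moving infected agents much
#'   less than the healthy compartments (the usual mobility reduction of
#'   symptomatic individuals). A single number is recycled to all three
#'   compartments.
#' @param n_steps Number of iterations to simulate.
#' @param seed Integer seed making the run reproducible.
#'
#' @return An object of class `sir_abm_config`.
#' @export
sir_abm_config <- function(n_agents = 3000,
                           domain_size = 10,
                           infection_radius = 0.3,
                           infection_probability = 0.2,
                           recovery_time = 14,
                           diffusivity = c(0.15, 0.02, 0.15),
                           n_steps = 100,
                           seed = 1L) {
  stopifnot(
    is.numeric(n_agents), length(n_agents) == 1L, n_agents >= 1,
    is.numeric(domain_size), length(domain_size) == 1L, domain_size > 0,
    is.numeric(infection_radius), infection_radius > 0,
    is.numeric(recovery_time), recovery_time > 0,
    is.numeric(diffusivity), all(diffusivity >= 0),
    is.numeric(n_steps), length(n_steps) == 1L
  )
  if (n_steps < 1) {
    stop("`n_steps` must be at least 1.", call. = FALSE)
  }
  if (infection_radius >= domain_size / 2) {
    stop("`infection_radius` must be smaller than `domain_size`/2.",
         call. = FALSE)
  }
  if (infection_probability < 0 || infection_probability > 1) {
    stop("`infection_probability` must lie in [0, 1].", call. = FALSE)
  }
  if (length(diffusivity) == 1L) diffusivity <- rep(diffusivity, 3L)
  stopifnot(length(diffusivity) == 3L)
  structure(
    list(
      n_agents = as.integer(n_agents),
      domain_size = domain_size,
      infection_radius = infection_radius,
      infection_probability = infection_probability,
      recovery_time = recovery_time,
      diffusivity = stats::setNames(diffusivity, c("S", "I", "R")),
      n_steps = as.integer(n_steps),
      seed = as.integer(seed)
    ),
    class = "sir_abm_config"
  )
}

#' Initialise an agent population
#'
#' Places all agents uniformly at random on the domain and infects a single
#' randomly chosen agent (time since infection 0). Uses the current RNG
#' state; seed it (or use [simulate_sir_abm()]) for reproducibility.
#'
#' @param config A [sir_abm_config()].
#' @return An object of class `sir_abm_population`: a list with `positions`
#'   (`N x 2` matrix), `compartment` (integer, 1 = S, 2 = I, 3 = R) and
#'   `time_since_infection` (numeric, `NA` for non-infected agents).
#' @export
sir_abm_init <- function(config) {
  n <- config$n_agents
  L <- config$domain_size
  pos <- matrix(stats::runif(2L * n, 0, L), ncol = 2L)
  comp <- rep(1L, n)
  tsi <- rep(NA_real_, n)
  i0 <- sample.int(n, 1L)
  comp[i0] <- 2L
  tsi[i0] <- 0
  structure(
    list(positions = pos, compartment = comp, time_since_infection = tsi),
    class = "sir_abm_population"
  )
}

# contact detection: which susceptibles have >=1 infected within r ------------

# Naive all-pairs scan (reference implementation, O(n_S * n_I)).
.contacts_naive <- function(pos_s, pos_i, r, L) {
  dx <- abs(outer(pos_s[, 1L], pos_i[, 1L], "-"))
  dx <- pmin(dx, L - dx)
  dy <- abs(outer(pos_s[, 2L], pos_i[, 2L], "-"))
  dy <- pmin(dy, L - dy)
  rowSums(dx * dx + dy * dy <= r * r) > 0
}

# Cell-list search with periodic neighbour cells; cell edge >= r so only the
# 3x3 neighbourhood needs scanning. Returns the same logical vector as the
# naive scan.
.contacts_cell <- function(pos_s, pos_i, r, L) {
  ncell <- max(2L, floor(L / r))
  edge <- L / ncell
  key <- function(p) {
    cx <- pmin(floor(p[, 1L] / edge), ncell - 1L)
    cy <- pmin(floor(p[, 2L] / edge), ncell - 1L)
    cbind(cx, cy)
  }
  ci <- key(pos_i)
  cs <- key(pos_s)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1))
  n_i <- nrow(pos_i)
  # replicate each infected agent into its 9 (wrapped) neighbour cells
  inf_keys <- integer(9L * n_i)
  inf_idx <- integer(9L * n_i)
  for (o in seq_len(9L)) {
    cx <- (ci[, 1L] + offs[o, 1L]) %% ncell
    cy <- (ci[, 2L] + offs[o, 2L]) %% ncell
    sl <- ((o - 1L) * n_i + 1L):(o * n_i)
    inf_keys[sl] <- cx + ncell * cy
    inf_idx[sl] <- seq_len(n_i)
  }
  by_cell <- split(inf_idx, inf_keys)
  cand <- by_cell[as.character(cs[, 1L] + ncell * cs[, 2L])]
  len <- lengths(cand)
  out <- logical(nrow(pos_s))
  if (all(len == 0L)) return(out)
  s_rep <- rep.int(seq_len(nrow(pos_s)), len)
  i_cand <- unlist(cand, use.names = FALSE)
  d2 <- .torus_dist2(pos_s[s_rep, , drop = FALSE],
                     pos_i[i_cand, , drop = FALSE], L)
  hit <- s_rep[d2 <= r * r]
  out[hit] <- TRUE
  out
}

#' One iteration of the SIR agent-based model
#'
#' Applies, in order: (1) a Gaussian random displacement per agent, scaled by
#' its compartment's diffusivity and wrapped periodically; (2) infection of
#' susceptibles within radius `r` of the current (post-move) infected set,
#' each with one Bernoulli(`p`) trial — newly infected agents cannot transmit
#' within the same step; (3) ageing of previously infected agents, with
#' recovery once the time since infection reaches `tau`. Recovered agents
#' never change compartment again.
#'
#' @param population A `sir_abm_population`.
#' @param config A [sir_abm_config()].
#' @param contact_method `"cell"` for the cell-list neighbour search
#'   (default) or `"naive"` for the all-pairs reference scan; both return
#'   identical infection candidates.
#' @return The updated `sir_abm_population`.
#' @export
sir_abm_step <- function(population, config,
                         contact_method = c("cell", "naive")) {
  contact_method <- match.arg(contact_method)
  L <- config$domain_size
  pos <- population$positions
  comp <- population$compartment
  tsi <- population$time_since_infection
  n <- nrow(pos)

  # 1. diffuse, wrap
  sd_per_agent <- config$diffusivity[comp]
  pos <- (pos + matrix(stats::rnorm(2L * n), ncol = 2L) * sd_per_agent) %% L

  # 2. infect against the current infected set
  was_infected <- which(comp == 2L)
  sus <- which(comp == 1L)
  if (length(was_infected) > 0L && length(sus) > 0L) {
    fn <- if (contact_method == "cell") .contacts_cell else .contacts_naive
    in_range <- fn(pos[sus, , drop = FALSE],
                   pos[was_infected, , drop = FALSE],
                   config$infection_radius, L)
    at_risk <- sus[in_range]
    if (length(at_risk) > 0L) {
      new_inf <- at_risk[stats::runif(length(at_risk)) <
                           config$infection_probability]
      comp[new_inf] <- 2L
      tsi[new_inf] <- 0
    }
  }

  # 3. age previously infected agents, recover at tau
  if (length(was_infected) > 0L) {
    tsi[was_infected] <- tsi[was_infected] + 1
    rec <- was_infected[tsi[was_infected] >= config$recovery_time]
    comp[rec] <- 3L
    tsi[rec] <- NA_real_
  }

  structure(
    list(positions = pos, compartment = comp, time_since_infection = tsi),
    class = "sir_abm_population"
  )
}

#' Simulate the diffusive SIR agent-based model
#'
#' Runs the agent-based model from a single randomly placed infected agent
#' and records the population fractions of each compartment after every
#' iteration. The first row is the initial condition (`I = 1/N`).
#'
#' @inheritParams sir_abm_step
#' @param config A [sir_abm_config()].
#' @return A tibble with columns `time`, `S`, `I`, `R` and `n_steps + 1`
#'   rows; the configuration is attached as attribute `"config"`.
#' @examples
#' cfg <- sir_abm_config(n_agents = 200, n_steps = 20, seed = 7)
#' simulate_sir_abm(cfg)
#' @export
simulate_sir_abm <- function(config, contact_method = c("cell", "naive")) {
  contact_method <- match.arg(contact_method)
  stopifnot(inherits(config, "sir_abm_config"))
  set.seed(config$seed)
  pop <- sir_abm_init(config)
  n <- config$n_agents
  counts <- matrix(0, nrow = config$n_steps + 1L, ncol = 3L)
  counts[1L, ] <- tabulate(pop$compartment, nbins = 3L)
  for (t in seq_len(config$n_steps)) {
    pop <- sir_abm_step(pop, config, contact_method = contact_method)
    counts[t + 1L, ] <- tabulate(pop$compartment, nbins = 3L)
  }
  out <- tibble::tibble(
    time = 0:config$n_steps,
    S = counts[, 1L] / n,
    I = counts[, 2L] / n,
    R = counts[, 3L] / n
  )
  attr(out, "config") <- config
  attr(out, "model_tag") <- "sir_abm"
  out
}
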