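# Small fixture builders shared across test files. Everything is generated
# in code at test time; no stored data.

tiny_hw_network <- function(n_origins = 8L, n_destinations = 4L, seed = 5L) {
  set.seed(seed)
  hw_network(
    origin_sizes = runif(n_origins, 0.1, 1),
    cost_matrix = matrix(1 - runif(n_origins * n_destinations),
                         n_origins, n_destinations),
    initial_sizes = runif(n_destinations, 0.1, 1)
  )
}

sir_sde_data <- function(beta = 0.3, tau = 14, n_steps = 100,
                         init = c(0.99, 0.01, 0)) {
  integrate_sir(init, sir_params(beta, tau, 0), n_steps = n_steps)
}

hw_default_priors <- rbind(alpha = c(0, 2), beta = c(0, 6), kappa = c(0, 5))

hw_net_config <- function(m) {
  net_config(input_dim = m, param_names = c("alpha", "beta", "kappa"),
             prior_ranges = hw_default_priors)
}

# central finite-difference gradient of a scalar function
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1L))
}
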