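sir_ncfg <- net_config(input_dim = 3, param_names = c("beta", "tau", "sigma"),
                       prior_ranges = rbind(c(0, 1), c(1, 30), c(0, 0.5)))

test_that("the modulus output activation guarantees nonnegative estimates", {
  set.seed(1)
  for (i in 1:50) {
    net <- neural_net(sir_ncfg)
    expect_true(all(net_forward(net, runif(3)) >= 0))
  }
})

test_that("zero weights and biases give a zero prediction", {
  net <- neural_net(sir_ncfg, seed = 1)
  net$W1[] <- 0; net$b1[] <- 0; net$W2[] <- 0; net$b2[] <- 0
  expect_equal(unname(net_forward(net, c(0.3, 0.2, 0.5))), c(0, 0, 0))
})

test_that("dimension mismatches raise a shape error", {
  net <- neural_net(sir_ncfg, seed = 2)
  expect_error(net_forward(net, c(1, 2)), "length 2.*expects 3")
})

test_that("batch loss matches hand-evaluated squared norms", {
  expect_equal(batch_loss(c(0.1, -0.1, 0), c(0, 0, 0)), 0.02)
  obs <- matrix(runif(12), 4, 3)
  expect_equal(batch_loss(obs, obs), 0)
  resid <- matrix(rnorm(12), 4, 3)
  expect_equal(batch_loss(obs + 2 * resid, obs),
               4 * batch_loss(obs + resid, obs))
  expect_error(batch_loss(matrix(0, 0, 3), matrix(0, 0, 3)), "empty batch")
})

test_that("uniform-prior initialisation yields uniform initial estimates", {
  x_ref <- c(0.9, 0.05, 0.05)
  draws <- matrix(0, 1000, 3)
  set.seed(7)
  for (i in 1:1000) {
    net <- initialize_uniform_prior(neural_net(sir_ncfg), x_ref)
    draws[i, ] <- net_forward(net, x_ref)
  }
  lo <- sir_ncfg$prior_ranges[, 1]; hi <- sir_ncfg$prior_ranges[, 2]
  for (j in 1:3) {
    u <- (draws[, j] - lo[j]) / (hi[j] - lo[j])
    ks <- suppressWarnings(stats::ks.test(u, "punif"))
    expect_lt(unname(ks$statistic), 0.1)
    expect_true(all(draws[, j] >= 0))
  }
})

test_that("a degenerate prior interval pins the initial output", {
  ncfg <- net_config(input_dim = 3, param_names = c("a", "b"),
                     prior_ranges = rbind(c(0.7, 0.7), c(2, 2)))
  set.seed(3)
  net <- initialize_uniform_prior(neural_net(ncfg), c(1, 0, 0))
  expect_equal(unname(net_forward(net, c(1, 0, 0))), c(0.7, 2),
               tolerance = 1e-10)
})

test_that("the sigmoid output activation confines estimates to the prior box", {
  ncfg <- net_config(input_dim = 4, param_names = c("a", "b"),
                     final_activation = "sigmoid",
                     prior_ranges = rbind(c(0, 2), c(0, 6)))
  set.seed(11)
  for (i in 1:30) {
    net <- neural_net(ncfg)
    net$b2 <- rnorm(2, sd = 10) # even extreme biases stay inside the box
    out <- net_forward(net, rnorm(4))
    expect_true(all(out > 0 & out < c(2, 6)))
  }
  # uniform-prior pinning still exact
  net <- initialize_uniform_prior(neural_net(ncfg, seed = 4), c(1, 1, 1, 1))
  expect_equal(unname(net_forward(net, c(1, 1, 1, 1))),
               unname(attr(net, "lambda0")), tolerance = 1e-6)
})

test_that("network backpropagation matches finite differences", {
  set.seed(5)
  for (fact in c("abs", "sigmoid")) {
    ncfg <- net_config(input_dim = 3, param_names = c("a", "b"),
                       final_activation = fact,
                       prior_ranges = rbind(c(0, 1), c(0, 2)))
    net <- neural_net(ncfg)
    x <- runif(3)
    target <- c(0.4, 1.1)
    loss_of <- function(net) sum((net_forward(net, x) - target)^2)
    cache <- neurocal:::.net_forward_cache(net, x)
    grads <- neurocal:::.net_backward(net, cache, 2 * (cache$lambda - target))
    for (nm in c("W1", "b1", "W2", "b2")) {
      fd <- grads[[nm]] * 0
      for (k in seq_along(net[[nm]])) {
        np <- net; np[[nm]][k] <- np[[nm]][k] + 1e-6
        nm2 <- net; nm2[[nm]][k] <- nm2[[nm]][k] - 1e-6
        fd[k] <- (loss_of(np) - loss_of(nm2)) / 2e-6
      }
      expect_equal(as.vector(grads[[nm]]), as.vector(fd), tolerance = 1e-5)
    }
  }
})
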