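test_that("flows distribute each origin's demand exactly", {
  net <- hw_network(4, matrix(c(1, 1), 1, 2), c(1, 1))
  f <- hw_flows(c(1, 1), net, 1.2, 4)
  expect_equal(unname(f$flows[1, ]), c(2, 2))
  expect_equal(f$demand, c(2, 2))

  # beta = 0 collapses the kernel: demand proportional to W^alpha
  net2 <- tiny_hw_network()
  w <- c(0.5, 1, 1.5, 2)
  f2 <- hw_flows(w, net2, 1.3, 0)
  expect_equal(f2$demand,
               w^1.3 / sum(w^1.3) * sum(net2$origin_sizes))

  # total demand equals total origin size for any inputs
  set.seed(3)
  for (i in 1:10) {
    w <- runif(4, 0.1, 3)
    f3 <- hw_flows(w, net2, runif(1, 0, 2), runif(1, 0, 6))
    expect_equal(sum(f3$demand), sum(net2$origin_sizes))
  }
})

test_that("degenerate all-zero cost rows are rejected", {
  expect_error(hw_network(c(1, 1), rbind(c(1, 1), c(0, 0)), c(1, 1)),
               "all-zero row")
})

test_that("a single destination converges to the logistic fixed point", {
  net <- hw_network(c(2, 3), matrix(1, 2, 1), 0.5)
  ss <- hw_steady_state(net, hw_params(1, 0, 2))
  expect_equal(as.numeric(ss), 5 / 2, tolerance = 1e-6)
})

test_that("steady states satisfy the demand balance to high accuracy", {
  net <- tiny_hw_network(12, 6, seed = 21)
  p <- hw_params(0.8, 3, 2) # alpha < 1: all zones persist
  ss <- hw_steady_state(net, p)
  expect_lt(max(abs(hw_balance_residual(as.numeric(ss), net, p))), 1e-6)
  # size-preference above one extinguishes some zones; the balance then
  # holds relative to the dominant scale
  p2 <- hw_params(1.2, 4, 2)
  ss2 <- hw_steady_state(net, p2)
  expect_lt(attr(ss2, "residual"), 1e-6)
})

test_that("the steady state does not depend on the responsiveness", {
  net <- tiny_hw_network(10, 5, seed = 8)
  base <- as.numeric(hw_steady_state(net, hw_params(0.9, 2, 2, epsilon = 1)))
  for (eps in c(0.5, 2)) {
    ss <- as.numeric(hw_steady_state(net, hw_params(0.9, 2, 2, epsilon = eps)))
    expect_equal(ss, base, tolerance = 1e-6)
  }
})

test_that("rescaling sizes leaves alpha/beta structure and scales kappa", {
  net <- tiny_hw_network(10, 5, seed = 13)
  p <- hw_params(0.9, 2, 2)
  base <- as.numeric(hw_steady_state(net, p))
  s <- 3.7
  net_s <- hw_network(s * net$origin_sizes, net$cost_matrix,
                      s * net$initial_sizes)
  # kappa has units cost/area: the same kappa with rescaled sizes gives the
  # rescaled steady state
  scaled <- as.numeric(hw_steady_state(net_s, p))
  expect_equal(scaled, s * base, tolerance = 1e-5)
  expect_equal(sum(net_s$origin_sizes) / sum(scaled),
               sum(net$origin_sizes) / sum(base), tolerance = 1e-6)
})

test_that("symmetric networks give equal sizes and zero inequality", {
  net <- hw_network(rep(1, 4), matrix(1, 4, 3), rep(0.5, 3))
  ss <- as.numeric(hw_steady_state(net, hw_params(1, 0, 2)))
  expect_equal(ss, rep(ss[1], 3), tolerance = 1e-8)
  expect_lt(nu_statistic(ss), 1e-8)
})

test_that("monopolised data still pin kappa through the total balance", {
  # alpha = 1, beta = 0: kappa equals total origin size over total size
  net <- tiny_hw_network(10, 5, seed = 2)
  ss <- as.numeric(hw_steady_state(net, hw_params(1, 0, 1.7)))
  expect_equal(sum(net$origin_sizes) / sum(ss), 1.7, tolerance = 1e-6)
})

test_that("noisy-path sensitivities match finite differences", {
  net <- tiny_hw_network(8, 4, seed = 31)
  frames <- integrate_hw(net, hw_params(1.1, 2, 2), n_steps = 5, dt = 0.01)
  prob <- neurocal:::.make_problem(frames[1, ], "harris_wilson", net,
                                   train_config(1, 1))
  loss_at <- function(l) prob$rollout(l, 1L, 1L)$loss
  for (l in list(c(1.2, 4, 2), c(0.7, 1, 3), c(1, 0.2, 1.5))) {
    g <- prob$rollout(l, 1L, 1L)$grad
    expect_equal(g, fd_grad(loss_at, l), tolerance = 1e-4)
  }
})

test_that("multi-step rollout gradients match finite differences", {
  net <- tiny_hw_network(8, 4, seed = 31)
  frames <- integrate_hw(net, hw_params(1.1, 2, 2), n_steps = 6, dt = 0.01)
  prob <- neurocal:::.make_problem(frames, "harris_wilson", net,
                                   train_config(1, 1))
  loss_at <- function(l) prob$rollout(l, 1L, 5L)$loss
  g <- prob$rollout(c(1.3, 2.5, 1.8), 1L, 5L)$grad
  expect_equal(g, fd_grad(loss_at, c(1.3, 2.5, 1.8)), tolerance = 1e-4)
})

test_that("noisy integration requires the late-time route, not steady_state", {
  net <- tiny_hw_network()
  expect_error(hw_steady_state(net, hw_params(1, 1, 2, sigma = 0.3)),
               "sigma = 0")
  tr <- integrate_hw(net, hw_params(1, 1, 2, sigma = 0.3), n_steps = 50,
                     seed = 4)
  expect_true(all(as.matrix(tr[, -1]) > 0))
})
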