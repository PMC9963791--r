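test_that("the cost kernel is unit-normalised and scale invariant", {
  d <- matrix(c(0, 1, 2, 4), 2, 2)
  ck <- cost_kernel(d)
  expect_equal(ck[1, 1], 1)
  expect_equal(ck[2, 2], exp(-1))
  expect_true(all(ck > 0 & ck <= 1))
  expect_equal(cost_kernel(2 * d), ck)
  expect_error(cost_kernel(matrix(0, 2, 2)), "positive")
})

test_that("the inequality statistic matches its closed form", {
  expect_equal(nu_statistic(c(1, 1, 1)), 0)
  expect_equal(nu_statistic(c(1, 0, 0)), 1)
  expect_equal(nu_statistic(c(1, 2, 3)), 1 / 3)
  expect_error(nu_statistic(c(0, 0)), "positive sum")
})

test_that("generated datasets pass the identifiability screening", {
  for (sd in 1:3) {
    gen <- generate_hw_data(hw_params(1.2, 4, 2), n_origins = 20,
                            n_destinations = 8, seed = sd)
    expect_gt(gen$nu, 0)
    expect_lt(gen$nu, 1)
    w <- as.matrix(gen$frames[, -1])[1, ]
    # noiseless frames satisfy the steady-state balance at the true params
    expect_lt(neurocal:::.hw_scale_residual(w, gen$network, gen$true_params),
              1e-6)
  }
})

test_that("generation is reproducible and labels its provenance", {
  a <- generate_hw_data(hw_params(1.2, 4, 2), n_origins = 10,
                        n_destinations = 5, seed = 7)
  b <- generate_hw_data(hw_params(1.2, 4, 2), n_origins = 10,
                        n_destinations = 5, seed = 7)
  expect_identical(a$frames, b$frames)
  expect_identical(a$network$cost_matrix, b$network$cost_matrix)
  expect_equal(a$seed, 7L)
})

test_that("a perfectly symmetric specification is rejected by screening", {
  # all-equal costs and sizes give nu = 0 for every candidate dataset
  expect_error(
    generate_hw_data(hw_params(1, 0, 2), n_origins = 3, n_destinations = 2,
                     size_range = c(0.5, 0.5), cost_model = "geometric",
                     max_tries = 3),
    "0 < nu < 1"
  )
})

test_that("noisy frames fluctuate around the noiseless steady state", {
  gen0 <- generate_hw_data(hw_params(0.8, 2, 2), n_origins = 12,
                           n_destinations = 5, seed = 3)
  genn <- generate_hw_data(hw_params(0.8, 2, 2, sigma = 0.05), n_origins = 12,
                           n_destinations = 5, n_frames = 4,
                           burn_in = 2e4, seed = 3)
  w0 <- as.matrix(gen0$frames[, -1])[1, ]
  wn <- colMeans(as.matrix(genn$frames[, -1]))
  expect_equal(nrow(genn$frames), 4L)
  expect_equal(wn, w0, tolerance = 0.2)
})

test_that("the inequality phase diagram has the expected corners", {
  net <- tiny_hw_network(12, 6, seed = 17)
  pd <- nu_phase_diagram(c(0.4, 1.6), c(0.5, 5), net, kappa = 2)
  expect_true(all(pd$nu >= 0 & pd$nu <= 1))
  hi <- pd$nu[pd$alpha == 1.6 & pd$beta == 0.5]
  lo <- pd$nu[pd$alpha == 0.4 & pd$beta == 5]
  expect_gt(hi, 0.6)
  expect_lt(lo, 0.4)
  expect_gt(hi, lo)
})

test_that("the calibration error is zero at the truth and grows with misfit", {
  net <- tiny_hw_network(10, 5, seed = 23)
  p <- hw_params(0.9, 2, 2)
  wstar <- as.numeric(hw_steady_state(net, p))
  m0 <- calibration_mspe(p, net, wstar, n_runs = 3, t_end = 80)
  expect_lt(m0$mspe, 1e-4)
  pn <- hw_params(0.9, 2, 2, sigma = 0.1)
  good <- calibration_mspe(pn, net, wstar, n_runs = 15, t_end = 10, seed = 2)
  bad <- calibration_mspe(hw_params(1.4, 2, 2, sigma = 0.1), net, wstar,
                          n_runs = 15, t_end = 10, seed = 2)
  expect_true(m0$mspe >= 0 && good$mspe >= 0)
  expect_lt(good$mspe, bad$mspe)
})
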