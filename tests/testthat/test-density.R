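test_that("posterior weights follow the shifted exponential of the loss", {
  w <- posterior_weights(data.frame(a = 1:3, loss = c(0.5, 0.5, 0.5)))$weight
  expect_equal(w, rep(1 / 3, 3))
  w2 <- posterior_weights(data.frame(a = 1:2, loss = c(0, Inf)))$weight
  expect_equal(w2, c(1, 0))
  w3 <- posterior_weights(data.frame(a = 1:2, loss = c(0, log(2))))$weight
  expect_equal(w3, c(2 / 3, 1 / 3))
  expect_error(posterior_weights(data.frame(a = 1, loss = NaN)), "degenerate")
})

test_that("marginals are normalised densities on their grid", {
  set.seed(4)
  s <- data.frame(theta = rnorm(400, 1, 0.2), loss = runif(400))
  m <- marginal(s, "theta")
  expect_true(all(m$density >= 0))
  expect_equal(neurocal:::.trapz(m$value, m$density), 1, tolerance = 1e-3)
  expect_error(marginal(s, "theta", bandwidth = 0), "bandwidth")
})

test_that("concentrated samples give a single narrow unit-mass peak", {
  s <- data.frame(theta = rep(2.5, 50), loss = rep(1, 50))
  m <- marginal(s, "theta")
  expect_equal(density_summary(m)$mle, 2.5, tolerance = 1e-2)
  expect_equal(neurocal:::.trapz(m$value, m$density), 1, tolerance = 1e-3)
})

test_that("a Gaussian sample is recovered with the convolved width", {
  set.seed(9)
  sd0 <- 0.3
  h <- 0.1
  s <- data.frame(theta = rnorm(4000, 2, sd0), loss = rep(0.2, 4000))
  m <- marginal(s, "theta", bandwidth = h)
  pk <- peak_widths(m)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$width, 2 * sqrt(2 * log(2)) * sqrt(sd0^2 + h^2),
               tolerance = 0.05)
  expect_equal(attr(pk, "sd_width"), 0)
})

test_that("weighted KDE matches a brute-force evaluation of the posterior", {
  set.seed(12)
  n <- 800
  s <- data.frame(theta = c(rnorm(n / 2, 0, 0.15), rnorm(n / 2, 1, 0.1)),
                  loss = runif(n, 0, 3))
  h <- 0.08
  m <- marginal(s, "theta", bandwidth = h, grid_size = 400)
  # oracle: direct summation of exp(-J) kernels on the same grid
  w <- exp(-(s$loss - min(s$loss)))
  w <- w / sum(w)
  rho <- vapply(m$value, function(g) sum(w * dnorm(g, s$theta, h)),
                numeric(1))
  rho <- rho / neurocal:::.trapz(m$value, rho)
  expect_lt(max(abs(rho - m$density)), 0.02 * max(rho))
})

test_that("summaries agree with symmetry and flag ambiguous maxima", {
  set.seed(2)
  s <- data.frame(theta = rnorm(3000, 1, 0.2), loss = rep(1, 3000))
  sm <- density_summary(marginal(s, "theta", bandwidth = 0.05))
  expect_equal(sm$mle, sm$mean, tolerance = 0.05)
  expect_equal(sm$sd, sqrt(0.2^2 + 0.05^2), tolerance = 0.05)

  flat <- tibble::tibble(value = seq(0, 1, length.out = 101),
                         density = rep(1, 101))
  attr(flat, "parameter") <- "theta"
  class(flat) <- c("marginal_density", class(flat))
  expect_error(density_summary(flat), "ambiguous MLE")

  # two equal peaks: expectation midway, MLE ambiguous
  g <- seq(-1, 2, length.out = 601)
  rho <- dnorm(g, 0, 0.1) + dnorm(g, 1, 0.1)
  bim <- tibble::tibble(value = g, density = rho / neurocal:::.trapz(g, rho))
  attr(bim, "parameter") <- "theta"
  class(bim) <- c("marginal_density", class(bim))
  expect_error(density_summary(bim), "ambiguous MLE")
  pk <- peak_widths(bim)
  expect_equal(nrow(pk), 2L)
  expect_lt(attr(pk, "sd_width"), 1e-3)
})

test_that("peak detection respects the prominence threshold", {
  g <- seq(0, 3, length.out = 500)
  rho <- dnorm(g, 1, 0.1) + 0.02 * dnorm(g, 2.5, 0.05)
  m <- tibble::tibble(value = g, density = rho / neurocal:::.trapz(g, rho))
  class(m) <- c("marginal_density", class(m))
  expect_equal(nrow(peak_widths(m, prominence = 0.05)), 1L)
  expect_equal(nrow(peak_widths(m, prominence = 0.001)), 2L)
  expect_error(peak_widths(m, prominence = 1.1), "no peak")
})
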