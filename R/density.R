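#' Posterior weights from loss values
#'
#' Interprets the loss values visited during training as a potential over
#' parameter space: each sample receives weight proportional to
#' `exp(-J)`. The loss is shifted by its minimum before exponentiation for
#' overflow safety (the posterior is scale-free, so this changes nothing),
#' and the weights are normalised to sum to one. The prior is uniform over
#' the sampled region by construction of the initialisation, so no extra
#' prior factor appears. Samples with infinite loss get weight zero.
#'
#' @param samples A data frame with a `loss` column (e.g.
#'   `calibration_fit$samples`).
#' @return The same data frame with a normalised `weight` column appended.
#' @examples
#' posterior_weights(data.frame(alpha = c(1, 2), loss = c(0, log(2))))
#' @export
posterior_weights <- function(samples) {
  stopifnot(is.data.frame(samples), "loss" %in% names(samples))
  if (nrow(samples) == 0L) stop("no samples.", call. = FALSE)
  J <- samples$loss
  if (all(!is.finite(J))) {
    stop("degenerate samples: every loss value is non-finite.",
         call. = FALSE)
  }
  w <- exp(-(J - min(J[is.finite(J)])))
  w[!is.finite(J)] <- 0
  samples$weight <- w / sum(w)
  tibble::as_tibble(samples)
}

#' Posterior marginal density of one parameter
#'
#' Estimates the marginal density of a single parameter coordinate from the
#' pooled training samples: a Gaussian kernel density of the visited values
#' weighted by `exp(-J)` (the other coordinates are integrated out simply
#' by dropping them, which is what the sample-based integral amounts to).
#' The result is renormalised to unit mass on its grid by trapezoidal
#' quadrature.
#'
#' @param samples A data frame of training samples with a `loss` column.
#' @param parameter Name of the parameter column.
#' @param bandwidth Gaussian kernel bandwidth; default is Scott's rule
#'   computed on the weighted sample.
#' @param grid_size Number of grid points (default 500).
#' @param range Optional length-2 grid range; default
#'   `[min - 3h, max + 3h]` of the finite-weight samples.
#' @return An object of class `marginal_density`: a tibble with columns
#'   `value` and `density`, with the parameter name, bandwidth and grid
#'   range as attributes.
#' @export
marginal <- function(samples, parameter, bandwidth = NULL,
                     grid_size = 500L, range = NULL) {
  stopifnot(parameter %in% names(samples))
  samples <- posterior_weights(samples)
  x <- samples[[parameter]]
  w <- samples$weight
  keep <- is.finite(x) & w > 0
  x <- x[keep]
  w <- w[keep] / sum(w[keep])
  if (length(unique(x)) < 2L && is.null(bandwidth)) {
    bandwidth <- 1e-3 * (abs(x[1L]) + 1)
  }
  if (is.null(bandwidth)) {
    # Scott's rule on the weighted sample
    n_eff <- 1 / sum(w^2)
    mu <- sum(w * x)
    sdw <- sqrt(sum(w * (x - mu)^2))
    bandwidth <- max(sdw * n_eff^(-1 / 5), 1e-8)
  }
  if (!is.numeric(bandwidth) || bandwidth <= 0) {
    stop("`bandwidth` must be a positive number.", call. = FALSE)
  }
  if (is.null(range)) {
    range <- c(min(x) - 3 * bandwidth, max(x) + 3 * bandwidth)
  }
  d <- stats::density(x, weights = w, bw = bandwidth, kernel = "gaussian",
                      n = grid_size, from = range[1L], to = range[2L])
  dens <- d$y
  mass <- .trapz(d$x, dens)
  dens <- dens / mass
  out <- tibble::tibble(value = d$x, density = dens)
  attr(out, "parameter") <- parameter
  attr(out, "bandwidth") <- bandwidth
  attr(out, "n_samples") <- length(x)
  class(out) <- c("marginal_density", class(out))
  out
}

.trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

#' Summarise a marginal density
#'
#' Maximum-likelihood estimate (grid argmax), expectation and standard
#' deviation (trapezoidal quadrature) of a normalised marginal.
#'
#' @param density A [marginal()] result.
#' @return A one-row tibble with columns `parameter`, `mle`, `mean`, `sd`.
#' @export
density_summary <- function(density) {
  stopifnot(inherits(density, "marginal_density"))
  g <- density$value
  rho <- density$density
  top <- which(rho >= max(rho) * (1 - 1e-10))
  # separated argmax points, or a plateau spanning a nontrivial stretch of
  # the grid, mean the MLE is not unique
  if (length(top) > 1L &&
      (any(diff(top) > 1L) || length(top) > 0.05 * length(g))) {
    stop(sprintf("ambiguous MLE: the density attains its maximum at %s.",
                 paste(signif(g[top], 5L), collapse = ", ")),
         call. = FALSE)
  }
  mle <- g[which.max(rho)]
  m <- .trapz(g, g * rho)
  v <- .trapz(g, (g - m)^2 * rho)
  tibble::tibble(parameter = attr(density, "parameter") %||% NA_character_,
                 mle = mle, mean = m, sd = sqrt(max(v, 0)))
}

#' Glance at a marginal density
#'
#' @param x A `marginal_density`.
#' @param ... Unused.
#' @return A one-row tibble: `parameter`, `mle`, `mean`, `sd`, `bandwidth`.
#' @method glance marginal_density
#' @export
glance.marginal_density <- function(x, ...) {
  out <- density_summary(x)
  out$bandwidth <- attr(x, "bandwidth")
  out
}

#' @method tidy marginal_density
#' @export
tidy.marginal_density <- function(x, ...) {
  tibble::tibble(value = x$value, density = x$density)
}

#' Peaks of a marginal density and their half-height widths
#'
#' Detects local maxima above a prominence threshold and measures, for each,
#' the full width at half its height (linear interpolation between grid
#' points; if the density never falls below half height before the grid
#' edge, the edge is used). The mean peak width over all detected peaks is
#' the uncertainty measure reported for noisy data; with a single peak the
#' width standard deviation is exactly 0.
#'
#' @param density A [marginal()] result.
#' @param prominence Minimum peak height as a fraction of the global
#'   maximum (default 0.05).
#' @return An object of class `peak_summary`: a tibble with one row per
#'   peak (`location`, `height`, `width`) and attributes `mean_width` and
#'   `sd_width`.
#' @export
peak_widths <- function(density, prominence = 0.05) {
  stopifnot(inherits(density, "marginal_density"))
  g <- density$value
  rho <- density$density
  n <- length(rho)
  thr <- prominence * max(rho)
  is_peak <- c(FALSE, rho[2:(n - 1)] > rho[1:(n - 2)] &
                 rho[2:(n - 1)] >= rho[3:n], FALSE)
  # grid-edge maxima count as peaks too
  if (rho[1L] > rho[2L]) is_peak[1L] <- TRUE
  if (rho[n] > rho[n - 1L]) is_peak[n] <- TRUE
  idx <- which(is_peak & rho > thr)
  if (length(idx) == 0L) {
    stop("no peak above the prominence threshold.", call. = FALSE)
  }
  cross <- function(i, dir) {
    half <- rho[i] / 2
    j <- i
    while (j + dir >= 1L && j + dir <= n && rho[j + dir] > half) j <- j + dir
    if (j + dir < 1L || j + dir > n) return(g[j])
    # linear interpolation between j and j+dir
    r0 <- rho[j]; r1 <- rho[j + dir]
    frac <- (r0 - half) / (r0 - r1)
    g[j] + frac * (g[j + dir] - g[j])
  }
  widths <- vapply(idx, function(i) cross(i, 1L) - cross(i, -1L), numeric(1L))
  out <- tibble::tibble(location = g[idx], height = rho[idx],
                        width = widths)
  attr(out, "mean_width") <- mean(widths)
  attr(out, "sd_width") <- if (length(widths) > 1L) stats::sd(widths) else 0
  attr(out, "parameter") <- attr(density, "parameter")
  class(out) <- c("peak_summary", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
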