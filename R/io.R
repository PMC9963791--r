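#' Read and write state trajectories
#'
#' Trajectories are plain CSV tables with a `time` column followed by one
#' column per state component (`S,I,R` for the SIR models, `W1..WM` for
#' Harris--Wilson). Any user-supplied table of this shape is accepted.
#'
#' @param x A trajectory tibble.
#' @param path File path.
#' @return `read_trajectory()` returns a tibble; `write_trajectory()`
#'   returns `path` invisibly.
#' @export
write_trajectory <- function(x, path) {
  stopifnot("time" %in% names(x))
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!"time" %in% names(out)) {
    stop("a trajectory file needs a `time` column.", call. = FALSE)
  }
  out
}

#' Read and write origin--destination networks
#'
#' A network is stored as three plain tables: a one-column CSV of origin
#' sizes, a one-column CSV of initial destination sizes, and a headerless
#' CSV cost matrix with one row per origin. Any user-supplied tables of
#' these shapes are accepted (e.g. real origin budgets, floor-space sizes
#' and travel-cost matrices).
#'
#' @param network An [hw_network()].
#' @param origins_path,sizes_path,costs_path File paths.
#' @return `read_hw_network()` returns an [hw_network()];
#'   `write_hw_network()` returns the paths invisibly.
#' @export
write_hw_network <- function(network, origins_path, sizes_path, costs_path) {
  stopifnot(inherits(network, "hw_network"))
  readr::write_csv(tibble::tibble(origin_size = network$origin_sizes),
                   origins_path)
  readr::write_csv(tibble::tibble(initial_size = network$initial_sizes),
                   sizes_path)
  utils::write.table(network$cost_matrix, costs_path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(c(origins_path, sizes_path, costs_path))
}

#' @rdname write_hw_network
#' @export
read_hw_network <- function(origins_path, sizes_path, costs_path) {
  O <- readr::read_csv(origins_path, show_col_types = FALSE)[[1L]]
  W0 <- readr::read_csv(sizes_path, show_col_types = FALSE)[[1L]]
  costs <- as.matrix(utils::read.table(costs_path, sep = ","))
  dimnames(costs) <- NULL
  hw_network(O, costs, W0)
}

#' Read and write training sample tables
#'
#' The flat table of visited parameter estimates: one row per optimizer
#' step with `init_id`, `epoch`, `batch`, one column per parameter and the
#' loss value.
#'
#' @param samples A samples tibble (e.g. `calibration_fit$samples`).
#' @param path File path.
#' @return `read_samples()` returns a tibble; `write_samples()` returns
#'   `path` invisibly.
#' @export
write_samples <- function(samples, path) {
  stopifnot("loss" %in% names(samples))
  readr::write_csv(samples, path)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!"loss" %in% names(out)) {
    stop("a samples file needs a `loss` column.", call. = FALSE)
  }
  out
}
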