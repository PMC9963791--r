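#' End-to-end experiment configuration
#'
#' One declarative object covering data generation, calibration, and
#' density estimation, with a single master seed from which every stage
#' seed is derived deterministically. Configurations round-trip through
#' YAML unchanged (see [write_experiment_config()]).
#'
#' @param model `"sir"` or `"harris_wilson"`.
#' @param generator Named list of generator arguments: for `"sir"`,
#'   arguments of [sir_abm_config()] (minus `seed`); for
#'   `"harris_wilson"`, `true_params` (list with `alpha`, `beta`, `kappa`,
#'   optional `sigma`) plus the other [generate_hw_data()] arguments.
#' @param train Named list of [train_config()] arguments (minus `seed`).
#' @param net Optional named list of [net_config()] arguments.
#' @param density Named list: optional `bandwidth`, `grid_size`,
#'   `prominence`.
#' @param seed Master seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(model = c("sir", "harris_wilson"),
                              generator = list(), train = list(),
                              net = NULL, density = list(), seed = 1L) {
  model <- match.arg(model)
  if (!all(c("epochs", "batch_size") %in% names(train))) {
    stop("`train` must supply at least `epochs` and `batch_size`.",
         call. = FALSE)
  }
  if (model == "harris_wilson" && !"true_params" %in% names(generator)) {
    stop("a harris_wilson generator needs `true_params`.", call. = FALSE)
  }
  structure(
    list(model = model, generator = generator, train = train, net = net,
         density = density, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Write or read an experiment configuration as YAML
#'
#' @param config An [experiment_config()].
#' @param path File path.
#' @return `read_experiment_config()` returns the reconstructed
#'   [experiment_config()]; the writer returns `path` invisibly.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  experiment_config(model = raw$model, generator = raw$generator,
                    train = raw$train, net = raw$net,
                    density = raw$density %||% list(),
                    seed = raw$seed %||% 1L)
}

.generate_stage <- function(config, seed) {
  if (config$model == "sir") {
    gen <- config$generator
    gen$seed <- seed
    abm <- do.call(sir_abm_config, gen)
    list(data = simulate_sir_abm(abm), network = NULL, truth = abm)
  } else {
    gen <- config$generator
    gen$true_params <- do.call(hw_params, gen$true_params)
    gen$seed <- seed
    ds <- do.call(generate_hw_data, gen)
    list(data = ds$frames, network = ds$network, truth = ds)
  }
}

#' Run a full calibration experiment
#'
#' Executes generate -> multi-initialisation calibrate -> marginals ->
#' summaries, derives every stage seed from the master seed (identical
#' seeds reproduce the sample table exactly), and optionally writes all
#' artifacts (data, samples, marginals as CSV; the report as JSON; the
#' configuration as YAML) to a directory. An existing non-empty output
#' directory is refused unless `force = TRUE`. If a stage fails, the
#' report marks the failed stage and completed artifacts are preserved.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory.
#' @param force Overwrite an existing non-empty `out_dir`.
#' @param dry_run Validate the configuration and return without computing.
#' @return A list of class `experiment_report`: `model`, `seed`,
#'   `summaries` (per-parameter tibble with MLE, expectation, SD, peak
#'   statistics), `final` (per-initialisation final estimates and losses),
#'   `fit` (the [calibrate()] result), `data`, and `failed_stage`
#'   (`NA` on success).
#' @export
run_experiment <- function(config, out_dir = NULL, force = FALSE,
                           dry_run = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (dry_run) {
    return(invisible(structure(list(model = config$model, dry_run = TRUE),
                               class = "experiment_report")))
  }
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !force) {
      stop(sprintf("output directory '%s' is not empty; use `force = TRUE` to overwrite.",
                   out_dir), call. = FALSE)
    }
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_experiment_config(config, file.path(out_dir, "config.yaml"))
  }
  report <- list(model = config$model, seed = config$seed,
                 failed_stage = NA_character_)
  class(report) <- "experiment_report"

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$failed_stage <<- name
      report$error <<- conditionMessage(e)
      NULL
    })
  }

  gen <- stage("generate", .generate_stage(config, .child_seed(config$seed, 101L)))
  if (is.null(gen)) return(report)
  report$data <- gen$data
  if (!is.null(out_dir)) {
    write_trajectory(gen$data, file.path(out_dir, "data.csv"))
    if (!is.null(gen$network)) {
      write_hw_network(gen$network, file.path(out_dir, "origins.csv"),
                       file.path(out_dir, "sizes.csv"),
                       file.path(out_dir, "costs.csv"))
    }
  }

  fit <- stage("calibrate", {
    tr <- config$train
    tr$seed <- .child_seed(config$seed, 202L)
    tcfg <- do.call(train_config, tr)
    ncfg <- if (!is.null(config$net)) do.call(net_config, config$net)
    calibrate(gen$data, model = if (config$model == "sir") "sir" else "harris_wilson",
              train_cfg = tcfg, network = gen$network, net_cfg = ncfg)
  })
  if (is.null(fit)) return(report)
  report$fit <- fit
  report$final <- fit$final
  if (!is.null(out_dir)) {
    write_samples(fit$samples, file.path(out_dir, "samples.csv"))
  }

  dens <- stage("density", {
    dcfg <- config$density
    pars <- fit$net_cfg$param_names
    lapply(stats::setNames(pars, pars), function(p) {
      m <- marginal(fit$samples, p, bandwidth = dcfg$bandwidth,
                    grid_size = dcfg$grid_size %||% 500L)
      pk <- tryCatch(peak_widths(m, prominence = dcfg$prominence %||% 0.05),
                     error = function(e) NULL)
      list(marginal = m, peaks = pk)
    })
  })
  if (is.null(dens)) return(report)
  report$marginals <- lapply(dens, `[[`, "marginal")
  report$summaries <- dplyr::bind_rows(lapply(names(dens), function(p) {
    s <- density_summary(dens[[p]]$marginal)
    pk <- dens[[p]]$peaks
    s$n_peaks <- if (is.null(pk)) 0L else nrow(pk)
    s$mean_peak_width <- if (is.null(pk)) NA_real_ else attr(pk, "mean_width")
    s$sd_peak_width <- if (is.null(pk)) NA_real_ else attr(pk, "sd_width")
    s
  }))
  if (!is.null(out_dir)) {
    for (p in names(report$marginals)) {
      readr::write_csv(tidy(report$marginals[[p]]),
                       file.path(out_dir, paste0("marginal_", p, ".csv")))
    }
    rep_json <- list(
      model = report$model, seed = report$seed,
      summaries = report$summaries,
      final = report$final
    )
    jsonlite::write_json(rep_json, file.path(out_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> model: %s | seed %s | failed stage: %s\n",
              x$model, x$seed %||% "?", x$failed_stage %||% "none"))
  if (!is.null(x$summaries)) print(x$summaries)
  invisible(x)
}

#' Ensemble forward prediction from a calibration fit
#'
#' Runs the forward model once per initialisation with that
#' initialisation's final parameter estimate, and aggregates the ensemble
#' mean and standard deviation per time point. For the SIR model the time
#' of peak infection of each member is recorded; averaged over the
#' ensemble it estimates the epidemic's true peak time.
#'
#' @param fit A [calibrate()] result.
#' @param init_state Initial state for the forward runs (length-3 SIR
#'   state, or `M` destination sizes).
#' @param n_steps Number of forward steps.
#' @param dt Time step; defaults to the fit's training step.
#' @param network An [hw_network()] (Harris--Wilson only).
#' @return A tibble in long layout: `time`, `component`, `mean`, `sd`,
#'   with per-member peak-infection times in attribute `"peak_times"` for
#'   the SIR model.
#' @export
predict_ensemble <- function(fit, init_state, n_steps, dt = NULL,
                             network = NULL) {
  stopifnot(inherits(fit, "calibration_fit"))
  runs <- lapply(seq_len(nrow(fit$final)), function(i) {
    fp <- fit$final[i, ]
    if (fit$model == "sir") {
      traj <- integrate_sir(init_state,
                            sir_params(fp$beta, max(fp$tau, 1e-3), 0),
                            n_steps = n_steps, dt = dt %||% 1)
    } else {
      stopifnot(!is.null(network))
      traj <- integrate_hw(network,
                           hw_params(fp$alpha, fp$beta,
                                     max(fp$kappa, 1e-6)),
                           n_steps = n_steps, dt = dt %||% 0.01)
    }
    traj
  })
  long <- dplyr::bind_rows(lapply(seq_along(runs), function(i) {
    tidyr::pivot_longer(runs[[i]], -"time", names_to = "component",
                        values_to = "value")
  }), .id = "member")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$time, .data$component),
    mean = mean(.data$value), sd = stats::sd(.data$value),
    .groups = "drop"
  )
  out$sd[is.na(out$sd)] <- 0
  if (fit$model == "sir") {
    attr(out, "peak_times") <- vapply(
      runs, function(tr) tr$time[which.max(tr$I)], numeric(1L)
    )
  }
  out
}
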