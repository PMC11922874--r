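# Calibration: max-normalised sum of squared errors between simulated and
# measured time courses, minimised by Nelder-Mead simplex in log-parameter
# space.

.succ_obs_vars <- c("glucose_gL", "biomass_gL", "SA_gL", "AA_gL", "FA_gL")

#' Read observation files
#'
#' Observations are delimited text files, one per experiment, with header
#' `time_h,glucose_gL,biomass_gL,SA_gL,AA_gL,FA_gL`; blank cells are missing
#' values.  The experiment label is taken from the file name (without
#' extension).
#'
#' @param paths one or more file paths, or a directory containing `.csv`
#'   files.
#' @return A tibble with columns `experiment`, `time_h` and the five
#'   observable columns.
#' @seealso [write_observations()]
#' @export
read_observations <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.csv$", full.names = TRUE)
  }
  if (length(paths) == 0) {
    rlang::abort("no observation files found", class = "succ_config_error")
  }
  purrr::map_dfr(paths, function(p) {
    d <- utils::read.csv(p, check.names = FALSE)
    need <- c("time_h", .succ_obs_vars)
    if (!all(need %in% names(d))) {
      rlang::abort(paste0("observation file ", p, " lacks required columns"),
                   class = "succ_config_error")
    }
    if (is.unsorted(d$time_h, strictly = TRUE)) {
      rlang::abort(paste0("times not strictly increasing in ", p),
                   class = "succ_config_error")
    }
    dplyr::bind_cols(
      tibble::tibble(experiment = sub("\\.[^.]*$", "", basename(p))),
      tibble::as_tibble(d[, need]))
  })
}

#' Write observation files
#'
#' @param observations a tibble as returned by [generate_dataset()] or
#'   [read_observations()] (one `experiment` column plus the observables).
#' @param dir output directory (created if needed); one
#'   `<experiment>.csv` per experiment.
#' @return The file paths, invisibly.
#' @export
write_observations <- function(observations, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::map_chr(split(observations, observations$experiment),
                          function(d) {
    p <- file.path(dir, paste0(d$experiment[1], ".csv"))
    utils::write.csv(d[, c("time_h", .succ_obs_vars)], p, row.names = FALSE,
                     na = "")
    p
  })
  invisible(unname(paths))
}

#' Max-normalised sum of squared errors
#'
#' For every experiment, the model is simulated with the candidate parameters
#' and evaluated exactly at the observation times; the objective accumulates
#' `(C_data - C_sim)^2 / max(C_data)` over experiments, observed variables
#' and times, where the normalising maximum is taken per variable within each
#' experiment.  Missing observations contribute nothing.  A failed simulation
#' returns `Inf` rather than raising.
#'
#' @param params candidate calibrated parameters.
#' @param observations observation tibble (see [read_observations()]).
#' @param fixed fixed parameters.
#' @param configs named list of experiment configurations covering every
#'   experiment label in `observations`; defaults to the packaged
#'   configurations for labels G1..G5.
#' @param options structural options.
#' @param solver solver settings.
#' @return Non-negative scalar.
#' @export
sse_objective <- function(params, observations, fixed = fixed_params(),
                          configs = NULL, options = model_options(),
                          solver = solver_options()) {
  total <- 0
  for (exp_name in unique(observations$experiment)) {
    obs <- observations[observations$experiment == exp_name, ]
    cfg <- if (!is.null(configs)) configs[[exp_name]] else
      experiment_config(exp_name)
    if (is.null(cfg)) {
      rlang::abort(paste0("no configuration for experiment '", exp_name, "'"),
                   class = "succ_config_error")
    }
    if (any(obs$time_h > cfg$t_end + 1e-9)) {
      rlang::abort(paste0("observation beyond t_end in '", exp_name, "'"),
                   class = "succ_config_error")
    }
    sim <- tryCatch(
      simulate_batch(cfg, params, fixed, options, solver,
                     times = sort(unique(obs$time_h))),
      error = function(e) NULL)
    if (is.null(sim)) return(Inf)
    sim <- sim[match(obs$time_h, sim$time_h), ]
    for (v in .succ_obs_vars) {
      meas <- obs[[v]]
      ok <- !is.na(meas)
      if (!any(ok)) next
      cmax <- max(meas[ok])
      if (cmax <= 0) next
      total <- total + sum((meas[ok] - sim[[v]][ok])^2) / cmax
    }
  }
  total
}

#' Calibrate kinetic parameters
#'
#' Minimises [sse_objective()] over a chosen subset of the calibrated
#' parameters using the Nelder-Mead simplex, working in log-parameter space
#' so every parameter stays strictly positive.  The returned fit never has a
#' higher objective than its starting point.
#'
#' @param start starting parameter vector ([calibrated_params()]).
#' @param observations observation tibble.
#' @param free character vector of parameter names to optimise; the rest stay
#'   frozen at their starting values.  Defaults to all 37.
#' @inheritParams sse_objective
#' @param control passed to [stats::optim()] (e.g. `maxit`, `reltol`).
#' @return An object of class `"succ_fit"`: the fitted parameters plus a
#'   convergence report.  Use [generics::tidy()] and [generics::glance()]
#'   to extract tidy summaries.
#' @export
calibrate_params <- function(start, observations, free = names(start),
                             fixed = fixed_params(), configs = NULL,
                             options = model_options(),
                             solver = solver_options(),
                             control = list(maxit = 500)) {
  stopifnot(inherits(start, "succ_params"))
  bad <- setdiff(free, names(start))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown free parameter(s): ", paste(bad, collapse = ", ")),
                 class = "succ_config_error")
  }
  make_params <- function(theta) {
    p <- unclass(start)
    p[free] <- exp(theta)
    structure(p, class = "succ_params")
  }
  fn <- function(theta) {
    sse_objective(make_params(theta), observations, fixed, configs, options,
                  solver)
  }
  theta0 <- log(unclass(start)[free])
  f0 <- fn(theta0)
  if (!is.finite(f0)) {
    rlang::abort("objective not finite at the starting point",
                 class = "succ_config_error")
  }
  # Nelder-Mead is the calibration algorithm by construction, also in one
  # dimension; silence optim's advisory about 1-D simplex use
  opt <- suppressWarnings(
    stats::optim(theta0, fn, method = "Nelder-Mead", control = control))
  if (opt$value <= f0) {
    best <- make_params(opt$par); best_sse <- opt$value
  } else {
    best <- start; best_sse <- f0
  }
  structure(list(params = best, start = start, free = free,
                 sse = best_sse, sse_initial = f0,
                 evaluations = unname(opt$counts[1]),
                 convergence = opt$convergence,
                 message = opt$message %||% ""),
            class = "succ_fit")
}

#' @export
print.succ_fit <- function(x, ...) {
  cat("<calibration fit>\n")
  cat("  free parameters:", length(x$free), "\n")
  cat("  SSE: ", format(x$sse_initial, digits = 6), " -> ",
      format(x$sse, digits = 6), "\n", sep = "")
  cat("  function evaluations:", x$evaluations,
      "| convergence code:", x$convergence, "\n")
  invisible(x)
}

#' Tidy a calibration fit
#'
#' @param x a `succ_fit` object.
#' @param ... unused.
#' @return One row per parameter: `parameter`, `start`, `estimate`, `free`.
#' @export
tidy.succ_fit <- function(x, ...) {
  tibble::tibble(parameter = names(x$params),
                 start = as.numeric(x$start),
                 estimate = as.numeric(x$params),
                 free = names(x$params) %in% x$free)
}

#' One-row summary of a calibration fit
#'
#' @param x a `succ_fit` object.
#' @param ... unused.
#' @importFrom generics glance
#' @export
glance.succ_fit <- function(x, ...) {
  tibble::tibble(sse_initial = x$sse_initial, sse = x$sse,
                 n_free = length(x$free), evaluations = x$evaluations,
                 convergence = x$convergence)
}
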