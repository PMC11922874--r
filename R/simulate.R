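# Batch simulation of the five reference experiments and the
# initial-glucose sweep.

.succ_experiments <- list(
  G1 = list(name = "G1", G0 = 0.03, X0 = 1.05e-3, t_end = 60),
  G2 = list(name = "G2", G0 = 0.12, X0 = 1.93e-3, t_end = 100),
  G3 = list(name = "G3", G0 = 0.24, X0 = 7.25e-4, t_end = 100),
  G4 = list(name = "G4", G0 = 0.37, X0 = 1.07e-3, t_end = 100),
  G5 = list(name = "G5", G0 = 0.45, X0 = 5.64e-4, t_end = 100)
)

#' Batch experiment configuration
#'
#' Initial conditions and horizon for one anaerobic batch run.  Intracellular
#' pools and acids start at zero; the ATP/ADP pools are derived from the
#' inoculum via [initial_energy()] unless overridden.
#'
#' @param name experiment label.  The five reference experiments `"G1"` to
#'   `"G5"` (initial glucose 5.40, 21.75, 42.65, 67.45 and 80.70 g/L) are
#'   built in; for those, the remaining arguments default to the packaged
#'   values and need not be given.
#' @param G0 initial glucose, mol/L (>= 0).
#' @param X0 inoculum, mol X/L (> 0).
#' @param t_end simulation horizon, h (> 0).
#' @param ATP0,ADP0 optional overrides of the initial energy pools.
#' @return A list of class `"succ_config"`.
#' @examples
#' experiment_config("G2")
#' experiment_config("custom", G0 = 0.2, X0 = 1e-3, t_end = 120)
#' @export
experiment_config <- function(name, G0 = NULL, X0 = NULL, t_end = NULL,
                              ATP0 = NULL, ADP0 = NULL) {
  if (name %in% names(.succ_experiments)) {
    def <- .succ_experiments[[name]]
    G0 <- G0 %||% def$G0; X0 <- X0 %||% def$X0; t_end <- t_end %||% def$t_end
  }
  if (is.null(G0) || is.null(X0) || is.null(t_end)) {
    rlang::abort(paste0("unknown experiment '", name,
                        "': supply G0, X0 and t_end explicitly"),
                 class = "succ_config_error")
  }
  if (!is.finite(G0) || G0 < 0) {
    rlang::abort("G0 must be >= 0", class = "succ_config_error")
  }
  if (!is.finite(X0) || X0 <= 0) {
    rlang::abort("X0 must be > 0", class = "succ_config_error")
  }
  if (!is.finite(t_end) || t_end <= 0) {
    rlang::abort("t_end must be > 0", class = "succ_config_error")
  }
  structure(list(name = name, G0 = G0, X0 = X0, t_end = t_end,
                 ATP0 = ATP0, ADP0 = ADP0),
            class = "succ_config")
}

#' The five reference batch experiments
#'
#' @return A tibble with one row per experiment: `name`, `G0` (mol/L),
#'   `glucose_gL`, `X0` (mol X/L), `t_end` (h) and the derived initial
#'   energy pool `ATP0`.
#' @export
batch_experiments <- function() {
  fx <- fixed_params()
  purrr::map_dfr(.succ_experiments, function(d) {
    tibble::tibble(name = d$name, G0 = d$G0,
                   glucose_gL = d$G0 * fx[["MW_G"]],
                   X0 = d$X0, t_end = d$t_end,
                   ATP0 = initial_energy(d$X0, fx)[["ATP"]])
  })
}

#' Solver settings
#'
#' @param method a stiff-capable `deSolve` integrator (default `"lsoda"`,
#'   which switches to BDF on stiffness).
#' @param rtol relative tolerance.
#' @param atol absolute tolerances, one per state component.  The three
#'   intracellular pools live at the 1e-10..1e-5 mol/(mol X) scale (the
#'   smallest saturation constant is ~2e-11 mol/(mol X)) and need a much
#'   tighter floor than the extracellular states.
#' @param dt output grid spacing, h.
#' @param maxsteps maximum internal steps per output interval.
#' @return A list of class `"succ_solver"`.
#' @export
solver_options <- function(method = "lsoda", rtol = 1e-8,
                           atol = c(G = 1e-10, G3P = 1e-16, PEP = 1e-16,
                                    P = 1e-16, X = 1e-12, SA = 1e-10,
                                    AA = 1e-10, FA = 1e-10, ATP = 1e-12,
                                    ADP = 1e-12),
                           dt = 0.1, maxsteps = 2e5) {
  structure(list(method = method, rtol = rtol, atol = atol, dt = dt,
                 maxsteps = maxsteps),
            class = "succ_solver")
}

.initial_state <- function(config, fixed) {
  en <- initial_energy(config$X0, fixed)
  state_vector(G = config$G0, X = config$X0,
               ATP = config$ATP0 %||% en[["ATP"]],
               ADP = config$ADP0 %||% en[["ADP"]])
}

# Low-level integration returning the deSolve matrix on the requested times.
.integrate <- function(config, params, fixed, options, solver, times) {
  y0 <- .initial_state(config, fixed)
  e <- .rate_context(params, fixed, options)
  rhs <- function(t, y, parms) list(.rhs_core(y, e))
  out <- withCallingHandlers(
    deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                 method = solver$method, rtol = solver$rtol,
                 atol = solver$atol, maxsteps = solver$maxsteps),
    warning = function(w) invokeRestart("muffleWarning"))
  if (nrow(out) < length(times) || any(!is.finite(out))) {
    rlang::abort(paste0("integration failed for experiment '", config$name, "'"),
                 class = "succ_integration_error")
  }
  neg <- sweep(out[, 1 + seq_along(y0), drop = FALSE], 2,
               unname(solver$atol), function(v, a) v < -a)
  if (any(neg)) {
    rlang::abort(paste0("state went negative beyond tolerance for experiment '",
                        config$name, "'"),
                 class = "succ_integration_error")
  }
  out
}

#' Convert a molar state to g/L observables
#'
#' @param state named state vector (or a matrix with named columns).
#' @param fixed fixed parameters.
#' @return Named vector (or tibble) with `glucose_gL`, `biomass_gL`, `SA_gL`,
#'   `AA_gL`, `FA_gL`.
#' @examples
#' to_observables(state_vector(G = 0.03, X = 1.05e-3), fixed_params())
#' @export
to_observables <- function(state, fixed = fixed_params()) {
  if (is.matrix(state)) {
    tibble::tibble(glucose_gL = state[, "G"] * fixed[["MW_G"]],
                   biomass_gL = state[, "X"] * fixed[["MW_X"]],
                   SA_gL = state[, "SA"] * fixed[["MW_SA"]],
                   AA_gL = state[, "AA"] * fixed[["MW_AA"]],
                   FA_gL = state[, "FA"] * fixed[["MW_FA"]])
  } else {
    c(glucose_gL = state[["G"]] * fixed[["MW_G"]],
      biomass_gL = state[["X"]] * fixed[["MW_X"]],
      SA_gL = state[["SA"]] * fixed[["MW_SA"]],
      AA_gL = state[["AA"]] * fixed[["MW_AA"]],
      FA_gL = state[["FA"]] * fixed[["MW_FA"]])
  }
}

#' Simulate a batch experiment
#'
#' Integrates the fermentation model from the configured initial state over a
#' dense output grid and returns the trajectory with both the molar state and
#' the g/L observables.  Observable columns with numerical undershoot within
#' the solver's absolute tolerance are clipped to zero; larger undershoot is
#' an integration error.
#'
#' @param config an experiment configuration, or an experiment name such as
#'   `"G2"` (see [experiment_config()]).
#' @param params calibrated parameters.
#' @param fixed fixed parameters.
#' @param options structural options.
#' @param solver solver settings, see [solver_options()].
#' @param times optional explicit output times (overrides the `dt` grid).
#' @return A tibble of class `"succ_trajectory"`: `time_h`, the ten state
#'   columns, and `glucose_gL`, `biomass_gL`, `SA_gL`, `AA_gL`, `FA_gL`.
#' @examples
#' \donttest{
#' traj <- simulate_batch("G1")
#' tail(traj[, c("time_h", "glucose_gL", "biomass_gL", "SA_gL")])
#' }
#' @export
simulate_batch <- function(config, params = calibrated_params(),
                           fixed = fixed_params(), options = model_options(),
                           solver = solver_options(), times = NULL) {
  if (is.character(config)) config <- experiment_config(config)
  stopifnot(inherits(config, "succ_config"))
  if (is.null(times)) {
    times <- seq(0, config$t_end, by = solver$dt)
    if (times[length(times)] < config$t_end) times <- c(times, config$t_end)
  } else {
    stopifnot(all(diff(times) > 0), times[1] >= 0)
    if (times[1] > 0) times <- c(0, times)
  }
  out <- .integrate(config, params, fixed, options, solver, times)
  states <- out[, .succ_state_names, drop = FALSE]
  obs <- to_observables(states, fixed)
  # clip solver-scale undershoot in reported observables only
  obs <- dplyr::mutate(obs, dplyr::across(dplyr::everything(), ~ pmax(., 0)))
  traj <- dplyr::bind_cols(tibble::tibble(time_h = out[, "time"]),
                           tibble::as_tibble(states), obs)
  attr(traj, "config") <- config
  attr(traj, "options") <- options
  class(traj) <- c("succ_trajectory", class(traj))
  traj
}

#' Initial-glucose sweep
#'
#' Repeats the batch simulation over a grid of initial glucose concentrations
#' with a fixed inoculum, recording for each run the maximum biomass reached
#' and the final succinic acid titre.  This is the numerical experiment used
#' to locate the glucose loading that maximises succinate yield.
#'
#' @param glucose_gL grid of initial glucose concentrations, g/L (>= 0).
#' @param X0 inoculum, mol X/L.
#' @param t_end horizon per run, h (long enough to reach steady state).
#' @inheritParams simulate_batch
#' @param dt output spacing used within each run, h.
#' @return A tibble: `initial_glucose_gL`, `max_biomass_gL`, `final_SA_gL`.
#' @export
sweep_initial_glucose <- function(glucose_gL, X0 = 1.0e-3,
                                  params = calibrated_params(),
                                  fixed = fixed_params(),
                                  options = model_options(),
                                  solver = solver_options(), t_end = 150,
                                  dt = 0.5) {
  stopifnot(length(glucose_gL) > 0, all(is.finite(glucose_gL)),
            all(glucose_gL >= 0))
  solver$dt <- dt
  rows <- purrr::map(glucose_gL, function(g) {
    cfg <- experiment_config(paste0("sweep_", format(g)), G0 = g / fixed[["MW_G"]],
                             X0 = X0, t_end = t_end)
    traj <- tryCatch(
      simulate_batch(cfg, params, fixed, options, solver),
      succ_integration_error = function(e) {
        rlang::abort(paste0("sweep failed at initial glucose ", g, " g/L"),
                     class = "succ_integration_error", parent = e)
      })
    tibble::tibble(initial_glucose_gL = g,
                   max_biomass_gL = max(traj$biomass_gL),
                   final_SA_gL = traj$SA_gL[nrow(traj)])
  })
  res <- dplyr::bind_rows(rows)
  class(res) <- c("succ_sweep", class(res))
  res
}
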