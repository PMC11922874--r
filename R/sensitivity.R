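# Local one-at-a-time sensitivity analysis: each calibrated parameter is
# perturbed by +/- a relative delta and the standardised elemental effect is
# accumulated over biomass and succinic acid trajectories.

.succ_param_groups <- c(
  v_Gly1 = "uptake", k_Gly1 = "uptake", a1 = "uptake", k1 = "uptake",
  G_mid1 = "uptake", a2 = "uptake", k2 = "uptake", R_mid = "uptake",
  v_Gly2 = "glycolysis", k_Gly2 = "glycolysis", v_Gly3 = "glycolysis",
  k_Gly3 = "glycolysis", G3P_max = "glycolysis", PEP_max = "glycolysis",
  P_max = "glycolysis",
  v_P1 = "production", k_P1 = "production", v_P2 = "production",
  k_P2 = "production", v_P3 = "production", k_P3 = "production",
  v_G = "growth", k_G = "growth", eta_X = "growth", n_X = "growth",
  k4 = "growth", G_mid2 = "growth",
  k3 = "energy", ATP_mid = "energy",
  n_SA = "acid-extrusion", n_AA = "acid-extrusion", n_FA = "acid-extrusion",
  k5 = "acid-extrusion", SA_mid = "acid-extrusion",
  k6 = "acid-extrusion", AA_mid = "acid-extrusion",
  k7 = "acid-extrusion", FA_mid = "acid-extrusion"
)

.sens_grid <- function(config, n_times) seq(0, config$t_end, length.out = n_times)

.sens_signal <- function(traj) cbind(traj$biomass_gL, traj$SA_gL)

# Standardised elemental effect of one perturbed trajectory against a
# baseline: (1/n) * sum_j sum_i (pert_ij - base_ij)^2 / (max_j - min_j),
# j over biomass and succinic acid.
.elemental_effect_from <- function(base_sig, pert_sig, n_params) {
  eff <- 0
  for (j in 1:2) {
    num <- sum((pert_sig[, j] - base_sig[, j])^2)
    if (num == 0) next
    den <- max(base_sig[, j]) - min(base_sig[, j])
    if (den <= 0) return(Inf)
    eff <- eff + num / den
  }
  eff / n_params
}

#' Elemental effect of one parameter perturbation
#'
#' Simulates one experiment with a single calibrated parameter scaled by
#' `1 + delta` and accumulates the squared deviation from the baseline
#' trajectory of biomass and succinic acid (g/L) on a fixed evaluation grid,
#' normalised per variable by the baseline range and divided by the number of
#' analysed parameters.
#'
#' @param param_name name of a calibrated parameter.
#' @param delta relative perturbation (e.g. `0.05` for +5%).
#' @param params baseline calibrated parameters.
#' @param fixed fixed parameters.
#' @param config experiment configuration (or name).
#' @param options structural options.
#' @param solver solver settings.
#' @param n_times number of equally spaced evaluation times on
#'   `[0, t_end]`.
#' @param n_params the `1/n` prefactor; defaults to the number of calibrated
#'   parameters.
#' @param baseline optional precomputed baseline trajectory on the same grid
#'   (to avoid re-simulation).
#' @return Non-negative scalar; `Inf` (with attribute `failed = TRUE`) if
#'   the perturbed simulation fails.
#' @export
elemental_effect <- function(param_name, delta, params = calibrated_params(),
                             fixed = fixed_params(), config,
                             options = model_options(),
                             solver = solver_options(), n_times = 101,
                             n_params = length(params), baseline = NULL) {
  if (!param_name %in% names(params)) {
    rlang::abort(paste0("unknown parameter '", param_name, "'"),
                 class = "succ_config_error")
  }
  if (is.character(config)) config <- experiment_config(config)
  grid <- .sens_grid(config, n_times)
  if (is.null(baseline)) {
    baseline <- simulate_batch(config, params, fixed, options, solver,
                               times = grid)
  }
  if (delta == 0) return(0)
  pert <- params
  pert[[param_name]] <- pert[[param_name]] * (1 + delta)
  ptraj <- tryCatch(
    simulate_batch(config, pert, fixed, options, solver, times = grid),
    error = function(e) NULL)
  if (is.null(ptraj)) {
    return(structure(Inf, failed = TRUE))
  }
  base_sig <- .sens_signal(baseline[match(grid, baseline$time_h), ])
  pert_sig <- .sens_signal(ptraj[match(grid, ptraj$time_h), ])
  .elemental_effect_from(base_sig, pert_sig, n_params)
}

#' Sensitivity table over parameters and experiments
#'
#' Computes the elemental effect of a +/-`delta` perturbation of every
#' calibrated parameter for each experiment, together with the total
#' variation (sum of the two signed effects) and its within-experiment rank.
#'
#' @param params baseline calibrated parameters.
#' @param fixed fixed parameters.
#' @param configs list of experiment configurations or names
#'   (default: all five reference experiments).
#' @param delta relative perturbation magnitude.
#' @inheritParams elemental_effect
#' @return A tibble of class `"succ_sensitivity"`: `experiment`, `parameter`,
#'   `group`, `effect_plus`, `effect_minus`, `total`, `rank` and `failed`.
#' @export
sensitivity_table <- function(params = calibrated_params(),
                              fixed = fixed_params(),
                              configs = as.list(names(.succ_experiments)),
                              delta = 0.05, options = model_options(),
                              solver = solver_options(), n_times = 101,
                              n_params = length(params)) {
  rows <- purrr::map(configs, function(cfg) {
    if (is.character(cfg)) cfg <- experiment_config(cfg)
    grid <- .sens_grid(cfg, n_times)
    baseline <- simulate_batch(cfg, params, fixed, options, solver,
                               times = grid)
    per_param <- purrr::map(names(params), function(pn) {
      ep <- elemental_effect(pn, delta, params, fixed, cfg, options, solver,
                             n_times, n_params, baseline = baseline)
      em <- elemental_effect(pn, -delta, params, fixed, cfg, options, solver,
                             n_times, n_params, baseline = baseline)
      tibble::tibble(experiment = cfg$name, parameter = pn,
                     group = unname(.succ_param_groups[pn]),
                     effect_plus = as.numeric(ep),
                     effect_minus = as.numeric(em),
                     total = as.numeric(ep) + as.numeric(em),
                     failed = isTRUE(attr(ep, "failed")) ||
                       isTRUE(attr(em, "failed")))
    })
    d <- dplyr::bind_rows(per_param)
    d$rank <- rank(-d$total, ties.method = "min")
    d
  })
  res <- dplyr::bind_rows(rows)
  class(res) <- c("succ_sensitivity", class(res))
  res
}
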