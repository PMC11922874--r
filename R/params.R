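#' @importFrom rlang %||% abort
#' @importFrom tibble tibble as_tibble
NULL

# Fixed (stoichiometric) parameters: molecular weights in g/mol, the ATP
# content of microbial mass s_ATP in g(X)^-1, and the mole ratios nu_* of the
# lumped reactions.  MW_X is the weight of the biomass monomer CH2O0.5N0.18.
.succ_fixed_defaults <- c(
  MW_X   = 24.55,
  MW_G   = 180.16,
  MW_G3P = 170.06,
  MW_PEP = 168.04,
  MW_P   = 88.06,
  MW_SA  = 118.09,
  MW_AA  = 60.05,
  MW_FA  = 46.03,
  s_ATP  = 1.00,
  nu_G3P = 2.00,
  nu_P   = 1.00,
  nu_Pyr = 1.00,
  nu_X   = 3.00,
  nu_SA  = 1.00,
  nu_AA  = 1.00,
  nu_FA  = 1.00,
  nu_ATP1 = 2.00,
  nu_ATP2 = 1.00,
  nu_ATP3 = 1.00,
  nu_ATP4 = 1.00,
  nu_ATP5 = 1.00
)

# Calibrated kinetic and response-curve parameters.  Maximum rates v_* are in
# mol (mol X)^-1 h^-1.  Saturation constants, intracellular caps and curve
# midpoints are on the mass scale (g L^-1 for extracellular quantities,
# g g(X)^-1 for intracellular ones) and are converted to molar units by the
# relevant molecular weight at the point of use; see the methods vignette.
.succ_calibrated_defaults <- c(
  v_Gly1 = 2.32,    k_Gly1 = 39.99,
  v_Gly2 = 1.78,    k_Gly2 = 1.24e-10,
  v_Gly3 = 1.08,    k_Gly3 = 9.90e-5,
  v_P1   = 0.27,    k_P1   = 2.65e-5,
  v_P2   = 0.12,    k_P2   = 6.71e-4,
  v_P3   = 0.20,    k_P3   = 3.70e-4,
  v_G    = 8.61e-2, k_G    = 1.89e-4,
  G3P_max = 4.97e-4,
  PEP_max = 4.70e-4,
  P_max   = 4.54e-4,
  eta_X  = 0.83,
  n_X    = 1.57,
  n_SA   = 1.49,
  n_AA   = 6.15,
  n_FA   = 3.01,
  a1     = 0.88,    k1     = 53.39,   G_mid1 = 51.49,
  a2     = 0.18,    k2     = 10.13,   R_mid  = 1.20,
  k3     = 22.06,   ATP_mid = 0.36,
  k4     = 4.10e2,  G_mid2 = 2.02,
  k5     = 13.84,   SA_mid = 23.05,
  k6     = 11.04,   AA_mid = 0.45,
  k7     = 8.67,    FA_mid = 1.08
)

# Pre-calibration starting values for the same parameter set.
.succ_calibrated_initial <- c(
  v_Gly1 = 1.50,    k_Gly1 = 1.00,
  v_Gly2 = 1.00,    k_Gly2 = 1.00e-5,
  v_Gly3 = 1.00,    k_Gly3 = 1.00e-5,
  v_P1   = 1.00,    k_P1   = 1.00e-5,
  v_P2   = 1.00,    k_P2   = 1.00e-5,
  v_P3   = 1.00,    k_P3   = 1.00e-5,
  v_G    = 0.50,    k_G    = 1.00e-5,
  G3P_max = 5.00e-4,
  PEP_max = 5.00e-4,
  P_max   = 5.00e-4,
  eta_X  = 0.70,
  n_X    = 1.00,
  n_SA   = 1.20,
  n_AA   = 5.00,
  n_FA   = 2.50,
  a1     = 1.00,    k1     = 2.00e2,  G_mid1 = 5.00,
  a2     = 1.00,    k2     = 2.00e2,  R_mid  = 5.00,
  k3     = 15.00,   ATP_mid = 0.25,
  k4     = 3.00e2,  G_mid2 = 2.50,
  k5     = 13.93,   SA_mid = 20.00,
  k6     = 5.00,    AA_mid = 2.00,
  k7     = 5.00,    FA_mid = 1.00
)

.validate_param_vec <- function(x, template, what) {
  nm <- names(template)
  extra <- setdiff(names(x), nm)
  if (length(extra) > 0) {
    abort(paste0("unknown ", what, " parameter(s): ", paste(extra, collapse = ", ")),
          class = "succ_config_error")
  }
  missing <- setdiff(nm, names(x))
  if (length(missing) > 0) {
    abort(paste0("missing ", what, " parameter(s): ", paste(missing, collapse = ", ")),
          class = "succ_config_error")
  }
  x <- x[nm]
  bad <- nm[!is.finite(x) | x <= 0]
  if (length(bad) > 0) {
    abort(paste0("non-positive or non-finite value for: ", paste(bad, collapse = ", ")),
          class = "succ_config_error")
  }
  x
}

#' Fixed stoichiometric parameters
#'
#' Molecular weights, the ATP content of microbial mass, and the mole ratios
#' of the lumped metabolic reactions.  These are physical constants of the
#' model and are not subject to calibration.
#'
#' @param ... named scalar overrides of individual entries (for example
#'   `nu_X = 2.5`).  Unknown names are an error.
#' @return A named numeric vector of class `"succ_fixed"`.
#' @examples
#' fx <- fixed_params()
#' fx[["MW_G"]]
#' @export
fixed_params <- function(...) {
  x <- .succ_fixed_defaults
  ov <- c(...)
  if (length(ov) > 0) {
    if (is.null(names(ov)) || any(names(ov) == "")) {
      abort("overrides must be named", class = "succ_config_error")
    }
    x[names(ov)] <- ov
  }
  x <- .validate_param_vec(x, .succ_fixed_defaults, "fixed")
  structure(x, class = "succ_fixed")
}

#' Calibrated kinetic parameters
#'
#' The 38 kinetic and response-curve parameters of the fermentation model:
#' maximum process rates and saturation constants of the three glycolytic
#' steps, the three fermentative production steps and growth; intracellular
#' metabolite caps; the biomass yield efficiency; ATP cost coefficients; and
#' the slope/midpoint pairs of the logistic response curves.
#'
#' @param ... named scalar overrides of individual entries.
#' @param set `"calibrated"` (the fitted values, default) or `"initial"`
#'   (the pre-calibration starting values).
#' @return A named numeric vector of class `"succ_params"`.
#' @examples
#' cp <- calibrated_params()
#' cp[["v_G"]]
#' start <- calibrated_params(set = "initial")
#' @export
calibrated_params <- function(..., set = c("calibrated", "initial")) {
  set <- match.arg(set)
  x <- if (set == "calibrated") .succ_calibrated_defaults else .succ_calibrated_initial
  ov <- c(...)
  if (length(ov) > 0) {
    if (is.null(names(ov)) || any(names(ov) == "")) {
      abort("overrides must be named", class = "succ_config_error")
    }
    x[names(ov)] <- ov
  }
  x <- .validate_param_vec(x, .succ_calibrated_defaults, "calibrated")
  if (x[["a1"]] > 1) {
    abort("a1 must lie in (0, 1]", class = "succ_config_error")
  }
  if (x[["a2"]] > 1) {
    abort("a2 must lie in (0, 1]", class = "succ_config_error")
  }
  structure(x, class = "succ_params")
}

#' Structural model options
#'
#' Settings that select between alternative readings of the model structure.
#' Defaults are the configuration under which the model reproduces the
#' reference batch experiments; see the methods vignette for the rationale
#' behind each choice.
#'
#' @param dilution_factor coefficient of the growth anti-dilution term in the
#'   ATP and ADP balances.  With the default 1 the summed energy pool per unit
#'   biomass, (ATP+ADP)/X, is exactly conserved; with a coefficient `c` the
#'   conserved quantity is (ATP+ADP)/X^c.
#' @param log_base base of the logarithm applied to the glucose/biomass ratio
#'   in the uptake response curve (natural log by default).
#' @param uptake_regulation orientation and scale of the glucose/biomass
#'   ratio response curve RC_v2.  `"high_glucose"` (default): the curve
#'   decreases from 1 towards `a2` as the per-gram availability index
#'   G/(X.MW_X) rises past `exp(R_mid)`, throttling uptake when glucose is
#'   abundant relative to the population.  `"as_printed"`: the curve
#'   increases from `a2` towards 1 with the molar ratio G/X.
#' @param secretion biomass secretion/decay rate subtracted from dX/dt
#'   (mol X L^-1 h^-1 per unit of the hook function; 0 disables, the default;
#'   cell death was not observed in the reference experiments).
#' @return A list of class `"succ_options"`.
#' @export
model_options <- function(dilution_factor = 1,
                          log_base = exp(1),
                          uptake_regulation = c("high_glucose", "as_printed"),
                          secretion = 0) {
  uptake_regulation <- match.arg(uptake_regulation)
  stopifnot(is.finite(dilution_factor), is.finite(log_base), log_base > 0,
            log_base != 1, is.finite(secretion), secretion >= 0)
  structure(list(dilution_factor = dilution_factor,
                 log_base = log_base,
                 uptake_regulation = uptake_regulation,
                 secretion = secretion),
            class = "succ_options")
}

#' @export
print.succ_fixed <- function(x, ...) {
  cat("<fixed stoichiometric parameters>\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.succ_params <- function(x, ...) {
  cat("<calibrated kinetic parameters (", length(x), ")>\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Read a parameter file
#'
#' Parameter sets are stored as flat `key: value` YAML maps.  The file must
#' contain exactly the keys of the corresponding parameter set, all strictly
#' positive; violations raise a config error naming the offending key.
#'
#' @param path file path; if `NULL`, packaged defaults are returned.
#' @param type `"calibrated"` or `"fixed"`; if `NULL` (default) the type is
#'   inferred from the keys present in the file.
#' @return A `succ_params` or `succ_fixed` vector.
#' @seealso [write_params()]
#' @export
read_params <- function(path = NULL, type = NULL) {
  if (is.null(path)) {
    if (is.null(type)) type <- "calibrated"
    return(switch(type,
                  calibrated = calibrated_params(),
                  fixed = fixed_params(),
                  abort("type must be 'calibrated' or 'fixed'",
                        class = "succ_config_error")))
  }
  if (!file.exists(path)) {
    abort(paste0("parameter file not found: ", path), class = "succ_config_error")
  }
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0) {
    abort("empty parameter file", class = "succ_config_error")
  }
  x <- vapply(raw, as.numeric, numeric(1))
  if (is.null(type)) {
    type <- if (any(names(x) %in% names(.succ_calibrated_defaults))) "calibrated" else "fixed"
  }
  template <- if (type == "calibrated") .succ_calibrated_defaults else .succ_fixed_defaults
  miss <- setdiff(names(template), names(x))
  if (length(miss) > 0) {
    abort(paste0("missing ", type, " parameter(s) in ", path, ": ",
                 paste(miss, collapse = ", ")),
          class = "succ_config_error")
  }
  if (type == "calibrated") {
    do.call(calibrated_params, as.list(x))
  } else {
    do.call(fixed_params, as.list(x))
  }
}

#' Write a parameter file
#'
#' Serialises a parameter vector to a flat YAML map.  Each value is written
#' with the fewest significant digits that read back to the identical double,
#' so a write/read round trip is lossless.
#'
#' @param params a `succ_params` or `succ_fixed` vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, c("succ_params", "succ_fixed")))
  fmt1 <- function(v) {
    for (d in c(6, 15, 17)) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    s
  }
  lines <- sprintf("%s: %s", names(params),
                   vapply(as.numeric(params), fmt1, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Tidy a parameter vector
#'
#' @param x a `succ_params` or `succ_fixed` vector.
#' @param ... unused.
#' @return A tibble with columns `parameter` and `value`.
#' @importFrom generics tidy
#' @export
tidy.succ_params <- function(x, ...) {
  tibble(parameter = names(x), value = as.numeric(x))
}

#' @rdname tidy.succ_params
#' @export
tidy.succ_fixed <- function(x, ...) {
  tibble(parameter = names(x), value = as.numeric(x))
}
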