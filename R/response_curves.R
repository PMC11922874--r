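# Logistic response curves.  Each curve is a two-parameter logistic gate in
# [0, 1] (RC_v1 in [1 - a1, 1], RC_v2 in [a2, 1]) that throttles a process
# rate as its controlling variable crosses a threshold.  stats::plogis is
# used for the logistic so that large arguments saturate to 0/1 instead of
# overflowing.

.check_X <- function(X) {
  if (any(!is.finite(X) | X <= 0)) {
    rlang::abort("microbial mass X must be strictly positive",
                 class = "succ_state_error")
  }
}

#' Glucose uptake response curves
#'
#' `rc_v1` is the up-regulation curve of glucose uptake: close to 1 at low
#' glucose (the phosphotransferase system is fully engaged) and decreasing to
#' `1 - a1` once glucose exceeds the midpoint `G_mid1/MW_G`.  `rc_v2`
#' modulates uptake by glucose availability per unit of biomass; in the
#' default `"high_glucose"` orientation it decreases from 1 to `a2` as the
#' per-gram availability index G/(X*MW_X) -- mol glucose per gram of biomass,
#' mirroring the energy index of `rc_atp` -- rises past `exp(R_mid)`, slowing
#' uptake when glucose is abundant relative to the population.
#'
#' @param G extracellular glucose, mol/L (vectorised; must be >= 0).
#' @param X microbial mass, mol X/L (strictly positive).
#' @param params calibrated parameters, see [calibrated_params()].
#' @param fixed fixed parameters, see [fixed_params()].
#' @param options structural options, see [model_options()].
#' @return Dimensionless fraction(s).
#' @examples
#' rc_v1(0.03, calibrated_params(), fixed_params())
#' @export
rc_v1 <- function(G, params, fixed) {
  1 - params[["a1"]] * stats::plogis(params[["k1"]] * (G - params[["G_mid1"]] / fixed[["MW_G"]]))
}

#' @rdname rc_v1
#' @export
rc_v2 <- function(G, X, params, fixed, options = model_options()) {
  .check_X(X)
  a2 <- params[["a2"]]
  k2 <- params[["k2"]]
  lb <- log(options$log_base)
  if (options$uptake_regulation == "high_glucose") {
    ratio <- G / (X * fixed[["MW_X"]])
    out <- ifelse(G <= 0, 1,
                  a2 + (1 - a2) *
                    stats::plogis(-k2 * (log(pmax(ratio, .Machine$double.xmin)) / lb -
                                           params[["R_mid"]])))
  } else {
    ratio <- G / X
    out <- ifelse(G <= 0, a2,
                  a2 + (1 - a2) *
                    stats::plogis(k2 * (log(pmax(ratio, .Machine$double.xmin)) / lb -
                                          params[["R_mid"]])))
  }
  out
}

#' Energy-balance response curves
#'
#' `rc_atp` gates ATP-consuming processes (glucose uptake, growth): it rises
#' from 0 to 1 as the energy index ATP/(X*MW_X) -- ATP per gram of biomass --
#' crosses `ATP_mid`.  `rc_adp` gates ATP-producing processes and is the
#' complement `1 - rc_atp`.
#'
#' @param ATP dimensionless ATP pool.
#' @inheritParams rc_v1
#' @return Dimensionless fraction(s), strictly increasing (`rc_atp`) or
#'   decreasing (`rc_adp`) in `ATP`.
#' @export
rc_atp <- function(ATP, X, params, fixed) {
  .check_X(X)
  stats::plogis(params[["k3"]] * (ATP / (X * fixed[["MW_X"]]) - params[["ATP_mid"]]))
}

#' @rdname rc_atp
#' @export
rc_adp <- function(ATP, X, params, fixed) {
  1 - rc_atp(ATP, X, params, fixed)
}

#' Growth nutrient response curve
#'
#' Inhibits growth when glucose becomes scarce: rises from ~0 at G = 0 to 1
#' once glucose exceeds the midpoint `G_mid2/MW_G`.
#'
#' @inheritParams rc_v1
#' @export
rc_g <- function(G, params, fixed) {
  stats::plogis(params[["k4"]] * (G - params[["G_mid2"]] / fixed[["MW_G"]]))
}

#' Acid extrusion resistance curve
#'
#' Shared logistic form for the three organic acids: the resistance to
#' extrusion (and hence the ATP cost of export) rises from ~0 to 1 as the
#' external acid concentration crosses `acid_mid/MW_acid`.
#'
#' @param acid_conc external acid concentration, mol/L.
#' @param k_acid slope, per mol.
#' @param acid_mid midpoint on the mass scale, g/L.
#' @param MW_acid molecular weight of the acid, g/mol.
#' @examples
#' p <- calibrated_params(); f <- fixed_params()
#' rc_acid(0.1, p[["k5"]], p[["SA_mid"]], f[["MW_SA"]])
#' @export
rc_acid <- function(acid_conc, k_acid, acid_mid, MW_acid) {
  stats::plogis(k_acid * (acid_conc - acid_mid / MW_acid))
}
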