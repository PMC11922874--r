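# Core model: the seven process rates and the coupled mass balances.
#
# State vector ordering (used throughout the package):
#   G    extracellular glucose        mol/L
#   G3P  glyceraldehyde-3-phosphate   mol/(mol X)
#   PEP  phosphoenolpyruvate          mol/(mol X)
#   P    pyruvate                     mol/(mol X)
#   X    microbial mass               mol X/L
#   SA   succinic acid                mol/L
#   AA   acetic acid                  mol/L
#   FA   formic acid                  mol/L
#   ATP  dimensionless energy pool
#   ADP  dimensionless energy pool

.succ_state_names <- c("G", "G3P", "PEP", "P", "X", "SA", "AA", "FA", "ATP", "ADP")

#' State vector constructor
#'
#' @param G,G3P,PEP,P,X,SA,AA,FA,ATP,ADP the ten dynamic quantities; see the
#'   package overview for units.
#' @return A named numeric vector in canonical order.
#' @export
state_vector <- function(G = 0, G3P = 0, PEP = 0, P = 0, X, SA = 0, AA = 0,
                         FA = 0, ATP = 0, ADP = 0) {
  c(G = G, G3P = G3P, PEP = PEP, P = P, X = X, SA = SA, AA = AA, FA = FA,
    ATP = ATP, ADP = ADP)
}

# Resolve all unit conversions once.  Saturation constants, intracellular
# caps and curve midpoints are stored on the mass scale (g/L or g/gX) and
# converted to molar units here; rate laws then work purely in mol.
.rate_context <- function(params, fixed, options = model_options()) {
  p <- as.list(params); f <- as.list(fixed)
  ctx <- c(p, f)
  ctx$k_Gly1_mol <- p$k_Gly1 / f$MW_G
  ctx$k_Gly2_mol <- p$k_Gly2 * f$MW_X / f$MW_G3P
  ctx$k_Gly3_mol <- p$k_Gly3 * f$MW_X / f$MW_PEP
  ctx$k_P1_mol   <- p$k_P1 * f$MW_X / f$MW_PEP
  ctx$k_P2_mol   <- p$k_P2 * f$MW_X / f$MW_P
  ctx$k_P3_mol   <- p$k_P3 * f$MW_X / f$MW_P
  ctx$k_G_mol    <- p$k_G * f$MW_X / f$MW_P
  ctx$G_mid1_mol <- p$G_mid1 / f$MW_G
  ctx$G_mid2_mol <- p$G_mid2 / f$MW_G
  ctx$SA_mid_mol <- p$SA_mid / f$MW_SA
  ctx$AA_mid_mol <- p$AA_mid / f$MW_AA
  ctx$FA_mid_mol <- p$FA_mid / f$MW_FA
  # intracellular caps, mol/(mol X); the printed brake (1 - pool/cap * MW
  # ratio) equals 1 - pool/cap_mol
  ctx$G3P_cap <- p$G3P_max * f$MW_X / f$MW_G3P
  ctx$PEP_cap <- p$PEP_max * f$MW_X / f$MW_PEP
  ctx$P_cap   <- p$P_max * f$MW_X / f$MW_P
  ctx$growth_yield <- p$eta_X * f$nu_X                 # X per pyruvate
  ctx$growth_cost  <- p$eta_X * p$n_X * f$nu_X         # ATP per pyruvate
  ctx$log_base_fac <- 1 / log(options$log_base)
  ctx$uptake_high  <- options$uptake_regulation == "high_glucose"
  ctx$avail_fac <- 1 / f$MW_X  # availability index: mol glucose per gram biomass
  ctx$dil <- options$dilution_factor
  ctx$secretion <- options$secretion
  list2env(ctx, parent = baseenv())
}

# Scalar rate kernel shared by process_rates(), ode_rhs() and simulate().
# Returns the seven process rates plus the response-curve values.
.rates_core <- function(y, e) {
  G <- y[[1L]]; G3P <- y[[2L]]; PEP <- y[[3L]]; P <- y[[4L]]; X <- y[[5L]]
  SA <- y[[6L]]; AA <- y[[7L]]; FA <- y[[8L]]; ATP <- y[[9L]]
  # integrator overshoot guard: substrate pools never drive a rate when <= 0
  Gp <- max(G, 0); G3Pp <- max(G3P, 0); PEPp <- max(PEP, 0); Pp <- max(P, 0)

  rcv1 <- 1 - e$a1 * stats::plogis(e$k1 * (G - e$G_mid1_mol))
  if (e$uptake_high) {
    rcv2 <- if (Gp <= 0) 1 else
      e$a2 + (1 - e$a2) *
        stats::plogis(-e$k2 * (log(Gp / X * e$avail_fac) * e$log_base_fac - e$R_mid))
  } else {
    rcv2 <- if (Gp <= 0) e$a2 else
      e$a2 + (1 - e$a2) *
        stats::plogis(e$k2 * (log(Gp / X) * e$log_base_fac - e$R_mid))
  }
  rcatp <- stats::plogis(e$k3 * (ATP / (X * e$MW_X) - e$ATP_mid))
  rcadp <- 1 - rcatp
  rcg <- stats::plogis(e$k4 * (G - e$G_mid2_mol))
  rcsa <- stats::plogis(e$k5 * (SA - e$SA_mid_mol))
  rcaa <- stats::plogis(e$k6 * (AA - e$AA_mid_mol))
  rcfa <- stats::plogis(e$k7 * (FA - e$FA_mid_mol))

  # product-saturation brakes, clamped at 0 (saturation, not reversal)
  sat1 <- max(0, 1 - G3Pp / e$G3P_cap)
  sat2 <- max(0, 1 - PEPp / e$PEP_cap)
  sat3 <- max(0, 1 - Pp / e$P_cap)

  gly1 <- max(0, e$v_Gly1 * rcv1 * rcv2 * Gp / (e$k_Gly1_mol + Gp) * X * sat1 * rcatp)
  gly2 <- max(0, e$v_Gly2 * G3Pp / (e$k_Gly2_mol + G3Pp) * X * sat2 * rcadp)
  gly3 <- max(0, e$v_Gly3 * PEPp / (e$k_Gly3_mol + PEPp) * X * sat3 * rcadp)
  pr1  <- max(0, e$v_P1 * PEPp / (e$k_P1_mol + PEPp) * X * rcadp)
  pr2  <- max(0, e$v_P2 * Pp / (e$k_P2_mol + Pp) * X * rcadp)
  pr3  <- max(0, e$v_P3 * Pp / (e$k_P3_mol + Pp) * X * rcadp)
  gro  <- max(0, e$v_G * Pp / (e$k_G_mol + Pp) * X * rcatp * rcg)

  list(gly1 = gly1, gly2 = gly2, gly3 = gly3, pr1 = pr1, pr2 = pr2,
       pr3 = pr3, gro = gro, rcsa = rcsa, rcaa = rcaa, rcfa = rcfa)
}

.rhs_core <- function(y, e) {
  r <- .rates_core(y, e)
  X <- y[[5L]]; ATP <- y[[9L]]; ADP <- y[[10L]]
  dX <- e$growth_yield * r$gro - e$secretion
  aa_flux <- r$pr2 + r$pr3
  extrusion <- e$n_SA * e$nu_SA * r$pr1 * r$rcsa +
    e$n_AA * e$nu_AA * aa_flux * r$rcaa +
    e$n_FA * e$nu_FA * r$pr3 * r$rcfa
  stoich <- -e$nu_ATP1 * r$gly1 + e$nu_ATP2 * r$gly2 + e$nu_ATP3 * r$gly3 +
    e$nu_ATP4 * e$nu_SA * r$pr1 + e$nu_ATP5 * e$nu_AA * aa_flux -
    e$growth_cost * r$gro - extrusion
  c(-r$gly1,
    (e$nu_G3P * r$gly1 - r$gly2) / X,
    (e$nu_P * r$gly2 - r$gly3 - r$pr1) / X,
    (e$nu_Pyr * r$gly3 - r$pr2 - r$pr3 - r$gro) / X,
    dX,
    e$nu_SA * r$pr1,
    e$nu_AA * aa_flux,
    e$nu_FA * r$pr3,
    stoich + e$dil * (ATP / X) * dX,
    -stoich + e$dil * (ADP / X) * dX)
}

#' Process rates at a state
#'
#' Evaluates the seven extensive process rates (mol/L/h, already multiplied
#' by the biomass) at one state: the three glycolytic steps (glucose to G3P,
#' G3P to PEP, PEP to pyruvate), the three fermentative productions
#' (PEP to succinate; pyruvate to acetate; pyruvate to acetate + formate)
#' and growth.  Every rate is clamped at zero.
#'
#' @param state named state vector, see [state_vector()].
#' @inheritParams rc_v1
#' @return Named numeric vector `glycolysis1..3`, `production1..3`, `growth`.
#' @export
process_rates <- function(state, params, fixed, options = model_options()) {
  .check_X(state[["X"]])
  e <- .rate_context(params, fixed, options)
  r <- .rates_core(state[.succ_state_names], e)
  c(glycolysis1 = r$gly1, glycolysis2 = r$gly2, glycolysis3 = r$gly3,
    production1 = r$pr1, production2 = r$pr2, production3 = r$pr3,
    growth = r$gro)
}

#' ODE right-hand side
#'
#' Time derivative of the ten-component state under the mass balances:
#' extracellular species change with the extensive process rates,
#' intracellular pools with the flux balance divided by the biomass, and the
#' ATP/ADP pools with the stoichiometric ATP yield/cost of every process,
#' the acid-extrusion costs, and a growth anti-dilution term
#' `dilution_factor * (pool/X) * dX/dt`.
#'
#' @param t time in hours (unused; the system is autonomous).
#' @param state named state vector.
#' @inheritParams rc_v1
#' @return Named numeric vector of derivatives.
#' @export
ode_rhs <- function(t, state, params, fixed, options = model_options()) {
  y <- state[.succ_state_names]
  if (any(!is.finite(y)) || y[["X"]] <= 0) {
    rlang::abort("non-finite state or non-positive biomass in ode_rhs",
                 class = "succ_integration_error")
  }
  e <- .rate_context(params, fixed, options)
  stats::setNames(.rhs_core(y, e), .succ_state_names)
}

#' Initial energy pools
#'
#' The initial ATP and ADP pools assume a fixed total energy content per gram
#' of biomass (`s_ATP`) split equally between the two pools:
#' `ATP0 = ADP0 = s_ATP * X0 * MW_X / 2`.
#'
#' @param X0 initial microbial mass, mol X/L (strictly positive).
#' @param fixed fixed parameters.
#' @return Named numeric vector `c(ATP = ..., ADP = ...)`.
#' @examples
#' initial_energy(1.05e-3, fixed_params())
#' @export
initial_energy <- function(X0, fixed = fixed_params()) {
  if (!is.numeric(X0) || any(!is.finite(X0) | X0 <= 0)) {
    rlang::abort("X0 must be strictly positive", class = "succ_config_error")
  }
  half <- fixed[["s_ATP"]] * X0 * fixed[["MW_X"]] / 2
  c(ATP = half, ADP = half)
}
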