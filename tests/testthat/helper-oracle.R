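# Independent scalar re-implementation of the model equations, written
# directly from the rate laws with explicit exponentials and no code shared
# with the package.  Used to pin the package's process_rates()/ode_rhs().

oracle_logistic <- function(q) {
  if (q > 700) return(1)
  if (q < -700) return(0)
  1 / (1 + exp(-q))
}

# params/fixed are plain named vectors; dil is the anti-dilution coefficient.
# Returns list(rates = ..., deriv = ...).
oracle_model <- function(y, params, fixed, dil = 1,
                         uptake = c("high_glucose", "as_printed")) {
  uptake <- match.arg(uptake)
  p <- as.list(unclass(params)); f <- as.list(unclass(fixed))
  G <- y[["G"]]; G3P <- y[["G3P"]]; PEP <- y[["PEP"]]; P <- y[["P"]]
  X <- y[["X"]]; SA <- y[["SA"]]; AA <- y[["AA"]]; FA <- y[["FA"]]
  ATP <- y[["ATP"]]; ADP <- y[["ADP"]]
  Gp <- max(G, 0); G3Pp <- max(G3P, 0); PEPp <- max(PEP, 0); Pp <- max(P, 0)

  rcv1 <- 1 - p$a1 * oracle_logistic(p$k1 * (G - p$G_mid1 / f$MW_G))
  rcv2 <- if (uptake == "high_glucose") {
    if (Gp <= 0) 1 else
      p$a2 + (1 - p$a2) * oracle_logistic(-p$k2 * (log(Gp / (X * f$MW_X)) - p$R_mid))
  } else {
    if (Gp <= 0) p$a2 else
      p$a2 + (1 - p$a2) * oracle_logistic(p$k2 * (log(Gp / X) - p$R_mid))
  }
  rcatp <- oracle_logistic(p$k3 * (ATP / (X * f$MW_X) - p$ATP_mid))
  rcadp <- 1 - rcatp
  rcg <- oracle_logistic(p$k4 * (G - p$G_mid2 / f$MW_G))
  rcsa <- oracle_logistic(p$k5 * (SA - p$SA_mid / f$MW_SA))
  rcaa <- oracle_logistic(p$k6 * (AA - p$AA_mid / f$MW_AA))
  rcfa <- oracle_logistic(p$k7 * (FA - p$FA_mid / f$MW_FA))

  sat1 <- max(0, 1 - (G3Pp / (p$G3P_max * f$MW_X / f$MW_G3P)))
  sat2 <- max(0, 1 - (PEPp / (p$PEP_max * f$MW_X / f$MW_PEP)))
  sat3 <- max(0, 1 - (Pp / (p$P_max * f$MW_X / f$MW_P)))

  gly1 <- max(0, p$v_Gly1 * rcv1 * rcv2 * Gp / (p$k_Gly1 / f$MW_G + Gp) * X * sat1 * rcatp)
  gly2 <- max(0, p$v_Gly2 * G3Pp / (p$k_Gly2 * f$MW_X / f$MW_G3P + G3Pp) * X * sat2 * rcadp)
  gly3 <- max(0, p$v_Gly3 * PEPp / (p$k_Gly3 * f$MW_X / f$MW_PEP + PEPp) * X * sat3 * rcadp)
  pr1 <- max(0, p$v_P1 * PEPp / (p$k_P1 * f$MW_X / f$MW_PEP + PEPp) * X * rcadp)
  pr2 <- max(0, p$v_P2 * Pp / (p$k_P2 * f$MW_X / f$MW_P + Pp) * X * rcadp)
  pr3 <- max(0, p$v_P3 * Pp / (p$k_P3 * f$MW_X / f$MW_P + Pp) * X * rcadp)
  gro <- max(0, p$v_G * Pp / (p$k_G * f$MW_X / f$MW_P + Pp) * X * rcatp * rcg)

  dX <- p$eta_X * f$nu_X * gro
  ext <- p$n_SA * f$nu_SA * pr1 * rcsa +
    p$n_AA * f$nu_AA * (pr2 + pr3) * rcaa +
    p$n_FA * f$nu_FA * pr3 * rcfa
  st <- -f$nu_ATP1 * gly1 + f$nu_ATP2 * gly2 + f$nu_ATP3 * gly3 +
    f$nu_ATP4 * f$nu_SA * pr1 + f$nu_ATP5 * f$nu_AA * (pr2 + pr3) -
    p$eta_X * p$n_X * f$nu_X * gro - ext

  list(rates = c(glycolysis1 = gly1, glycolysis2 = gly2, glycolysis3 = gly3,
                 production1 = pr1, production2 = pr2, production3 = pr3,
                 growth = gro),
       deriv = c(G = -gly1,
                 G3P = (f$nu_G3P * gly1 - gly2) / X,
                 PEP = (f$nu_P * gly2 - gly3 - pr1) / X,
                 P = (f$nu_Pyr * gly3 - pr2 - pr3 - gro) / X,
                 X = dX,
                 SA = f$nu_SA * pr1,
                 AA = f$nu_AA * (pr2 + pr3),
                 FA = f$nu_FA * pr3,
                 ATP = st + dil * (ATP / X) * dX,
                 ADP = -st + dil * (ADP / X) * dX))
}

# Draw a random admissible state (all pools non-negative, X > 0).
random_state <- function(fixed) {
  X <- stats::runif(1, 1e-4, 0.08)
  caps <- c(G3P = 4.97e-4 * fixed[["MW_X"]] / fixed[["MW_G3P"]],
            PEP = 4.70e-4 * fixed[["MW_X"]] / fixed[["MW_PEP"]],
            P = 4.54e-4 * fixed[["MW_X"]] / fixed[["MW_P"]])
  total_energy <- fixed[["s_ATP"]] * X * fixed[["MW_X"]]
  atp <- stats::runif(1, 0, total_energy)
  state_vector(G = stats::runif(1, 0, 0.5),
               G3P = stats::runif(1, 0, caps[["G3P"]] * 1.1),
               PEP = stats::runif(1, 0, caps[["PEP"]] * 1.1),
               P = stats::runif(1, 0, caps[["P"]] * 1.1),
               X = X,
               SA = stats::runif(1, 0, 0.3),
               AA = stats::runif(1, 0, 0.15),
               FA = stats::runif(1, 0, 0.1),
               ATP = atp, ADP = total_energy - atp)
}

# Shared small fixtures
fast_solver <- function(dt = 0.5) solver_options(dt = dt)
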