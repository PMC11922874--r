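p <- calibrated_params()
fx <- fixed_params()

test_that("experiment configurations carry the published initial values", {
  tab <- batch_experiments()
  expect_equal(tab$name, paste0("G", 1:5))
  expect_equal(tab$G0, c(0.03, 0.12, 0.24, 0.37, 0.45))
  expect_equal(tab$X0, c(1.05e-3, 1.93e-3, 7.25e-4, 1.07e-3, 5.64e-4))
  expect_equal(tab$t_end, c(60, 100, 100, 100, 100))
  # unit bridge: the molar values equal the g/L loadings at 2 decimals
  expect_equal(round(c(5.40, 21.75, 42.65, 67.45, 80.70) / fx[["MW_G"]], 2),
               tab$G0)
  expect_error(experiment_config("G9"), class = "succ_config_error")
  expect_error(experiment_config("x", G0 = -1, X0 = 1e-3, t_end = 10),
               class = "succ_config_error")
})

test_that("zero initial glucose is a fixed point of the culture", {
  cfg <- experiment_config("zero", G0 = 0, X0 = 1e-3, t_end = 20)
  tr <- simulate_batch(cfg, p, fx, solver = fast_solver())
  expect_equal(max(abs(tr$glucose_gL)), 0)
  expect_equal(max(tr$SA_gL + tr$AA_gL + tr$FA_gL), 0)
  expect_equal(tr$biomass_gL, rep(1e-3 * fx[["MW_X"]], nrow(tr)),
               tolerance = 1e-10)
})

test_that("trajectories respect the batch monotonicity invariants", {
  for (nm in c("G1", "G3")) {
    tr <- simulate_batch(nm, p, fx, solver = fast_solver())
    tol <- 1e-9
    expect_true(all(diff(tr$glucose_gL) <= tol))
    expect_true(all(diff(tr$biomass_gL) >= -tol))
    expect_true(all(diff(tr$SA_gL) >= -tol))
    expect_true(all(diff(tr$AA_gL) >= -tol))
    expect_true(all(diff(tr$FA_gL) >= -tol))
    expect_true(all(tr$time_h == cummax(tr$time_h)))
  }
})

test_that("observables are the molar states scaled by molecular weight", {
  tr <- simulate_batch("G2", p, fx, solver = fast_solver())
  expect_equal(tr$glucose_gL, pmax(tr$G * fx[["MW_G"]], 0))
  expect_equal(tr$biomass_gL, pmax(tr$X * fx[["MW_X"]], 0))
  expect_equal(tr$SA_gL, pmax(tr$SA * fx[["MW_SA"]], 0))
  ob <- to_observables(state_vector(G = 0.03, X = 1.93e-3), fx)
  expect_equal(ob[["glucose_gL"]], 5.4048)
  expect_equal(to_observables(state_vector(X = 1e-9), fx)[["SA_gL"]], 0)
})

test_that("the summed energy pool follows the anti-dilution scaling law", {
  # default coefficient 1: (ATP+ADP)/X is conserved
  tr <- simulate_batch("G2", p, fx, solver = fast_solver())
  q1 <- (tr$ATP + tr$ADP) / tr$X
  expect_lt(diff(range(q1)) / q1[1], 1e-6)
  # coefficient 3: (ATP+ADP)/X^3 is conserved instead
  o3 <- model_options(dilution_factor = 3)
  tr3 <- simulate_batch("G2", p, fx, o3, fast_solver())
  q3 <- (tr3$ATP + tr3$ADP) / tr3$X^3
  expect_lt(diff(range(q3)) / q3[1], 1e-6)
})

test_that("simulation is bitwise reproducible", {
  a <- simulate_batch("G1", p, fx, solver = fast_solver())
  b <- simulate_batch("G1", p, fx, solver = fast_solver())
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("terminal state is stable under tolerance refinement", {
  loose <- fast_solver()
  tight <- solver_options(rtol = 1e-9, atol = loose$atol / 10, dt = 0.5)
  for (nm in paste0("G", 1:5)) {
    a <- simulate_batch(nm, p, fx, solver = loose)
    b <- simulate_batch(nm, p, fx, solver = tight)
    fa <- unlist(a[nrow(a), c("glucose_gL", "biomass_gL", "SA_gL", "AA_gL", "FA_gL")])
    fb <- unlist(b[nrow(b), c("glucose_gL", "biomass_gL", "SA_gL", "AA_gL", "FA_gL")])
    expect_equal(fa, fb, tolerance = 1e-3)
  }
})

test_that("explicit output times are honoured", {
  tr <- simulate_batch("G1", p, fx, times = c(0, 5, 17.5, 60))
  expect_equal(tr$time_h, c(0, 5, 17.5, 60))
})

test_that("the glucose sweep records maxima and propagates failures", {
  sw <- sweep_initial_glucose(c(0, 10), X0 = 1e-3, params = p, fixed = fx,
                              t_end = 30, dt = 1)
  expect_s3_class(sw, "succ_sweep")
  expect_equal(nrow(sw), 2)
  expect_equal(sw$max_biomass_gL[1], 1e-3 * fx[["MW_X"]], tolerance = 1e-9)
  expect_equal(sw$final_SA_gL[1], 0)
  expect_gt(sw$final_SA_gL[2], 0)
  expect_error(sweep_initial_glucose(numeric(0)))
  expect_error(sweep_initial_glucose(c(-5)))
})
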