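p <- calibrated_params()
fx <- fixed_params()

test_that("uptake up-regulation curve has the right floor, midpoint and limits", {
  # saturates at 1 - a1 for large G
  expect_equal(rc_v1(10, p, fx), 1 - p[["a1"]], tolerance = 1e-12)
  # logistic midpoint
  expect_equal(rc_v1(p[["G_mid1"]] / fx[["MW_G"]], p, fx), 1 - p[["a1"]] / 2)
  # value at G = 0, pinned by direct evaluation of the logistic
  expect_equal(rc_v1(0, p, fx),
               1 - 0.88 / (1 + exp(53.39 * 51.49 / 180.16)),
               tolerance = 1e-12)
  expect_gt(rc_v1(0, p, fx), 0.9999997)
})

test_that("uptake ratio curve hits its midpoint and limits in both readings", {
  X <- 1.05e-3
  # midpoint: availability index at exp(R_mid) gives a2 + (1-a2)/2 = 0.59
  G_mid <- exp(p[["R_mid"]]) * X * fx[["MW_X"]]
  expect_equal(rc_v2(G_mid, X, p, fx), p[["a2"]] + (1 - p[["a2"]]) / 2)
  # default orientation: abundant glucose throttles, scarce glucose frees
  expect_equal(rc_v2(0, X, p, fx), 1)
  expect_equal(rc_v2(100, X, p, fx), p[["a2"]], tolerance = 1e-9)
  # direct scalar evaluation at the G1 starting state
  expect_equal(rc_v2(0.03, X, p, fx),
               0.18 + 0.82 / (1 + exp(10.13 * (log(0.03 / (X * 24.55)) - 1.2))),
               tolerance = 1e-12)
  # printed orientation rises with the molar ratio and tends to a2 at G -> 0
  oa <- model_options(uptake_regulation = "as_printed")
  expect_equal(rc_v2(exp(p[["R_mid"]]) * X, X, p, fx, oa),
               p[["a2"]] + (1 - p[["a2"]]) / 2)
  expect_equal(rc_v2(0, X, p, fx, oa), p[["a2"]])
  expect_equal(rc_v2(1e-9, X, p, fx, oa), p[["a2"]], tolerance = 1e-6)
  expect_error(rc_v2(0.03, 0, p, fx), class = "succ_state_error")
})

test_that("energy response curve is a logistic in ATP per gram of biomass", {
  X <- 2e-3
  atp_mid <- p[["ATP_mid"]] * X * fx[["MW_X"]]
  expect_equal(rc_atp(atp_mid, X, p, fx), 0.5)
  # the initial condition puts the index at s_ATP/2 = 0.5
  en <- initial_energy(X, fx)
  expect_equal(rc_atp(en[["ATP"]], X, p, fx),
               1 / (1 + exp(-22.06 * (0.5 - 0.36))), tolerance = 1e-12)
  expect_equal(rc_atp(en[["ATP"]], X, p, fx), 0.95639, tolerance = 1e-4)
  expect_equal(rc_atp(0, X, p, fx), 1 / (1 + exp(22.06 * 0.36)),
               tolerance = 1e-12)
  expect_error(rc_atp(0.1, -1, p, fx), class = "succ_state_error")
})

test_that("ADP curve is the exact complement of the ATP curve", {
  set.seed(11)
  for (i in 1:1000) {
    X <- runif(1, 1e-5, 0.1)
    ATP <- runif(1, 0, 2 * X * fx[["MW_X"]])
    expect_identical(rc_adp(ATP, X, p, fx), 1 - rc_atp(ATP, X, p, fx))
  }
})

test_that("growth nutrient curve midpoint and starvation limit", {
  expect_equal(rc_g(p[["G_mid2"]] / fx[["MW_G"]], p, fx), 0.5)
  expect_equal(rc_g(0, p, fx), 1 / (1 + exp(410 * 2.02 / 180.16)),
               tolerance = 1e-12)
  expect_equal(rc_g(0, p, fx), 0.0100, tolerance = 1e-2)
  expect_equal(rc_g(0.03, p, fx), 0.99955, tolerance = 1e-4)
})

test_that("acid extrusion curve: shared form instantiated per acid", {
  expect_equal(rc_acid(p[["SA_mid"]] / fx[["MW_SA"]], p[["k5"]], p[["SA_mid"]],
                       fx[["MW_SA"]]), 0.5)
  expect_equal(rc_acid(p[["AA_mid"]] / fx[["MW_AA"]], p[["k6"]], p[["AA_mid"]],
                       fx[["MW_AA"]]), 0.5)
  expect_equal(rc_acid(0, p[["k5"]], p[["SA_mid"]], fx[["MW_SA"]]),
               1 / (1 + exp(13.84 * 23.05 / 118.09)), tolerance = 1e-12)
  expect_equal(rc_acid(0, p[["k5"]], p[["SA_mid"]], fx[["MW_SA"]]), 0.0631,
               tolerance = 1e-2)
})

test_that("curves are monotone and bounded on random grids", {
  set.seed(7)
  G <- sort(runif(50, 0, 0.6))
  v1 <- rc_v1(G, p, fx)
  expect_true(all(diff(v1) <= 1e-15))
  expect_true(all(v1 >= 1 - p[["a1"]] - 1e-12 & v1 <= 1))

  X <- 1.3e-3
  v2 <- rc_v2(G, X, p, fx)
  expect_true(all(diff(v2) <= 1e-15))   # default: non-increasing in G
  expect_true(all(v2 >= p[["a2"]] - 1e-12 & v2 <= 1))
  v2p <- rc_v2(G[G > 0], X, p, fx, model_options(uptake_regulation = "as_printed"))
  expect_true(all(diff(v2p) >= -1e-15))

  ATP <- sort(runif(50, 0, 0.1))
  va <- rc_atp(ATP, X, p, fx)
  expect_true(all(diff(va) >= 0))
  expect_true(all(va >= 0 & va <= 1))

  vg <- rc_g(G, p, fx)
  expect_true(all(diff(vg) >= 0) && all(vg >= 0 & vg <= 1))

  SA <- sort(runif(50, 0, 0.4))
  vs <- rc_acid(SA, p[["k5"]], p[["SA_mid"]], fx[["MW_SA"]])
  expect_true(all(diff(vs) >= 0) && all(vs >= 0 & vs <= 1))
})

test_that("extreme arguments saturate instead of overflowing", {
  expect_equal(rc_v1(1e6, p, fx), 1 - p[["a1"]])
  expect_equal(rc_g(1e6, p, fx), 1)
  expect_equal(rc_acid(1e6, p[["k5"]], p[["SA_mid"]], fx[["MW_SA"]]), 1)
  expect_equal(rc_atp(1e9, 1e-3, p, fx), 1)
  expect_false(any(is.nan(c(rc_v1(1e300, p, fx), rc_v2(1e300, 1e-3, p, fx)))))
})
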