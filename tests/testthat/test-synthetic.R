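p <- calibrated_params()
fx <- fixed_params()

test_that("the default sampling schedule mirrors the batch protocol", {
  g1 <- default_sampling("G1")
  expect_length(g1, 22)          # 13 two-hourly + 9 four-hourly points
  expect_true(all(diff(g1) > 0))
  expect_lte(max(g1), 60)
  short <- default_sampling(experiment_config("s", G0 = 0.1, X0 = 1e-3,
                                              t_end = 24))
  expect_length(short, 13)
  g2 <- default_sampling("G2")
  expect_lte(max(g2), 100)
  expect_equal(g2[1:3], c(0, 2, 4))
})

test_that("noise-free generation reproduces the simulation exactly", {
  times <- c(0, 6, 12, 30)
  obs <- generate_dataset(p, fx, configs = list("G1"),
                          sampling = list(G1 = times),
                          noise = noise_model(cv = 0))
  tr <- simulate_batch("G1", p, fx, times = times)
  expect_equal(obs$glucose_gL, tr$glucose_gL)
  expect_equal(obs$SA_gL, tr$SA_gL)
  expect_equal(obs$time_h, times)
})

test_that("generation is reproducible under a fixed seed", {
  a <- generate_dataset(p, fx, configs = list("G1"),
                        noise = noise_model(cv = 0.05, seed = 123))
  b <- generate_dataset(p, fx, configs = list("G1"),
                        noise = noise_model(cv = 0.05, seed = 123))
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- generate_dataset(p, fx, configs = list("G1"),
                         noise = noise_model(cv = 0.05, seed = 124))
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
})

test_that("generation does not disturb the global RNG stream", {
  set.seed(77); before <- rnorm(1)
  set.seed(77)
  invisible(generate_dataset(p, fx, configs = list("G1"),
                             noise = noise_model(cv = 0.05, seed = 1)))
  expect_identical(rnorm(1), before)
})

test_that("relative noise averages out within the standard-error bound", {
  times <- seq(4, 80, length.out = 20)
  cv <- 0.05
  obs <- generate_dataset(p, fx, configs = list("G2"),
                          sampling = list(G2 = times),
                          noise = noise_model(cv = cv, seed = 2024))
  tr <- simulate_batch("G2", p, fx, times = times)
  tr <- tr[match(times, tr$time_h), ]
  for (v in c("glucose_gL", "biomass_gL", "SA_gL")) {
    rel <- obs[[v]] / tr[[v]] - 1
    expect_lt(abs(mean(rel)), 3 * cv / sqrt(length(times)))
  }
})

test_that("negative draws are clipped to the detection floor", {
  times <- seq(0, 40, 4)
  obs <- generate_dataset(p, fx, configs = list("G1"),
                          sampling = list(G1 = times),
                          noise = noise_model(cv = 5, floor = 0.01, seed = 3))
  vals <- unlist(obs[, c("glucose_gL", "biomass_gL", "SA_gL", "AA_gL", "FA_gL")])
  expect_true(all(vals >= 0))
  expect_true(any(vals == 0.01))
  expect_error(generate_dataset(p, fx, configs = list("G1"),
                                sampling = list(G1 = c(0, 999))),
               class = "succ_config_error")
})

test_that("calibration started at truth stays at truth on noise-free data", {
  obs <- generate_dataset(p, fx, configs = list("G1"),
                          sampling = list(G1 = seq(0, 60, 12)),
                          noise = noise_model(cv = 0))
  fit <- calibrate_params(p, obs, free = c("v_G", "v_P1"), fixed = fx,
                          control = list(maxit = 30))
  expect_lt(fit$sse, 1e-8)
  expect_equal(as.numeric(fit$params[c("v_G", "v_P1")]),
               as.numeric(p[c("v_G", "v_P1")]), tolerance = 0.02)
})
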