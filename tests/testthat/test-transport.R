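# Transport engine: determinism, linearity, closed-form physics checks and
# estimator consistency.

test_that("same seed and config give bit-identical tallies", {
  app <- test_applicator(); det <- test_detector()
  cfg <- engine_config(n_histories = 2e5, seed = 12)
  t1 <- simulate_dose(rep(1, 35), build_phantom("spherical", 0), app, det, cfg)
  t2 <- simulate_dose(rep(1, 35), build_phantom("spherical", 0), app, det, cfg)
  expect_identical(t1$dose_per_history, t2$dose_per_history)
  expect_identical(t1$rse, t2$rse)
})

test_that("tally is exactly linear in dwell weights", {
  app <- test_applicator(); det <- test_detector()
  cfg <- engine_config(n_histories = 2e5, seed = 13)
  w <- numeric(35); w[17] <- 1
  t1 <- simulate_dose(w, build_phantom("spherical", 0), app, det, cfg)
  t2 <- simulate_dose(2 * w, build_phantom("spherical", 0), app, det, cfg)
  expect_equal(t2$dose_per_history, 2 * t1$dose_per_history, tolerance = 1e-14)
  # and under post-hoc reweighting of the same run
  t3 <- reweight_tally(t1, 2 * w)
  expect_equal(t3$dose_per_history, 2 * t1$dose_per_history, tolerance = 1e-14)
  expect_equal(t3$rse, t1$rse, tolerance = 1e-12)
})

test_that("an all-zero plan yields a zero tally with zero error", {
  app <- test_applicator(); det <- test_detector()
  t0 <- simulate_dose(rep(0, 35), build_phantom("spherical", 0), app, det,
                      engine_config(n_histories = 1e4, seed = 1))
  expect_equal(t0$dose_per_history, 0)
  expect_equal(t0$rse, 0)
})

test_that("a detector outside the world is rejected", {
  app <- test_applicator()
  expect_error(
    simulate_dose(rep(1, 35), build_phantom("spherical", 0), app,
                  list(center = c(0, 60, 0), radius = 0.17),
                  engine_config(n_histories = 1e4)),
    "world")
})

test_that("fluence follows the inverse-square law in vacuum", {
  ps <- point_source_tally(0.3, 6e5, seed = 3, medium = "vacuum",
                           detectors = list(list(center = c(0, 5, 0), radius = 0.5),
                                            list(center = c(0, -10, 0), radius = 0.5)))
  ratio <- ps$tally$track_length[1] / ps$tally$track_length[2]
  sigma <- 4 * sqrt(sum(ps$tally$track_rse^2))
  expect_lt(abs(ratio - 4), 3 * sigma)
})

test_that("narrow-beam attenuation matches exp(-mu t)", {
  pp <- point_source_tally(0.3, 2e5, seed = 4, medium = "water", mode = "pencil")
  d1 <- pp$first_collision_cm
  mu <- mu_over_rho("water", 0.3, "total_no_coherent") # water density 1
  for (t in c(2, 5, 10)) {
    frac <- mean(d1 > t)
    expected <- exp(-mu * t)
    se <- sqrt(expected * (1 - expected) / length(d1))
    expect_lt(abs(frac - expected), 3 * se)
  }
})

test_that("track-length and collision estimators agree", {
  app <- test_applicator(); det <- test_detector()
  cfg <- engine_config(n_histories = 4e6, seed = 15)
  tl <- simulate_dose(rep(1, 35), build_phantom("spherical", 5), app, det, cfg)
  co <- balloonbrachy:::tally_with_estimator(tl, "collision")
  sigma <- sqrt((tl$dose_per_history * tl$rse)^2 +
                  (co$dose_per_history * co$rse)^2)
  expect_lt(abs(tl$dose_per_history - co$dose_per_history), 3 * sigma)
})

test_that("estimated error scales as 1/sqrt(n) over a 100x range", {
  app <- test_applicator(); det <- test_detector()
  ph <- build_phantom("spherical", 0)
  ns <- c(4e4, 4e5, 4e6)
  rses <- vapply(ns, function(n) {
    simulate_dose(rep(1, 35), ph, app, det,
                  engine_config(n_histories = n, seed = 16))$rse
  }, 0)
  slope <- coef(lm(log(rses) ~ log(ns)))[2]
  expect_lt(abs(slope + 0.5), 0.05)
})

test_that("symmetric-plan tally is invariant under 90-degree rotation", {
  app <- test_applicator()
  dets <- lapply(c("A", "B", "C", "D"), build_detector, applicator = app)
  tal <- simulate_dose(rep(1, 35), build_phantom("spherical", 0), app, dets,
                       engine_config(n_histories = 4e6, seed = 17))
  d <- tal$dose_per_history
  s <- d * tal$rse
  for (i in 1:3) for (j in (i + 1):4) {
    expect_lt(abs(d[i] - d[j]), 3 * sqrt(s[i]^2 + s[j]^2))
  }
})

test_that("full scatter gives at least the finite-depth dose", {
  app <- test_applicator(); det <- test_detector()
  cfg <- engine_config(n_histories = 2e6, seed = 18)
  ful <- run_full_scatter_reference(rep(1, 35), app, det, cfg)
  fin <- simulate_dose(rep(1, 35), build_phantom("spherical", 0), app, det, cfg)
  sigma <- sqrt((ful$dose_per_history * ful$rse)^2 +
                  (fin$dose_per_history * fin$rse)^2)
  expect_gt(ful$dose_per_history - fin$dose_per_history, -3 * sigma)
  # definitional: a tally against itself gives DMF exactly 1
  expect_equal(compute_dmf(ful, ful)$dmf, 1)
})

test_that("30 cm of margin is effectively full scatter", {
  app <- test_applicator(); det <- test_detector()
  cfg <- engine_config(n_histories = 6e6, seed = 19)
  m30 <- run_full_scatter_reference(rep(1, 35), app, det, cfg, margin = 30)
  ph40 <- build_phantom("spherical", 30)
  ph40$sphere_r <- 43.2 # same protocol, 40 cm margin
  m40 <- simulate_dose(rep(1, 35), ph40, app, det, cfg)
  rel <- abs(m40$dose_per_history / m30$dose_per_history - 1)
  sigma <- sqrt(m30$rse^2 + m40$rse^2)
  expect_lt(rel, 0.002 + 3 * sigma)
})

test_that("coherent-scattering toggle moves the tally less than 3 sigma", {
  app <- test_applicator(); det <- test_detector()
  on <- simulate_dose(rep(1, 35), build_phantom("spherical", 2), app, det,
                      engine_config(n_histories = 1e6, seed = 20, coherent = TRUE))
  off <- simulate_dose(rep(1, 35), build_phantom("spherical", 2), app, det,
                       engine_config(n_histories = 1e6, seed = 20))
  sigma <- sqrt((on$dose_per_history * on$rse)^2 +
                  (off$dose_per_history * off$rse)^2)
  expect_lt(abs(on$dose_per_history - off$dose_per_history), 3 * sigma)
})
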