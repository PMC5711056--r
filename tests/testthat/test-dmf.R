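# Dose modification factor analysis.

test_that("DMF of identical tallies is exactly 1", {
  app <- test_applicator(); det <- test_detector()
  tal <- simulate_dose(rep(1, 35), build_phantom("spherical", 0), app, det,
                       engine_config(n_histories = 1e5, seed = 41))
  p <- compute_dmf(tal, tal)
  expect_identical(p$dmf, 1)
  expect_identical(p$underdose_percent, 0)
  expect_equal(p$tissue_depth_cm, 0)
})

test_that("a zero finite-phantom dose is rejected", {
  app <- test_applicator(); det <- test_detector()
  z <- simulate_dose(rep(0, 35), build_phantom("spherical", 0), app, det,
                     engine_config(n_histories = 1e4, seed = 1))
  t1 <- simulate_dose(rep(1, 35), build_phantom("spherical", 0), app, det,
                      engine_config(n_histories = 1e5, seed = 1))
  expect_error(compute_dmf(z, t1), "zero")
})

test_that("DMF is invariant under global plan rescaling", {
  app <- test_applicator(); det <- test_detector()
  cfg <- engine_config(n_histories = 2e5, seed = 42)
  fin <- simulate_dose(rep(1, 35), build_phantom("spherical", 0), app, det, cfg)
  ful <- run_full_scatter_reference(rep(1, 35), app, det, cfg)
  d1 <- compute_dmf(fin, ful)$dmf
  d2 <- compute_dmf(reweight_tally(fin, rep(4, 35)),
                    reweight_tally(ful, rep(4, 35)))$dmf
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("DMF curves decrease with depth and sphere exceeds cuboid", {
  app <- test_applicator(); det <- test_detector()
  ref <- select_detector(study_reference(), 1)
  sph0 <- select_detector(study_sphere_d0(), 1)
  cub0 <- study_cuboid_d0()
  cfg <- function(n, s = 43) engine_config(n_histories = n, seed = s)
  sph10 <- simulate_dose(rep(1, 35), build_phantom("spherical", 10), app, det,
                         cfg(8e6))
  cub10 <- simulate_dose(rep(1, 35), build_phantom("cuboid", 10), app, det,
                         cfg(6e6))
  dmf <- function(fin) compute_dmf(fin, ref)
  rows_s <- dplyr::bind_rows(dmf(sph0), dmf(sph10))
  rows_c <- dplyr::bind_rows(dmf(cub0), dmf(cub10))
  # dmf >= 1 - 3 rse everywhere (backscatter only adds dose)
  expect_true(all(rows_s$dmf >= 1 - 3 * rows_s$rse))
  expect_true(all(rows_c$dmf >= 1 - 3 * rows_c$rse))
  # both curves share the reference run, so the depth-0 vs depth-10
  # difference cancels its noise; sigma uses the finite-run errors
  pair_sigma <- function(rows) {
    fin_rse <- sqrt(pmax(rows$rse^2 - ref$rse[1]^2, 0))
    sqrt(sum((rows$dmf * fin_rse)^2) + (diff(rows$dmf) * ref$rse[1])^2)
  }
  # the worst-case (spherical) curve decreases strictly from no backscatter
  # to 10 cm, beyond 3 sigma; the milder cuboid curve is monotone
  # non-increasing within 3 sigma
  expect_gt(rows_s$dmf[1] - rows_s$dmf[2], 3 * pair_sigma(rows_s))
  expect_gt(rows_c$dmf[1] - rows_c$dmf[2], -3 * pair_sigma(rows_c))
  # underdose strictly positive at depth 0 for both phantom shapes
  expect_gt(rows_s$underdose_percent[1], 300 * rows_s$rse[1])
  expect_gt(rows_c$underdose_percent[1], 300 * rows_c$rse[1])
  # spherical curve sits at or above the cuboid curve at every common depth
  sig <- sqrt((rows_s$dmf * rows_s$rse)^2 + (rows_c$dmf * rows_c$rse)^2)
  expect_true(all(rows_s$dmf - rows_c$dmf >= -3 * sig))
})

test_that("dmf_sweep assembles curves and compares them consistently", {
  app <- test_applicator(); det <- test_detector()
  ref <- select_detector(study_reference(), 1)
  cfg <- function(s) engine_config(n_histories = 2e6, seed = s)
  sph <- dmf_sweep(rep(1, 35), "spherical", c(0, 10), app, det, cfg(43),
                   reference = ref)
  expect_s3_class(sph, "dmf_curve")
  expect_equal(sph$tissue_depth_cm, c(0, 10))
  expect_true(all(sph$underdose_percent == 100 * (sph$dmf - 1)))
  cmp <- compare_curves(sph, sph)
  expect_true(all(cmp$per_depth$difference == 0))
  expect_error(compare_curves(sph, sph[-1, ]), "depth")
  # two independent seeds agree within 3 sigma at every depth
  sph2 <- dmf_sweep(rep(1, 35), "spherical", c(0, 10), app, det, cfg(997),
                    reference = ref)
  cmp2 <- compare_curves(sph, sph2)
  expect_true(all(abs(cmp2$per_depth$difference) <= 3 * cmp2$per_depth$sigma))
})

test_that("depth domain is validated", {
  app <- test_applicator(); det <- test_detector()
  expect_error(dmf_sweep(rep(1, 35), "cuboid", c(-1, 2), app, det,
                         engine_config(n_histories = 1e4)), "depths")
})

test_that("a zero-radius wire is a null geometry with exactly zero effect", {
  app <- test_applicator(); det <- test_detector()
  we <- wire_effect(rep(1, 35), "cuboid", 0, app, det,
                    engine_config(n_histories = 2e5, seed = 44),
                    wire_radius = 0)
  expect_identical(we$delta_dmf, 0)
  expect_identical(we$rel_dose_change, 0)
})
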