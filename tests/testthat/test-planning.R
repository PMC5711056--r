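# Symmetric and asymmetric dwell-weight plans, asymmetry and dose-volume
# metrics.

test_that("symmetric plan holds all four cardinal points at prescription", {
  k <- test_kernel(); app <- test_applicator()
  plan <- make_symmetric_plan(app, k, prescription = 340)
  expect_true(all(plan$weights > 0))
  expect_equal(length(unique(plan$weights)), 1)
  d <- point_dose(k, app, plan, reference_points(app))
  expect_equal(mean(d), 340, tolerance = 1e-9)
  expect_true(all(abs(d / 340 - 1) < 0.01))
})

test_that("asymmetric plan zeroes two lumens and holds the other three points", {
  k <- test_kernel(); app <- test_applicator()
  plan <- make_asymmetric_plan(app, k, prescription = 340)
  dw <- app$dwells
  expect_equal(sum(plan$weights > 0), 21)
  expect_true(all(plan$weights[dw$lumen %in% c("central", "A")] == 0))
  # equal weights within each active lumen
  for (lu in c("B", "C", "D")) {
    expect_equal(length(unique(plan$weights[dw$lumen == lu])), 1)
  }
  rp <- reference_points(app)
  d <- point_dose(k, app, plan, rp)
  held <- rp$point != "A"
  expect_true(all(abs(d[held] / 340 - 1) < 0.01))
  # the spared point is strictly below prescription
  expect_lt(d[!held], 340)
})

test_that("asymmetry is invariant under global weight rescaling", {
  k <- test_kernel(); app <- test_applicator()
  plan <- make_asymmetric_plan(app, k)
  rp <- reference_points(app)
  asym <- function(w) {
    d <- point_dose(k, app, w, rp)
    held <- rp$point != "A"
    100 * (mean(d[held]) - d[!held]) / mean(d[held])
  }
  expect_equal(asym(plan$weights), asym(3.7 * plan$weights), tolerance = 1e-12)
})

test_that("rotating the excluded lumen leaves the asymmetry unchanged", {
  k <- test_kernel(); app <- test_applicator()
  rp <- reference_points(app)
  vals <- vapply(c("A", "B", "C", "D"), function(p) {
    plan <- make_asymmetric_plan(app, k, asym_point = p)
    d <- point_dose(k, app, plan, rp)
    held <- rp$point != p
    100 * (mean(d[held]) - d[!held]) / mean(d[held])
  }, 0)
  # the applicator is 4-fold symmetric, so all four exclusions are equivalent
  expect_lt(max(vals) - min(vals), 1e-8)
})

test_that("an infeasible held-point system reports the offending lumen", {
  k <- test_kernel()
  # a synthetic kernel that grows with distance makes far lumens dominate and
  # forces a negative per-lumen scale
  k_bad <- k
  k_bad$K <- outer(k$r^4, rep(1, length(k$theta_deg)))
  expect_error(make_asymmetric_plan(test_applicator(), k_bad), "lumen")
})

test_that("dose-volume counting matches an exhaustive per-voxel oracle", {
  set.seed(31)
  n <- 21
  grid <- structure(list(values = array(runif(n^3, 0, 800), dim = rep(n, 3)),
                         n_axis = n, spacing = 0.25, origin = c(0, 0, 0),
                         prescription = 340, balloon_radius = 2.2),
                    class = "dose_grid")
  ax <- (seq_len(n) - (n + 1) / 2) * 0.25
  for (thr in c(1.0, 1.5, 2.0)) {
    count <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) for (l in seq_len(n)) {
      r2 <- ax[i]^2 + ax[j]^2 + ax[l]^2
      if (grid$values[i, j, l] >= thr * 340 && r2 > 2.2^2) count <- count + 1
    }
    expect_equal(dvh_volume(grid, thr), count * 0.25^3)
  }
  # volume is monotone non-increasing in the threshold
  vols <- vapply(seq(0.5, 2.5, by = 0.25), dvh_volume, 0, grid = grid)
  expect_true(all(diff(vols) <= 0))
  # a uniform grid exactly at prescription has V150 = 0
  grid$values[] <- 340
  expect_equal(dvh_volume(grid, 1.5), 0)
  expect_gt(dvh_volume(grid, 1.0), 0)
})

test_that("plan metrics assemble asymmetry, V150/V200 and the RTOG flags", {
  k <- test_kernel(); app <- test_applicator()
  plan <- make_asymmetric_plan(app, k)
  g <- compute_dose_grid(k, app, plan)
  pm <- plan_metrics(plan, k, app, grid = g)
  expect_s3_class(pm, "plan_metrics")
  expect_gt(pm$asymmetry_percent, 0)
  expect_lte(pm$v200_cc, pm$v150_cc)
  expect_equal(pm$v150_cc, dvh_volume(g, 1.5))
  gl <- glance(pm)
  expect_identical(gl$v150_pass, gl$v150_cc <= 50)
  # symmetric plan: asymmetry vanishes to within interpolation tolerance
  ps <- make_symmetric_plan(app, k)
  d <- point_dose(k, app, ps, reference_points(app))
  asym <- 100 * (mean(d[-1]) - d[1]) / mean(d[-1])
  expect_lt(abs(asym), 1)
})

test_that("plans serialize to CSV + JSON and read back identically", {
  k <- test_kernel(); app <- test_applicator()
  plan <- make_asymmetric_plan(app, k)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".json"))))
  write_plan(plan, path)
  p2 <- read_plan(path)
  expect_equal(p2$weights, plan$weights, tolerance = 1e-12)
  expect_identical(p2$label, plan$label)
  expect_equal(p2$prescription, plan$prescription)
})
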