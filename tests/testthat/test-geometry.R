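# Applicator construction, phantom parameterization and ray tracing.

test_that("applicator has 35 dwells in 5 lumens with the device dimensions", {
  app <- test_applicator()
  dw <- app$dwells
  expect_equal(nrow(dw), 35)
  expect_equal(sort(unique(dw$lumen)), sort(c("central", "A", "B", "C", "D")))
  expect_true(all(table(dw$lumen) == 7))
  expect_true(all(dw$radius == 0.017))
  expect_true(all(dw$half_length == 0.25))
  expect_equal(app$balloon_radius, 2.2)
  # unit axes
  expect_true(all(abs(sqrt(dw$ax^2 + dw$ay^2 + dw$az^2) - 1) < 1e-12))
  # adjacent dwell centres within a lumen are 0.5 cm apart along the path
  expect_true(all(abs(diff(dw$s[dw$lumen == "A"]) - 0.5) < 1e-12))
})

test_that("outer lumens reach exactly the apex offset at the equator", {
  app <- test_applicator()
  eq <- app$dwells |> dplyr::filter(.data$s == 0, .data$lumen != "central")
  expect_equal(sqrt(eq$x^2 + eq$y^2), rep(0.5, 4), tolerance = 1e-9)
  expect_equal(eq$z, rep(0, 4), tolerance = 1e-12)
})

test_that("every dwell cylinder lies entirely inside the balloon", {
  app <- test_applicator()
  dw <- app$dwells
  set.seed(4)
  for (i in seq_len(nrow(dw))) {
    # brute-force point sampling of the cylinder volume and end rims
    u <- runif(400, -1, 1) * dw$half_length[i]
    u <- c(u, rep(c(-1, 1) * dw$half_length[i], 50))
    rr <- dw$radius[i] * sqrt(runif(length(u)))
    ph <- runif(length(u), 0, 2 * pi)
    ax <- c(dw$ax[i], dw$ay[i], dw$az[i])
    e1 <- if (abs(ax[3]) < 0.9) c(-ax[2], ax[1], 0) else c(0, -ax[3], ax[2])
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(ax[2] * e1[3] - ax[3] * e1[2],
            ax[3] * e1[1] - ax[1] * e1[3],
            ax[1] * e1[2] - ax[2] * e1[1])
    pts <- cbind(dw$x[i] + u * ax[1] + rr * cos(ph) * e1[1] + rr * sin(ph) * e2[1],
                 dw$y[i] + u * ax[2] + rr * cos(ph) * e1[2] + rr * sin(ph) * e2[2],
                 dw$z[i] + u * ax[3] + rr * cos(ph) * e1[3] + rr * sin(ph) * e2[3])
    expect_true(all(rowSums(pts^2) < app$balloon_radius^2))
  }
})

test_that("reference points sit at cardinal azimuths 1 cm beyond the surface", {
  rp <- reference_points(test_applicator())
  expect_equal(nrow(rp), 4)
  expect_equal(sqrt(rp$x^2 + rp$y^2 + rp$z^2), rep(3.2, 4))
  expect_equal(sum(rp$asymmetry_point), 1)
  # pairwise angles are multiples of 90 degrees
  v <- as.matrix(rp[, c("x", "y", "z")]) / 3.2
  g <- round(v %*% t(v), 10)
  expect_true(all(g[upper.tri(g)] %in% c(0, -1)))
})

test_that("phantom extents follow the tissue depth", {
  p0 <- build_phantom("cuboid", 0)
  expect_equal(p0$box_hi[2] - p0$box_lo[2], 23.2)
  expect_equal(p0$box_hi[2], 3.2)
  p10 <- build_phantom("spherical", 10)
  expect_equal(p10$sphere_r, 13.2)
  expect_equal(full_scatter_phantom()$sphere_r, 33.2)
  expect_error(build_phantom("spherical", -1), "tissue_depth")
  expect_error(build_applicator(balloon_radius = 1.5), "balloon_radius")
})

test_that("trace returns the exact chord from a sphere centre", {
  ph <- build_phantom("spherical", 0)
  for (d in list(c(1, 0, 0), c(0, 1, 0), c(0.36, -0.48, 0.8))) {
    tr <- trace_ray(c(0, 0, 0), d, ph)
    expect_equal(tr$distance, 3.2, tolerance = 1e-9)
    expect_equal(tr$material, "air")
  }
})

test_that("rays outside the world terminate", {
  ph <- build_phantom("cuboid", 0)
  tr <- trace_ray(c(60, 0, 0), c(1, 0, 0), ph)
  expect_true(is.na(tr$distance))
  expect_error(trace_ray(c(0, 0, 0), c(0, 0, 0), ph), "direction")
})

test_that("analytic tracing agrees with a fine-step marching oracle", {
  app <- test_applicator()
  ph <- build_phantom("cuboid", 2)
  set.seed(7)
  n_ok <- 0
  for (k in 1:100) {
    pos <- runif(3, -4, 4)
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    a <- trace_ray(pos, d, ph, app, wire = TRUE, source_attenuation = TRUE)
    b <- balloonbrachy:::trace_ray_march(pos, d, ph, app, wire = TRUE,
                         source_attenuation = TRUE, step = 1e-4)
    expect_lt(abs(a$distance - b$distance), 1e-4)
    expect_identical(a$material, b$material)
    n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 100)
})

test_that("traced segments partition the chord through the world", {
  app <- test_applicator()
  ph <- build_phantom("spherical", 4)
  set.seed(8)
  for (k in 1:40) {
    pos <- runif(3, -3, 3)
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    # independent world-exit distance by the slab formula
    t_exit <- min(((50 * sign(d) - pos) / d)[d != 0])
    # walk the analytic trace to the world boundary
    tot <- 0; p <- pos; guard <- 0
    repeat {
      tr <- trace_ray(p, d, ph, app, wire = TRUE, source_attenuation = TRUE)
      if (is.na(tr$distance) || tr$material == "outside") {
        tot <- tot + if (is.na(tr$distance)) 0 else tr$distance
        break
      }
      tot <- tot + tr$distance + 1e-9
      p <- p + (tr$distance + 1e-9) * d
      guard <- guard + 1
      expect_lt(guard, 200)
    }
    expect_equal(tot, t_exit, tolerance = 1e-3)
  }
})
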