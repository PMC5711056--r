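# Shared, lazily-built fixtures. Kernels and full-scatter reference tallies
# are the expensive objects in the suite, so they are derived once and
# reused; every seed is fixed so the whole suite is deterministic.

fx <- new.env(parent = emptyenv())

test_applicator <- function() {
  if (is.null(fx$app)) fx$app <- build_applicator()
  fx$app
}

test_detector <- function() build_detector(test_applicator())

# desk-scale kernel for unit tests (2e6 histories)
test_kernel <- function() {
  if (is.null(fx$kernel)) {
    fx$kernel <- derive_kernel(engine_config(n_histories = 2e6, seed = 91))
  }
  fx$kernel
}

# study-scale kernel for the planning / dose-volume checks
study_kernel <- function() {
  if (is.null(fx$kernel_big)) {
    fx$kernel_big <- derive_kernel(engine_config(n_histories = 1.6e7, seed = 7))
  }
  fx$kernel_big
}

# study-scale full-scatter reference tally over all four cardinal detectors
# (unit dwell weights; per-dwell sub-tallies are reweighted per plan, and the
# fully symmetric configuration allows detector averaging)
study_reference <- function() {
  if (is.null(fx$ref)) {
    dets <- lapply(c("A", "B", "C", "D"), build_detector,
                   applicator = test_applicator())
    fx$ref <- run_full_scatter_reference(
      rep(1, 35), test_applicator(), dets,
      engine_config(n_histories = 2.6e7, seed = 310))
  }
  fx$ref
}

# depth-0 tallies at study scale, shared between the reproduction checks and
# the DMF property tests
study_sphere_d0 <- function() {
  if (is.null(fx$sph0)) {
    dets <- lapply(c("A", "B", "C", "D"), build_detector,
                   applicator = test_applicator())
    fx$sph0 <- simulate_dose(rep(1, 35), build_phantom("spherical", 0),
                             test_applicator(), dets,
                             engine_config(n_histories = 3e7, seed = 310))
  }
  fx$sph0
}

study_cuboid_d0 <- function() {
  if (is.null(fx$cub0)) {
    fx$cub0 <- simulate_dose(rep(1, 35), build_phantom("cuboid", 0),
                             test_applicator(), test_detector(),
                             engine_config(n_histories = 3e7, seed = 310))
  }
  fx$cub0
}

# numerical Klein-Nishina differential cross section (oracle, independent of
# the sampler): d sigma / d cos(theta) up to a constant factor
kn_dsigma <- function(mu, E) {
  eps <- 1 / (1 + (E / 0.510998928) * (1 - mu))
  eps^2 * (eps + 1 / eps - 1 + mu^2)
}
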