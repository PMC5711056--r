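# Applicator, phantom, detector and reference-point construction, plus the
# ray-tracing surface used by the transport engine.
#
# Coordinate convention: balloon centre at the origin, applicator axis along
# +z, asymmetry point on +y; lengths in cm; right-handed frame.

lumen_azimuth_deg <- c(A = 90, B = 0, C = 270, D = 180) # A = asymmetry azimuth

# outer-lumen arc in the (rho, z) half-plane: circle pinned to the poles
# (0, -Rb), (0, +Rb) with apex offset `a` at the equator
arc_params <- function(balloon_radius, apex_offset) {
  rho_c <- (apex_offset^2 - balloon_radius^2) / (2 * apex_offset)
  list(rho_c = rho_c, R_arc = apex_offset - rho_c)
}

# position and tangent at signed arc length s from the apex
arc_point <- function(arc, s) {
  th <- s / arc$R_arc
  list(rho = arc$rho_c + arc$R_arc * cos(th),
       z = arc$R_arc * sin(th),
       t_rho = -sin(th), t_z = cos(th))
}

#' Build the multilumen balloon applicator
#'
#' Constructs the balloon applicator model: a spherical balloon with one
#' central lumen along the axis and four outer lumens at cardinal azimuths,
#' each outer lumen a circular arc pinned to the balloon poles with a 0.5 cm
#' offset from the axis at the equator. Each lumen carries 7 source dwell
#' positions at a 0.5 cm step (measured as arc length, centred on the
#' equator), for 35 dwell cylinders of 0.5 cm length and 0.017 cm radius.
#'
#' @param balloon_radius Balloon radius in cm; must lie in [2, 3]. Default
#'   2.2 cm.
#' @param apex_offset Offset of the outer lumens from the axis at the balloon
#'   equator, cm. Default 0.5 cm (the device's maximum central-to-outer lumen
#'   separation).
#' @return An object of class `applicator`: a list with the balloon geometry
#'   and a `dwells` tibble (index, lumen, centre, unit axis, half-length,
#'   radius).
#' @examples
#' app <- build_applicator()
#' nrow(app$dwells)  # 35
#' @export
build_applicator <- function(balloon_radius = 2.2, apex_offset = 0.5) {
  if (!is.finite(balloon_radius) || balloon_radius < 2 || balloon_radius > 3) {
    abort("`balloon_radius` must lie in [2, 3] cm")
  }
  steps <- seq(-1.5, 1.5, by = 0.5)
  arc <- arc_params(balloon_radius, apex_offset)

  central <- tibble(
    lumen = "central", s = steps,
    x = 0, y = 0, z = steps, ax = 0, ay = 0, az = 1)

  outer <- purrr::map_dfr(names(lumen_azimuth_deg), function(lu) {
    phi <- lumen_azimuth_deg[[lu]] * pi / 180
    e <- c(cos(phi), sin(phi))
    pt <- arc_point(arc, steps)
    tibble(lumen = lu, s = steps,
           x = pt$rho * e[1], y = pt$rho * e[2], z = pt$z,
           ax = pt$t_rho * e[1], ay = pt$t_rho * e[2], az = pt$t_z)
  })

  dwells <- bind_rows(central, outer) |>
    mutate(index = dplyr::row_number(), half_length = 0.25, radius = 0.017) |>
    select("index", "lumen", "s", "x", "y", "z", "ax", "ay", "az",
           "half_length", "radius")

  structure(list(balloon_radius = balloon_radius,
                 balloon_center = c(0, 0, 0),
                 axis = c(0, 0, 1),
                 apex_offset = apex_offset,
                 arc = arc,
                 dwells = dwells),
            class = "applicator")
}

#' @export
print.applicator <- function(x, ...) {
  cat(sprintf("<applicator> balloon radius %.2f cm, %d dwells in %d lumens\n",
              x$balloon_radius, nrow(x$dwells), length(unique(x$dwells$lumen))))
  invisible(x)
}

#' Cardinal reference points
#'
#' The four reference points at cardinal azimuths in the central transverse
#' plane, each 1 cm beyond the balloon surface. The point at the `A` lumen
#' azimuth (+y) is flagged as the asymmetry/measurement point.
#'
#' @param applicator An [build_applicator()] object.
#' @return A tibble with columns `point`, `azimuth_deg`, `x`, `y`, `z`,
#'   `asymmetry_point`.
#' @export
reference_points <- function(applicator) {
  r <- applicator$balloon_radius + 1.0
  az <- lumen_azimuth_deg
  tibble(point = names(az),
         azimuth_deg = unname(az),
         x = unname(r * cos(az * pi / 180)),
         y = unname(r * sin(az * pi / 180)),
         z = 0,
         asymmetry_point = names(az) == "A")
}

#' Build a water phantom
#'
#' Constructs the water phantom surrounding the applicator, embedded in a
#' 100 cm cube of air. The cuboid phantom is 40 cm x (23.2 + depth) cm x
#' 40 cm with 20 cm of water behind the balloon centre and
#' (1 + balloon radius + depth) cm in front, so the tissue depth is the water
#' thickness beyond the reference point 1 cm from the balloon surface. The
#' spherical phantom is concentric with the balloon with radius
#' (3.2 + depth) cm.
#'
#' @param kind `"cuboid"` or `"spherical"`.
#' @param tissue_depth Water thickness beyond the reference point, cm, in
#'   [0, 30].
#' @return An object of class `phantom`.
#' @examples
#' build_phantom("cuboid", 0)$box_hi[2]   # 3.2
#' @export
build_phantom <- function(kind = c("cuboid", "spherical"), tissue_depth) {
  kind <- match.arg(kind)
  if (!is.finite(tissue_depth) || tissue_depth < 0 || tissue_depth > 30) {
    abort("`tissue_depth` must lie in [0, 30] cm")
  }
  front <- 3.2 + tissue_depth
  structure(list(kind = kind,
                 tissue_depth = tissue_depth,
                 box_lo = c(-20, -20, -20),
                 box_hi = c(20, front, 20),
                 sphere_r = front,
                 world_half = 50),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  if (x$kind == "cuboid") {
    cat(sprintf("<phantom> cuboid 40 x %.1f x 40 cm (tissue depth %.1f cm)\n",
                x$box_hi[2] - x$box_lo[2], x$tissue_depth))
  } else {
    cat(sprintf("<phantom> sphere r = %.1f cm (tissue depth %.1f cm)\n",
                x$sphere_r, x$tissue_depth))
  }
  invisible(x)
}

#' Full-scatter reference phantom
#'
#' A spherical water phantom providing at least `margin` cm of water beyond
#' the reference point in every direction, used as the homogeneous-medium
#' denominator of the dose modification factor.
#'
#' @param margin Water margin beyond the reference point, cm (default 30,
#'   the conventional full-scatter condition).
#' @return A `phantom` object.
#' @export
full_scatter_phantom <- function(margin = 30) {
  build_phantom("spherical", margin)
}

#' Detector (measurement) volume
#'
#' The spherical measurement volume of radius 0.17 cm centred on one of the
#' four cardinal reference points.
#'
#' @param applicator An applicator object.
#' @param point Which reference point, one of `"A"` (the asymmetry point,
#'   default), `"B"`, `"C"`, `"D"`.
#' @param radius Detector radius, cm (default 0.17).
#' @return A list with `center` (length-3) and `radius`.
#' @export
build_detector <- function(applicator, point = "A", radius = 0.17) {
  rp <- reference_points(applicator)
  row <- rp[rp$point == point, ]
  if (nrow(row) != 1) abort("`point` must be one of A, B, C, D")
  list(center = c(row$x, row$y, row$z), radius = radius)
}

# detectors argument -> matrix (x, y, z, R)
detector_matrix <- function(detector) {
  if (!is.null(detector$center)) detector <- list(detector)
  if (!length(detector)) {
    m <- matrix(numeric(0), nrow = 0, ncol = 4)
    colnames(m) <- c("x", "y", "z", "R")
    return(m)
  }
  m <- do.call(rbind, lapply(detector, function(d) c(d$center, d$radius)))
  colnames(m) <- c("x", "y", "z", "R")
  m
}

# steel source-cable segments along the lumen paths of the given lumens,
# from the lower balloon entry pole up to the bottom of the occupied dwell
# span (the cable trails the source train; it does not overlay the sources,
# which keeps paired wire-on/off runs maximally correlated)
wire_segments <- function(applicator, lumens, wire_radius = 0.045, n_seg = 12) {
  Rb <- applicator$balloon_radius
  arc <- applicator$arc
  s_bot <- -(1.5 + 0.25)
  segs <- list()
  for (lu in lumens) {
    if (lu == "central") {
      segs[[length(segs) + 1]] <- c(0, 0, -Rb, 0, 0, s_bot, wire_radius)
    } else {
      phi <- lumen_azimuth_deg[[lu]] * pi / 180
      e <- c(cos(phi), sin(phi))
      s_pole <- arc$R_arc * asin(Rb / arc$R_arc)
      ss <- seq(-s_pole, s_bot, length.out = n_seg + 1)
      pt <- arc_point(arc, ss)
      px <- pt$rho * e[1]; py <- pt$rho * e[2]; pz <- pt$z
      for (k in seq_len(n_seg)) {
        segs[[length(segs) + 1]] <-
          c(px[k], py[k], pz[k], px[k + 1], py[k + 1], pz[k + 1], wire_radius)
      }
    }
  }
  m <- do.call(rbind, segs)
  colnames(m) <- c("x0", "y0", "z0", "x1", "y1", "z1", "r")
  m
}

# scene list handed to the C++ engine
build_scene <- function(phantom, applicator, detector = NULL,
                        wire = FALSE, wire_lumens = NULL, wire_radius = 0.045,
                        vacuum = FALSE, source_attenuation = FALSE) {
  dw <- applicator$dwells
  wires <- matrix(numeric(0), nrow = 0, ncol = 7)
  if (isTRUE(wire)) {
    if (is.null(wire_lumens)) wire_lumens <- unique(dw$lumen)
    wires <- wire_segments(applicator, wire_lumens, wire_radius)
  }
  det <- if (is.null(detector)) {
    matrix(numeric(0), nrow = 0, ncol = 4)
  } else {
    detector_matrix(detector)
  }
  list(phantom_kind = if (is.null(phantom)) 2L
       else if (phantom$kind == "cuboid") 0L else 1L,
       box_lo = if (is.null(phantom)) c(0, 0, 0) else phantom$box_lo,
       box_hi = if (is.null(phantom)) c(0, 0, 0) else phantom$box_hi,
       sphere_r = if (is.null(phantom)) 0 else phantom$sphere_r,
       world_half = if (is.null(phantom)) 50 else phantom$world_half,
       vacuum = isTRUE(vacuum),
       source_attenuation = isTRUE(source_attenuation),
       wires = wires,
       detectors = det,
       dwell_centers = as.matrix(dw[, c("x", "y", "z")]),
       dwell_axes = as.matrix(dw[, c("ax", "ay", "az")]),
       dwell_half = dw$half_length[1],
       dwell_radius = dw$radius[1])
}

material_names <- c("water", "air", "steel", "outside", "vacuum", "iridium")

#' Trace a ray to the next material boundary
#'
#' Analytic intersection of a ray with the phantom, air-world and (optional)
#' steel-wire surfaces: returns the distance to the nearest boundary crossing
#' ahead and the material entered beyond it.
#'
#' @param position Length-3 numeric, cm.
#' @param direction Length-3 unit vector.
#' @param phantom A [build_phantom()] object.
#' @param applicator An applicator (needed for the wire geometry); may be
#'   omitted when `wire = FALSE`.
#' @param wire Include the steel source-wire geometry?
#' @param wire_radius Wire radius, cm.
#' @param source_attenuation Include the iridium dwell cylinders as
#'   attenuating regions?
#' @return A list with `distance` (cm; `NA` if the ray leaves the world) and
#'   `material` (`"water"`, `"air"`, `"steel"`, `"iridium"` or `"outside"`).
#' @export
trace_ray <- function(position, direction, phantom, applicator = NULL,
                      wire = FALSE, wire_radius = 0.045,
                      source_attenuation = FALSE) {
  n <- sqrt(sum(direction^2))
  if (!is.finite(n) || n < 1e-12) abort("`direction` must be a nonzero vector")
  direction <- direction / n
  if (is.null(applicator)) applicator <- build_applicator()
  scene <- build_scene(phantom, applicator, wire = wire,
                       wire_radius = wire_radius,
                       source_attenuation = source_attenuation)
  res <- trace_ray_cpp(position, direction, scene)
  list(distance = res$distance, material = material_names[res$material + 1L])
}

# brute-force marching oracle over the same scene (membership tests only)
trace_ray_march <- function(position, direction, phantom, applicator = NULL,
                            wire = FALSE, wire_radius = 0.045, step = 1e-4,
                            source_attenuation = FALSE) {
  n <- sqrt(sum(direction^2))
  direction <- direction / n
  if (is.null(applicator)) applicator <- build_applicator()
  scene <- build_scene(phantom, applicator, wire = wire,
                       wire_radius = wire_radius,
                       source_attenuation = source_attenuation)
  res <- trace_march_cpp(position, direction, scene, step)
  list(distance = res$distance, material = material_names[res$material + 1L])
}
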