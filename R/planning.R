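# Dwell-weight treatment plans: symmetric and maximally asymmetric forward
# plans, dose asymmetry, and V150/V200 evaluation against the RTOG 0413
# limits (<= 50 cc and <= 10 cc).

new_plan <- function(weights, active_lumens, prescription, label,
                     normalized = TRUE) {
  structure(list(weights = weights, active_lumens = active_lumens,
                 prescription = prescription, label = label,
                 normalized = normalized),
            class = "balloon_plan")
}

#' @export
print.balloon_plan <- function(x, ...) {
  cat(sprintf("<balloon_plan> %s, %d active dwells, prescription %.0f cGy\n",
              x$label, sum(x$weights > 0), x$prescription))
  invisible(x)
}

#' @export
tidy.balloon_plan <- function(x, ...) {
  app <- build_applicator()
  tibble(index = app$dwells$index, lumen = app$dwells$lumen,
         weight = x$weights)
}

#' Symmetric dwell-weight plan
#'
#' Equal weights on all 35 dwell positions, scaled so the mean dose over the
#' four cardinal reference points equals the prescription. By symmetry the
#' four point doses agree within interpolation tolerance.
#'
#' @param applicator An applicator.
#' @param kernel A dose kernel from [derive_kernel()].
#' @param prescription Prescription dose per fraction, cGy (default 340).
#' @return A `balloon_plan`.
#' @export
make_symmetric_plan <- function(applicator, kernel, prescription = 340) {
  rp <- reference_points(applicator)
  unit <- point_dose(kernel, applicator, rep(1, nrow(applicator$dwells)), rp)
  w <- prescription / mean(unit)
  new_plan(rep(w, nrow(applicator$dwells)),
           active_lumens = unique(applicator$dwells$lumen),
           prescription = prescription, label = "symmetric")
}

#' Maximally asymmetric dwell-weight plan
#'
#' The two-lumen-exclusion construction: the central lumen and the outer
#' lumen at the asymmetry point's azimuth are given zero weight (leaving 21
#' active dwells), weights are equal within each remaining lumen, and the
#' three per-lumen scale factors are solved exactly (a 3 x 3 linear system)
#' so that the three held reference points each receive the prescription.
#' The dose at the fourth (asymmetry) point is thereby reduced as far as
#' this construction allows.
#'
#' @inheritParams make_symmetric_plan
#' @param asym_point Which cardinal point is spared (default `"A"`); the
#'   excluded outer lumen is the one at this azimuth.
#' @return A `balloon_plan`.
#' @export
make_asymmetric_plan <- function(applicator, kernel, prescription = 340,
                                 asym_point = "A") {
  rp <- reference_points(applicator)
  if (!asym_point %in% rp$point) abort("`asym_point` must be one of A, B, C, D")
  held <- rp[rp$point != asym_point, ]
  active <- setdiff(names(lumen_azimuth_deg), asym_point)
  dw <- applicator$dwells
  M <- sapply(active, function(lu) {
    w <- as.numeric(dw$lumen == lu)
    point_dose(kernel, applicator, w, held)
  })
  s <- solve(M, rep(prescription, 3))
  if (any(s <= 0)) {
    abort(sprintf("infeasible plan: non-positive weight for lumen %s",
                  paste(active[s <= 0], collapse = ", ")))
  }
  w <- numeric(nrow(dw))
  for (k in seq_along(active)) w[dw$lumen == active[k]] <- s[k]
  new_plan(w, active_lumens = active, prescription = prescription,
           label = "asymmetric")
}

#' Volume above a dose threshold
#'
#' Counts grid voxels (node-centred, voxel volume = spacing cubed) whose dose
#' is at least `threshold_fraction` times the prescription, excluding the
#' balloon interior by default (the balloon is not tissue), and converts to
#' cm\eqn{^3}.
#'
#' @param grid A [compute_dose_grid()] result.
#' @param threshold_fraction Threshold as a fraction of prescription (1.5
#'   for V150, 2.0 for V200).
#' @param include_balloon Count voxels inside the balloon too? Default
#'   `FALSE`.
#' @return Volume in cm\eqn{^3}.
#' @export
dvh_volume <- function(grid, threshold_fraction, include_balloon = FALSE) {
  thr <- threshold_fraction * grid$prescription
  ax <- grid_axis(grid)
  hot <- grid$values >= thr
  if (!include_balloon) {
    r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
    hot <- hot & (r2 > grid$balloon_radius^2)
  }
  sum(hot) * grid$spacing^3
}

#' Plan quality metrics
#'
#' Doses at the four cardinal reference points, the dose asymmetry
#' (percent difference between the mean of the three held points and the
#' asymmetry point), and V150/V200 from the 3-D dose grid with the RTOG 0413
#' pass flags (V150 <= 50 cc, V200 <= 10 cc).
#'
#' @inheritParams make_symmetric_plan
#' @param plan A normalized `balloon_plan`.
#' @param grid Optional precomputed [compute_dose_grid()] (saves the grid
#'   evaluation).
#' @param asym_point The asymmetry point (default `"A"`).
#' @return An object of class `plan_metrics`.
#' @export
plan_metrics <- function(plan, kernel, applicator, grid = NULL,
                         asym_point = "A") {
  rp <- reference_points(applicator)
  doses <- point_dose(kernel, applicator, plan, rp)
  held <- rp$point != asym_point
  asym <- 100 * (mean(doses[held]) - doses[!held]) / mean(doses[held])
  if (is.null(grid)) grid <- compute_dose_grid(kernel, applicator, plan)
  v150 <- dvh_volume(grid, 1.5)
  v200 <- dvh_volume(grid, 2.0)
  structure(list(point_doses = tibble(point = rp$point, dose_cGy = doses,
                                      held = held),
                 asymmetry_percent = asym,
                 v150_cc = v150, v200_cc = v200,
                 prescription = plan$prescription,
                 plan_label = plan$label),
            class = "plan_metrics")
}

#' @export
print.plan_metrics <- function(x, ...) {
  cat(sprintf("<plan_metrics> %s plan, prescription %.0f cGy\n",
              x$plan_label, x$prescription))
  cat(sprintf("  asymmetry: %.1f%%\n", x$asymmetry_percent))
  cat(sprintf("  V150: %.1f cc (limit 50, %s)  V200: %.1f cc (limit 10, %s)\n",
              x$v150_cc, if (x$v150_cc <= 50) "pass" else "FAIL",
              x$v200_cc, if (x$v200_cc <= 10) "pass" else "FAIL"))
  invisible(x)
}

#' @export
tidy.plan_metrics <- function(x, ...) {
  x$point_doses
}

#' @export
glance.plan_metrics <- function(x, ...) {
  tibble(plan = x$plan_label,
         asymmetry_percent = x$asymmetry_percent,
         v150_cc = x$v150_cc, v200_cc = x$v200_cc,
         v150_pass = x$v150_cc <= 50,
         v200_pass = x$v200_cc <= 10,
         prescription_cGy = x$prescription)
}

#' Serialize a plan as CSV plus JSON sidecar
#'
#' The dwell table goes to `<path>` as CSV (index, lumen, weight); the
#' prescription, label, active lumens and normalization flag go to
#' `<path>.json`.
#'
#' @param plan A `balloon_plan`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_plan <- function(plan, path) {
  utils::write.csv(tidy(plan), path, row.names = FALSE)
  jsonlite::write_json(list(prescription = plan$prescription,
                            label = plan$label,
                            active_lumens = plan$active_lumens,
                            normalized = plan$normalized),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  tab <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_plan(tab$weight, meta$active_lumens, meta$prescription, meta$label,
           normalized = isTRUE(meta$normalized))
}
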