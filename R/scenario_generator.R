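# Deterministic study-manifest generation and execution: the full simulation
# matrix of the backscatter study ({cuboid, spherical} phantoms x tissue
# depths 0-10 cm x {symmetric, asymmetric} plans), full-scatter references,
# and wire on/off variants of the cuboid symmetric sweep.

#' Build the study manifest
#'
#' Generates the complete, deterministic scenario table: 2 phantoms x 11
#' depths (0-10 cm) x 2 plans finite-depth records, one full-scatter
#' reference per plan, wire-on variants of the cuboid symmetric sweep and a
#' wire-on reference. Per-scenario seeds are derived from the master seed;
#' the manifest is a pure function of `(master_seed, scale)`.
#'
#' @param master_seed Integer master seed.
#' @param scale Fraction of the full-study 5e7 histories per scenario to
#'   run, in (0, 1]. The default desk scale 0.02 gives 1e6 histories per
#'   scenario.
#' @return A tibble with class `study_manifest`: columns `id`, `phantom`,
#'   `tissue_depth_cm` (`NA` for full-scatter references), `plan`, `wire`,
#'   `n_histories`, `seed`.
#' @export
build_manifest <- function(master_seed = 1L, scale = 0.02) {
  if (!is.finite(scale) || scale <= 0 || scale > 1) {
    abort("`scale` must lie in (0, 1]")
  }
  finite <- tidyr::expand_grid(phantom = c("cuboid", "spherical"),
                               tissue_depth_cm = 0:10,
                               plan = c("symmetric", "asymmetric"),
                               wire = FALSE)
  refs <- tibble(phantom = "full_scatter", tissue_depth_cm = NA_real_,
                 plan = c("symmetric", "asymmetric"), wire = FALSE)
  wire_on <- tibble(phantom = "cuboid", tissue_depth_cm = as.numeric(0:10),
                    plan = "symmetric", wire = TRUE)
  wire_ref <- tibble(phantom = "full_scatter", tissue_depth_cm = NA_real_,
                     plan = "symmetric", wire = TRUE)
  m <- bind_rows(finite, refs, wire_on, wire_ref) |>
    mutate(id = sprintf("%s_%s_%s%s", .data$phantom,
                        ifelse(is.na(.data$tissue_depth_cm), "ref",
                               sprintf("d%02d", .data$tissue_depth_cm)),
                        .data$plan,
                        ifelse(.data$wire, "_wire", "")),
           n_histories = round(scale * 5e7),
           seed = (as.integer(master_seed) * 10007L +
                     as.integer(dplyr::row_number()) * 97L) %% 2147483647L,
           .before = 1) |>
    select("id", "phantom", "tissue_depth_cm", "plan", "wire",
           "n_histories", "seed")
  stopifnot(!anyDuplicated(m$id))
  class(m) <- c("study_manifest", class(m))
  attr(m, "master_seed") <- as.integer(master_seed)
  attr(m, "scale") <- scale
  m
}

#' Execute a study manifest
#'
#' Runs every (optionally filtered) scenario through the transport engine
#' and assembles the tally and DMF result tables. Finite-depth DMF rows use
#' the manifest's matching full-scatter reference (same plan and wire flag).
#' Failures in individual scenarios are recorded and the run continues.
#'
#' @param manifest A [build_manifest()] tibble.
#' @param applicator An applicator.
#' @param kernel A dose kernel, needed to construct the dwell-weight plans.
#' @param detector Detector (default: asymmetry point of the applicator).
#' @param filter Optional character vector of scenario ids to run.
#' @param out_dir Optional directory; when given, `tallies.csv`, `dmf.csv`
#'   and `run_log.txt` are written there.
#' @return A list with tibbles `tallies` and `dmf`, and `errors` (per-id
#'   messages, empty on success).
#' @export
run_manifest <- function(manifest, applicator, kernel, detector = NULL,
                         filter = NULL, out_dir = NULL) {
  if (is.null(detector)) detector <- build_detector(applicator)
  rows <- if (is.null(filter)) manifest else manifest[manifest$id %in% filter, ]
  plans <- list(symmetric = make_symmetric_plan(applicator, kernel),
                asymmetric = make_asymmetric_plan(applicator, kernel))
  errors <- character(0)
  log <- character(0)
  tallies <- vector("list", nrow(rows))
  for (k in seq_len(nrow(rows))) {
    sc <- rows[k, ]
    res <- tryCatch({
      cfg <- engine_config(n_histories = sc$n_histories, seed = sc$seed,
                           wire = sc$wire)
      phantom <- if (sc$phantom == "full_scatter") full_scatter_phantom()
      else build_phantom(sc$phantom, sc$tissue_depth_cm)
      t0 <- Sys.time()
      tl <- simulate_dose(plans[[sc$plan]], phantom, applicator, detector, cfg)
      log <- c(log, sprintf("%s %s seed=%d n=%g elapsed=%.2fs",
                             format(t0, "%Y-%m-%dT%H:%M:%S"), sc$id, sc$seed,
                             cfg$n_histories,
                             as.numeric(Sys.time() - t0, units = "secs")))
      tl
    }, error = function(e) {
      errors <<- c(errors, setNames(conditionMessage(e), sc$id))
      NULL
    })
    tallies[[k]] <- res
  }
  ok <- !vapply(tallies, is.null, logical(1))
  tally_tbl <- purrr::map2_dfr(tallies[ok], split(rows[ok, ], seq_len(sum(ok))),
    function(tl, sc) {
      tibble(id = sc$id, phantom = sc$phantom,
             tissue_depth_cm = sc$tissue_depth_cm, plan = sc$plan,
             wire = sc$wire, estimator = tl$estimator,
             dose_per_history = tl$dose_per_history[1], rse = tl$rse[1],
             n_histories = tl$n_histories, seed = tl$seed)
    })
  refs <- tally_tbl |> filter(.data$phantom == "full_scatter")
  dmf_tbl <- tally_tbl |>
    filter(.data$phantom != "full_scatter") |>
    inner_join(refs |> select("plan", "wire",
                              ref_dose = "dose_per_history", ref_rse = "rse"),
               by = c("plan", "wire")) |>
    mutate(dmf = .data$ref_dose / .data$dose_per_history,
           rse = sqrt(.data$rse^2 + .data$ref_rse^2),
           underdose_percent = 100 * (.data$dmf - 1)) |>
    select("id", "phantom", "plan", "wire", "tissue_depth_cm", "dmf", "rse",
           "underdose_percent")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_csv(tally_tbl, file.path(out_dir, "tallies.csv"),
                     "per-scenario detector tallies")
    write_result_csv(dmf_tbl, file.path(out_dir, "dmf.csv"),
                     "dose modification factors vs tissue depth")
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  list(tallies = tally_tbl, dmf = dmf_tbl, errors = errors, log = log)
}

#' Write / read a manifest as plain text
#'
#' @param manifest A `study_manifest`.
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) {
  con <- file(path, "w")
  writeLines(c("# study_manifest",
               sprintf("# master_seed: %d", attr(manifest, "master_seed")),
               sprintf("# scale: %g", attr(manifest, "scale"))), con)
  write.table(as.data.frame(manifest), con, row.names = FALSE, quote = FALSE,
              sep = "\t")
  close(con)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  hdr <- readLines(path, n = 4)
  m <- as_tibble(read.delim(path, comment.char = "#"))
  class(m) <- c("study_manifest", class(m))
  attr(m, "master_seed") <-
    as.integer(sub(".*: ", "", grep("master_seed", hdr, value = TRUE)))
  attr(m, "scale") <-
    as.numeric(sub(".*: ", "", grep("scale", hdr, value = TRUE)))
  m
}
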