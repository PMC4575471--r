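# Two-button treatment orchestration: Start D&L, then Start Therapy.

#' Build a run configuration
#'
#' Collects every knob of the two-command treatment sequence. All
#' randomness is seeded from `seed`.
#'
#' @param diameter_cm,n_bifurcations,n_bleeders,length_cm phantom spec.
#' @param n_panels cuff panel count (default matched to the limb size:
#'   4 panels up to 10 cm, 7 panels for the largest limbs).
#' @param seed master seed.
#' @param voxel_size_mm D&L rendering resolution.
#' @param ri_threshold bleeder classification threshold.
#' @param dT_threshold_c dose shut-off threshold (deg C).
#' @param targeting_tol_mm,max_iter closed-loop targeting controls.
#' @param thermometry "TSI" or "RNN".
#' @param minTx,maxTx tile-group size bounds.
#' @param dose_grid_mm,dose_grid_half_mm thermal grid resolution and
#'   half-width around each target.
#' @param out_dir output directory (created on demand); NULL disables
#'   persistence.
#' @return list of class `run_config`.
#' @export
run_config <- function(diameter_cm = 15, n_bifurcations = 3, n_bleeders = 1,
                       length_cm = 8, n_panels = NULL, seed = 1,
                       voxel_size_mm = 0.5,
                       ri_threshold = dbac_requirements()$ri_threshold,
                       dT_threshold_c = 5,
                       targeting_tol_mm = dbac_requirements()$targeting_tol_mm,
                       max_iter = 5, thermometry = "TSI",
                       minTx = 2, maxTx = 6,
                       dose_grid_mm = 1, dose_grid_half_mm = 16,
                       out_dir = NULL) {
  if (is.null(n_panels))
    n_panels <- if (diameter_cm <= 10) 4L else if (diameter_cm <= 18) 5L else 7L
  structure(as.list(environment()), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %g-cm limb, %d panels, seed %d, thermometry %s\n",
              x$diameter_cm, x$n_panels, x$seed, x$thermometry))
  invisible(x)
}

#' Load / save a run configuration as YAML
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Start detection & localization (button 1)
#'
#' Builds the phantom and cuff from the configuration, runs the full D&L
#' chain, logs phase timings, and (if `out_dir` is set) persists the
#' report, phantom and cuff descriptions.
#'
#' @param cfg a [run_config()].
#' @return list with `phantom`, `cuff` and the `dl_report`.
#' @export
start_dl <- function(cfg) {
  phantom <- make_limb_phantom(cfg$diameter_cm, cfg$n_bifurcations,
                               cfg$n_bleeders, seed = cfg$seed,
                               length_cm = cfg$length_cm)
  cuff <- build_cuff(cfg$n_panels, cfg$diameter_cm)
  report <- run_dl(phantom, cuff, seed = cfg$seed,
                   voxel_size_mm = cfg$voxel_size_mm,
                   ri_threshold = cfg$ri_threshold)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_phantom_json(phantom, file.path(cfg$out_dir, "phantom.json"))
    write_cuff_json(cuff, file.path(cfg$out_dir, "cuff.json"))
    write_dl_report_json(report, file.path(cfg$out_dir, "dl_report.json"))
  }
  list(phantom = phantom, cuff = cuff, dl_report = report)
}

#' Start therapy (button 2)
#'
#' For each bleeder in the D&L report, in order: recruit and equalize a
#' tile group, run closed-loop targeting correction, compute the dithered
#' deposition map, and deliver a thermometry-controlled dose. A planning
#' failure on one bleeder is recorded and does not abort the others.
#'
#' @param cfg a [run_config()].
#' @param dl result of [start_dl()] (phantom, cuff, dl_report).
#' @return object of class `run_report`.
#' @export
start_therapy <- function(cfg, dl) {
  report <- dl$dl_report
  if (report$n_bleeders == 0) {
    message("no bleeders detected; nothing to treat")
    return(structure(list(doses = list(), n_treated = 0,
                          pass_matrix = NULL), class = "run_report"))
  }
  tcfg <- if (identical(cfg$thermometry, "RNN"))
    thermometry_config("RNN", estimator = train_estimator(seed = cfg$seed))
  else thermometry_config("TSI")
  req <- dbac_requirements()
  doses <- list()
  for (bi in seq_len(report$n_bleeders)) {
    b <- report$bleeders[[bi]]
    target <- as.numeric(b$target_coordinate)
    entry <- list(bleeder = b, error = NULL)
    res <- tryCatch({
      cands <- available_tiles(dl$cuff, dl$phantom, target)
      plan <- select_tile_group(cands, target, minTx = cfg$minTx,
                                maxTx = cfg$maxTx,
                                tissue = dl$phantom$tissue,
                                depth_cm = point_depth_mm(dl$phantom, target) / 10)
      fix <- correct_targeting(plan, target,
                               initial_offsets = 5, max_iter = cfg$max_iter,
                               tol_mm = cfg$targeting_tol_mm,
                               seed = cfg$seed + 17 * bi)
      grid <- grid_around(target, cfg$dose_grid_half_mm, cfg$dose_grid_mm)
      dep <- deposition_from_plan(plan, dl$phantom, grid)
      rec <- dose_controller(plan, dl$phantom, dep, tcfg,
                             dT_threshold = cfg$dT_threshold_c,
                             seed = cfg$seed + 23 * bi)
      entry$plan <- plan; entry$targeting <- fix; entry$dose <- rec
      entry$pass <- c(
        min_td = rec$pass_min_td,
        targeting = all(vapply(fix, `[[`, TRUE, "converged")),
        t_dose = rec$t_dose_s <= req$t_dose_max_s)
      entry
    }, error = function(e) { entry$error <- conditionMessage(e); entry })
    doses[[bi]] <- res
  }
  out <- structure(list(dl_report = report, doses = doses,
                        n_treated = sum(vapply(doses, function(d)
                          is.null(d$error), TRUE))),
                   class = "run_report")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summarize_run(out),
                         file.path(cfg$out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

summarize_run <- function(run) {
  list(n_bleeders = run$dl_report$n_bleeders,
       n_treated = run$n_treated,
       doses = lapply(run$doses, function(d) {
         if (!is.null(d$error)) return(list(error = d$error))
         list(target = d$bleeder$target_coordinate,
              tiles = vapply(d$plan$tiles, `[[`, 0L, "id"),
              t_dose_s = d$dose$t_dose_s,
              shutoff = d$dose$shutoff_cause,
              dT_eod = as.list(d$dose$dT_eod),
              pass = as.list(d$pass))
       }))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d bleeder(s), %d treated\n",
              if (is.null(x$dl_report)) 0L else x$dl_report$n_bleeders,
              x$n_treated))
  for (d in x$doses) {
    if (!is.null(d$error)) { cat("  FAILED:", d$error, "\n"); next }
    cat(sprintf("  dose: t=%gs (%s) dT_eod min/max %.1f/%.1f C  pass[minTD]=%s\n",
                d$dose$t_dose_s, d$dose$shutoff_cause,
                d$dose$dT_eod[["min"]], d$dose$dT_eod[["max"]],
                d$pass[["min_td"]]))
  }
  invisible(x)
}

#' Run the full two-command sequence unattended
#' @param cfg a [run_config()].
#' @return a `run_report` (with `$dl` attached).
#' @export
run_all <- function(cfg) {
  dl <- start_dl(cfg)
  out <- start_therapy(cfg, dl)
  out$dl <- dl
  out
}
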