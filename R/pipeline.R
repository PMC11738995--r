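# End-to-end pipeline: simulate -> estimate -> scene -> polarity ->
# morphometry, with a JSON report.

#' Validate a pipeline run configuration
#'
#' Checks a (possibly JSON-loaded) configuration list before any stage
#' runs. Units are declared, never inferred: lengths are um, times hours,
#' angles degrees, and a config carrying a different `units` declaration is
#' rejected. A master `seed` is mandatory; per-stage streams are derived
#' from it.
#'
#' @param config A named list with components `seed` (required), and
#'   optionally `cycle` (arguments to [cycle_sim_params()]), `schedule`
#'   ([pulse_schedule()]), `scene` ([scene_params()]), `thresholds`
#'   (`max_dist_um`, `tolerance_um`), `n_bins`, `n_boot`, `units`.
#' @return The validated, default-filled config (class `run_config`).
#' @export
pipeline_config <- function(config) {
  if (!is.list(config)) vk_stop("bad_config", "config must be a named list")
  if (is.null(config$seed))
    vk_stop("bad_config", "config is missing the mandatory `seed`")
  seed <- check_seed(config$seed)
  units <- config$units %||% list(length = "um", time = "h", angle = "deg")
  if (!identical(units[c("length", "time", "angle")],
                 list(length = "um", time = "h", angle = "deg")))
    vk_stop("bad_config",
            "units must be declared as um / h / deg (got: %s)",
            paste(unlist(units), collapse = ", "))
  thr <- config$thresholds %||% list()
  thresholds <- list(
    max_dist_um = check_scalar(thr$max_dist_um %||% 5, "max_dist_um", 0),
    tolerance_um = check_scalar(thr$tolerance_um %||% 0, "tolerance_um", 0))
  cycle <- do.call(cycle_sim_params,
                   c(config$cycle %||% list(), list(seed = seed + 1L)))
  schedule <- do.call(pulse_schedule, as_schedule_args(config$schedule))
  scene <- do.call(scene_params,
                   c(config$scene %||% list(), list(seed = seed + 2L)))
  n_bins <- check_scalar(config$n_bins %||% 24, "n_bins", 1)
  n_boot <- check_scalar(config$n_boot %||% 500, "n_boot", 100)
  structure(list(seed = seed, units = units, cycle = cycle,
                 schedule = schedule, scene = scene, thresholds = thresholds,
                 n_bins = n_bins, n_boot = n_boot),
            class = "run_config")
}

as_schedule_args <- function(x) {
  if (is.null(x)) return(list())
  lapply(x, function(v) as.numeric(unlist(v)))
}

#' Run the full synthetic pipeline and produce a report
#'
#' Executes, under one master seed: (1) the dual-pulse labeling simulation
#' and the cell-cycle estimators with bootstrap confidence intervals; (2)
#' the 3D vessel scene, geometry extraction, nucleus-Golgi pairing, polarity
#' angles and their circular summary; (3) compartment classification of the
#' scene's cells against its vessel mask, compared against ground truth.
#' The report is a plain list (serializable to JSON) stamped with the
#' configuration hash and seed; identical configurations yield identical
#' reports.
#'
#' @param config A list accepted by [pipeline_config()].
#' @param out_json Optional path; when given the report is also written as
#'   JSON.
#' @return The report list (class `pipeline_report`), invisibly when
#'   `out_json` is given.
#' @export
run_pipeline <- function(config, out_json = NULL) {
  cfg <- if (inherits(config, "run_config")) config else pipeline_config(config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      vk_stop("stage_failure", "stage `%s` failed: %s", name,
              conditionMessage(e))
    })
  }

  sim <- stage("simulate_pulse", simulate_pulse_labeling(cfg$cycle,
                                                         cfg$schedule))
  est <- stage("cellcycle", bootstrap_estimates(
    sim$cells, t_i = cfg$schedule$t_i, n_boot = cfg$n_boot,
    seed = cfg$seed + 3L))

  scene <- stage("scene", generate_vessel_scene(cfg$scene))
  nuc_geom <- stage("geometry", extract_geometry(scene$nuclei))
  gol_geom <- stage("geometry", extract_geometry(scene$golgi))
  pairs <- stage("polarity", compute_polarity_angles(
    pair_nuclei_golgi(nuc_geom, gol_geom,
                      max_dist_um = cfg$thresholds$max_dist_um)))
  ang <- stage("polarity", summarize_angles(
    pairs$angle_deg[pairs$included], n_bins = cfg$n_bins,
    n_excluded = sum(pairs$status == "excluded"),
    n_unmatched = sum(pairs$status == "unmatched")))

  scene_cells <- data.frame(cell_id = scene$ground_truth$cell_id,
                            x_um = scene$ground_truth$x_um,
                            y_um = scene$ground_truth$y_um,
                            z_um = scene$ground_truth$z_um)
  scene_cells <- stage("morphometry", classify_compartment(
    scene_cells, scene$vessel,
    tolerance_um = cfg$thresholds$tolerance_um))
  counts <- stage("morphometry", count_population(scene_cells))

  report <- list(
    config_hash = rlang::hash(unclass_deep(cfg)),
    seed = cfg$seed,
    cellcycle = list(
      t_s = est$t_s, t_c = est$t_c, gf = est$gf,
      ci = est$ci, n_boot = est$n_boot, n_failed = est$n_failed,
      counts = unclass(est$counts)[c("p_cells", "s_cells", "l_cells",
                                     "ki67_pos", "t_i")],
      truth = list(t_cycle = cfg$cycle$t_cycle, t_s = cfg$cycle$t_s,
                   growth_fraction = cfg$cycle$growth_fraction)),
    polarity = list(
      n_included = ang$n_included, n_excluded = ang$n_excluded,
      n_unmatched = ang$n_unmatched,
      mean_deg = ang$mean_deg, R = ang$R, rayleigh_p = ang$rayleigh_p,
      bin_edges = ang$bin_edges, counts = ang$counts,
      truth = list(mu_deg = cfg$scene$mu_deg, kappa = cfg$scene$kappa)),
    morphometry = list(
      n_inside = sum(scene_cells$compartment == "inside"),
      n_outside = sum(scene_cells$compartment == "outside"),
      n_unassigned = sum(scene_cells$compartment == "unassigned"),
      agrees_with_truth = mean(scene_cells$compartment ==
                                 scene$ground_truth$compartment),
      truth = list(n_inside = cfg$scene$n_inside,
                   n_outside = cfg$scene$n_outside)))

  report <- structure(report, class = "pipeline_report")
  if (!is.null(out_json)) {
    jsonlite::write_json(unclass_deep(report), out_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}

# Strip S3 classes recursively so hashing/serialization see plain lists.
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}
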