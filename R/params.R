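#' Parameters of the cycling-population simulator
#'
#' Describes an asynchronous population of cells progressing through a cell
#' cycle of total length `t_cycle` hours containing a contiguous S-phase
#' window of length `t_s` hours. A fraction `growth_fraction` of cells is
#' actively cycling (KI67-positive); the remainder never enters S-phase.
#' Cycling cells are assigned a uniformly random cycle position at time zero,
#' which is the steady-state (asynchronous) phase distribution.
#'
#' @param t_cycle Total cell-cycle duration T_C, hours (> 0).
#' @param t_s S-phase duration T_S, hours (> 0 and < `t_cycle`).
#' @param growth_fraction Proportion of cells actively cycling, in `[0, 1]`.
#' @param n_cells Number of cells to simulate.
#' @param s_phase_start Position of the S-phase window within the cycle,
#'   hours in `[0, t_cycle - t_s]`. Under the uniform-phase assumption the
#'   pulse-labeling counts are independent of this value; the default centers
#'   S within the cycle.
#' @param seed Integer seed; all sampling in [simulate_pulse_labeling()] is
#'   reproducible given this seed.
#' @return An object of class `cycle_sim_params`.
#' @seealso [pulse_schedule()], [simulate_pulse_labeling()]
#' @export
cycle_sim_params <- function(t_cycle = 26.6, t_s = 10, growth_fraction = 0.8,
                             n_cells = 50000L,
                             s_phase_start = (t_cycle - t_s) / 2,
                             seed = 1L) {
  t_cycle <- check_scalar(t_cycle, "t_cycle", lower = 0, strict_lower = TRUE)
  t_s <- check_scalar(t_s, "t_s", lower = 0, strict_lower = TRUE)
  if (t_s >= t_cycle)
    vk_stop("bad_param", "t_s (%g h) must be strictly less than t_cycle (%g h)",
            t_s, t_cycle)
  growth_fraction <- check_scalar(growth_fraction, "growth_fraction", 0, 1)
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1 ||
      n_cells != as.integer(n_cells))
    vk_stop("bad_param", "`n_cells` must be a positive integer")
  s_phase_start <- check_scalar(s_phase_start, "s_phase_start",
                                lower = 0, upper = t_cycle - t_s)
  structure(list(t_cycle = t_cycle, t_s = t_s,
                 growth_fraction = growth_fraction,
                 n_cells = as.integer(n_cells),
                 s_phase_start = s_phase_start,
                 seed = check_seed(seed)),
            class = "cycle_sim_params")
}

#' Thymidine-analogue availability schedule of a dual-pulse experiment
#'
#' Encodes when each analogue can be incorporated by cells in S-phase, plus
#' the injection interval `t_i` used by the duration estimators. The default
#' reproduces the protocol of repeated EdU injections keeping EdU available
#' over 0--6 h, a BrdU pulse at 6 h, and harvest at 8 h, with T_i = 6 h.
#'
#' @param edu_window Numeric `[start, end]`, hours, of EdU availability.
#' @param brdu_window Numeric `[start, end]`, hours, of BrdU availability;
#'   its end is the harvest time.
#' @param t_i Injection interval T_i, hours (> 0): the time during which an
#'   initially EdU-labeled cell can leave S-phase before BrdU becomes
#'   available.
#' @return An object of class `pulse_schedule`.
#' @export
pulse_schedule <- function(edu_window = c(0, 6), brdu_window = c(6, 8),
                           t_i = 6) {
  for (w in list(edu = edu_window, brdu = brdu_window)) {
    if (!is.numeric(w) || length(w) != 2L || any(!is.finite(w)) || w[1] >= w[2])
      vk_stop("bad_param", "analogue windows must be non-degenerate [start, end] in hours")
  }
  if (edu_window[1] >= brdu_window[1])
    vk_stop("bad_param", "the EdU window must open before the BrdU window")
  t_i <- check_scalar(t_i, "t_i", lower = 0, strict_lower = TRUE)
  structure(list(edu_window = as.numeric(edu_window),
                 brdu_window = as.numeric(brdu_window), t_i = t_i),
            class = "pulse_schedule")
}

#' Parameters of the synthetic 3D vessel scene
#'
#' Describes a voxel volume containing a straight tubular vessel and a set of
#' nucleus/Golgi sphere pairs. Each Golgi centroid is displaced from its
#' nucleus centroid by `golgi_offset` um in the x-y plane along a direction
#' drawn from a von Mises distribution with mean `mu_deg` and concentration
#' `kappa` (`kappa = 0` gives uniformly random directions). `n_inside` nuclei
#' are placed with their centroid inside the vessel tube and `n_outside`
#' clearly outside it.
#'
#' @param volume_shape Integer voxels per axis, `(z, y, x)` order.
#' @param voxel_spacing um per voxel along `(z, y, x)`; anisotropy is allowed
#'   and respected throughout.
#' @param vessel_axis Axis the tube runs along: `"x"`, `"y"` or `"z"`.
#' @param vessel_radius_um Tube radius, um.
#' @param n_inside,n_outside Numbers of cells inside / outside the vessel.
#' @param golgi_offset Nucleus-to-Golgi centroid distance in the x-y plane, um.
#' @param mu_deg Mean polarity direction, degrees on the body-axis compass.
#' @param kappa von Mises concentration (>= 0).
#' @param nucleus_radius,golgi_radius Sphere radii, um.
#' @param seed Integer seed for placement and angle sampling.
#' @return An object of class `scene_params`.
#' @seealso [generate_vessel_scene()]
#' @export
scene_params <- function(volume_shape = c(50L, 180L, 180L),
                         voxel_spacing = c(2, 0.5, 0.5),
                         vessel_axis = "x",
                         vessel_radius_um = 14,
                         n_inside = 5L, n_outside = 9L,
                         golgi_offset = 6,
                         mu_deg = 90, kappa = 2,
                         nucleus_radius = 3, golgi_radius = 1.5,
                         seed = 1L) {
  if (length(volume_shape) != 3L || any(volume_shape < 4) ||
      any(volume_shape != as.integer(volume_shape)))
    vk_stop("bad_param", "`volume_shape` must be 3 integer voxel counts (z, y, x)")
  if (length(voxel_spacing) != 3L || any(!is.finite(voxel_spacing)) ||
      any(voxel_spacing <= 0))
    vk_stop("bad_param", "`voxel_spacing` must be 3 positive um values (z, y, x)")
  vessel_axis <- match.arg(vessel_axis, c("x", "y", "z"))
  vessel_radius_um <- check_scalar(vessel_radius_um, "vessel_radius_um",
                                   lower = 0, strict_lower = TRUE)
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa < 0)
    vk_stop("bad_param", "`kappa` must be a single number >= 0")
  nucleus_radius <- check_scalar(nucleus_radius, "nucleus_radius",
                                 lower = 0, strict_lower = TRUE)
  golgi_radius <- check_scalar(golgi_radius, "golgi_radius",
                               lower = 0, strict_lower = TRUE)
  golgi_offset <- check_scalar(golgi_offset, "golgi_offset",
                               lower = 0, strict_lower = TRUE)
  if (n_inside < 0 || n_outside < 0 || n_inside + n_outside < 1)
    vk_stop("bad_param", "need at least one cell (n_inside + n_outside >= 1)")
  structure(list(volume_shape = as.integer(volume_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 vessel_axis = vessel_axis,
                 vessel_radius_um = vessel_radius_um,
                 n_inside = as.integer(n_inside),
                 n_outside = as.integer(n_outside),
                 golgi_offset = golgi_offset,
                 mu_deg = check_scalar(mu_deg, "mu_deg"),
                 kappa = kappa,
                 nucleus_radius = nucleus_radius,
                 golgi_radius = golgi_radius,
                 seed = check_seed(seed)),
            class = "scene_params")
}
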