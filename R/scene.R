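# Synthetic 3D vessel scenes: a tubular vessel plus nucleus/Golgi sphere
# pairs with known polarity angles and compartments.

# Rasterize a sphere into `arr` ((z,y,x) array) by marking voxels whose
# center lies within `radius_um` of `center_xyz` (physical um, anisotropic
# spacing respected). Returns the modified array.
rasterize_sphere <- function(arr, center_xyz, radius_um, spacing, value) {
  d <- dim(arr)
  # candidate index range per axis (z, y, x)
  rng <- function(axis_dim, sp, c_um) {
    lo <- max(1L, floor((c_um - radius_um) / sp) + 1L)
    hi <- min(axis_dim, ceiling((c_um + radius_um) / sp))
    if (lo > hi) integer(0) else lo:hi
  }
  iz <- rng(d[1], spacing[1], center_xyz[3])
  iy <- rng(d[2], spacing[2], center_xyz[2])
  ix <- rng(d[3], spacing[3], center_xyz[1])
  if (!length(iz) || !length(iy) || !length(ix)) return(arr)
  dz2 <- ((iz - 0.5) * spacing[1] - center_xyz[3])^2
  dy2 <- ((iy - 0.5) * spacing[2] - center_xyz[2])^2
  dx2 <- ((ix - 0.5) * spacing[3] - center_xyz[1])^2
  d2 <- outer(outer(dz2, dy2, "+"), dx2, "+")
  sub <- arr[iz, iy, ix, drop = FALSE]
  sub[d2 <= radius_um^2] <- value
  arr[iz, iy, ix] <- sub
  arr
}

# Planar distance of (x, y, z) um points from the tube centerline.
tube_planar_dist <- function(xyz, axis, center_xyz) {
  planar <- switch(axis, x = c(2, 3), y = c(1, 3), z = c(1, 2))
  xyz <- matrix(xyz, ncol = 3)
  sqrt((xyz[, planar[1]] - center_xyz[planar[1]])^2 +
       (xyz[, planar[2]] - center_xyz[planar[2]])^2)
}

#' Generate a synthetic 3D vessel scene with polarized nucleus/Golgi pairs
#'
#' Builds a voxelized scene emulating a segmented embryonic vessel and
#' surrounding cells: a straight tube (binary vessel mask), one labeled
#' sphere per nucleus, and one labeled sphere per Golgi, the Golgi centroid
#' displaced from its nucleus centroid by `golgi_offset` um in the x-y plane
#' along a direction drawn from von Mises(`mu_deg`, `kappa`) on the
#' body-axis compass (0 deg = +y "dorsal", 90 deg = +x "lateral").
#' `n_inside` nuclei are centered inside the tube and `n_outside` clearly
#' outside it, with a minimum nucleus separation that guarantees each Golgi
#' is nearer (border-to-border) to its own nucleus than to any other.
#'
#' Matching labels pair nuclei with their Golgi (nucleus label k and Golgi
#' label k belong to the same cell), and the exact sampled angle and
#' compartment of every cell are returned as ground truth.
#'
#' @param params A [scene_params()] object.
#' @return A list of class `vessel_scene`: `nuclei` and `golgi`
#'   ([label_mask()]s), `vessel` (binary [label_mask()]), and `ground_truth`
#'   (data.frame: `cell_id`, `nucleus_label`, `golgi_label`, nucleus centroid
#'   `x_um`/`y_um`/`z_um`, `angle_deg`, `compartment`), plus `params`.
#' @export
generate_vessel_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  d <- params$volume_shape
  sp <- params$voxel_spacing
  ext <- c(x = d[3] * sp[3], y = d[2] * sp[2], z = d[1] * sp[1])
  center <- ext / 2
  axis <- params$vessel_axis
  r_vessel <- params$vessel_radius_um
  n_r <- params$nucleus_radius
  g_r <- params$golgi_radius
  off <- params$golgi_offset
  n_total <- params$n_inside + params$n_outside

  # margins keeping generated centroids classifiable by a voxel lookup
  # despite rasterization (<= half-voxel centroid shift) and voxel-center
  # discretization
  slack <- max(sp) + 0.5
  r_in <- r_vessel - slack
  r_out <- r_vessel + slack
  if (params$n_inside > 0 && r_in <= 0)
    vk_stop("placement_failure",
            "vessel radius (%g um) too small relative to voxel spacing to place inside cells",
            r_vessel)
  # minimum nucleus-centroid separation guaranteeing unambiguous pairing and
  # non-overlapping rasterized objects
  min_sep <- 2 * (off + g_r) + 2

  scene <- with_seed(params$seed, {
    angles <-
      if (is.infinite(params$kappa) || params$kappa >= VM_KAPPA_CAP)
        rep(mod_pos(params$mu_deg, 360), n_total)
      else if (params$kappa == 0) stats::runif(n_total, 0, 360)
      else rvonmises_deg(n_total, params$mu_deg, params$kappa)

    centers <- matrix(NA_real_, n_total, 3,
                      dimnames = list(NULL, c("x", "y", "z")))
    compartment <- rep(c("inside", "outside"),
                       c(params$n_inside, params$n_outside))
    max_tries <- 5000L
    for (i in seq_len(n_total)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- c(stats::runif(1, 0, ext["x"]),
                  stats::runif(1, 0, ext["y"]),
                  stats::runif(1, 0, ext["z"]))
        pd <- tube_planar_dist(cand, axis, center)
        if (compartment[i] == "inside" && pd > r_in) next
        if (compartment[i] == "outside" && pd < r_out) next
        a <- angles[i] * pi / 180
        gol <- cand + c(sin(a), cos(a), 0) * off
        # both spheres must fit in the volume
        if (any(cand < n_r) || any(cand > ext - n_r)) next
        if (any(gol < g_r) || any(gol > ext - g_r)) next
        if (i > 1) {
          prev <- centers[seq_len(i - 1), , drop = FALSE]
          if (min(sqrt(rowSums((prev - rep(cand, each = i - 1))^2))) < min_sep)
            next
        }
        centers[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed)
        vk_stop("placement_failure",
                paste("could not place %s cell %d after %d tries; constraints:",
                      "sphere-in-volume, %s tube radius band, and %g um",
                      "minimum nucleus separation"),
                compartment[i], i, max_tries, compartment[i], min_sep)
    }
    list(angles = angles, centers = centers, compartment = compartment)
  })

  # vessel mask: voxels whose center is within r_vessel of the centerline
  grid_um <- list(z = (seq_len(d[1]) - 0.5) * sp[1],
                  y = (seq_len(d[2]) - 0.5) * sp[2],
                  x = (seq_len(d[3]) - 0.5) * sp[3])
  dz2 <- (grid_um$z - center["z"])^2
  dy2 <- (grid_um$y - center["y"])^2
  dx2 <- (grid_um$x - center["x"])^2
  zero <- function(k) rep(0, d[k])
  planar2 <- switch(axis,
    x = outer(outer(dz2, dy2, "+"), zero(3), "+"),
    y = outer(outer(dz2, zero(2), "+"), dx2, "+"),
    z = outer(outer(zero(1), dy2, "+"), dx2, "+"))
  vessel <- array(as.integer(planar2 <= r_vessel^2), dim = d)

  nuclei <- array(0L, dim = d)
  golgi <- array(0L, dim = d)
  golgi_centers <- scene$centers +
    cbind(sin(scene$angles * pi / 180), cos(scene$angles * pi / 180), 0) * off
  for (i in seq_len(n_total)) {
    nuclei <- rasterize_sphere(nuclei, scene$centers[i, ], n_r, sp, i)
    golgi <- rasterize_sphere(golgi, golgi_centers[i, ], g_r, sp, i)
  }

  gt <- data.frame(cell_id = seq_len(n_total),
                   nucleus_label = seq_len(n_total),
                   golgi_label = seq_len(n_total),
                   x_um = scene$centers[, 1], y_um = scene$centers[, 2],
                   z_um = scene$centers[, 3],
                   angle_deg = scene$angles,
                   compartment = scene$compartment,
                   stringsAsFactors = FALSE)

  structure(list(nuclei = label_mask(nuclei, sp),
                 golgi = label_mask(golgi, sp),
                 vessel = label_mask(vessel, sp),
                 ground_truth = gt, params = params),
            class = "vessel_scene")
}
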