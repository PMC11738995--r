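# LabelMask: a 3D integer array in (z, y, x) axis order carrying per-axis
# voxel spacing in um. Voxel (iz, iy, ix) (1-based) has its physical center
# at ((ix - 0.5) * sx, (iy - 0.5) * sy, (iz - 0.5) * sz) um.

#' Construct a 3D label mask
#'
#' @param voxels 3D integer array, `(z, y, x)` axis order; 0 is background,
#'   positive integers are object labels.
#' @param spacing Numeric length 3: um per voxel along `(z, y, x)`.
#' @return A `label_mask` object (the array with a `spacing` attribute).
#' @export
label_mask <- function(voxels, spacing) {
  if (length(dim(voxels)) != 3L)
    vk_stop("bad_mask", "a label mask must be a 3D array (z, y, x)")
  if (missing(spacing) || is.null(spacing))
    vk_stop("missing_spacing",
            "voxel spacing (um per axis, z,y,x) is required and never guessed")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    vk_stop("bad_param", "`spacing` must be 3 positive um values (z, y, x)")
  if (any(voxels < 0) || any(voxels != round(voxels)))
    vk_stop("bad_mask", "label masks must contain non-negative integers")
  storage.mode(voxels) <- "integer"
  structure(voxels, spacing = as.numeric(spacing),
            class = c("label_mask", class(voxels)))
}

mask_spacing <- function(mask) attr(mask, "spacing")

# Physical (x, y, z) um coordinates of voxel centers given 1-based (z, y, x)
# array indices (a 3-column matrix).
voxel_centers_um <- function(idx_zyx, spacing) {
  cbind(x = (idx_zyx[, 3] - 0.5) * spacing[3],
        y = (idx_zyx[, 2] - 0.5) * spacing[2],
        z = (idx_zyx[, 1] - 0.5) * spacing[1])
}

# 1-based (z, y, x) voxel index containing a physical (x, y, z) um point;
# rows of NA where the point lies outside the volume.
point_to_voxel <- function(xyz_um, dim_zyx, spacing) {
  xyz_um <- matrix(xyz_um, ncol = 3)
  idx <- cbind(floor(xyz_um[, 3] / spacing[1]) + 1,
               floor(xyz_um[, 2] / spacing[2]) + 1,
               floor(xyz_um[, 1] / spacing[3]) + 1)
  bad <- idx[, 1] < 1 | idx[, 1] > dim_zyx[1] |
         idx[, 2] < 1 | idx[, 2] > dim_zyx[2] |
         idx[, 3] < 1 | idx[, 3] > dim_zyx[3]
  idx[bad, ] <- NA_integer_
  storage.mode(idx) <- "integer"
  idx
}

# Logical array marking foreground voxels with at least one background
# 6-neighbor (voxels on the volume edge count as boundary).
boundary_voxels <- function(fg) {
  d <- dim(fg)
  shift_bg <- function(axis, by) {
    # TRUE where the neighbor in direction (axis, by) is background or
    # outside the volume
    out <- array(TRUE, d)
    n <- d[axis]
    src <- 2:n; dst <- 1:(n - 1)
    if (by < 0) { tmp <- src; src <- dst; dst <- tmp }
    idx_dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx_src <- idx_dst
    idx_dst[[axis]] <- dst; idx_src[[axis]] <- src
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      !fg[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  nb_bg <- shift_bg(1, 1) | shift_bg(1, -1) | shift_bg(2, 1) |
    shift_bg(2, -1) | shift_bg(3, 1) | shift_bg(3, -1)
  fg & nb_bg
}

#' Extract per-object geometry from a label mask
#'
#' For every nonzero label, computes the object's centroid (unweighted mean
#' of its voxel centers, physical um) and its boundary voxels (foreground
#' voxels with at least one 6-connected background neighbor or lying on the
#' volume edge), also in physical um.
#'
#' @param mask A [label_mask()].
#' @return A data.frame of class `object_geometry` with one row per label:
#'   `label_id`, centroid `x_um`, `y_um`, `z_um`, `n_voxels`, and a
#'   list-column `boundary_um` of n x 3 matrices of boundary-voxel center
#'   coordinates `(x, y, z)`. An empty mask yields zero rows.
#' @export
extract_geometry <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  spacing <- mask_spacing(mask)
  fg_idx <- which(mask > 0)
  out0 <- data.frame(label_id = integer(0), x_um = numeric(0),
                     y_um = numeric(0), z_um = numeric(0),
                     n_voxels = integer(0))
  out0$boundary_um <- list()
  if (length(fg_idx) == 0L)
    return(structure(out0, class = c("object_geometry", "data.frame")))

  idx <- arrayInd(fg_idx, dim(mask))
  labs <- as.integer(mask[fg_idx])
  centers <- voxel_centers_um(idx, spacing)
  on_boundary <- boundary_voxels(mask > 0L)[fg_idx]

  ord <- order(labs)
  labs <- labs[ord]; centers <- centers[ord, , drop = FALSE]
  on_boundary <- on_boundary[ord]
  uniq <- unique(labs)
  grp <- match(labs, uniq)
  cx <- tapply(centers[, 1], grp, mean)
  cy <- tapply(centers[, 2], grp, mean)
  cz <- tapply(centers[, 3], grp, mean)
  nv <- tabulate(grp)
  boundary <- lapply(seq_along(uniq), function(g) {
    b <- centers[grp == g & on_boundary, , drop = FALSE]
    colnames(b) <- c("x", "y", "z")
    b
  })
  out <- data.frame(label_id = uniq, x_um = as.numeric(cx),
                    y_um = as.numeric(cy), z_um = as.numeric(cz),
                    n_voxels = nv)
  out$boundary_um <- boundary
  structure(out, class = c("object_geometry", "data.frame"))
}
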