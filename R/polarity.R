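# Nucleus-Golgi pairing, polarity angles, and circular summaries.

# Minimum Euclidean distance between two point sets (n x 3, m x 3 matrices,
# physical um).
min_cross_dist <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(Inf)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

# Full matrix of min border-border distances, nuclei x golgi.
border_distance_matrix <- function(nuclei, golgi) {
  D <- matrix(Inf, nrow(nuclei), ncol = nrow(golgi))
  for (i in seq_len(nrow(nuclei)))
    for (j in seq_len(nrow(golgi)))
      D[i, j] <- min_cross_dist(nuclei$boundary_um[[i]],
                                golgi$boundary_um[[j]])
  D
}

#' Pair nuclei with their Golgi by closest border-border distance
#'
#' Computes the minimum boundary-voxel-to-boundary-voxel Euclidean distance
#' (3D, physical um) between every nucleus and every Golgi, then matches
#' them one-to-one. The default `"greedy"` policy repeatedly assigns the
#' globally closest unassigned nucleus-Golgi pair (so a Golgi claims at most
#' one nucleus); `"optimal"` minimizes the total distance of the assignment
#' by exhaustive search and is intended for small validation scenes
#' (at most 9 objects on the smaller side). Pairs with border distance
#' above `max_dist_um` are retained but flagged excluded; nuclei left
#' without a Golgi are reported as unmatched.
#'
#' @param nuclei,golgi `object_geometry` tables from [extract_geometry()].
#' @param max_dist_um Exclusion threshold on border-border distance, um
#'   (default 5).
#' @param method Conflict-resolution policy, `"greedy"` or `"optimal"`.
#' @return A data.frame of class `nucleus_golgi_pairs`, one row per nucleus:
#'   `nucleus_id`, `golgi_id` (`NA` when unmatched), `border_distance` um,
#'   `status` (`"included"`, `"excluded"` or `"unmatched"`), `included`
#'   (logical), and the two centroids (`nucleus_x/y/z`, `golgi_x/y/z`, um).
#' @export
pair_nuclei_golgi <- function(nuclei, golgi, max_dist_um = 5,
                              method = c("greedy", "optimal")) {
  method <- match.arg(method)
  stopifnot(inherits(nuclei, "object_geometry"),
            inherits(golgi, "object_geometry"))
  max_dist_um <- check_scalar(max_dist_um, "max_dist_um", lower = 0)
  n <- nrow(nuclei); m <- nrow(golgi)
  out <- data.frame(nucleus_id = nuclei$label_id,
                    golgi_id = NA_integer_,
                    border_distance = NA_real_,
                    status = "unmatched", included = FALSE,
                    nucleus_x = nuclei$x_um, nucleus_y = nuclei$y_um,
                    nucleus_z = nuclei$z_um,
                    golgi_x = NA_real_, golgi_y = NA_real_,
                    golgi_z = NA_real_,
                    stringsAsFactors = FALSE)
  if (m == 0L) {
    if (n > 0L)
      vk_warn("no_golgi", "no Golgi objects: all %d nuclei left unmatched", n)
    return(structure(out, class = c("nucleus_golgi_pairs", "data.frame")))
  }
  if (n == 0L)
    return(structure(out, class = c("nucleus_golgi_pairs", "data.frame")))

  D <- border_distance_matrix(nuclei, golgi)
  assign_g <- rep(NA_integer_, n)
  if (method == "greedy") {
    ord <- order(D)
    free_n <- rep(TRUE, n); free_g <- rep(TRUE, m)
    left <- min(n, m)
    for (k in ord) {
      i <- ((k - 1) %% n) + 1
      j <- ((k - 1) %/% n) + 1
      if (free_n[i] && free_g[j] && is.finite(D[i, j])) {
        assign_g[i] <- j
        free_n[i] <- FALSE; free_g[j] <- FALSE
        left <- left - 1
        if (left == 0) break
      }
    }
  } else {
    if (min(n, m) > 9L)
      vk_stop("too_large",
              "optimal assignment by exhaustive search is limited to 9 objects on the smaller side (got %d x %d); use method = \"greedy\"",
              n, m)
    assign_g <- optimal_assignment(D)
  }

  matched <- !is.na(assign_g)
  out$golgi_id[matched] <- golgi$label_id[assign_g[matched]]
  out$border_distance[matched] <- D[cbind(which(matched), assign_g[matched])]
  out$golgi_x[matched] <- golgi$x_um[assign_g[matched]]
  out$golgi_y[matched] <- golgi$y_um[assign_g[matched]]
  out$golgi_z[matched] <- golgi$z_um[assign_g[matched]]
  out$included <- matched & out$border_distance <= max_dist_um
  out$status <- ifelse(!matched, "unmatched",
                       ifelse(out$included, "included", "excluded"))
  attr(out, "max_dist_um") <- max_dist_um
  structure(out, class = c("nucleus_golgi_pairs", "data.frame"))
}

# Minimum-total-distance one-to-one assignment by exhaustive enumeration of
# permutations. Returns, per row of D, the assigned column (NA if none).
optimal_assignment <- function(D) {
  n <- nrow(D); m <- ncol(D)
  transposed <- n > m
  if (transposed) D <- t(D)
  k <- nrow(D); l <- ncol(D)
  combs <- utils::combn(l, k, simplify = FALSE)
  best <- NULL; best_cost <- Inf
  for (cols in combs) {
    perms <- all_permutations(cols)
    for (p in perms) {
      cost <- sum(D[cbind(seq_len(k), p)])
      if (cost < best_cost) { best_cost <- cost; best <- p }
    }
  }
  if (transposed) {
    out <- rep(NA_integer_, m)
    out[best] <- seq_len(k)
    out
  } else best
}

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(all_permutations(v[-i]), function(p) c(v[i], p)))
  out
}

#' Nucleus-to-Golgi polarity angles on the body-axis compass
#'
#' For each matched pair, forms the x-y projection of the nucleus-to-Golgi
#' centroid vector, normalizes it to a unit vector A, and measures its angle
#' against the reference unit vector B (the dorsal body axis, default
#' `c(0, 1)` = image +y) as theta = arccos(A.B), then signs theta with the
#' 2D cross product of B and A so that the `+90 deg` ("lateral") side of B
#' in a right-handed x-y frame maps to 90 and the opposite side to 270,
#' yielding the compass convention 0 dorsal / 90 lateral / 180 ventral /
#' 270 medial on `[0, 360)`.
#'
#' Pairs whose centroids coincide in the x-y projection carry no direction;
#' they get `angle_deg = NA` and are excluded with reason
#' `"zero_xy_vector"`.
#'
#' @param pairs A `nucleus_golgi_pairs` table from [pair_nuclei_golgi()].
#' @param reference_axis Numeric length 2, the dorsal direction in the x-y
#'   plane (need not be normalized; must be nonzero).
#' @return `pairs` with columns `angle_deg` (degrees in `[0, 360)`, `NA`
#'   for unmatched or degenerate pairs) and `exclusion_reason` added;
#'   degenerate pairs are demoted to `status = "excluded"`.
#' @export
compute_polarity_angles <- function(pairs, reference_axis = c(0, 1)) {
  stopifnot(inherits(pairs, "nucleus_golgi_pairs"))
  if (length(reference_axis) != 2L || !all(is.finite(reference_axis)) ||
      sum(reference_axis^2) == 0)
    vk_stop("bad_param", "`reference_axis` must be a nonzero 2D vector")
  B <- reference_axis / sqrt(sum(reference_axis^2))
  vx <- pairs$golgi_x - pairs$nucleus_x
  vy <- pairs$golgi_y - pairs$nucleus_y
  len <- sqrt(vx^2 + vy^2)
  degenerate <- !is.na(len) & len == 0
  angle <- rep(NA_real_, nrow(pairs))
  ok <- !is.na(len) & len > 0
  ax <- vx[ok] / len[ok]; ay <- vy[ok] / len[ok]
  theta <- acos(pmax(-1, pmin(1, ax * B[1] + ay * B[2]))) * 180 / pi
  cross_z <- B[1] * ay - B[2] * ax
  angle[ok] <- mod_pos(ifelse(cross_z <= 0, theta, 360 - theta), 360)
  pairs$angle_deg <- angle
  pairs$exclusion_reason <- ifelse(degenerate, "zero_xy_vector",
                                   NA_character_)
  pairs$included[degenerate] <- FALSE
  pairs$status[degenerate] <- "excluded"
  pairs
}

#' Summarize an angular distribution
#'
#' Bins angles into `n_bins` equal-width sectors over `[0, 360)` (a rose /
#' polar histogram), and computes the circular mean direction, the mean
#' resultant length `R = |sum(exp(i theta))| / n`, and a Rayleigh test of
#' uniformity. The Rayleigh p value uses the standard series approximation
#' `p = exp(-n R^2) * (1 + (2 n R^2 - (n R^2)^2) / (4 n))` (clamped to
#' `[0, 1]`); for small samples a Monte Carlo null (uniform resampling of
#' `R`) is available.
#'
#' @param angles Numeric angles in degrees (any real values; reduced mod
#'   360). `NA`s are dropped.
#' @param n_bins Number of histogram sectors (default 24, i.e. 15 deg).
#' @param n_excluded,n_unmatched Optional bookkeeping counts carried into
#'   the summary.
#' @param p_method `"approx"` (default) or `"monte_carlo"`.
#' @param n_sim,seed Monte Carlo null settings (used only for
#'   `"monte_carlo"`).
#' @return An `angular_distribution` list: `bin_edges` (degrees,
#'   `n_bins + 1` values), `counts`, `n_included`, `n_excluded`,
#'   `n_unmatched`, `mean_deg`, `R`, `rayleigh_p`, `p_method`.
#' @export
summarize_angles <- function(angles, n_bins = 24, n_excluded = 0L,
                             n_unmatched = 0L,
                             p_method = c("approx", "monte_carlo"),
                             n_sim = 9999L, seed = 1L) {
  p_method <- match.arg(p_method)
  angles <- angles[!is.na(angles)]
  if (length(angles) == 0L)
    vk_stop("empty_input", "no angles to summarize")
  if (n_bins < 1 || n_bins != round(n_bins))
    vk_stop("bad_param", "`n_bins` must be a positive integer")
  angles <- mod_pos(angles, 360)
  n <- length(angles)
  width <- 360 / n_bins
  counts <- tabulate(pmin(floor(angles / width) + 1L, n_bins), nbins = n_bins)
  rad <- angles * pi / 180
  cbar <- mean(cos(rad)); sbar <- mean(sin(rad))
  R <- sqrt(cbar^2 + sbar^2)
  mean_deg <- mod_pos(atan2(sbar, cbar) * 180 / pi, 360)
  z <- n * R^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n))
  p <- min(1, max(0, p))
  if (p_method == "monte_carlo") {
    r_null <- with_seed(check_seed(seed), {
      vapply(seq_len(n_sim), function(i) {
        th <- stats::runif(n, 0, 2 * pi)
        sqrt(mean(cos(th))^2 + mean(sin(th))^2)
      }, numeric(1))
    })
    p <- (1 + sum(r_null >= R)) / (n_sim + 1)
  }
  structure(list(bin_edges = seq(0, 360, by = width), counts = counts,
                 n_included = n, n_excluded = as.integer(n_excluded),
                 n_unmatched = as.integer(n_unmatched),
                 mean_deg = mean_deg, R = R, rayleigh_p = p,
                 p_method = p_method),
            class = "angular_distribution")
}

#' @export
print.angular_distribution <- function(x, ...) {
  cat(sprintf("Angular distribution: n = %d (excluded %d, unmatched %d)\n",
              x$n_included, x$n_excluded, x$n_unmatched))
  cat(sprintf("  circular mean = %.1f deg, R = %.3f, Rayleigh p = %.3g (%s)\n",
              x$mean_deg, x$R, x$rayleigh_p, x$p_method))
  invisible(x)
}

#' Rose (polar histogram) plot of an angular distribution
#'
#' Renders the binned angular distribution on a polar axis with 0 deg
#' (dorsal) at the top and angles increasing clockwise, matching the compass
#' convention of [compute_polarity_angles()]. Requires ggplot2.
#'
#' @param dist An `angular_distribution` from [summarize_angles()].
#' @return A ggplot object.
#' @export
plot_rose <- function(dist) {
  stopifnot(inherits(dist, "angular_distribution"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    vk_stop("missing_package", "plot_rose requires the ggplot2 package")
  mid <- utils::head(dist$bin_edges, -1) + diff(dist$bin_edges) / 2
  df <- data.frame(mid = mid, count = dist$counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(dist$bin_edges)[1], colour = "grey30",
                      fill = "steelblue", alpha = 0.8) +
    ggplot2::coord_polar(start = 0, direction = 1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = c(0, 90, 180, 270),
                                labels = c("dorsal 0°", "lateral 90°",
                                           "ventral 180°", "medial 270°")) +
    ggplot2::labs(x = NULL, y = "cells") +
    ggplot2::theme_minimal()
}

#' Write a rose plot to an SVG file
#'
#' @param dist An `angular_distribution`.
#' @param path Output SVG path.
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
write_rose_svg <- function(dist, path, width = 5, height = 5) {
  p <- plot_rose(dist)
  grDevices::svg(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}
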