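# Geometry extraction, nucleus-Golgi pairing, polarity angles, circular
# summaries.

test_that("centroids and boundaries come out of label masks correctly", {
  # single 1-voxel object: centroid at the voxel center in um
  arr <- array(0L, c(5, 6, 7))
  arr[2, 3, 4] <- 1L
  g <- extract_geometry(label_mask(arr, c(2, 1, 1)))
  expect_equal(nrow(g), 1)
  expect_equal(c(g$x_um, g$y_um, g$z_um), c(3.5, 2.5, 3.0))
  expect_equal(nrow(g$boundary_um[[1]]), 1)

  # empty mask: empty geometry, not an error
  expect_equal(nrow(extract_geometry(label_mask(array(0L, c(3, 3, 3)),
                                               c(1, 1, 1)))), 0)

  # solid sphere: centroid within half a voxel of the geometric center
  sp <- c(2, 0.5, 0.5)
  sc <- generate_vessel_scene(scene_params(n_inside = 1, n_outside = 0,
                                           kappa = 0, seed = 8))
  gn <- extract_geometry(sc$nuclei)
  gt <- sc$ground_truth
  expect_lt(abs(gn$x_um - gt$x_um), sp[3] / 2)
  expect_lt(abs(gn$y_um - gt$y_um), sp[2] / 2)
  expect_lt(abs(gn$z_um - gt$z_um), sp[1] / 2)
})

test_that("random-blob centroids match the accumulation oracle exactly", {
  mask <- make_blob_mask(seed = 7)
  g <- extract_geometry(mask)
  oc <- oracle_centroids(unclass(mask), attr(mask, "spacing"))
  expect_equal(as.matrix(g[, c("x_um", "y_um", "z_um")]),
               oc, ignore_attr = TRUE)
})

test_that("boundary voxels are exactly those with a background 6-neighbor", {
  arr <- array(0L, c(5, 5, 5))
  arr[2:4, 2:4, 2:4] <- 1L  # 3x3x3 cube: only the center voxel is interior
  g <- extract_geometry(label_mask(arr, c(1, 1, 1)))
  expect_equal(g$n_voxels, 27)
  expect_equal(nrow(g$boundary_um[[1]]), 26)
  expect_false(any(g$boundary_um[[1]][, "x"] == 2.5 &
                   g$boundary_um[[1]][, "y"] == 2.5 &
                   g$boundary_um[[1]][, "z"] == 2.5))
})

test_that("pairing respects the border-distance threshold", {
  # two spheres with a known border gap along x
  mk <- function(cx_vox) {
    arr <- array(0L, c(9, 9, 40))
    arr[5, 5, cx_vox] <- 1L
    arr
  }
  sp <- c(1, 1, 1)
  nuc <- extract_geometry(label_mask(mk(5), sp))
  gol3 <- extract_geometry(label_mask(mk(9), sp))   # gap 4 um (center 4 apart, 1-voxel objects)
  p <- pair_nuclei_golgi(nuc, gol3, max_dist_um = 5)
  expect_equal(p$status, "included")
  expect_equal(p$border_distance, 4)

  gol6 <- extract_geometry(label_mask(mk(11), sp))  # gap 6 um: paired but excluded
  p6 <- pair_nuclei_golgi(nuc, gol6, max_dist_um = 5)
  expect_equal(p6$status, "excluded")
  expect_false(p6$included)

  # no Golgi at all: unmatched with a warning
  empty <- extract_geometry(label_mask(array(0L, c(9, 9, 40)), sp))
  expect_warning(pu <- pair_nuclei_golgi(nuc, empty),
                 class = "vasckinetics_warning_no_golgi")
  expect_equal(pu$status, "unmatched")
})

test_that("pairing equals the exhaustive all-pairs greedy oracle", {
  sc <- generate_vessel_scene(scene_params(n_inside = 4, n_outside = 6,
                                           kappa = 1, seed = 12))
  nuc <- extract_geometry(sc$nuclei)
  gol <- extract_geometry(sc$golgi)
  p <- pair_nuclei_golgi(nuc, gol, max_dist_um = 5)
  oc <- oracle_greedy_pairs(nuc$boundary_um, gol$boundary_um)
  oc <- oc[order(oc$i), ]
  expect_equal(p$golgi_id, gol$label_id[oc$j])
  expect_equal(p$border_distance, oc$d, tolerance = 1e-12)
})

test_that("greedy and optimal assignment agree on well-separated scenes", {
  sc <- generate_vessel_scene(scene_params(n_inside = 3, n_outside = 4,
                                           kappa = 0, seed = 23))
  nuc <- extract_geometry(sc$nuclei)
  gol <- extract_geometry(sc$golgi)
  pg <- pair_nuclei_golgi(nuc, gol, method = "greedy")
  po <- pair_nuclei_golgi(nuc, gol, method = "optimal")
  expect_equal(pg$golgi_id, po$golgi_id)
})

test_that("polarity angles follow the body-axis compass convention", {
  mk_pairs <- function(gx, gy) {
    structure(data.frame(nucleus_id = 1L, golgi_id = 1L, border_distance = 1,
                         status = "included", included = TRUE,
                         nucleus_x = 0, nucleus_y = 0, nucleus_z = 0,
                         golgi_x = gx, golgi_y = gy, golgi_z = 0),
              class = c("nucleus_golgi_pairs", "data.frame"))
  }
  ref <- c(0, 1)  # +y is dorsal
  expect_equal(compute_polarity_angles(mk_pairs(0, 2), ref)$angle_deg, 0)
  expect_equal(compute_polarity_angles(mk_pairs(3, 0), ref)$angle_deg, 90)
  expect_equal(compute_polarity_angles(mk_pairs(0, -1), ref)$angle_deg, 180)
  expect_equal(compute_polarity_angles(mk_pairs(-5, 0), ref)$angle_deg, 270)

  # coincident centroids in x-y: excluded with a reason, never NaN angles
  pz <- compute_polarity_angles(mk_pairs(0, 0), ref)
  expect_true(is.na(pz$angle_deg))
  expect_equal(pz$exclusion_reason, "zero_xy_vector")
  expect_equal(pz$status, "excluded")
})

test_that("angles equal the rotation-matrix oracle to 1e-9 degrees", {
  set.seed(314)
  n <- 200
  vx <- rnorm(n); vy <- rnorm(n)
  refs <- list(c(0, 1), c(1, 0), c(0.3, -0.8), c(-2, 5))
  for (ref in refs) {
    pairs <- structure(
      data.frame(nucleus_id = seq_len(n), golgi_id = seq_len(n),
                 border_distance = 1, status = "included", included = TRUE,
                 nucleus_x = 0, nucleus_y = 0, nucleus_z = 0,
                 golgi_x = vx, golgi_y = vy, golgi_z = 0),
      class = c("nucleus_golgi_pairs", "data.frame"))
    got <- compute_polarity_angles(pairs, ref)$angle_deg
    want <- vapply(seq_len(n),
                   function(i) oracle_polarity_angle(c(vx[i], vy[i]), ref),
                   numeric(1))
    expect_lt(max(angular_diff(got, want)), 1e-9)
  }
})

test_that("angles are equivariant under in-plane rotation", {
  set.seed(99)
  n <- 50
  vx <- rnorm(n); vy <- rnorm(n)
  base <- structure(
    data.frame(nucleus_id = seq_len(n), golgi_id = seq_len(n),
               border_distance = 1, status = "included", included = TRUE,
               nucleus_x = 0, nucleus_y = 0, nucleus_z = 0,
               golgi_x = vx, golgi_y = vy, golgi_z = 0),
    class = c("nucleus_golgi_pairs", "data.frame"))
  a0 <- compute_polarity_angles(base, c(0, 1))$angle_deg
  for (phi_deg in c(30, 117, 260)) {
    phi <- phi_deg * pi / 180
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    v <- R %*% rbind(vx, vy)
    ref <- as.numeric(R %*% c(0, 1))
    rot <- base
    rot$golgi_x <- v[1, ]; rot$golgi_y <- v[2, ]
    a1 <- compute_polarity_angles(rot, ref)$angle_deg
    expect_lt(max(angular_diff(a0, a1)), 1e-6)
  }
})

test_that("raising max_dist never decreases the included count, and every nucleus is accounted for once", {
  sc <- generate_vessel_scene(scene_params(n_inside = 4, n_outside = 6,
                                           kappa = 0, seed = 31))
  nuc <- extract_geometry(sc$nuclei)
  gol <- extract_geometry(sc$golgi)
  thresholds <- c(0.5, 1, 2, 5, 10)
  n_inc <- vapply(thresholds, function(th) {
    p <- pair_nuclei_golgi(nuc, gol, max_dist_um = th)
    expect_equal(nrow(p), nrow(nuc))
    expect_equal(sum(p$status == "included") + sum(p$status == "excluded") +
                   sum(p$status == "unmatched"), nrow(nuc))
    sum(p$included)
  }, numeric(1))
  expect_true(all(diff(n_inc) >= 0))
})

test_that("angular summaries capture degenerate and symmetric inputs", {
  s1 <- summarize_angles(rep(90, 50))
  expect_equal(s1$R, 1)
  expect_equal(s1$mean_deg, 90)
  expect_lt(s1$rayleigh_p, 1e-12)

  s4 <- summarize_angles(rep(c(0, 90, 180, 270), each = 10))
  expect_lt(s4$R, 1e-12)

  expect_error(summarize_angles(numeric(0)),
               class = "vasckinetics_error_empty_input")
})

test_that("histogram counts conserve the included total for any binning", {
  a <- sample_polarity_angles(10, 1.5, 777, seed = 6)
  for (nb in c(4, 7, 24, 36)) {
    s <- summarize_angles(a, n_bins = nb)
    expect_equal(sum(s$counts), length(a))
    expect_equal(length(s$counts), nb)
    expect_equal(length(s$bin_edges), nb + 1)
  }
})

test_that("a concentrated sample is detected as non-uniform", {
  a <- sample_polarity_angles(0, 2, 2000, seed = 13)
  s <- summarize_angles(a)
  expect_lt(s$rayleigh_p, 0.001)
  expect_lt(angular_diff(s$mean_deg, 0), 5)
  # Monte Carlo p agrees with the approximation for a clearly uniform case
  u <- sample_polarity_angles(0, 0, 80, seed = 14)
  pa <- summarize_angles(u)$rayleigh_p
  pm <- summarize_angles(u, p_method = "monte_carlo", n_sim = 2000,
                         seed = 15)$rayleigh_p
  expect_lt(abs(pa - pm), 0.1)
})

test_that("scene round-trip recovers generated angles within voxel error", {
  sc <- generate_vessel_scene(scene_params(n_inside = 5, n_outside = 9,
                                           kappa = 3, mu_deg = 120, seed = 44))
  nuc <- extract_geometry(sc$nuclei)
  gol <- extract_geometry(sc$golgi)
  p <- compute_polarity_angles(pair_nuclei_golgi(nuc, gol))
  expect_true(all(p$status == "included"))
  expect_equal(p$golgi_id, p$nucleus_id)  # ground-truth pairing by label
  truth <- sc$ground_truth$angle_deg[match(p$nucleus_id,
                                           sc$ground_truth$nucleus_label)]
  tol <- atan(max(attr(sc$nuclei, "spacing")[2:3]) /
                sc$params$golgi_offset) * 180 / pi
  expect_lt(max(angular_diff(p$angle_deg, truth)), tol)
})

test_that("kappa = 0 scenes are statistically unpolarized across seeds", {
  # true angles fall below the 5% Rayleigh critical value in >= 90% of seeds
  rejections <- vapply(1:20, function(s) {
    a <- sample_polarity_angles(0, 0, 2000, seed = 700 + s)
    summarize_angles(a)$rayleigh_p < 0.05
  }, logical(1))
  expect_lte(sum(rejections), 2)
})
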