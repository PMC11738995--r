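# Compartment classification, population counts, expansion statistics.

make_tube_scene <- function(seed = 5, ...) {
  generate_vessel_scene(scene_params(seed = seed, ...))
}

test_that("axis points are inside and far points are outside", {
  sc <- make_tube_scene(n_inside = 1, n_outside = 1, kappa = 0)
  sp <- attr(sc$vessel, "spacing")
  d <- dim(sc$vessel)
  ext <- c(d[3] * sp[3], d[2] * sp[2], d[1] * sp[1])  # x, y, z um
  cells <- data.frame(cell_id = 1:2,
                      x_um = c(ext[1] / 2, 2),
                      y_um = c(ext[2] / 2, 2),
                      z_um = c(ext[3] / 2, 2))
  out <- classify_compartment(cells, sc$vessel)
  expect_equal(out$compartment, c("inside", "outside"))

  # out-of-bounds centroids stay unassigned
  oob <- data.frame(cell_id = 1, x_um = -5, y_um = 1, z_um = 1)
  expect_equal(classify_compartment(oob, sc$vessel)$compartment, "unassigned")

  # empty mask and mismatched spacing are errors
  empty <- label_mask(array(0L, dim(sc$vessel)), sp)
  expect_error(classify_compartment(cells, empty),
               class = "vasckinetics_error_empty_mask")
  expect_error(classify_compartment(cells, sc$vessel, spacing = c(1, 1, 1)),
               class = "vasckinetics_error_spacing_mismatch")
})

test_that("classification equals brute-force nearest-voxel search", {
  sc <- make_tube_scene(seed = 61, n_inside = 1, n_outside = 1,
                        volume_shape = c(16L, 48L, 48L),
                        voxel_spacing = c(2, 1, 1), vessel_radius_um = 9)
  set.seed(606)
  n <- 1000
  sp <- attr(sc$vessel, "spacing")
  d <- dim(sc$vessel)
  pts <- cbind(runif(n, 0, d[3] * sp[3]), runif(n, 0, d[2] * sp[2]),
               runif(n, 0, d[1] * sp[1]))
  cells <- data.frame(cell_id = seq_len(n), x_um = pts[, 1],
                      y_um = pts[, 2], z_um = pts[, 3])
  for (tol in c(0, 1.5, 4)) {
    got <- classify_compartment(cells, sc$vessel, tolerance_um = tol)
    want <- oracle_classify(pts, unclass(sc$vessel), sp, tol)
    expect_equal(got$compartment, unname(want),
                 info = sprintf("tolerance %.1f", tol))
  }
})

test_that("raising the tolerance never shrinks the inside population", {
  sc <- make_tube_scene(seed = 62, n_inside = 2, n_outside = 4)
  cells <- data.frame(cell_id = sc$ground_truth$cell_id,
                      x_um = sc$ground_truth$x_um,
                      y_um = sc$ground_truth$y_um,
                      z_um = sc$ground_truth$z_um)
  ns <- vapply(c(0, 2, 5, 10, 25), function(tol)
    sum(classify_compartment(cells, sc$vessel,
                             tolerance_um = tol)$compartment == "inside"),
    numeric(1))
  expect_true(all(diff(ns) >= 0))
})

test_that("tolerance classification matches classifying against a dilated mask", {
  sc <- make_tube_scene(seed = 63, n_inside = 1, n_outside = 1,
                        volume_shape = c(16L, 40L, 40L),
                        voxel_spacing = c(1, 1, 1), vessel_radius_um = 8)
  sp <- attr(sc$vessel, "spacing")
  d_um <- 3
  # dilate by marking voxels within d_um of the tube (exact for this
  # analytic tube: radius + d_um)
  sc_dil <- make_tube_scene(seed = 63, n_inside = 1, n_outside = 1,
                            volume_shape = c(16L, 40L, 40L),
                            voxel_spacing = c(1, 1, 1),
                            vessel_radius_um = 8 + d_um)
  set.seed(99)
  pts <- cbind(runif(400, 0, 40), runif(400, 0, 40), runif(400, 0, 16))
  cells <- data.frame(cell_id = 1:400, x_um = pts[, 1], y_um = pts[, 2],
                      z_um = pts[, 3])
  a <- classify_compartment(cells, sc$vessel, tolerance_um = d_um)$compartment
  b <- classify_compartment(cells, sc_dil$vessel)$compartment
  # agreement up to voxel discretization at the dilated surface
  expect_gt(mean(a == b), 0.97)
})

test_that("population counts partition by compartment and honor queries", {
  cells <- data.frame(
    cell_id = 1:8,
    x_um = 0, y_um = 0, z_um = 0,
    erg = c(1, 1, 1, 1, 1, 1, 0, 0),
    prox1 = c(1, 1, 0, 0, 1, 1, 1, 0),
    compartment = c("inside", "inside", "inside", "outside", "outside",
                    "unassigned", "outside", "inside"),
    stage_label = "E10.5")
  pc <- count_population(cells, "erg & prox1")  # hits rows 1, 2, 5, 6
  expect_equal(attr(pc, "n_total"), 4)
  expect_equal(pc$n[pc$compartment == "inside"], 2)
  expect_equal(pc$n[pc$compartment == "outside"], 1)
  expect_equal(pc$n[pc$compartment == "unassigned"], 1)
  expect_equal(sum(pc$n), attr(pc, "n_total"))

  # complement queries partition the compartment totals
  p1 <- count_population(cells, "erg & prox1")
  p2 <- count_population(cells, "erg & !prox1")
  p3 <- count_population(cells, "!erg")
  tot <- count_population(cells, "TRUE")
  expect_equal(p1$n + p2$n + p3$n, tot$n)

  # empty table: all zeros
  expect_equal(sum(count_population(cells[0, ], "erg")$n), 0)

  # unknown flag names are rejected with the valid set listed
  err <- tryCatch(count_population(cells, "erg & nonexistent"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "nonexistent")
  expect_match(err, "prox1")
})

test_that("scene counts match generator ground truth exactly", {
  sc <- make_tube_scene(seed = 64, n_inside = 5, n_outside = 7)
  cells <- data.frame(cell_id = sc$ground_truth$cell_id,
                      x_um = sc$ground_truth$x_um,
                      y_um = sc$ground_truth$y_um,
                      z_um = sc$ground_truth$z_um)
  cells <- classify_compartment(cells, sc$vessel)
  expect_equal(cells$compartment, sc$ground_truth$compartment)
  pc <- count_population(cells)
  expect_equal(pc$n[pc$compartment == "inside"], 5)
  expect_equal(pc$n[pc$compartment == "outside"], 7)
})

test_that("fold changes are ratios of stage means with propagated sd", {
  reps <- data.frame(stage_label = rep(c("E9.5", "E11"), each = 3),
                     value = c(340, 350, 363, 11000, 11500, 12030))
  fc <- fold_change(reps, "E9.5", "E11")
  expect_equal(fc$fold$fold, mean(c(11000, 11500, 12030)) / mean(c(340, 350, 363)))
  expect_gt(fc$fold$fold_sd, 0)

  # identical means: fold 1
  same <- data.frame(stage_label = rep(c("a", "b"), each = 2),
                     value = c(5, 7, 4, 8))
  expect_equal(fold_change(same, "a", "b")$fold$fold, 1)

  # zero baseline is an error
  z <- data.frame(stage_label = c("a", "b"), value = c(0, 10))
  expect_error(fold_change(z, "a", "b"),
               class = "vasckinetics_error_zero_baseline")
})

test_that("fold changes compose across stages", {
  reps <- data.frame(stage_label = rep(c("E9.5", "E10.5", "E11"), each = 3),
                     value = c(351, 420, 290, 3000, 3400, 2800,
                               11510, 12000, 10000))
  f13 <- fold_change(reps, "E9.5", "E11")$fold$fold
  f12 <- fold_change(reps, "E9.5", "E10.5")$fold$fold
  f23 <- fold_change(reps, "E10.5", "E11")$fold$fold
  expect_equal(f13, f12 * f23)
})

test_that("group comparisons match the textbook t formula and handle degeneracy", {
  set.seed(55)
  a <- rnorm(6, 10, 2); b <- rnorm(8, 12, 2)
  res <- compare_groups(c(a, b), rep(c("a", "b"), c(6, 8)), test = "t")
  expect_equal(res$statistic, oracle_t_statistic(a, b), tolerance = 1e-9)
  expect_equal(res$df, 12)

  ident <- compare_groups(c(1, 1, 1, 1), c("a", "a", "b", "b"))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  sep <- compare_groups(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_true(is.infinite(sep$statistic))
  expect_lt(sep$p_value, 1e-300)

  expect_error(compare_groups(c(1, 2), c("a", "b")),
               class = "vasckinetics_error_too_few_replicates")

  anov <- compare_groups(c(a, b), rep(c("a", "b"), c(6, 8)), test = "anova")
  expect_equal(anov$statistic, res$statistic^2, tolerance = 1e-9)
})
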