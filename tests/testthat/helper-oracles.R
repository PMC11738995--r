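# Independent brute-force oracles used to validate the vectorized
# implementations. These deliberately share no code with the package
# internals they check.

# Was this cell in S-phase at any time in [w0, w1]? Brute-force time
# stepping at resolution dt.
oracle_in_s_during <- function(phase0, t_cycle, t_s, s_start, w0, w1,
                               dt = 0.005) {
  for (t in seq(w0, w1, by = dt)) {
    pos <- (phase0 + t - s_start) %% t_cycle
    if (pos < t_s) return(TRUE)
  }
  # also probe the exact window end (seq may undershoot)
  pos <- (phase0 + w1 - s_start) %% t_cycle
  pos < t_s
}

# Naive von Mises rejection sampler: accept uniform proposals theta with
# probability exp(kappa * (cos(theta - mu) - 1)).
oracle_rvonmises_deg <- function(n, mu_deg, kappa) {
  mu <- mu_deg * pi / 180
  out <- numeric(0)
  while (length(out) < n) {
    th <- runif(2 * n, 0, 2 * pi)
    acc <- runif(2 * n) < exp(kappa * (cos(th - mu) - 1))
    out <- c(out, th[acc])
  }
  (out[seq_len(n)] * 180 / pi) %% 360
}

# Per-label centroid by explicit accumulation over every voxel.
# Voxel (iz, iy, ix) center: ((ix-.5)*sx, (iy-.5)*sy, (iz-.5)*sz) um.
oracle_centroids <- function(arr, spacing) {
  d <- dim(arr)
  acc <- list()
  for (iz in seq_len(d[1])) for (iy in seq_len(d[2])) for (ix in seq_len(d[3])) {
    lab <- arr[iz, iy, ix]
    if (lab > 0) {
      key <- as.character(lab)
      p <- c((ix - 0.5) * spacing[3], (iy - 0.5) * spacing[2],
             (iz - 0.5) * spacing[1])
      if (is.null(acc[[key]])) acc[[key]] <- list(s = p, n = 1)
      else acc[[key]] <- list(s = acc[[key]]$s + p, n = acc[[key]]$n + 1)
    }
  }
  labs <- sort(as.integer(names(acc)))
  t(vapply(as.character(labs),
           function(k) acc[[k]]$s / acc[[k]]$n, numeric(3)))
}

# All-pairs greedy matching oracle over explicit point-set distances.
oracle_greedy_pairs <- function(nuc_boundaries, gol_boundaries) {
  n <- length(nuc_boundaries); m <- length(gol_boundaries)
  cand <- expand.grid(i = seq_len(n), j = seq_len(m))
  cand$d <- mapply(function(i, j) {
    a <- nuc_boundaries[[i]]; b <- gol_boundaries[[j]]
    best <- Inf
    for (p in seq_len(nrow(a))) for (q in seq_len(nrow(b))) {
      dd <- sqrt(sum((a[p, ] - b[q, ])^2))
      if (dd < best) best <- dd
    }
    best
  }, cand$i, cand$j)
  cand <- cand[order(cand$d), ]
  used_i <- logical(n); used_j <- logical(m)
  out <- data.frame(i = integer(0), j = integer(0), d = numeric(0))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!used_i[i] && !used_j[j]) {
      used_i[i] <- TRUE; used_j[j] <- TRUE
      out <- rbind(out, data.frame(i = i, j = j, d = cand$d[r]))
    }
  }
  out
}

# Rotation-matrix polarity angle: rotate the frame so the reference becomes
# (0, 1), then read the compass angle off atan2.
oracle_polarity_angle <- function(v_xy, ref_xy) {
  b <- ref_xy / sqrt(sum(ref_xy^2))
  # rotation taking b to (0, 1): angle of rotation = angle from b to +y
  phi <- atan2(1, 0) - atan2(b[2], b[1])
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  a <- R %*% (v_xy / sqrt(sum(v_xy^2)))
  (90 - atan2(a[2], a[1]) * 180 / pi) %% 360
}

# Brute-force inside/outside classification: centroid-in-voxel lookup plus
# nearest distance over every vessel voxel center.
oracle_classify <- function(xyz, vessel, spacing, tolerance_um) {
  d <- dim(vessel)
  fg <- which(vessel > 0, arr.ind = TRUE)
  fg_um <- cbind((fg[, 3] - 0.5) * spacing[3], (fg[, 2] - 0.5) * spacing[2],
                 (fg[, 1] - 0.5) * spacing[1])
  apply(xyz, 1, function(p) {
    idx <- c(floor(p[3] / spacing[1]) + 1, floor(p[2] / spacing[2]) + 1,
             floor(p[1] / spacing[3]) + 1)
    if (any(idx < 1) || any(idx > d)) return("unassigned")
    if (vessel[idx[1], idx[2], idx[3]] > 0) return("inside")
    dmin <- min(sqrt(colSums((t(fg_um) - p)^2)))
    if (dmin <= tolerance_um) "inside" else "outside"
  })
}

# Student's t statistic from the textbook pooled-variance formula.
oracle_t_statistic <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# Tiny deterministic label mask with a few hand-placed blobs.
make_blob_mask <- function(dim_zyx = c(6L, 10L, 12L), spacing = c(2, 1, 0.5),
                           n_blobs = 3L, seed = 1L) {
  set.seed(seed)
  arr <- array(0L, dim_zyx)
  for (lab in seq_len(n_blobs)) {
    cz <- sample(2:(dim_zyx[1] - 1), 1)
    cy <- sample(2:(dim_zyx[2] - 1), 1)
    cx <- sample(2:(dim_zyx[3] - 1), 1)
    arr[max(1, cz - 1):min(dim_zyx[1], cz + 1),
        max(1, cy - 1):min(dim_zyx[2], cy + 1),
        max(1, cx - 1):min(dim_zyx[3], cx + 1)] <- lab
  }
  label_mask(arr, spacing)
}

angular_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}
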