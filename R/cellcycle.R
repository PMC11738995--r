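#' Scored counts from a dual-pulse labeling experiment
#'
#' Container for the tallies the cell-cycle estimators operate on: the scored
#' population `p_cells` (e.g. PROX1+ nuclei), `s_cells` (EdU+BrdU+
#' double-positive cells, i.e. cells in S-phase at the end of the
#' experiment), `l_cells` (EdU+BrdU- cells, which left S-phase during the
#' injection interval), and `ki67_pos` (KI67-immunoreactive cells, used for
#' the growth fraction).
#'
#' @param p_cells Total scored cells (> 0 for downstream estimation).
#' @param s_cells EdU+BrdU+ count.
#' @param l_cells EdU+BrdU- count.
#' @param ki67_pos KI67+ count.
#' @param t_i Injection interval T_i, hours (> 0).
#' @param group_label Optional text label (e.g. `"inside_vein"`).
#' @return An object of class `pulse_counts`.
#' @export
pulse_counts <- function(p_cells, s_cells, l_cells, ki67_pos, t_i = 6,
                         group_label = NA_character_) {
  for (nm in c("p_cells", "s_cells", "l_cells", "ki67_pos")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != round(v))
      vk_stop("bad_param", "`%s` must be a single non-negative integer", nm)
  }
  if (s_cells + l_cells > p_cells)
    vk_stop("bad_param",
            "s_cells + l_cells (%d) exceeds p_cells (%d): EdU+ cells cannot outnumber the scored population",
            s_cells + l_cells, p_cells)
  if (ki67_pos > p_cells)
    vk_stop("bad_param", "ki67_pos (%d) exceeds p_cells (%d)", ki67_pos, p_cells)
  t_i <- check_scalar(t_i, "t_i", lower = 0, strict_lower = TRUE)
  structure(list(p_cells = as.integer(p_cells), s_cells = as.integer(s_cells),
                 l_cells = as.integer(l_cells), ki67_pos = as.integer(ki67_pos),
                 t_i = t_i, group_label = group_label),
            class = "pulse_counts")
}

#' @export
print.pulse_counts <- function(x, ...) {
  cat(sprintf("Dual-pulse counts%s: P = %d, S (EdU+BrdU+) = %d, L (EdU+BrdU-) = %d, KI67+ = %d, T_i = %g h\n",
              if (is.na(x$group_label)) "" else paste0(" [", x$group_label, "]"),
              x$p_cells, x$s_cells, x$l_cells, x$ki67_pos, x$t_i))
  invisible(x)
}

#' Growth fraction from KI67 scoring
#'
#' The growth fraction GF is the proportion of the scored population that is
#' actively cycling, estimated as the KI67+ proportion:
#' GF = KI67+ cells / P_cells.
#'
#' @param counts A [pulse_counts()] object.
#' @return The growth fraction, a number in `[0, 1]`.
#' @export
compute_growth_fraction <- function(counts) {
  stopifnot(inherits(counts, "pulse_counts"))
  if (counts$p_cells == 0)
    vk_stop("empty_population", "empty population: p_cells = 0")
  counts$ki67_pos / counts$p_cells
}

#' S-phase duration from dual-pulse counts
#'
#' Estimates the S-phase duration as T_S = T_i / (L_cells / S_cells): during
#' the injection interval T_i a fraction of the initially EdU-labeled S-phase
#' population leaves S (becoming EdU+BrdU-, the L cells), at a steady-state
#' rate proportional to 1/T_S per hour of S-phase occupancy.
#'
#' @param counts A [pulse_counts()] object with `s_cells > 0` and
#'   `l_cells > 0`.
#' @return Estimated T_S in hours.
#' @export
estimate_ts <- function(counts) {
  stopifnot(inherits(counts, "pulse_counts"))
  if (counts$s_cells == 0)
    vk_stop("no_s_cells", "no double-positive cells: cannot estimate T_S")
  if (counts$l_cells == 0)
    vk_stop("no_l_cells",
            "no EdU-only cells: T_i too short or population saturated")
  counts$t_i * counts$s_cells / counts$l_cells
}

#' Total cell-cycle duration from dual-pulse counts
#'
#' Estimates T_C = T_S / (S_cells / (P_cells x GF)): the fraction of cycling
#' cells occupying S-phase at harvest equals T_S / T_C at steady state. The
#' growth fraction corrects for non-cycling cells, which would otherwise
#' inflate T_C.
#'
#' @param counts A [pulse_counts()] object.
#' @param gf Growth fraction; defaults to [compute_growth_fraction()] of
#'   `counts`.
#' @return A `cell_cycle_estimate` list with `t_s`, `t_c`, `gf` and the
#'   input counts.
#' @export
estimate_tc <- function(counts, gf = compute_growth_fraction(counts)) {
  stopifnot(inherits(counts, "pulse_counts"))
  gf <- check_scalar(gf, "gf", 0, 1)
  if (gf == 0)
    vk_stop("zero_growth_fraction",
            "growth fraction is 0: no cycling cells, T_C is undefined")
  t_s <- estimate_ts(counts)
  cycling <- counts$p_cells * gf
  if (counts$s_cells > cycling)
    vk_warn("inconsistent_counts",
            "s_cells (%d) exceeds p_cells x GF (%.1f): counts are inconsistent (T_C < T_S)",
            counts$s_cells, cycling)
  t_c <- t_s * cycling / counts$s_cells
  structure(list(t_s = t_s, t_c = t_c, gf = gf, counts = counts,
                 group_label = counts$group_label),
            class = "cell_cycle_estimate")
}

#' @export
print.cell_cycle_estimate <- function(x, ...) {
  cat(sprintf("Cell-cycle estimate%s:\n",
              if (is.null(x$group_label) || is.na(x$group_label)) ""
              else paste0(" [", x$group_label, "]")))
  fmt <- function(nm, v, unit) {
    ci <- x$ci[[nm]]
    cat(sprintf("  %-4s = %6.2f %s%s\n", toupper(gsub("_", "", nm)), v, unit,
                if (!is.null(ci)) sprintf("  (95%% CI %.2f-%.2f, %d bootstrap replicates)",
                                          ci[1], ci[2], x$n_boot) else ""))
  }
  fmt("t_s", x$t_s, "h"); fmt("t_c", x$t_c, "h"); fmt("gf", x$gf, " ")
  invisible(x)
}

#' Bootstrap confidence intervals for the cell-cycle estimators
#'
#' Resamples cells with replacement from a cell-level table and recomputes
#' T_S, T_C and GF on each replicate, returning percentile (2.5/97.5)
#' confidence intervals. Because the estimators depend on the data only
#' through the counts of the eight (EdU, BrdU, KI67) flag combinations,
#' resampling `n` rows with replacement is carried out as a single
#' multinomial draw over those strata, which is distributionally identical
#' and independent of table ordering.
#'
#' Replicates in which `s_cells` or `l_cells` is zero cannot be estimated and
#' are recorded as failed; if more than 20% of replicates fail the function
#' errors, advising a larger sample.
#'
#' @param cell_table A data.frame with logical/0-1 columns `edu`, `brdu`,
#'   `ki67` (one row per cell), e.g. the `cells` component of
#'   [simulate_pulse_labeling()] or [read_cell_table()].
#' @param t_i Injection interval T_i, hours.
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param group_label Optional label carried into the estimate.
#' @return A `cell_cycle_estimate` with an added `ci` list (`t_s`, `t_c`,
#'   `gf`, each `c(low, high)`), `n_boot`, and `n_failed`.
#' @export
bootstrap_estimates <- function(cell_table, t_i = 6, n_boot = 1000L, seed = 1L,
                                group_label = NA_character_) {
  for (col in c("edu", "brdu", "ki67"))
    if (!col %in% names(cell_table))
      vk_stop("missing_column", "cell table lacks required column `%s`", col)
  if (n_boot < 100) vk_stop("bad_param", "n_boot must be at least 100")
  seed <- check_seed(seed)
  n <- nrow(cell_table)
  if (n == 0) vk_stop("empty_population", "empty cell table")

  edu <- as.logical(cell_table$edu)
  brdu <- as.logical(cell_table$brdu)
  ki67 <- as.logical(cell_table$ki67)
  # stratum index 1..8 over the flag combinations
  stratum <- 1L + edu + 2L * brdu + 4L * ki67
  n_strat <- tabulate(stratum, nbins = 8L)
  is_s <- c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE)  # edu & brdu
  is_l <- c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)  # edu & !brdu
  is_k <- c(rep(FALSE, 4), rep(TRUE, 4))                           # ki67

  point <- estimate_tc(pulse_counts(
    p_cells = n, s_cells = sum(n_strat[is_s]), l_cells = sum(n_strat[is_l]),
    ki67_pos = sum(n_strat[is_k]), t_i = t_i, group_label = group_label))

  draws <- with_seed(seed, stats::rmultinom(n_boot, n, n_strat / n))
  s_b <- colSums(draws[is_s, , drop = FALSE])
  l_b <- colSums(draws[is_l, , drop = FALSE])
  k_b <- colSums(draws[is_k, , drop = FALSE])
  ok <- s_b > 0 & l_b > 0 & k_b > 0
  n_failed <- sum(!ok)
  if (n_failed > 0.2 * n_boot)
    vk_stop("bootstrap_failure",
            "%d of %d bootstrap replicates had no S or no L cells; sample more cells",
            n_failed, n_boot)
  ts_b <- t_i * s_b[ok] / l_b[ok]
  gf_b <- k_b[ok] / n
  tc_b <- ts_b * n * gf_b / s_b[ok]

  ci <- function(v) unname(stats::quantile(v, c(0.025, 0.975), type = 7))
  point$ci <- list(t_s = ci(ts_b), t_c = ci(tc_b), gf = ci(gf_b))
  point$n_boot <- as.integer(n_boot)
  point$n_failed <- as.integer(n_failed)
  point
}
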