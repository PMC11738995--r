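# Inside/outside-vessel classification, population counting and expansion
# statistics.

#' Classify cells as inside or outside a segmented vessel
#'
#' A cell is `"inside"` when its centroid falls within the vessel mask, or
#' lies within `tolerance_um` (physical um, anisotropic spacing respected)
#' of the nearest vessel voxel center — i.e. its signed distance to the
#' vessel surface, interior negative, is at most `tolerance_um`. Centroids
#' outside the volume bounds are `"unassigned"`. Distances to the surface
#' are computed against the vessel's boundary voxels, which for points
#' outside the mask carry the same nearest-voxel distance as the full mask.
#'
#' @param cells A cell table (data.frame) with centroid columns `x_um`,
#'   `y_um`, `z_um`.
#' @param vessel A binary [label_mask()] (nonzero = vessel).
#' @param spacing Optional; if supplied it must equal the mask's spacing
#'   (guards against mixing resolutions).
#' @param tolerance_um Distance cutoff, um (default 0: strict
#'   centroid-in-mask).
#' @return `cells` with its `compartment` column set to
#'   `"inside"`/`"outside"`/`"unassigned"`.
#' @export
classify_compartment <- function(cells, vessel, spacing = NULL,
                                 tolerance_um = 0) {
  stopifnot(inherits(vessel, "label_mask"))
  for (col in c("x_um", "y_um", "z_um"))
    if (!col %in% names(cells))
      vk_stop("missing_column", "cell table lacks required column `%s`", col)
  tolerance_um <- check_scalar(tolerance_um, "tolerance_um", lower = 0)
  sp <- mask_spacing(vessel)
  if (!is.null(spacing) && !isTRUE(all.equal(as.numeric(spacing), sp)))
    vk_stop("spacing_mismatch",
            "supplied spacing (%s) does not match the mask's (%s)",
            paste(spacing, collapse = ","), paste(sp, collapse = ","))
  if (!any(vessel > 0))
    vk_stop("empty_mask", "vessel mask contains no foreground voxels")

  xyz <- as.matrix(cells[, c("x_um", "y_um", "z_um")])
  idx <- point_to_voxel(xyz, dim(vessel), sp)
  in_bounds <- !is.na(idx[, 1])
  compartment <- rep("unassigned", nrow(cells))
  in_mask <- rep(FALSE, nrow(cells))
  in_mask[in_bounds] <- vessel[idx[in_bounds, , drop = FALSE]] > 0
  compartment[in_bounds] <- ifelse(in_mask[in_bounds], "inside", "outside")

  if (tolerance_um > 0) {
    near <- in_bounds & !in_mask
    if (any(near)) {
      bnd_idx <- which(boundary_voxels(vessel > 0L))
      bnd <- voxel_centers_um(arrayInd(bnd_idx, dim(vessel)), sp)
      pts <- xyz[near, , drop = FALSE]
      # chunked nearest-surface-voxel distances
      dmin <- numeric(nrow(pts))
      step <- max(1L, floor(2e7 / nrow(bnd)))
      for (s in seq(1, nrow(pts), by = step)) {
        e <- min(nrow(pts), s + step - 1)
        blk <- pts[s:e, , drop = FALSE]
        d2 <- outer(rowSums(blk^2), rowSums(bnd^2), "+") -
          2 * tcrossprod(blk, bnd)
        dmin[s:e] <- sqrt(pmax(0, apply(d2, 1, min)))
      }
      compartment[which(near)[dmin <= tolerance_um]] <- "inside"
    }
  }
  cells$compartment <- compartment
  cells
}

#' Count marker-defined cell populations by compartment
#'
#' Tallies cells matching a marker predicate (an R logical expression over
#' the table's flag columns, e.g. `"erg & prox1"` or `"prox1 & !edu"`),
#' split by compartment and, when present, by `stage_label`. Cells with
#' `compartment == "unassigned"` are reported separately, never folded into
#' inside or outside.
#'
#' @param cells A cell table with logical/0-1 marker columns and a
#'   `compartment` column.
#' @param query Predicate string over flag columns; `TRUE` (default) counts
#'   every cell.
#' @param by_stage Split counts by `stage_label` when the column exists.
#' @return A data.frame of class `population_counts`: (`stage_label`,)
#'   `compartment`, `n`, with the query and totals as attributes.
#' @export
count_population <- function(cells, query = "TRUE", by_stage = TRUE) {
  non_flags <- c("cell_id", "x_um", "y_um", "z_um", "compartment",
                 "stage_label")
  flag_cols <- setdiff(names(cells)[vapply(cells, function(col)
    is.logical(col) || (is.numeric(col) && all(col %in% c(0, 1, NA))),
    logical(1))], non_flags)
  expr <- tryCatch(str2lang(query),
                   error = function(e) vk_stop("bad_query",
                     "cannot parse query `%s`: %s", query, conditionMessage(e)))
  vars <- all.vars(expr)
  unknown <- setdiff(vars, flag_cols)
  if (length(unknown))
    vk_stop("unknown_flag",
            "unknown flag%s %s; valid flags: %s",
            if (length(unknown) > 1) "s" else "",
            paste0("`", unknown, "`", collapse = ", "),
            if (length(flag_cols)) paste0("`", flag_cols, "`", collapse = ", ")
            else "(none)")
  env <- as.data.frame(lapply(cells[, vars, drop = FALSE], as.logical))
  hit <- if (nrow(cells) == 0L) logical(0)
         else rep_len(eval(expr, envir = env, enclos = baseenv()), nrow(cells))
  hit[is.na(hit)] <- FALSE

  compartment <- factor(cells$compartment %||% rep("unassigned", nrow(cells)),
                        levels = c("inside", "outside", "unassigned"))
  if (by_stage && "stage_label" %in% names(cells)) {
    tab <- as.data.frame(table(stage_label = cells$stage_label[hit],
                               compartment = compartment[hit]),
                         responseName = "n")
  } else {
    tab <- as.data.frame(table(compartment = compartment[hit]),
                         responseName = "n")
  }
  tab$compartment <- as.character(tab$compartment)
  if ("stage_label" %in% names(tab))
    tab$stage_label <- as.character(tab$stage_label)
  attr(tab, "query") <- query
  attr(tab, "n_total") <- sum(hit)
  attr(tab, "n_unassigned") <- sum(hit & compartment == "unassigned")
  structure(tab, class = c("population_counts", "data.frame"))
}

#' Stage-to-stage expansion (fold change) of a cell population
#'
#' Summarizes per-replicate (typically per-embryo) cell counts by stage and
#' computes the fold change between two named stages as the ratio of stage
#' means (never the mean of per-replicate ratios). The replicate standard
#' deviations are propagated to the ratio by the delta method:
#' `sd(fold) ~ fold * sqrt((sd_b/mean_b)^2 + (sd_a/mean_a)^2)`.
#'
#' @param replicates A data.frame with columns `stage_label` and `value`
#'   (one row per replicate).
#' @param from,to Stage labels; the fold is `mean(to) / mean(from)`.
#' @return A list of class `timecourse_summary`: `stages` (data.frame
#'   `stage_label`, `n`, `mean`, `sd`) and `fold` (data.frame `from`, `to`,
#'   `fold`, `fold_sd`).
#' @export
fold_change <- function(replicates, from, to) {
  if (!all(c("stage_label", "value") %in% names(replicates)))
    vk_stop("missing_column",
            "`replicates` needs columns `stage_label` and `value`")
  for (s in c(from, to))
    if (!s %in% replicates$stage_label)
      vk_stop("missing_stage", "stage `%s` not present in the data", s)
  agg <- do.call(rbind, lapply(split(replicates$value,
                                     replicates$stage_label), function(v)
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)))
  agg <- data.frame(stage_label = rownames(agg), agg, row.names = NULL)
  m_from <- agg$mean[agg$stage_label == from]
  m_to <- agg$mean[agg$stage_label == to]
  if (m_from <= 0)
    vk_stop("zero_baseline",
            "mean count at stage `%s` is %g: fold change undefined", from,
            m_from)
  fold <- m_to / m_from
  cv2 <- function(s, m) if (is.na(s)) 0 else (s / m)^2
  fold_sd <- fold * sqrt(cv2(agg$sd[agg$stage_label == to], m_to) +
                         cv2(agg$sd[agg$stage_label == from], m_from))
  if (fold_sd == 0) fold_sd <- NA_real_
  structure(list(stages = agg,
                 fold = data.frame(from = from, to = to, fold = fold,
                                   fold_sd = fold_sd)),
            class = "timecourse_summary")
}

#' @export
print.timecourse_summary <- function(x, ...) {
  cat("Per-stage counts (mean ± s.d. across replicates):\n")
  print(x$stages, row.names = FALSE)
  cat(sprintf("Fold change %s -> %s: %.2f%s\n", x$fold$from, x$fold$to,
              x$fold$fold,
              if (is.na(x$fold$fold_sd)) ""
              else sprintf(" ± %.2f", x$fold$fold_sd)))
  invisible(x)
}

#' Compare replicate measurements between groups
#'
#' Thin reporting utility: an unpaired, two-tailed Student's t-test (equal
#' variances) for two groups, or a one-way ANOVA for two or more. When both
#' groups have zero within-group variance the t statistic degenerates: equal
#' means give `t = 0, p = 1`; different means give `t = +/-Inf` with the p
#' value capped at the smallest positive double.
#'
#' @param values Numeric measurements.
#' @param group Group labels, same length as `values`.
#' @param test `"t"` or `"anova"`.
#' @return A one-row data.frame: `test`, `statistic`, `df` (residual df),
#'   `p_value`, `n_groups`.
#' @export
compare_groups <- function(values, group, test = c("t", "anova")) {
  test <- match.arg(test)
  group <- as.factor(group)
  if (length(values) != length(group))
    vk_stop("bad_param", "`values` and `group` must have equal length")
  tab <- table(group)
  if (any(tab < 2))
    vk_stop("too_few_replicates",
            "every group needs at least 2 replicates (got: %s)",
            paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  if (test == "t") {
    if (nlevels(group) != 2L)
      vk_stop("bad_param", "t-test requires exactly 2 groups (got %d)",
              nlevels(group))
    a <- values[group == levels(group)[1]]
    b <- values[group == levels(group)[2]]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (mean(a) == mean(b)) {
        stat <- 0; p <- 1
      } else {
        stat <- sign(mean(a) - mean(b)) * Inf
        p <- .Machine$double.xmin
      }
      df <- length(values) - 2L
    } else {
      fit <- stats::t.test(a, b, var.equal = TRUE)
      stat <- unname(fit$statistic); df <- unname(fit$parameter)
      p <- max(fit$p.value, .Machine$double.xmin)
    }
    data.frame(test = "student_t", statistic = stat, df = df, p_value = p,
               n_groups = 2L)
  } else {
    fit <- stats::aov(values ~ group)
    s <- summary(fit)[[1]]
    data.frame(test = "anova", statistic = s[["F value"]][1],
               df = s[["Df"]][2],
               p_value = max(s[["Pr(>F)"]][1], .Machine$double.xmin),
               n_groups = nlevels(group))
  }
}
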