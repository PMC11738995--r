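# Readers/writers: multi-page TIFF label masks and CSV/TSV cell tables.

#' Read a 3D label mask from a multi-page TIFF
#'
#' Pages are stacked as z-slices in `(z, y, x)` axis order. Labels are read
#' exactly as stored (no rescaling). Float-typed TIFFs are rejected: label
#' masks must be integer exports. The voxel spacing is required and never
#' guessed from metadata.
#'
#' @param path TIFF file path.
#' @param spacing um per voxel along `(z, y, x)`.
#' @return A [label_mask()].
#' @export
read_label_mask <- function(path, spacing) {
  if (missing(spacing) || is.null(spacing))
    vk_stop("missing_spacing",
            "voxel spacing (um per axis, z,y,x) is required and never guessed")
  if (!file.exists(path)) vk_stop("missing_file", "no such file: %s", path)
  raw <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(raw)) raw <- list(raw)
  norm <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(norm)) norm <- list(norm)
  for (k in seq_along(raw)) {
    bits <- attr(raw[[k]], "bits.per.sample") %||% 16L
    recon <- round(norm[[k]] * (2^bits - 1))
    if (any(raw[[k]] < 0) || max(abs(recon - raw[[k]])) > 0.51)
      vk_stop("float_tiff",
              paste("page %d of %s does not contain integer labels",
                    "(float-typed TIFF?); export the segmentation as an",
                    "integer label image"), k, path)
  }
  arr <- aperm(simplify2array(raw), c(3, 1, 2))  # (z, y, x)
  label_mask(arr, spacing)
}

#' Write a 3D label mask to a multi-page TIFF
#'
#' Stores labels as 16-bit pages (z-slices); labels must not exceed 65535.
#' Round trips exactly through [read_label_mask()].
#'
#' @param mask A [label_mask()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask) > 65535L)
    vk_stop("label_overflow", "labels above 65535 cannot be stored as 16-bit")
  pages <- lapply(seq_len(dim(mask)[1]),
                  function(iz) mask[iz, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

REQUIRED_CELL_COLS <- c("cell_id", "x_um", "y_um", "z_um")
KNOWN_FLAG_COLS <- c("edu", "brdu", "ki67", "erg", "prox1", "lineage")

#' Read a cell table from CSV/TSV
#'
#' Expects one row per cell with at least `cell_id`, `x_um`, `y_um`, `z_um`
#' (um). Headers are matched case-insensitively (`"EdU"` is `edu`). Marker
#' flag columns (`edu`, `brdu`, `ki67`, `erg`, `prox1`, `lineage`) are
#' coerced from 0/1 or TRUE/FALSE to logical; a missing `compartment`
#' column defaults to `"unassigned"`. Unknown columns are preserved
#' untouched.
#'
#' @param path CSV (`.csv`) or TSV (`.tsv`/`.txt`) file path.
#' @return A `cell_table` data.frame.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) vk_stop("missing_file", "no such file: %s", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  known <- c(REQUIRED_CELL_COLS, KNOWN_FLAG_COLS, "compartment", "stage_label")
  canon <- match(tolower(names(df)), known)
  names(df)[!is.na(canon)] <- known[canon[!is.na(canon)]]
  missing_cols <- setdiff(REQUIRED_CELL_COLS, names(df))
  if (length(missing_cols))
    vk_stop("missing_column", "cell table %s lacks required column%s: %s",
            path, if (length(missing_cols) > 1) "s" else "",
            paste(missing_cols, collapse = ", "))
  for (col in intersect(KNOWN_FLAG_COLS, names(df))) {
    v <- df[[col]]
    if (!all(v %in% c(0, 1, TRUE, FALSE, NA)))
      vk_stop("bad_flag", "flag column `%s` must be 0/1 or TRUE/FALSE", col)
    df[[col]] <- as.logical(v)
  }
  if (!"compartment" %in% names(df)) df$compartment <- "unassigned"
  if (anyDuplicated(df$cell_id))
    vk_stop("duplicate_ids", "cell_id values must be unique")
  class(df) <- c("cell_table", "data.frame")
  df
}

#' Write a cell table to CSV/TSV
#'
#' Logical flags are written as 0/1; the format follows the file extension
#' (`.tsv`/`.txt` for tab-separated, comma otherwise).
#'
#' @param cells A cell table (data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  out <- as.data.frame(cells)
  for (col in names(out))
    if (is.logical(out[[col]])) out[[col]] <- as.integer(out[[col]])
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
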