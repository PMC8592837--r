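## Tabular I/O and validation ----------------------------------------------
##
## CSV dialect: header row, UTF-8, "." decimal, empty field = missing.
## Coordinates are 0-based pixel centres; no unit conversion at I/O time.

REGION_LEVELS <- c("IT", "PT", "CTRL")
CELL_BASE_COLS <- c("cell_id", "patient_id", "core_id", "region", "x_px", "y_px")

validate_cell_table <- function(cells, flavor) {
  missing_cols <- setdiff(CELL_BASE_COLS, colnames(cells))
  if (length(missing_cols) > 0)
    stop("cell table schema error: missing required column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (flavor == "hne" && !"is_lymphocyte" %in% colnames(cells))
    stop("cell table schema error: missing required column is_lymphocyte (H&E flavor)",
         call. = FALSE)
  markers <- setdiff(colnames(cells), c(CELL_BASE_COLS, "is_lymphocyte", "panel_id"))
  if (flavor == "mihc" && length(markers) == 0)
    stop("cell table schema error: mIHC flavor requires at least one marker intensity column",
         call. = FALSE)
  if (anyDuplicated(cells$cell_id))
    stop("cell table validation error: duplicated cell_id", call. = FALSE)
  bad_region <- setdiff(unique(cells$region), REGION_LEVELS)
  if (length(bad_region) > 0)
    stop("cell table validation error: unknown region label(s) ",
         paste(bad_region, collapse = ", "), call. = FALSE)
  bad_xy <- !is.finite(cells$x_px) | !is.finite(cells$y_px)
  if (any(bad_xy))
    stop(sprintf("cell table validation error: %d row(s) with non-finite coordinates (first: %s)",
                 sum(bad_xy), cells$cell_id[which(bad_xy)[1]]), call. = FALSE)
  attr(cells, "flavor") <- flavor
  attr(cells, "markers") <- markers
  cells
}

#' Read a per-cell table
#'
#' @param path CSV file with columns `cell_id`, `patient_id`, `core_id`,
#'   `region` (IT/PT/CTRL), `x_px`, `y_px`, plus `is_lymphocyte` (H&E
#'   flavor) and/or marker intensity columns (mIHC flavor). Unknown columns
#'   are preserved.
#' @param flavor "hne" (lymphocyte flag required) or "mihc" (at least one
#'   marker column required).
#' @return Validated data.frame with attributes `flavor` and `markers`.
#' @export
read_cell_table <- function(path, flavor = c("hne", "mihc")) {
  flavor <- match.arg(flavor)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("is_lymphocyte" %in% colnames(cells))
    cells$is_lymphocyte <- as.logical(cells$is_lymphocyte)
  validate_cell_table(cells, flavor)
}

#' Write a per-cell table
#' @param cells Cell table data.frame.
#' @param path Output CSV path.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a patient clinical table
#'
#' Requires `patient_id`, `os_time` (days, nonnegative) and `os_event`
#' (0/1); recognised optional columns include `pfs_time`/`pfs_event`,
#' `tumor_stage`, `fuhrman_grade`, `n_metastatic_organs`, `mskcc_class`,
#' `age_years`, `tumor_size`, `necrosis`. One row per patient.
#'
#' @param path CSV path.
#' @return Validated data.frame.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  clin <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "os_time", "os_event")
  missing_cols <- setdiff(req, colnames(clin))
  if (length(missing_cols) > 0)
    stop("clinical table schema error: missing required column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(clin$patient_id))
    stop("clinical table validation error: duplicated patient_id", call. = FALSE)
  if (any(clin$os_time < 0, na.rm = TRUE))
    stop("clinical table validation error: negative os_time", call. = FALSE)
  if (!all(clin$os_event %in% c(0, 1, NA)))
    stop("clinical table validation error: os_event must be 0/1", call. = FALSE)
  clin
}

#' Read a binary patient-by-gene mutation table
#'
#' First column `patient_id`, remaining columns one gene each with values
#' 0 (wild-type), 1 (somatic alteration) or empty (missing call).
#'
#' @param path CSV path.
#' @return Validated data.frame.
#' @export
read_mutation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  mut <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% colnames(mut))
    stop("mutation table schema error: missing required column patient_id", call. = FALSE)
  if (anyDuplicated(mut$patient_id))
    stop("mutation table validation error: duplicated patient_id", call. = FALSE)
  genes <- setdiff(colnames(mut), "patient_id")
  for (g in genes) {
    if (!all(mut[[g]] %in% c(0, 1, NA)))
      stop(sprintf("mutation table validation error: gene %s has values outside {0,1,NA}", g),
           call. = FALSE)
  }
  mut
}

#' Write clinical / mutation tables
#' @param x Table to write.
#' @param path Output CSV path.
#' @rdname write_cell_table
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Drop tissue cores with too few detected cells
#'
#' Cores with fewer than `min_cells` cells are eliminated before any
#' downstream analysis; cell counts are taken across all regions of a core
#' by default (set `per_region = TRUE` to filter each core-region
#' separately).
#'
#' @param cells Cell table.
#' @param min_cells Minimum cell count for a core to be retained
#'   (default 1500).
#' @param per_region Apply the threshold per core-region instead of per
#'   core.
#' @return List with `cells` (retained rows) and `dropped` (character
#'   vector of eliminated core ids, or core/region ids).
#' @export
filter_low_cellularity <- function(cells, min_cells = 1500, per_region = FALSE) {
  if (nrow(cells) == 0)
    return(list(cells = cells, dropped = character(0)))
  key <- if (per_region) paste(cells$core_id, cells$region, sep = ":") else cells$core_id
  counts <- table(key)
  dropped <- names(counts)[counts < min_cells]
  keep <- !(key %in% dropped)
  list(cells = cells[keep, , drop = FALSE], dropped = dropped)
}
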