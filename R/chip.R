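#' Assemble a chip dataset
#'
#' A chip dataset holds every microchamber of one SCBC run: the chamber
#' bookkeeping table (id, grid position, bright-field cell count), the raw
#' fluorescence intensity matrix (chambers x analytes, arbitrary units), and
#' per-analyte saturation flags. At least one zero-cell chamber is required,
#' because the assay background is defined by zero-cell chambers.
#'
#' @param chip_id Chip identifier.
#' @param panel An [analyte_panel()].
#' @param condition A [cohort_condition()].
#' @param chambers data.frame with columns `chamber_id`, `row`, `col`,
#'   `cell_count` (0-based integer grid coordinates, row-major).
#' @param intensity Numeric matrix, one row per chamber, one column per panel
#'   analyte (column order = panel order).
#' @param saturated Logical matrix of the same shape, or `NULL` to derive the
#'   flags as `intensity >= saturation_ceiling`.
#' @param saturation_ceiling Scanner ceiling in AU (default 65535, a 16-bit
#'   detector); values at or above it are treated as censored.
#' @return An object of class `scbc_chip`.
#' @export
chip_dataset <- function(chip_id, panel, condition, chambers, intensity,
                         saturated = NULL, saturation_ceiling = 65535) {
  stopifnot(inherits(panel, "scbc_panel"), inherits(condition, "scbc_condition"))
  chambers <- as.data.frame(chambers)
  needed <- c("chamber_id", "row", "col", "cell_count")
  miss <- setdiff(needed, names(chambers))
  if (length(miss)) {
    stop_format(paste0("chamber table lacks column(s): ",
                       paste(miss, collapse = ", ")))
  }
  chambers <- chambers[needed]
  if (anyDuplicated(chambers$chamber_id)) {
    dup <- unique(chambers$chamber_id[duplicated(chambers$chamber_id)])
    stop_integrity(paste0("duplicate chamber_id: ",
                          paste(dup, collapse = ", ")))
  }
  cc <- chambers$cell_count
  if (anyNA(cc) || any(cc < 0) || any(cc != as.integer(cc))) {
    stop_integrity("cell counts must be non-negative integers")
  }
  chambers$cell_count <- as.integer(cc)
  chambers$chamber_id <- as.integer(chambers$chamber_id)
  chambers$row <- as.integer(chambers$row)
  chambers$col <- as.integer(chambers$col)
  if (any(chambers$row < 0L) || any(chambers$col < 0L)) {
    stop_integrity("grid coordinates must be non-negative (0-based)")
  }

  intensity <- as.matrix(intensity)
  if (nrow(intensity) != nrow(chambers) || ncol(intensity) != panel$size) {
    stop_integrity("intensity matrix shape does not match chambers x panel")
  }
  if (!all(is.finite(intensity)) || any(intensity < 0)) {
    stop_integrity("raw intensities must be finite and non-negative")
  }
  colnames(intensity) <- panel$names
  rownames(intensity) <- NULL

  if (is.null(saturated)) {
    saturated <- intensity >= saturation_ceiling
  } else {
    saturated <- as.matrix(saturated)
    if (!identical(dim(saturated), dim(intensity))) {
      stop_integrity("saturated flag matrix shape mismatch")
    }
    storage.mode(saturated) <- "logical"
  }
  colnames(saturated) <- panel$names
  rownames(saturated) <- NULL

  if (!any(chambers$cell_count == 0L)) {
    stop_integrity(
      "dataset has no 0-cell chamber; background fitting is impossible")
  }

  structure(
    list(chip_id = as.character(chip_id), panel = panel,
         condition = condition, chambers = chambers,
         intensity = intensity, saturated = saturated,
         saturation_ceiling = as.numeric(saturation_ceiling)),
    class = "scbc_chip"
  )
}

#' @export
print.scbc_chip <- function(x, ...) {
  occ <- table(x$chambers$cell_count)
  cat(sprintf("<scbc_chip> %s (%s): %d chambers, %d analytes\n",
              x$chip_id, x$condition$label, nrow(x$chambers), x$panel$size))
  cat("  occupancy:",
      paste(sprintf("%s-cell: %d", names(occ), occ), collapse = ", "), "\n")
  invisible(x)
}

#' Number of chambers on a chip
#' @param dataset An `scbc_chip`.
#' @return Integer chamber count.
#' @export
n_chambers <- function(dataset) nrow(dataset$chambers)

#' Partition a chip by chamber occupancy
#'
#' Splits chambers by bright-field cell count. Downstream single-cell
#' statistics use only the 1-cell class; the 0-cell class feeds background
#' fitting; classes with two or more cells are retained for QC only and are
#' never mixed into single-cell statistics.
#'
#' @param dataset An `scbc_chip`.
#' @return Named list keyed by occupancy ("0", "1", ...), each element a
#'   data.frame of chamber rows with the per-analyte raw intensities appended.
#' @export
partition_by_occupancy <- function(dataset) {
  stopifnot(inherits(dataset, "scbc_chip"))
  full <- cbind(dataset$chambers, as.data.frame(dataset$intensity))
  idx <- split(seq_len(nrow(full)), dataset$chambers$cell_count)
  lapply(idx, function(i) full[i, , drop = FALSE])
}

# Row indices of chambers with a given occupancy.
occupancy_index <- function(dataset, k) {
  which(dataset$chambers$cell_count == k)
}

# Zero-cell, non-saturated raw intensities for one analyte.
background_values <- function(dataset, analyte) {
  i <- occupancy_index(dataset, 0L)
  v <- dataset$intensity[i, analyte]
  sat <- dataset$saturated[i, analyte]
  list(values = v[!sat], rows = dataset$chambers$row[i][!sat],
       cols = dataset$chambers$col[i][!sat])
}
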