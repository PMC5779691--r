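#' Describe a cohort condition
#'
#' A condition records the experimental design around one chip: the bulk
#' priming window `T1_hours` (cells interacting in culture under molecular
#' stimulation), the on-chip secretion window `T2_hours` (single cells
#' isolated in microchambers, over which captured signal accumulates and by
#' which rates are normalized), the stimulation regimen, and optionally the
#' loading cell density. When the design holds the total stimulation time
#' T = T1 + T2 constant, pass `total_hours` and the sum is checked.
#'
#' @param label Condition label, unique within a cohort.
#' @param T1_hours Priming duration in hours (>= 0).
#' @param T2_hours On-chip secretion window in hours (> 0).
#' @param stimulation Free-text stimulation descriptor.
#' @param cell_density Loading density in cells/ml, or `NA`.
#' @param total_hours If given, `T1_hours + T2_hours` must equal it (1e-9).
#' @return An object of class `scbc_condition`.
#' @export
cohort_condition <- function(label, T1_hours, T2_hours,
                             stimulation = "unspecified",
                             cell_density = NA_real_,
                             total_hours = NULL) {
  T1_hours <- as.numeric(T1_hours)
  T2_hours <- as.numeric(T2_hours)
  if (!is.finite(T1_hours) || T1_hours < 0) {
    stop_domain("T1_hours must be a non-negative number")
  }
  if (!is.finite(T2_hours) || T2_hours <= 0) {
    stop_domain("T2_hours must be a positive number")
  }
  if (!is.null(total_hours) &&
      abs(T1_hours + T2_hours - total_hours) > 1e-9) {
    stop_domain(sprintf(
      "T1 + T2 = %g does not match the declared total time %g",
      T1_hours + T2_hours, total_hours))
  }
  structure(
    list(label = as.character(label), T1_hours = T1_hours,
         T2_hours = T2_hours, stimulation = as.character(stimulation),
         cell_density = as.numeric(cell_density)),
    class = "scbc_condition"
  )
}

#' @export
print.scbc_condition <- function(x, ...) {
  cat(sprintf("<scbc_condition> %s: T1 = %g h, T2 = %g h, stim = %s\n",
              x$label, x$T1_hours, x$T2_hours, x$stimulation))
  invisible(x)
}
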