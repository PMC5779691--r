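#' Define an analyte panel
#'
#' An analyte panel names the proteins captured by the antibody-barcode array
#' and maps each analyte to its barcode stripe position. Background is
#' estimated per stripe, so the stripe map travels with the panel.
#'
#' @param names Character vector of unique analyte identifiers, in panel order.
#' @param stripe_index Non-negative integer stripe position for each analyte;
#'   defaults to `0:(length(names) - 1)` (panel order equals stripe order).
#' @return An object of class `scbc_panel` with fields `names`, `size` and
#'   `stripe_index` (named integer vector).
#' @examples
#' p <- analyte_panel(c("IL2", "CCL3", "IFNg"))
#' p$size
#' @export
analyte_panel <- function(names, stripe_index = seq_along(names) - 1L) {
  names <- as.character(names)
  if (length(names) < 1L) stop_domain("panel must contain at least one analyte")
  if (anyDuplicated(names)) stop_domain("analyte names must be unique")
  stripe_index <- as.integer(stripe_index)
  if (length(stripe_index) != length(names) || anyNA(stripe_index) ||
      any(stripe_index < 0L)) {
    stop_domain("every analyte needs exactly one non-negative stripe index")
  }
  names(stripe_index) <- names
  structure(
    list(names = names, size = length(names), stripe_index = stripe_index),
    class = "scbc_panel"
  )
}

#' Default 11-plex T-cell secretion panel
#'
#' A configurable default: the assay measures 11 secreted proteins per cell.
#' IL2, CCL3, CCL4, IFN-gamma and TNF-alpha are the analytes discussed in the
#' analyses shipped with this package; the remaining six entries are
#' placeholder names for a typical effector T-cell panel and should be
#' replaced with the panel actually printed on the chip in use.
#'
#' @return An `scbc_panel` of size 11.
#' @export
default_panel <- function() {
  analyte_panel(c(
    "IL2", "CCL3", "CCL4", "IFNg", "TNFa",
    "IL6", "IL10", "IL17A", "GMCSF", "GranzymeB", "Perforin"
  ))
}

#' @export
print.scbc_panel <- function(x, ...) {
  cat("<scbc_panel> ", x$size, " analytes: ",
      paste(x$names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

same_panel <- function(a, b) {
  identical(a$names, b$names) && identical(a$stripe_index, b$stripe_index)
}
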