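#' Call secretion for every single-cell chamber
#'
#' Converts the raw intensities of 1-cell chambers into boolean secretion
#' calls and time-normalized net rates. For each cell and analyte:
#' \itemize{
#'   \item `call`: raw intensity strictly above the analyte's cutoff
#'     (`mu + 2 * sigma`); ties at the cutoff are negative. Saturated
#'     analytes are called positive and keep their flag.
#'   \item `net`: `max(raw - mu, 0)` — background-mean subtraction clamped
#'     at zero (any gradient correction is assumed already applied to the
#'     dataset the models were fitted on).
#'   \item `rate`: `net / T2_hours`, the secretion rate in AU per hour over
#'     the on-chip secretion window.
#' }
#' Chambers with zero or multiple cells never enter the table: every
#' downstream statistic here is a single-cell quantity.
#'
#' @param dataset An `scbc_chip` (gradient-corrected if applicable).
#' @param models Named list of [fit_background()] models covering exactly
#'   the panel analytes.
#' @return An object of class `scbc_calls` with matrices `call`, `net`,
#'   `rate`, `saturated` (cells x analytes), `chamber_id`, the condition
#'   and the panel.
#' @export
call_secretion <- function(dataset, models) {
  stopifnot(inherits(dataset, "scbc_chip"))
  panel <- dataset$panel
  if (!setequal(names(models), panel$names)) {
    stop_integrity("background models do not match the panel analytes")
  }
  T2 <- dataset$condition$T2_hours
  if (!is.finite(T2) || T2 <= 0) stop_domain("T2_hours must be positive")

  mu <- vapply(panel$names, function(a) models[[a]]$mu, numeric(1))
  cutoff <- vapply(panel$names, function(a) models[[a]]$cutoff, numeric(1))

  idx <- occupancy_index(dataset, 1L)
  raw <- dataset$intensity[idx, , drop = FALSE]
  sat <- dataset$saturated[idx, , drop = FALSE]

  cut_m <- matrix(cutoff, nrow(raw), panel$size, byrow = TRUE)
  mu_m <- matrix(mu, nrow(raw), panel$size, byrow = TRUE)
  call <- (raw > cut_m) | sat
  net <- pmax(raw - mu_m, 0)
  rate <- net / T2

  structure(list(
    condition = dataset$condition, panel = panel,
    chamber_id = dataset$chambers$chamber_id[idx],
    call = call, net = net, rate = rate, saturated = sat,
    n_cells = length(idx)
  ), class = "scbc_calls")
}

#' @export
print.scbc_calls <- function(x, ...) {
  cat(sprintf("<scbc_calls> %s: %d single cells x %d analytes\n",
              x$condition$label, x$n_cells, x$panel$size))
  invisible(x)
}

#' Fraction of cells with detectable secretion
#'
#' Fraction of single cells whose number of positive per-analyte calls is at
#' least `min_k`. `min_k = 1` gives the detectable-secretion fraction;
#' `min_k = 2` the polyfunctional fraction.
#'
#' @param table An `scbc_calls`.
#' @param min_k Positive integer call-count threshold.
#' @return Fraction in [0, 1].
#' @export
fraction_secreting <- function(table, min_k = 1L) {
  stopifnot(inherits(table, "scbc_calls"))
  if (table$n_cells < 1L) stop_empty("secretion call table is empty")
  min_k <- as.integer(min_k)
  if (min_k < 1L) stop_domain("min_k must be a positive integer")
  mean(rowSums(table$call) >= min_k)
}

#' Per-cell positive-call counts
#' @param table An `scbc_calls`.
#' @return Integer vector, one count per cell.
#' @export
call_counts <- function(table) {
  stopifnot(inherits(table, "scbc_calls"))
  as.integer(rowSums(table$call))
}
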