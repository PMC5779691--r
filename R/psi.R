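#' Polyfunctionality histogram
#'
#' Counts single cells by k, the number of distinct proteins each secretes
#' above its per-analyte cutoff, for k = 0..panel size.
#'
#' @param table An `scbc_calls`.
#' @return data.frame with columns `k`, `n`, `fraction`; fractions sum to 1.
#' @export
polyfunction_histogram <- function(table) {
  stopifnot(inherits(table, "scbc_calls"))
  if (table$n_cells < 1L) stop_empty("secretion call table is empty")
  k <- call_counts(table)
  ks <- 0:table$panel$size
  n <- vapply(ks, function(x) sum(k == x), integer(1))
  data.frame(k = ks, n = n, fraction = n / table$n_cells)
}

#' Polyfunctional strength index (pSI) profile
#'
#' The pSI of stratum k is the fraction of cells secreting exactly k
#' distinct proteins multiplied by the mean total secreted intensity of
#' those cells, where a cell's total is the sum of its T2-normalized net
#' rates over its positively-called analytes only. The total index sums the
#' strata with k >= 1; cells with no calls contribute nothing. Internal
#' computation keeps exact k; pooled "3 or more" display bins are a
#' reporting view (see [psi_display_bins()]).
#'
#' @param table An `scbc_calls` (rates already T2-normalized).
#' @param use_rates If `FALSE`, raw net intensities (AU) are used instead of
#'   rates (AU/h) — a sensitivity mode; the default follows the
#'   time-normalized definition.
#' @return An object of class `scbc_profile`: `condition`, `panel`,
#'   `n_cells`, `per_k` (k, n, fraction, mean_total_rate, psi), `psi_total`,
#'   `per_analyte_psi` (call-gated decomposition summing to `psi_total`),
#'   `per_analyte_mean_rate` and `per_analyte_median_rate` (ungated ensemble
#'   rates over all single cells, used for fold changes).
#' @export
compute_psi <- function(table, use_rates = TRUE) {
  stopifnot(inherits(table, "scbc_calls"))
  if (table$n_cells < 1L) stop_empty("secretion call table is empty")
  hist <- polyfunction_histogram(table)
  val <- if (use_rates) table$rate else table$net
  gated <- val * table$call
  total_per_cell <- rowSums(gated)
  k <- call_counts(table)

  mean_total <- vapply(hist$k, function(kk) {
    cells <- k == kk
    if (!any(cells)) 0 else mean(total_per_cell[cells])
  }, numeric(1))
  psi_k <- hist$fraction * mean_total
  psi_k[hist$k == 0] <- 0
  per_k <- cbind(hist, mean_total_rate = mean_total, psi = psi_k)

  structure(list(
    condition = table$condition, panel = table$panel,
    n_cells = table$n_cells, per_k = per_k,
    psi_total = sum(psi_k),
    per_analyte_psi = colSums(gated) / table$n_cells,
    per_analyte_mean_rate = colMeans(val),
    per_analyte_median_rate = apply(val, 2, stats::median)
  ), class = "scbc_profile")
}

#' @export
print.scbc_profile <- function(x, ...) {
  cat(sprintf("<scbc_profile> %s: %d cells, pSI total = %.3f\n",
              x$condition$label, x$n_cells, x$psi_total))
  print(x$per_k, row.names = FALSE)
  invisible(x)
}

#' Per-analyte pSI decomposition
#'
#' Splits the total pSI by analyte: each analyte's share is the mean (over
#' all single cells) of its call-gated rate. The decomposition sums to
#' `psi_total` exactly, because the per-k stratification and the per-analyte
#' split are two marginalizations of the same cell x analyte gated-rate sum.
#'
#' @param table An `scbc_calls`.
#' @param use_rates As in [compute_psi()].
#' @return Named numeric vector, one contribution per analyte.
#' @export
psi_by_analyte <- function(table, use_rates = TRUE) {
  stopifnot(inherits(table, "scbc_calls"))
  if (table$n_cells < 1L) stop_empty("secretion call table is empty")
  val <- if (use_rates) table$rate else table$net
  colSums(val * table$call) / table$n_cells
}

#' Pooled display bins for pSI reporting
#'
#' Reporting view pooling k >= `pool_from` into one "or more" stratum, as
#' polyfunctionality figures conventionally show 1, 2, 3+ strata.
#'
#' @param profile An `scbc_profile`.
#' @param pool_from Pool strata with k at or above this value (default 3).
#' @return data.frame with columns `stratum`, `n`, `fraction`, `psi`.
#' @export
psi_display_bins <- function(profile, pool_from = 3L) {
  stopifnot(inherits(profile, "scbc_profile"))
  pk <- profile$per_k
  keep <- pk$k < pool_from & pk$k > 0
  pooled <- pk$k >= pool_from
  out <- data.frame(
    stratum = c(as.character(pk$k[keep]), paste0(pool_from, "+")),
    n = c(pk$n[keep], sum(pk$n[pooled])),
    fraction = c(pk$fraction[keep], sum(pk$fraction[pooled])),
    psi = c(pk$psi[keep], sum(pk$psi[pooled]))
  )
  out
}
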