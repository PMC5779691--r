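#' Compare polyfunctional profiles across conditions
#'
#' Builds a cohort summary table (one row per condition: cell count,
#' detectable fraction, polyfunctional fraction, total pSI, total ensemble
#' rate) and per-analyte fold changes between every ordered condition pair.
#' Fold changes are ratios of ensemble mean net rates over all single cells
#' (medians via `stat = "median"`); a pseudo-analyte `"total"` carries the
#' ratio of summed per-analyte rates. A zero denominator yields an
#' undefined (NA) fold flagged `defined = FALSE`, never an infinity.
#'
#' @param profiles List of `scbc_profile` sharing one panel (>= 2).
#' @param stat `"mean"` (default) or `"median"` ensemble rate.
#' @return An object of class `scbc_summary`: `summary` data.frame,
#'   `fold_changes` data.frame (`from`, `to`, `analyte`, `fold`, `defined`),
#'   and `per_analyte` rate matrix (conditions x analytes).
#' @export
compare_conditions <- function(profiles, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (length(profiles) < 2L) {
    stop_domain("need at least two profiles to compare")
  }
  panel <- profiles[[1]]$panel
  for (p in profiles) {
    stopifnot(inherits(p, "scbc_profile"))
    if (!same_panel(p$panel, panel)) {
      stop_integrity("profiles use different analyte panels")
    }
  }
  labels <- unname(vapply(profiles, function(p) p$condition$label,
                          character(1)))

  rate_field <- if (stat == "mean") "per_analyte_mean_rate" else
    "per_analyte_median_rate"
  rates <- do.call(rbind, lapply(profiles, function(p) p[[rate_field]]))
  rownames(rates) <- labels

  frac_ge <- function(p, k) sum(p$per_k$fraction[p$per_k$k >= k])
  col <- function(f, ...) unname(vapply(profiles, f, numeric(1), ...))
  summary <- data.frame(
    condition = unname(labels),
    T1_hours = col(function(p) p$condition$T1_hours),
    T2_hours = col(function(p) p$condition$T2_hours),
    n_cells = col(function(p) p$n_cells),
    fraction_secreting = col(frac_ge, k = 1),
    fraction_polyfunctional = col(frac_ge, k = 2),
    psi_total = col(function(p) p$psi_total),
    total_rate = unname(rowSums(rates))
  )

  fc <- list()
  analytes <- c(panel$names, "total")
  totals <- rowSums(rates)
  for (i in seq_along(profiles)) for (j in seq_along(profiles)) {
    if (i == j) next
    num <- c(rates[j, ], totals[j])
    den <- c(rates[i, ], totals[i])
    defined <- den > 0
    fold <- ifelse(defined, num / den, NA_real_)
    fc[[length(fc) + 1L]] <- data.frame(
      from = labels[i], to = labels[j], analyte = analytes,
      fold = unname(fold), defined = unname(defined))
  }
  fold_changes <- do.call(rbind, fc)
  rownames(fold_changes) <- NULL

  structure(list(summary = summary, fold_changes = fold_changes,
                 per_analyte = rates, stat = stat),
            class = "scbc_summary")
}

#' @export
print.scbc_summary <- function(x, ...) {
  cat("<scbc_summary>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Look up one fold change from a cohort summary
#'
#' @param summary An `scbc_summary`.
#' @param from,to Condition labels (denominator, numerator).
#' @param analyte Analyte name, or `"total"` for summed rates.
#' @return The fold change (possibly `NA` if undefined).
#' @export
fold_change <- function(summary, from, to, analyte = "total") {
  stopifnot(inherits(summary, "scbc_summary"))
  fc <- summary$fold_changes
  row <- fc[fc$from == from & fc$to == to & fc$analyte == analyte, ]
  if (nrow(row) != 1L) stop_domain("no such condition pair / analyte")
  row$fold
}

#' Per-analyte composition of the secretion signal
#'
#' Share of each analyte in the condition's summed ensemble mean rate.
#' Scale-invariant: multiplying all rates by a constant leaves it unchanged.
#'
#' @param profile An `scbc_profile` with `psi_total > 0`.
#' @return Named fractions summing to 1.
#' @export
secretion_composition <- function(profile) {
  stopifnot(inherits(profile, "scbc_profile"))
  if (profile$psi_total <= 0) {
    stop_empty_signal("no secretion signal to decompose (psi_total is 0)")
  }
  r <- profile$per_analyte_mean_rate
  r / sum(r)
}

#' Embed and cluster single-cell secretion profiles
#'
#' Principal-component embedding of the cells x analytes rate matrix
#' (log1p-transformed by default — secretion rates are heavy-tailed —
#' then column-centered), followed by k-means clustering on the retained
#' components. Deterministic under a fixed seed; the caller's RNG state is
#' untouched. Degenerate inputs (all cells identical) return a zero
#' embedding and a single cluster.
#'
#' @param table An `scbc_calls`.
#' @param n_components Number of principal components (<= panel size).
#' @param n_clusters Number of k-means clusters (<= number of cells).
#' @param log_transform Apply `log1p` before PCA (default `TRUE`).
#' @param seed Integer seed for k-means initialization.
#' @return List with `embedding` (cells x components), `cluster` (integer
#'   labels), `variance_explained`.
#' @export
embed_and_cluster <- function(table, n_components = 2L, n_clusters = 2L,
                              log_transform = TRUE, seed = 1L) {
  stopifnot(inherits(table, "scbc_calls"))
  P <- table$panel$size
  if (n_components > P) {
    stop_domain("n_components exceeds the panel size")
  }
  if (table$n_cells < n_clusters) {
    stop_domain("need at least n_clusters cells")
  }
  X <- table$rate
  if (!all(is.finite(X))) stop_domain("rates must be finite")
  if (log_transform) X <- log1p(X)

  if (all(apply(X, 2, stats::sd) < .Machine$double.eps^0.5)) {
    return(list(
      embedding = matrix(0, table$n_cells, n_components),
      cluster = rep(1L, table$n_cells),
      variance_explained = rep(0, n_components)))
  }

  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ncomp <- min(n_components, ncol(pc$x))
  emb <- pc$x[, seq_len(ncomp), drop = FALSE]
  if (ncomp < n_components) {
    emb <- cbind(emb, matrix(0, nrow(emb), n_components - ncomp))
  }
  ve <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]
  ve[is.na(ve)] <- 0

  n_distinct <- nrow(unique(emb))
  k_eff <- min(n_clusters, n_distinct)
  labels <- with_seed(seed, {
    if (k_eff < 2L) {
      rep(1L, nrow(emb))
    } else {
      km <- stats::kmeans(emb, centers = k_eff, nstart = 10L,
                          iter.max = 100L)
      as.integer(km$cluster)
    }
  })
  list(embedding = emb, cluster = labels, variance_explained = ve)
}

#' Run the full single-chip pipeline
#'
#' Gradient correction (per analyte, applied only where the zero-cell trend
#' is significant), background fitting, secretion calling and pSI profiling
#' for one chip.
#'
#' @param dataset An `scbc_chip`.
#' @param correct_gradient Run [correct_all_gradients()] first (default
#'   `TRUE`).
#' @param gradient_p Slope significance gate (default 0.01).
#' @param min_background Minimum usable zero-cell chambers (default 30).
#' @param quiet Suppress advisory KS warnings (default `TRUE`).
#' @return List with `dataset` (as analyzed), `models`, `gradient_report`,
#'   `calls`, `profile`.
#' @export
run_chip_pipeline <- function(dataset, correct_gradient = TRUE,
                              gradient_p = 0.01, min_background = 30,
                              quiet = TRUE) {
  gradient_report <- NULL
  if (correct_gradient) {
    g <- correct_all_gradients(dataset, p_threshold = gradient_p,
                               min_n = min_background)
    dataset <- g$dataset
    gradient_report <- g$report
  }
  fit <- function() fit_background_all(dataset, min_n = min_background)
  models <- if (quiet) suppressWarnings(fit()) else fit()
  if (!is.null(gradient_report)) {
    for (i in seq_len(nrow(gradient_report))) {
      a <- gradient_report$analyte[i]
      models[[a]]$gradient_slope <- gradient_report$slope[i]
      models[[a]]$gradient_applied <- gradient_report$corrected[i]
    }
  }
  calls <- call_secretion(dataset, models)
  profile <- compute_psi(calls)
  list(dataset = dataset, models = models,
       gradient_report = gradient_report, calls = calls, profile = profile)
}
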