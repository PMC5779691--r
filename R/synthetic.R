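# Run expr under a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Recycle a scalar or named/unnamed vector to one value per panel analyte.
per_analyte <- function(x, panel, what) {
  if (length(x) == 1L) {
    out <- rep(as.numeric(x), panel$size)
  } else if (!is.null(names(x))) {
    miss <- setdiff(panel$names, names(x))
    if (length(miss)) {
      stop_config(paste0(what, " missing analyte(s): ",
                         paste(miss, collapse = ", ")))
    }
    out <- as.numeric(x[panel$names])
  } else if (length(x) == panel$size) {
    out <- as.numeric(x)
  } else {
    stop_config(paste0(what, " must be scalar or one value per analyte"))
  }
  names(out) <- panel$names
  out
}

#' Configure a synthetic chip
#'
#' Defines the generative model for one simulated SCBC chip:
#' \itemize{
#'   \item Occupancy: either an explicit map of cell count to chamber count
#'     (default `c("0" = 300, "1" = 400, "2" = 350, "3" = 200)`, the typical
#'     loading of a ~1500-chamber chip) or Poisson loading
#'     (`poisson_lambda` cells/chamber over `n_chambers`).
#'   \item Background: per-stripe Gaussian `N(mu_b + gradient_slope * row,
#'     sigma_b)`; the default exemplar is `N(106, 16.2)` AU.
#'   \item Secretion: a cell is a secretor with probability
#'     `secreting_fraction`; a secretor secretes each analyte independently
#'     with probability `analyte_activity[analyte]`. The per-hour secreted
#'     amplitude is lognormal(`signal_meanlog`, `signal_sdlog`); when
#'     `coupling` is on, the log-mean gains `coupling_delta` per additional
#'     secreted analyte, so polyfunctional cells carry the highest signals.
#'     Chamber net signal is the amplitude summed over that chamber's cells
#'     and scaled by the condition's secretion window T2.
#'   \item Detector: intensities clip at `saturation_ceiling` and the
#'     saturation flag is set.
#' }
#'
#' @param panel An [analyte_panel()].
#' @param occupancy Named integer vector mapping cell count to number of
#'   chambers, or `NULL` to use Poisson loading.
#' @param poisson_lambda,n_chambers Poisson loading parameters (used only
#'   when `occupancy` is `NULL`).
#' @param background_mean,background_sd Stripe background Gaussian (AU);
#'   scalar or per-analyte.
#' @param gradient_slope Background drift in AU per row index; scalar or
#'   per-analyte; 0 disables the gradient.
#' @param secreting_fraction Probability a cell is a secretor, in [0, 1].
#' @param analyte_activity Conditional probability a secretor secretes each
#'   analyte; scalar or per-analyte.
#' @param signal_meanlog,signal_sdlog Lognormal parameters of the per-hour
#'   net secreted amplitude (AU/h); scalar or per-analyte.
#' @param coupling Logical; couple signal amplitude to polyfunctionality.
#' @param coupling_delta Log-units added to `signal_meanlog` per extra
#'   secreted analyte (default 0.5).
#' @param saturation_ceiling Detector ceiling in AU.
#' @param n_cols Chamber grid width used to lay chambers out row-major.
#' @param seed Integer seed used by [generate_chip()] unless overridden.
#' @return An object of class `scbc_config`.
#' @export
synthetic_chip_config <- function(panel = default_panel(),
                                  occupancy = c("0" = 300, "1" = 400,
                                                "2" = 350, "3" = 200),
                                  poisson_lambda = NULL,
                                  n_chambers = NULL,
                                  background_mean = 106,
                                  background_sd = 16.2,
                                  gradient_slope = 0,
                                  secreting_fraction = 0.2,
                                  analyte_activity = 0.3,
                                  signal_meanlog = log(5),
                                  signal_sdlog = 0.5,
                                  coupling = TRUE,
                                  coupling_delta = 0.5,
                                  saturation_ceiling = 65535,
                                  n_cols = 30,
                                  seed = 1L) {
  stopifnot(inherits(panel, "scbc_panel"))
  if (is.null(occupancy)) {
    if (is.null(poisson_lambda) || is.null(n_chambers)) {
      stop_config("give either an explicit occupancy map or poisson_lambda + n_chambers")
    }
    if (poisson_lambda <= 0) stop_config("poisson_lambda must be positive")
    if (n_chambers < 1) stop_config("n_chambers must be >= 1")
  } else {
    occupancy <- round(occupancy)
    if (is.null(names(occupancy)) || anyNA(suppressWarnings(
      as.integer(names(occupancy))))) {
      stop_config("occupancy must be named by cell count, e.g. c('0'=300, ...)")
    }
    if (any(occupancy < 0) || sum(occupancy) < 1) {
      stop_config("occupancy counts must be non-negative and sum to >= 1")
    }
  }
  sf <- secreting_fraction
  if (!is.finite(sf) || sf < 0 || sf > 1) {
    stop_config("secreting_fraction must lie in [0, 1]")
  }
  act <- per_analyte(analyte_activity, panel, "analyte_activity")
  if (any(act < 0) || any(act > 1)) {
    stop_config("analyte_activity must lie in [0, 1]")
  }
  sd_b <- per_analyte(background_sd, panel, "background_sd")
  if (any(sd_b <= 0)) stop_config("background_sd must be positive")
  sdl <- per_analyte(signal_sdlog, panel, "signal_sdlog")
  if (any(sdl <= 0)) stop_config("signal_sdlog must be positive")
  if (saturation_ceiling <= 0) stop_config("saturation_ceiling must be positive")

  structure(list(
    panel = panel, occupancy = occupancy,
    poisson_lambda = poisson_lambda, n_chambers = n_chambers,
    background_mean = per_analyte(background_mean, panel, "background_mean"),
    background_sd = sd_b,
    gradient_slope = per_analyte(gradient_slope, panel, "gradient_slope"),
    secreting_fraction = sf,
    analyte_activity = act,
    signal_meanlog = per_analyte(signal_meanlog, panel, "signal_meanlog"),
    signal_sdlog = sdl,
    coupling = isTRUE(coupling),
    coupling_delta = as.numeric(coupling_delta),
    saturation_ceiling = as.numeric(saturation_ceiling),
    n_cols = as.integer(n_cols),
    seed = as.integer(seed)
  ), class = "scbc_config")
}

#' Generate one synthetic chip
#'
#' Draws a [chip_dataset()] from the generative model in `config` under the
#' given condition. Identical `(config, condition, seed)` triples produce
#' bitwise-identical datasets; the caller's RNG state is left untouched.
#'
#' @param config An [synthetic_chip_config()].
#' @param condition A [cohort_condition()]; its `T2_hours` scales the
#'   secreted signal.
#' @param seed Integer seed (defaults to `config$seed`).
#' @param chip_id Chip identifier.
#' @return An `scbc_chip`.
#' @export
generate_chip <- function(config, condition, seed = config$seed,
                          chip_id = paste0("sim_", condition$label)) {
  stopifnot(inherits(config, "scbc_config"),
            inherits(condition, "scbc_condition"))
  panel <- config$panel
  P <- panel$size
  with_seed(seed, {
    # chamber occupancies, shuffled over the grid
    if (is.null(config$occupancy)) {
      counts <- stats::rpois(config$n_chambers, config$poisson_lambda)
    } else {
      counts <- rep(as.integer(names(config$occupancy)),
                    times = config$occupancy)
      counts <- sample(counts)
    }
    n <- length(counts)
    rows <- (seq_len(n) - 1L) %/% config$n_cols
    cols <- (seq_len(n) - 1L) %% config$n_cols

    # per-stripe Gaussian background with optional row gradient
    inten <- matrix(0, n, P, dimnames = list(NULL, panel$names))
    for (j in seq_len(P)) {
      mu_j <- config$background_mean[j] + config$gradient_slope[j] * rows
      inten[, j] <- stats::rnorm(n, mu_j, config$background_sd[j])
    }
    inten[inten < 0] <- 0

    # per-cell secretion, summed within chambers
    total_cells <- sum(counts)
    if (total_cells > 0) {
      chamber_of <- rep.int(seq_len(n), counts)
      secretor <- stats::rbinom(total_cells, 1L, config$secreting_fraction)
      secrete <- matrix(stats::rbinom(total_cells * P, 1L,
                                      rep(config$analyte_activity,
                                          each = total_cells)),
                        total_cells, P)
      secrete <- secrete * secretor
      m <- rowSums(secrete)
      delta <- if (config$coupling) config$coupling_delta else 0
      for (j in seq_len(P)) {
        active <- secrete[, j] == 1L
        if (any(active)) {
          amp <- stats::rlnorm(sum(active),
                               config$signal_meanlog[j] +
                                 delta * (m[active] - 1),
                               config$signal_sdlog[j])
          add <- rowsum(amp * condition$T2_hours,
                        group = chamber_of[active])
          inten[as.integer(rownames(add)), j] <-
            inten[as.integer(rownames(add)), j] + add[, 1]
        }
      }
    }

    sat <- inten >= config$saturation_ceiling
    inten[sat] <- config$saturation_ceiling

    chip_dataset(
      chip_id = chip_id, panel = panel, condition = condition,
      chambers = data.frame(chamber_id = seq_len(n) - 1L,
                            row = rows, col = cols, cell_count = counts),
      intensity = inten, saturated = sat,
      saturation_ceiling = config$saturation_ceiling
    )
  })
}

#' Add a linear background gradient to a chip
#'
#' Adds `slope[analyte] * row` to every chamber's raw intensity. Used to
#' emulate the device-wide background drift some chips exhibit; the returned
#' dataset is new and the input is unmodified. Values are not re-clipped, so
#' injecting `s` followed by `-s` restores the original intensities.
#'
#' @param dataset An `scbc_chip`.
#' @param slope Gradient in AU per row index; scalar or per-analyte.
#' @return A new `scbc_chip`.
#' @export
inject_gradient <- function(dataset, slope) {
  stopifnot(inherits(dataset, "scbc_chip"))
  s <- per_analyte(slope, dataset$panel, "slope")
  inten <- dataset$intensity +
    outer(as.numeric(dataset$chambers$row), s)
  inten[inten < 0] <- 0
  chip_dataset(dataset$chip_id, dataset$panel, dataset$condition,
               dataset$chambers, inten, saturated = dataset$saturated,
               saturation_ceiling = dataset$saturation_ceiling)
}
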