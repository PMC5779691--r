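# Small builders shared across test files. Everything is generated in code;
# no fixture files.

toy_panel <- function(n = 3) {
  analyte_panel(paste0("A", seq_len(n)))
}

# A minimal chip built directly from matrices (not via the generator), with
# controllable occupancy and intensities.
toy_chip <- function(cell_counts, intensity, panel = NULL,
                     T2 = 10, n_cols = 10, ceiling_au = 65535) {
  n <- length(cell_counts)
  if (is.null(panel)) panel <- toy_panel(ncol(intensity))
  chip_dataset(
    chip_id = "toy", panel = panel,
    condition = cohort_condition("toy", 1, T2),
    chambers = data.frame(chamber_id = seq_len(n) - 1L,
                          row = (seq_len(n) - 1L) %/% n_cols,
                          col = (seq_len(n) - 1L) %% n_cols,
                          cell_count = cell_counts),
    intensity = intensity, saturation_ceiling = ceiling_au
  )
}

# Gaussian-background chip: n0 zero-cell chambers + n1 one-cell chambers with
# prescribed added net signal per analyte (matrix n1 x P or 0).
gaussian_chip <- function(n0 = 300, n1 = 100, mu = 106, sigma = 16.2,
                          panel = toy_panel(3), signal = 0, T2 = 10,
                          seed = 1) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  withr_seed({
    n <- n0 + n1
    P <- panel$size
    inten <- matrix(rnorm(n * P, mu, sigma), n, P)
    if (!identical(signal, 0)) {
      inten[(n0 + 1):n, ] <- inten[(n0 + 1):n, ] + signal
    }
    inten[inten < 0] <- 0
    toy_chip(c(rep(0L, n0), rep(1L, n1)), inten, panel = panel, T2 = T2)
  })
}

# Independent brute-force pSI oracle: per-cell loops, no matrix algebra
# shared with the implementation.
oracle_psi <- function(call, rate) {
  n <- nrow(call); P <- ncol(call)
  k <- integer(n); tot <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(P)) {
      if (call[i, j]) {
        k[i] <- k[i] + 1L
        tot[i] <- tot[i] + rate[i, j]
      }
    }
  }
  psi_k <- numeric(P + 1)
  for (kk in 1:P) {
    cells <- which(k == kk)
    if (length(cells)) {
      psi_k[kk + 1] <- (length(cells) / n) * mean(tot[cells])
    }
  }
  by_analyte <- numeric(P)
  for (j in seq_len(P)) {
    s <- 0
    for (i in seq_len(n)) if (call[i, j]) s <- s + rate[i, j]
    by_analyte[j] <- s / n
  }
  list(psi_k = psi_k, psi_total = sum(psi_k), by_analyte = by_analyte,
       n_k = tabulate(k + 1L, P + 1))
}

# Sampling s.e. of a per-analyte null call rate when the cutoff itself is
# fitted from n0 background chambers: binomial component plus the
# delta-method term for the estimated mu + 2*sigma threshold
# (var(cutoff) ~ 3*sigma^2/n0, d(rate)/d(cutoff) = -dnorm(2)/sigma).
null_call_rate_se <- function(n1, n0) {
  q <- pnorm(2, lower.tail = FALSE)
  sqrt(q * (1 - q) / n1 + dnorm(2)^2 * 3 / n0)
}

# Hand-built call table for pSI arithmetic tests.
toy_calls <- function(call, rate, T2 = 10, panel = NULL) {
  call <- as.matrix(call); rate <- as.matrix(rate)
  if (is.null(panel)) panel <- toy_panel(ncol(call))
  storage.mode(call) <- "logical"
  structure(list(
    condition = cohort_condition("toy", 1, T2),
    panel = panel, chamber_id = seq_len(nrow(call)) - 1L,
    call = call, net = rate * T2, rate = rate,
    saturated = matrix(FALSE, nrow(call), ncol(call)),
    n_cells = nrow(call)
  ), class = "scbc_calls")
}
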