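cond10 <- function(T2 = 10) cohort_condition("c", 1, T2)

test_that("explicit occupancy is reproduced exactly", {
  cfg <- synthetic_chip_config(panel = toy_panel(2),
                               occupancy = c("0" = 300, "1" = 400,
                                             "2" = 350, "3" = 200))
  chip <- generate_chip(cfg, cond10())
  occ <- table(chip$chambers$cell_count)
  expect_equal(as.integer(occ), c(300L, 400L, 350L, 200L))
  expect_equal(n_chambers(chip), 1250L)
})

test_that("generation is deterministic and leaves the caller's RNG alone", {
  cfg <- synthetic_chip_config(panel = toy_panel(3), seed = 5L)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  a <- generate_chip(cfg, cond10())
  after <- runif(1)
  b <- generate_chip(cfg, cond10())
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$chambers, b$chambers)
  expect_identical(before, after)
})

test_that("null chips produce ~2.3% per-analyte positives under mu + 2 sd", {
  # secreting_fraction = 0, no gradient: the 1-cell call rate per analyte
  # concentrates at the Gaussian upper 2-sigma tail, within 3 s.e. of the
  # rate measured at a fitted cutoff
  q <- pnorm(2, lower.tail = FALSE)
  n_chips <- 5
  rates <- sapply(seq_len(n_chips), function(s) {
    cfg <- synthetic_chip_config(panel = toy_panel(3),
                                 occupancy = c("0" = 300, "1" = 400),
                                 secreting_fraction = 0, seed = 20L + s)
    chip <- generate_chip(cfg, cond10())
    models <- suppressWarnings(fit_background_all(chip))
    colMeans(call_secretion(chip, models)$call)
  })
  se <- null_call_rate_se(400, 300) / sqrt(n_chips)
  for (a in rownames(rates)) {
    expect_lt(abs(mean(rates[a, ]) - q), 3 * se)
  }
})

test_that("Poisson loading matches the Poisson pmf", {
  lambda <- 1.0
  n <- 10000L
  cfg <- synthetic_chip_config(panel = toy_panel(1), occupancy = NULL,
                               poisson_lambda = lambda, n_chambers = n,
                               seed = 8L)
  chip <- generate_chip(cfg, cond10())
  counts <- chip$chambers$cell_count

  # 0-cell count near n * exp(-lambda), within 3 binomial s.e.
  p0 <- exp(-lambda)
  expect_lt(abs(sum(counts == 0) - n * p0), 3 * sqrt(n * p0 * (1 - p0)))

  # chi-square GOF against the Poisson pmf (tail pooled)
  kmax <- 6
  obs <- vapply(0:kmax, function(k) sum(counts == k), integer(1))
  obs <- c(obs, n - sum(obs))
  expected_p <- c(dpois(0:kmax, lambda), ppois(kmax, lambda, lower.tail = FALSE))
  gof <- suppressWarnings(chisq.test(obs, p = expected_p))
  expect_gt(gof$p.value, 0.01)
})

test_that("inject_gradient is identity at slope 0, invertible, and linear", {
  cfg <- synthetic_chip_config(panel = toy_panel(2),
                               occupancy = c("0" = 100, "1" = 100),
                               seed = 3L, n_cols = 5)
  chip <- generate_chip(cfg, cond10())

  expect_identical(inject_gradient(chip, 0)$intensity, chip$intensity)

  fwd <- inject_gradient(chip, 0.5)
  back <- inject_gradient(fwd, -0.5)
  expect_lt(max(abs(back$intensity - chip$intensity)), 1e-9)
  expect_false(identical(fwd$intensity, chip$intensity))

  # mean 0-cell intensity separates top vs bottom row by slope * (rows - 1)
  n_rows <- max(chip$chambers$row) + 1L
  z <- chip$chambers$cell_count == 0
  top <- fwd$intensity[z & fwd$chambers$row == n_rows - 1L, 1]
  bot <- fwd$intensity[z & fwd$chambers$row == 0L, 1]
  t0 <- chip$intensity[z & chip$chambers$row == n_rows - 1L, 1]
  b0 <- chip$intensity[z & chip$chambers$row == 0L, 1]
  expect_equal((mean(top) - mean(bot)) - (mean(t0) - mean(b0)),
               0.5 * (n_rows - 1), tolerance = 1e-9)
})

test_that("saturation ceiling clips intensities and sets the flag", {
  cfg <- synthetic_chip_config(panel = toy_panel(1),
                               occupancy = c("0" = 50, "1" = 50),
                               secreting_fraction = 1, analyte_activity = 1,
                               signal_meanlog = log(1e5), signal_sdlog = 0.3,
                               saturation_ceiling = 5000, seed = 4L)
  chip <- generate_chip(cfg, cond10())
  one <- chip$chambers$cell_count == 1
  expect_true(all(chip$intensity <= 5000))
  expect_true(all(chip$saturated[one, 1]))
  expect_false(any(chip$saturated[!one, 1]))
})

test_that("cohort generation is deterministic and per-condition seeded", {
  sc <- human_cd8_scenario()
  a <- generate_cohort(sc, 7)
  b <- generate_cohort(sc, 7)
  expect_identical(a, b)
  expect_equal(length(a), 2L)
  expect_named(a, c("T1_0h", "T1_8h"))
  c2 <- generate_cohort(sc, 8)
  expect_false(identical(a[[1]]$intensity, c2[[1]]$intensity))
})

test_that("OT1 scenario holds total stimulation time at 24 h", {
  sc <- ot1_tetramer_scenario()
  T1 <- vapply(sc$conditions, function(x) x$condition$T1_hours, numeric(1))
  T2 <- vapply(sc$conditions, function(x) x$condition$T2_hours, numeric(1))
  expect_equal(T1, c(0.2, 4, 16))
  expect_equal(T2, c(23.8, 20, 8))
  expect_equal(T1 + T2, rep(24, 3))
})

test_that("invalid generator configuration is rejected", {
  expect_error(synthetic_chip_config(secreting_fraction = 1.5),
               class = "scbc_config_error")
  expect_error(synthetic_chip_config(analyte_activity = -0.1),
               class = "scbc_config_error")
  expect_error(synthetic_chip_config(background_sd = 0),
               class = "scbc_config_error")
  expect_error(synthetic_chip_config(occupancy = NULL),
               class = "scbc_config_error")
})

test_that("calibration inverts the measured call-count distribution", {
  # brute-force oracle: simulate the two-layer Bernoulli call model directly
  # (truth + false positives), no chip machinery involved
  act <- c(0.8, 0.5, 0.2, 0.2, 0.2)
  q <- pnorm(2, lower.tail = FALSE)
  target <- 0.40
  p <- calibrate_secreting_fraction(target, act, min_k = 1)
  set.seed(99)
  n <- 200000
  secretor <- rbinom(n, 1, p)
  truth <- sapply(act, function(a) rbinom(n, 1, a)) * secretor
  fp <- matrix(rbinom(n * 5, 1, q), n, 5) * (1 - truth)
  kk <- rowSums(pmax(truth, fp))
  expect_equal(mean(kk >= 1), target, tolerance = 0.01)
})
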