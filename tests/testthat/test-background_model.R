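test_that("background fit recovers the generating Gaussian", {
  # 300 zero-cell values from N(106, 16.2): mu and sigma back within 2 AU
  chip <- gaussian_chip(n0 = 300, n1 = 30, mu = 106, sigma = 16.2, seed = 7)
  m <- suppressWarnings(fit_background(chip, "A1"))
  expect_lt(abs(m$mu - 106), 2)
  expect_lt(abs(m$sigma - 16.2), 2)
  expect_equal(m$cutoff, m$mu + 2 * m$sigma)
  expect_equal(m$n_background, 300)

  # histogram least-squares fit agrees with moments within 5%
  h <- suppressWarnings(fit_background(chip, "A1", method = "histogram"))
  expect_lt(abs(h$mu - m$mu) / m$mu, 0.05)
  expect_lt(abs(h$sigma - m$sigma) / m$sigma, 0.05)
})

test_that("fit estimates tighten as the background sample grows", {
  err <- vapply(c(100, 300, 1000), function(n) {
    reps <- vapply(1:20, function(s) {
      chip <- gaussian_chip(n0 = n, n1 = 1, mu = 106, sigma = 16.2,
                            panel = toy_panel(1), seed = 1000 * n + s)
      m <- suppressWarnings(fit_background(chip, "A1"))
      abs(m$mu - 106)
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_true(err[3] < err[1])
})

test_that("degenerate and undersized backgrounds are refused", {
  inten <- matrix(100, 50, 1)
  chip <- toy_chip(c(rep(0L, 40), rep(1L, 10)), inten, panel = toy_panel(1))
  expect_error(fit_background(chip, "A1"),
               class = "scbc_degenerate_background_error")

  chip2 <- gaussian_chip(n0 = 10, n1 = 30, panel = toy_panel(1), seed = 2)
  expect_error(fit_background(chip2, "A1"),
               class = "scbc_sample_size_error")
  expect_error(fit_background(chip2, "nope"),
               class = "scbc_integrity_error")
})

test_that("saturated zero-cell values are excluded from the fit", {
  set.seed(5)
  v <- rnorm(300, 106, 16.2)
  v[1:20] <- 200  # these will be flagged saturated by a low ceiling
  chip <- toy_chip(c(rep(0L, 300), 1L), matrix(c(v, 100), ncol = 1),
                   panel = toy_panel(1), ceiling_au = 200)
  m <- suppressWarnings(fit_background(chip, "A1"))
  expect_equal(m$n_background, 280)
  expect_lt(abs(m$mu - 106), 3)
})

test_that("KS diagnostic holds its size under the null and rejects bimodality", {
  # true null: values from the reference Gaussian itself
  set.seed(31)
  v <- rnorm(300, 106, 16.2)
  ks <- test_normality(v, 106, 16.2)
  expect_gt(ks$ks_p, 0.05)
  expect_equal(length(ks$histogram$mids), 20)

  # type-I error over replicates with a-priori parameters is ~nominal
  rej <- vapply(1:1000, function(i) {
    set.seed(i)
    test_normality(rnorm(300, 106, 16.2), 106, 16.2)$ks_p < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))

  # strongly bimodal mixture vs its moment-matched Gaussian: high power
  rej2 <- vapply(1:50, function(i) {
    set.seed(i)
    v <- c(rnorm(150, 50, 5), rnorm(150, 200, 5))
    test_normality(v, mean(v), sd(v))$ks_p < 0.05
  }, logical(1))
  expect_gt(mean(rej2), 0.9)

  expect_error(test_normality(rnorm(50), 0, -1), class = "scbc_domain_error")
  expect_error(test_normality(rnorm(5), 0, 1),
               class = "scbc_sample_size_error")
})

test_that("binned KS mode runs and roughly tracks the raw mode", {
  set.seed(41)
  v <- rnorm(300, 106, 16.2)
  raw <- test_normality(v, 106, 16.2, on = "raw")
  binned <- test_normality(v, 106, 16.2, on = "binned")
  expect_lt(abs(raw$ks_stat - binned$ks_stat), 0.1)
})

test_that("an injected linear gradient is detected, estimated and removed", {
  cfg <- synthetic_chip_config(panel = toy_panel(2),
                               occupancy = c("0" = 300, "1" = 400),
                               secreting_fraction = 0, seed = 17L, n_cols = 18)
  flat <- generate_chip(cfg, cohort_condition("g", 1, 10))
  tilted <- inject_gradient(flat, 0.5)

  res <- detect_and_correct_gradient(tilted, "A1")
  expect_true(res$corrected)
  expect_lt(abs(res$slope - 0.5), 0.1)

  # residual zero-cell trend after correction is flat
  bg <- res$dataset
  z <- bg$chambers$cell_count == 0
  refit <- lm(bg$intensity[z, "A1"] ~ bg$chambers$row[z])
  expect_lt(abs(coef(refit)[2]), 0.05)

  # second pass is a no-op
  res2 <- detect_and_correct_gradient(res$dataset, "A1")
  expect_false(res2$corrected)
  expect_identical(res2$dataset$intensity, res$dataset$intensity)
})

test_that("gradient-free chips are rarely 'corrected' at the p<0.01 gate", {
  hits <- vapply(1:100, function(s) {
    cfg <- synthetic_chip_config(panel = toy_panel(1),
                                 occupancy = c("0" = 120, "1" = 20),
                                 secreting_fraction = 0, seed = s, n_cols = 10)
    chip <- generate_chip(cfg, cohort_condition("g", 1, 10))
    detect_and_correct_gradient(chip, "A1")$corrected
  }, logical(1))
  expect_lte(mean(hits), 0.04) # nominal 0.01 plus binomial noise at n = 100
})

test_that("gradient correction leaves secretor net signals unbiased", {
  panel <- toy_panel(1)
  sig <- 400
  chip <- gaussian_chip(n0 = 300, n1 = 200, panel = panel, signal = sig,
                        T2 = 10, seed = 23)
  base <- run_chip_pipeline(chip, correct_gradient = FALSE)
  tilt <- run_chip_pipeline(inject_gradient(chip, 0.5))
  expect_true(tilt$gradient_report$corrected[1])
  m0 <- mean(base$calls$net[base$calls$call[, 1], 1])
  m1 <- mean(tilt$calls$net[tilt$calls$call[, 1], 1])
  expect_lt(abs(m1 - m0) / m0, 0.02)
})

test_that("gradient detection refuses insufficient spatial span", {
  inten <- matrix(rnorm(80, 106, 16.2), 80, 1)
  chip <- toy_chip(c(rep(0L, 60), rep(1L, 20)), inten, panel = toy_panel(1),
                   n_cols = 100)  # all chambers in row 0
  expect_error(detect_and_correct_gradient(chip, "A1"),
               class = "scbc_insufficient_span_error")
})

test_that("cutoff arithmetic and monotonicity", {
  expect_equal(compute_cutoff(106, 16.2), 138.4)
  expect_equal(compute_cutoff(0, 1), 2)
  expect_error(compute_cutoff(1, 0), class = "scbc_domain_error")
  mus <- seq(-5, 5, length.out = 7)
  sigmas <- seq(0.5, 4, length.out = 7)
  for (i in seq_along(mus)[-1]) {
    expect_gt(compute_cutoff(mus[i], 1), compute_cutoff(mus[i - 1], 1))
    expect_gt(compute_cutoff(0, sigmas[i]), compute_cutoff(0, sigmas[i - 1]))
  }
})

test_that("cutoff minus mu equals two sigma for every fitted model", {
  chip <- gaussian_chip(n0 = 100, n1 = 50, panel = toy_panel(4), seed = 9)
  models <- suppressWarnings(fit_background_all(chip))
  for (m in models) expect_equal(m$cutoff - m$mu, 2 * m$sigma)
})
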