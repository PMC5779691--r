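test_that("chamber table round-trips bit for bit through read/write", {
  panel <- toy_panel(3)
  chip <- gaussian_chip(n0 = 30, n1 = 6, panel = panel, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_chamber_table(chip, path)
  back <- read_chamber_table(path, panel)
  expect_identical(back$chambers, chip$chambers)
  expect_identical(back$intensity, chip$intensity)
  expect_identical(back$saturated, chip$saturated)
  expect_identical(back$condition$T2_hours, chip$condition$T2_hours)
  expect_identical(back$chip_id, chip$chip_id)
  # and a second cycle is stable too
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_chamber_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("a small toy table parses with the expected occupancy", {
  panel <- toy_panel(2)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "# chip_id: c1", "# T1_hours: 1", "# T2_hours: 5", "# stimulation: s",
    "chamber_id,row,col,cell_count,A1,A2",
    "0,0,0,0,100,101", "1,0,1,0,99,98", "2,0,2,1,200,90",
    "3,1,0,1,95,400", "4,1,1,2,300,300", "5,1,2,3,500,500"
  ), path)
  ds <- read_chamber_table(path, panel)
  expect_equal(n_chambers(ds), 6)
  part <- partition_by_occupancy(ds)
  expect_equal(vapply(part, nrow, integer(1)),
               c("0" = 2L, "1" = 2L, "2" = 1L, "3" = 1L))
})

test_that("reader validation catches missing analytes, duplicates, and missing 0-cells", {
  panel <- analyte_panel(c("IL2", "A2"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# T2_hours: 5", "chamber_id,row,col,cell_count,A2",
               "0,0,0,0,1", "1,0,1,1,2"), path)
  expect_error(read_chamber_table(path, panel), "IL2",
               class = "scbc_format_error")

  writeLines(c("# T2_hours: 5", "chamber_id,row,col,cell_count,IL2,A2",
               "7,0,0,0,1,1", "7,0,1,1,2,2"), path)
  expect_error(read_chamber_table(path, panel), "7",
               class = "scbc_integrity_error")

  writeLines(c("# T2_hours: 5", "chamber_id,row,col,cell_count,IL2,A2",
               "0,0,0,1,1,1", "1,0,1,2,2,2"), path)
  expect_error(read_chamber_table(path, panel),
               class = "scbc_integrity_error")

  # invalid cell counts are rejected row-wise with a warning
  writeLines(c("# T2_hours: 5", "chamber_id,row,col,cell_count,IL2,A2",
               "0,0,0,0,1,1", "1,0,1,-2,2,2", "2,0,2,1,3,3"), path)
  expect_warning(ds <- read_chamber_table(path, panel), "rejected")
  expect_equal(n_chambers(ds), 2)
})

test_that("merge joins on chamber_id, logs dropped ids, errors on empty join", {
  counts <- data.frame(chamber_id = c(1, 2), cell_count = c(0, 1))
  inten <- data.frame(chamber_id = c(2, 3), A1 = c(5, 6))
  expect_message(m <- merge_counts_and_intensities(counts, inten),
                 "dropped 2")
  expect_equal(m$chamber_id, 2)
  expect_equal(m$cell_count, 1)
  expect_equal(attr(m, "dropped"), c(1, 3))

  one <- merge_counts_and_intensities(data.frame(chamber_id = 5, cell_count = 1),
                                      data.frame(chamber_id = 5, A1 = 9))
  expect_equal(one$cell_count, 1)

  expect_error(
    merge_counts_and_intensities(data.frame(chamber_id = 1, cell_count = 0),
                                 data.frame(chamber_id = 2, A1 = 1)),
    class = "scbc_integrity_error")
})

test_that("merge is order-independent", {
  set.seed(11)
  counts <- data.frame(chamber_id = sample(1:50), cell_count = rpois(50, 1))
  inten <- data.frame(chamber_id = sample(5:60), A1 = runif(56), A2 = runif(56))
  a <- merge_counts_and_intensities(counts, inten)
  b <- suppressMessages(
    merge_counts_and_intensities(counts[sample(nrow(counts)), ],
                                 inten[rev(seq_len(nrow(inten))), ]))
  rownames(b) <- NULL
  attr(a, "dropped") <- attr(b, "dropped") <- NULL
  expect_equal(suppressMessages(a), b)
})

test_that("occupancy partition is disjoint and exhaustive on random chips", {
  for (seed in 1:3) {
    cfg <- synthetic_chip_config(panel = toy_panel(2), occupancy = NULL,
                                 poisson_lambda = 1, n_chambers = 300,
                                 seed = seed)
    chip <- generate_chip(cfg, cohort_condition("x", 1, 5))
    part <- partition_by_occupancy(chip)
    ids <- unlist(lapply(part, function(p) p$chamber_id), use.names = FALSE)
    expect_equal(sort(ids), sort(chip$chambers$chamber_id))
    expect_equal(sum(vapply(part, nrow, integer(1))), n_chambers(chip))
    for (k in names(part)) {
      expect_true(all(part[[k]]$cell_count == as.integer(k)))
    }
  }
})

test_that("panel and condition invariants are enforced", {
  expect_error(analyte_panel(c("a", "a")), class = "scbc_domain_error")
  expect_error(cohort_condition("x", 1, 0), class = "scbc_domain_error")
  expect_error(cohort_condition("x", 4, 21, total_hours = 24),
               class = "scbc_domain_error")
  ok <- cohort_condition("x", 4, 20, total_hours = 24)
  expect_equal(ok$T2_hours, 20)
  expect_equal(default_panel()$size, 11)
})
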