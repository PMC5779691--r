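#!/usr/bin/env Rscript
# Call secretion for every 1-cell chamber (raw > mu + 2 sd, strict) and
# tabulate detectable (k >= 1) and polyfunctional (k >= 2) fractions per
# condition. Net intensities are background-subtracted and normalized by the
# secretion window T2.
suppressMessages(library(scbcsec))

tab_dir <- file.path("results", "tables")
files <- list.files(tab_dir, pattern = "\\.csv$", full.names = TRUE)
stopifnot(length(files) > 0)
panel <- default_panel()

rows <- list()
for (f in files) {
  chip <- read_chamber_table(f, panel)
  res <- run_chip_pipeline(chip)
  rows[[f]] <- data.frame(
    chip_id = chip$chip_id,
    condition = chip$condition$label,
    T1_hours = chip$condition$T1_hours,
    T2_hours = chip$condition$T2_hours,
    n_cells = res$calls$n_cells,
    fraction_secreting = fraction_secreting(res$calls, 1),
    fraction_polyfunctional = fraction_secreting(res$calls, 2),
    n_saturated_calls = sum(res$calls$saturated)
  )
}
out <- do.call(rbind, rows)
out <- out[order(sub("_T1_.*$", "", out$chip_id), out$T1_hours), ]
rownames(out) <- NULL
print(out, row.names = FALSE, digits = 3)
write.csv(out, file.path("results", "secretion_summary.csv"),
          row.names = FALSE)

ot1 <- out[grepl("^OT1", out$chip_id), ]
if (nrow(ot1) == 3) {
  cat(sprintf(
    "\nOT1 sweep: detectable secretion rises from %.0f%% (T1 = 0.2 h) to %.0f%% (4 h) to %.0f%% (16 h).\n",
    100 * ot1$fraction_secreting[1], 100 * ot1$fraction_secreting[2],
    100 * ot1$fraction_secreting[3]))
}
cat("done: per-condition call summary in results/secretion_summary.csv\n")
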