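#' Read a merged chamber table
#'
#' The on-disk format is self-describing delimited text: `#`-prefixed
#' `key: value` metadata lines (chip_id, T1_hours, T2_hours, stimulation,
#' density, saturation_ceiling, label), then a comma-separated table with
#' columns `chamber_id,row,col,cell_count,<analyte1>,...,<analyteN>`.
#' Saturation flags are derived at read time as
#' `raw >= saturation_ceiling`. Rows whose cell count is negative or
#' non-integer are rejected with a warning.
#'
#' @param path Path to the chamber table file.
#' @param panel The [analyte_panel()] the file must provide columns for.
#' @return A validated [chip_dataset()].
#' @export
read_chamber_table <- function(path, panel) {
  if (!file.exists(path)) stop_format(paste0("no such file: ", path))
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop_format("chamber table has no data rows")
  tab <- utils::read.csv(text = body, check.names = FALSE,
                         stringsAsFactors = FALSE)

  for (a in panel$names) {
    if (!a %in% names(tab)) {
      stop_format(paste0("missing analyte column: ", a))
    }
  }
  for (col in c("chamber_id", "row", "col", "cell_count")) {
    if (!col %in% names(tab)) stop_format(paste0("missing column: ", col))
  }

  bad <- !is.finite(tab$cell_count) | tab$cell_count < 0 |
    tab$cell_count != floor(tab$cell_count)
  if (any(bad)) {
    warning(sprintf("rejected %d row(s) with invalid cell counts", sum(bad)))
    tab <- tab[!bad, , drop = FALSE]
  }
  if (!nrow(tab)) stop_format("no valid chamber rows after filtering")
  if (anyDuplicated(tab$chamber_id)) {
    dup <- unique(tab$chamber_id[duplicated(tab$chamber_id)])
    stop_integrity(paste0("duplicate chamber_id: ",
                          paste(dup, collapse = ", ")))
  }

  getm <- function(key, default = NULL) {
    if (!is.null(meta[[key]])) meta[[key]] else default
  }
  cond <- cohort_condition(
    label = getm("label", getm("chip_id", "unlabeled")),
    T1_hours = as.numeric(getm("T1_hours", 0)),
    T2_hours = as.numeric(getm("T2_hours", 1)),
    stimulation = getm("stimulation", "unspecified"),
    cell_density = {
      d <- getm("density", NA)
      if (identical(d, "NA") || is.na(d)) NA_real_ else as.numeric(d)
    }
  )
  ceiling_au <- as.numeric(getm("saturation_ceiling", 65535))

  chip_dataset(
    chip_id = getm("chip_id", "chip"),
    panel = panel, condition = cond,
    chambers = tab[c("chamber_id", "row", "col", "cell_count")],
    intensity = as.matrix(tab[panel$names]),
    saturation_ceiling = ceiling_au
  )
}

#' Write a chip dataset as a chamber table
#'
#' Inverse of [read_chamber_table()]: numeric values are written with 17
#' significant digits so that a read/write/read cycle reproduces the dataset
#' bit for bit.
#'
#' @param dataset An `scbc_chip`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chamber_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "scbc_chip"))
  num <- function(x) sprintf("%.17g", x)
  cond <- dataset$condition
  hdr <- c(
    paste0("# chip_id: ", dataset$chip_id),
    paste0("# label: ", cond$label),
    paste0("# T1_hours: ", num(cond$T1_hours)),
    paste0("# T2_hours: ", num(cond$T2_hours)),
    paste0("# stimulation: ", cond$stimulation),
    paste0("# density: ", ifelse(is.na(cond$cell_density), "NA",
                                 num(cond$cell_density))),
    paste0("# saturation_ceiling: ", num(dataset$saturation_ceiling))
  )
  header_row <- paste(c("chamber_id", "row", "col", "cell_count",
                        dataset$panel$names), collapse = ",")
  ch <- dataset$chambers
  inten <- dataset$intensity
  rows <- vapply(seq_len(nrow(ch)), function(i) {
    paste(c(ch$chamber_id[i], ch$row[i], ch$col[i], ch$cell_count[i],
            num(inten[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(hdr, header_row, rows), path)
  invisible(path)
}

#' Merge bright-field cell counts with barcode intensities
#'
#' Single-cell chip data arrives from two sources: bright-field video
#' (chamber occupancy) and scanned immunoassay fluorescence (per-analyte
#' intensities). This joins them on `chamber_id`. Chambers present in only
#' one source are dropped and their count reported.
#'
#' @param counts data.frame with columns `chamber_id`, `cell_count` (and
#'   optionally `row`, `col`).
#' @param intensities data.frame with `chamber_id` plus one column per
#'   analyte.
#' @return data.frame of inner-joined chamber records, ordered by
#'   `chamber_id`, with attribute `dropped` listing unmatched ids.
#' @export
merge_counts_and_intensities <- function(counts, intensities) {
  counts <- as.data.frame(counts)
  intensities <- as.data.frame(intensities)
  if (!"chamber_id" %in% names(counts) ||
      !"chamber_id" %in% names(intensities)) {
    stop_format("both tables must carry a chamber_id column")
  }
  common <- intersect(counts$chamber_id, intensities$chamber_id)
  if (!length(common)) {
    stop_integrity("no chamber_id is shared by the two tables")
  }
  dropped <- c(setdiff(counts$chamber_id, common),
               setdiff(intensities$chamber_id, common))
  if (length(dropped)) {
    message(sprintf("merge: dropped %d unmatched chamber(s)", length(dropped)))
  }
  merged <- merge(counts, intensities, by = "chamber_id")
  merged <- merged[order(merged$chamber_id), , drop = FALSE]
  rownames(merged) <- NULL
  attr(merged, "dropped") <- sort(dropped)
  merged
}
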