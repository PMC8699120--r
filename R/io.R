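# Event-table I/O in NONMEM-style comma-separated layout, with row-level
# validation so real pharmacometric datasets can be ingested unchanged.

pk_required_cols <- c("ID", "TIME", "EVID", "AMT", "DV", "CMT", "MDV")
pk_all_cols <- c(pk_required_cols, "BLQ", "DOSEGRP", "RENGRP", "CR", "BUN",
                 "CCR", "WT")

validate_pk_dataset <- function(data) {
  missing_cols <- setdiff(pk_required_cols, names(data))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  problems <- character()
  bad_time <- which(!is.finite(data$TIME) | data$TIME < 0)
  if (length(bad_time)) {
    problems <- c(problems, paste0("negative or missing TIME at row(s) ",
                                   paste(utils::head(bad_time, 5), collapse = ", ")))
  }
  bad_dv <- which(data$MDV == 0 & !is.finite(data$DV))
  if (length(bad_dv)) {
    problems <- c(problems, paste0("DV missing where MDV = 0 at row(s) ",
                                   paste(utils::head(bad_dv, 5), collapse = ", ")))
  }
  if (nrow(data)) {
    dose_counts <- data |>
      dplyr::group_by(.data$ID) |>
      dplyr::summarise(n_dose = sum(.data$EVID == 1L & .data$TIME == 0),
                       n_obs = sum(.data$EVID == 0L), .groups = "drop")
    orphans <- dose_counts$ID[dose_counts$n_dose == 0 & dose_counts$n_obs > 0]
    if (length(orphans)) {
      problems <- c(problems,
                    paste0("observation rows without a time-zero dose row for subject(s) ",
                           paste(utils::head(orphans, 5), collapse = ", ")))
    }
    multi <- dose_counts$ID[dose_counts$n_dose > 1]
    if (length(multi)) {
      problems <- c(problems, paste0("multiple time-zero dose rows for subject(s) ",
                                     paste(utils::head(multi, 5), collapse = ", ")))
    }
    unsorted <- data |>
      dplyr::filter(.data$EVID == 0L) |>
      dplyr::group_by(.data$ID, .data$CMT) |>
      dplyr::summarise(bad = is.unsorted(.data$TIME), .groups = "drop")
    if (any(unsorted$bad)) {
      problems <- c(problems,
                    paste0("observation times not non-decreasing for subject(s) ",
                           paste(utils::head(unsorted$ID[unsorted$bad], 5),
                                 collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop("invalid dataset:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(data)
}

#' Read a study event table
#'
#' Reads a comma-separated NONMEM-style event table (`ID`, `TIME` in hours,
#' `EVID`, `AMT` in mg/kg, `DV` in µg/mL for plasma or cumulative µg for
#' urine, `CMT`, `MDV`, plus covariates) and validates it: missing mandatory
#' columns, negative times, observations without a dose record, and `DV`/
#' `MDV` inconsistencies are rejected with row-level messages.
#'
#' @param path File path.
#' @param time_minutes If `TRUE`, `TIME` is given in minutes and converted to
#'   hours on read.
#' @return A validated tibble.
#' @export
read_pk_dataset <- function(path, time_minutes = FALSE) {
  # columns come in as text and numerics go through R's strtod, which is
  # correctly rounded, so written doubles round-trip bit-exactly
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = "c"))
  num_cols <- c("ID", "TIME", "AMT", "DV", "DOSEGRP", "CR", "BUN", "CCR", "WT")
  for (cc in intersect(num_cols, names(data))) {
    data[[cc]] <- as.numeric(data[[cc]])
  }
  for (cc in setdiff(names(data),
                     c(num_cols, "EVID", "MDV", "BLQ", "CMT", "RENGRP"))) {
    conv <- suppressWarnings(as.numeric(data[[cc]]))
    if (!any(is.na(conv) & !is.na(data[[cc]]))) data[[cc]] <- conv
  }
  if ("BLQ" %in% names(data)) data$BLQ <- as.logical(data$BLQ)
  if (!"BLQ" %in% names(data)) data$BLQ <- FALSE
  for (cc in c("EVID", "MDV")) {
    if (cc %in% names(data)) data[[cc]] <- as.integer(data[[cc]])
  }
  if (time_minutes) data$TIME <- data$TIME / 60
  validate_pk_dataset(data)
  data
}

#' Write a study event table
#'
#' Writes the dataset as comma-separated text with a stable column order and
#' full numeric precision (values round-trip exactly); identical input
#' produces byte-identical files. An empty dataset yields a header-only file.
#'
#' @param data A validated event table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(data, path) {
  validate_pk_dataset(data)
  ordered <- c(intersect(pk_all_cols, names(data)),
               setdiff(names(data), pk_all_cols))
  out <- data[, ordered]
  # 17 significant digits guarantee exact double round-trips
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::where(is.double),
    function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  ))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
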