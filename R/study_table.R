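# Packaged 30-implant study table and cohort summaries.

# md5 of the packaged fixture, frozen at packaging time.
.STUDY_TABLE_MD5 <- "e794cf1eea24f2e4508bbc59482e0383"

#' Load the packaged orbital-implant study table
#'
#' Returns the 30-record CBCT orbital-implant table shipped with the package:
#' manufacturer (factory) and sphere-fit estimated diameters, implant lifespan
#' in days, uncalibrated implant-volume mean/SD HU, the published corrected
#' mean HU, the contralateral corpus-vitreum mean HU and the dedicated-volume
#' maximum HU used as per-scan calibration anchors.
#'
#' Values are transcribed verbatim from the printed source table (decimal
#' commas in diameters converted to points at packaging time). Record
#' `1.26`'s factory diameter is printed as 10 mm, inconsistent with its
#' 19.66 mm sphere-fit estimate and the 16/18/20 mm size list; it is kept as
#' printed and carries the quality flag `"suspect_diameter"`. All records
#' load with `included = TRUE`: the two scans the original analysts excluded
#' are identified in the source only by table shading, which is not
#' recoverable, so exclusion is left to the caller (see
#' [run_study_reanalysis()]'s `exclude_ids`).
#'
#' @return A data frame of 30 rows with columns `id_label`,
#'   `diameter_measured_mm`, `diameter_estimated_mm`, `lifespan_days`,
#'   `oi_mean_hu`, `oi_sd_hu`, `corrected_mean_hu`, `cv_mean_hu`,
#'   `dv_max_hu`, `included` (logical) and `quality_flags`
#'   (semicolon-separated, `""` when none).
#' @seealso [summarize_cohort()], [build_calibration()]
#' @examples
#' tab <- load_study_table()
#' tab[tab$id_label == "1.1", ]
#' @export
load_study_table <- function() {
  path <- system.file("extdata", "study_table.csv", package = "orbcal",
                      mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged study table fixture is missing; reinstall 'orbcal'",
         call. = FALSE)
  }
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, .STUDY_TABLE_MD5)) {
    stop("study table fixture checksum mismatch (expected ",
         .STUDY_TABLE_MD5, ", got ", sum,
         "): packaged data is corrupt", call. = FALSE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id_label = "character"))
  tab$included <- TRUE
  tab$quality_flags <- ""
  tab$quality_flags[tab$id_label == "1.26"] <- "suspect_diameter"
  validate_records(tab)
  tab
}

# Shared contract for anything shaped like the study table (packaged or
# synthetic): the calibration anchors must be usable downstream.
validate_records <- function(records) {
  needed <- c("id_label", "diameter_measured_mm", "diameter_estimated_mm",
              "lifespan_days", "oi_mean_hu", "cv_mean_hu", "dv_max_hu")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("records are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(
    all(records$lifespan_days > 0),
    all(records$diameter_measured_mm > 0),
    all(records$diameter_estimated_mm > 0),
    all(records$dv_max_hu > records$cv_mean_hu)
  )
  invisible(records)
}

#' Summarise an implant cohort
#'
#' Lifespan range and mean over all supplied records, and the sample standard
#' deviation (n − 1) of the sphere-fit diameter deviation (estimated minus
#' factory diameter). Records flagged `"suspect_diameter"` are excluded from
#' the deviation SD only; they still contribute to the lifespan summary.
#'
#' @param records A data frame as returned by [load_study_table()] or
#'   [generate_cohort()].
#' @return A list of class `"cohort_summary"` with `n_records`,
#'   `lifespan_min_days`, `lifespan_max_days`, `lifespan_mean_days` and
#'   `diameter_deviation_sd_mm`.
#' @examples
#' summarize_cohort(load_study_table())
#' @export
summarize_cohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("'records' must be a non-empty data frame", call. = FALSE)
  }
  validate_records(records)
  flags <- if ("quality_flags" %in% names(records)) records$quality_flags else ""
  ok_diam <- !grepl("suspect_diameter", flags, fixed = TRUE)
  dev <- records$diameter_estimated_mm[ok_diam] -
    records$diameter_measured_mm[ok_diam]
  out <- list(
    n_records = nrow(records),
    lifespan_min_days = min(records$lifespan_days),
    lifespan_max_days = max(records$lifespan_days),
    lifespan_mean_days = mean(records$lifespan_days),
    diameter_deviation_sd_mm = if (length(dev) >= 2L) stats::sd(dev) else NA_real_
  )
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d implants\n", x$n_records))
  cat(sprintf("  lifespan: %d-%d days (mean %.1f)\n",
              x$lifespan_min_days, x$lifespan_max_days, x$lifespan_mean_days))
  cat(sprintf("  diameter deviation SD (estimated - factory): %.4f mm\n",
              x$diameter_deviation_sd_mm))
  invisible(x)
}

#' Write implant records to CSV or JSON
#'
#' @param records Data frame of implant records.
#' @param path Output file; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  validate_records(records)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(records, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA)
  } else {
    stop("unsupported export format: '", ext, "' (use .csv or .json)",
         call. = FALSE)
  }
  invisible(path)
}
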