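# Ordinary least squares trend of implant density against implant lifespan.

#' Closed-form ordinary least squares trend fit
#'
#' Fits `y = intercept + slope * x` by the closed-form least-squares
#' estimator (slope = sum((x - mean(x)) (y - mean(y))) / sum((x - mean(x))^2)),
#' with x in days and the slope also reported per year. The coefficient of
#' determination is the explained-variance ratio, defined as 0 when the
#' response has zero variance. The slope standard error uses the usual
#' residual-variance formula with n - 2 degrees of freedom.
#'
#' @param x Implant lifespans in days.
#' @param y HU values (same length).
#' @param days_per_year Days-per-year constant used to rescale the slope
#'   (default 365.25).
#' @return A list of class `"trend_fit"` with `slope_hu_per_day`,
#'   `slope_hu_per_year`, `intercept_hu`, `r_squared`, `slope_se_hu_per_day`,
#'   `slope_se_hu_per_year` and `n`.
#' @examples
#' ols_fit(c(0, 100, 200), c(1, 201, 401))  # slope 2 HU/day, intercept 1
#' @export
ols_fit <- function(x, y, days_per_year = 365.25) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            days_per_year > 0)
  n <- length(x)
  if (n < 3L) {
    stop("insufficient data: need at least 3 points, got ", n, call. = FALSE)
  }
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) {
    stop("degenerate design: all lifespans identical", call. = FALSE)
  }
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum((y - intercept - slope * x)^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  se <- if (n > 2L) sqrt(ss_res / (n - 2L) / sxx) else NA_real_
  structure(list(
    slope_hu_per_day = slope,
    slope_hu_per_year = slope * days_per_year,
    intercept_hu = intercept,
    r_squared = max(0, min(1, r2)),
    slope_se_hu_per_day = se,
    slope_se_hu_per_year = se * days_per_year,
    n = n
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "OLS trend (n = %d): %.4g HU/year (SE %.3g), intercept %.4g HU, R^2 = %.3f\n",
    x$n, x$slope_hu_per_year, x$slope_se_hu_per_year, x$intercept_hu,
    x$r_squared))
  invisible(x)
}

#' Density-versus-lifespan trend over an implant cohort
#'
#' Regresses implant density on implant lifespan, pooled or per group (e.g.
#' per implant material when a material map is available). Three density
#' readings are supported: `"recomputed"` applies the two-point correction
#' ([build_calibration()]) to each record's uncalibrated implant mean using
#' that record's own scan anchors; `"published"` uses the packaged corrected
#' column as printed; `"raw"` uses the uncalibrated implant means (the
#' uncorrected scatter the study also plotted).
#'
#' @param records Data frame of implant records ([load_study_table()] /
#'   [generate_cohort()]); only rows with `included = TRUE` are fitted.
#' @param group_map Optional data frame with columns `id_label` and `group`
#'   (or a named character vector id -> group). `NULL` fits one pooled trend
#'   (group `"all"`). IDs absent from `records` are an error.
#' @param use Density reading: `"recomputed"` (default), `"published"` or
#'   `"raw"`.
#' @param reference [msct_reference()] for the recomputed reading.
#' @param literal,tol_hu Passed to [build_calibration()].
#' @param days_per_year Passed to [ols_fit()].
#' @return A named list of [ols_fit()] results, one per group.
#' @examples
#' density_trend(load_study_table())  # pooled corrected trend
#' @export
density_trend <- function(records, group_map = NULL,
                          use = c("recomputed", "published", "raw"),
                          reference = msct_reference(), literal = TRUE,
                          tol_hu = 1, days_per_year = 365.25) {
  use <- match.arg(use)
  validate_records(records)
  if ("included" %in% names(records)) records <- records[records$included, ]
  if (nrow(records) == 0L) stop("no included records", call. = FALSE)

  y <- switch(use,
    recomputed = corrected_density(records, reference, literal, tol_hu),
    published = {
      if (!"corrected_mean_hu" %in% names(records)) {
        stop("records carry no published corrected column", call. = FALSE)
      }
      records$corrected_mean_hu
    },
    raw = records$oi_mean_hu
  )

  if (is.null(group_map)) {
    groups <- rep("all", nrow(records))
  } else {
    if (is.character(group_map) && !is.null(names(group_map))) {
      group_map <- data.frame(id_label = names(group_map),
                              group = unname(group_map))
    }
    stopifnot(is.data.frame(group_map),
              all(c("id_label", "group") %in% names(group_map)))
    unknown <- setdiff(group_map$id_label, records$id_label)
    if (length(unknown)) {
      stop("group map refers to unknown record IDs: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    m <- match(records$id_label, group_map$id_label)
    keep <- !is.na(m)
    records <- records[keep, ]
    y <- y[keep]
    groups <- group_map$group[m[keep]]
  }

  fits <- lapply(split(seq_len(nrow(records)), groups), function(i) {
    if (length(i) < 3L) {
      stop("insufficient data: group with fewer than 3 included records",
           call. = FALSE)
    }
    ols_fit(records$lifespan_days[i], y[i], days_per_year = days_per_year)
  })
  fits
}

# Per-record two-point correction of the implant mean using each scan's own
# anchors (one calibration per acquisition).
corrected_density <- function(records, reference = msct_reference(),
                              literal = TRUE, tol_hu = 1) {
  vapply(seq_len(nrow(records)), function(i) {
    cal <- build_calibration(records$cv_mean_hu[i], records$dv_max_hu[i],
                             reference = reference, tol_hu = tol_hu,
                             literal = literal)
    correct_hu(records$oi_mean_hu[i], cal)
  }, numeric(1))
}
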