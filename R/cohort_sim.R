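# Synthetic implant cohorts with known longitudinal ground truth, shaped
# like the packaged study table so the whole correction + trend pipeline
# runs on them unchanged.

#' Specify a synthetic implant cohort
#'
#' Each record gets a lifespan drawn uniformly over the study's observed
#' range (79-2636 days), a true corrected density
#' `baseline + slope * lifespan / days_per_year + N(0, residual_sd)`, and
#' per-scan calibration anchors drawn from a simple anchor model (a normal
#' corpus-vitreum mean plus a normal, floor-truncated anchor span). The raw
#' uncalibrated implant mean is then back-computed by inverting the literal
#' two-point correction, so running the pipeline's correction on the record
#' recovers the generated true corrected density exactly.
#'
#' Group defaults mirror the study's two materials: n = 17 and 11 with
#' yearly density slopes of -10 and -14 HU/year. Day-0 baselines (700 and
#' 750 HU) and the residual SD (150 HU) are the generator's own choices,
#' picked once to match the spread of the printed corrected column.
#'
#' @param n_per_group Named integer vector of group sizes
#'   (default `c(HA = 17, AO = 11)`).
#' @param baseline_hu Named day-0 corrected densities per group, HU.
#' @param slope_hu_per_year Named yearly density slopes per group, HU/year.
#' @param lifespan_range_days Inclusive lifespan range, days.
#' @param residual_sd_hu SD of the residual scatter around the trend, HU.
#' @param cv_anchor_mean_hu,cv_anchor_sd_hu Normal model for each scan's
#'   uncalibrated corpus-vitreum mean.
#' @param anchor_span_mean_hu,anchor_span_sd_hu,anchor_span_min_hu Normal
#'   model (floor-truncated) for the scan's DV-max minus CV-mean span.
#' @param diameter_sd_mm SD of the sphere-fit diameter deviation around the
#'   factory diameter (default 0.2839 mm, the study's reported value).
#' @param reference [msct_reference()] whose anchors the back-computation
#'   inverts.
#' @param days_per_year Year convention (default 365.25).
#' @param seed Integer seed.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_per_group = c(HA = 17L, AO = 11L),
                        baseline_hu = c(HA = 700, AO = 750),
                        slope_hu_per_year = c(HA = -10, AO = -14),
                        lifespan_range_days = c(79, 2636),
                        residual_sd_hu = 150,
                        cv_anchor_mean_hu = -150, cv_anchor_sd_hu = 150,
                        anchor_span_mean_hu = 2250, anchor_span_sd_hu = 300,
                        anchor_span_min_hu = 500,
                        diameter_sd_mm = 0.2839,
                        reference = msct_reference(),
                        days_per_year = 365.25,
                        seed = 1L) {
  stopifnot(length(n_per_group) >= 1L, all(n_per_group > 0),
            !is.null(names(n_per_group)),
            all(names(n_per_group) %in% names(baseline_hu)),
            all(names(n_per_group) %in% names(slope_hu_per_year)),
            length(lifespan_range_days) == 2L,
            lifespan_range_days[1] > 0,
            lifespan_range_days[1] <= lifespan_range_days[2],
            residual_sd_hu >= 0, anchor_span_min_hu > 0,
            inherits(reference, "msct_reference"), days_per_year > 0)
  structure(list(n_per_group = n_per_group, baseline_hu = baseline_hu,
                 slope_hu_per_year = slope_hu_per_year,
                 lifespan_range_days = lifespan_range_days,
                 residual_sd_hu = residual_sd_hu,
                 cv_anchor_mean_hu = cv_anchor_mean_hu,
                 cv_anchor_sd_hu = cv_anchor_sd_hu,
                 anchor_span_mean_hu = anchor_span_mean_hu,
                 anchor_span_sd_hu = anchor_span_sd_hu,
                 anchor_span_min_hu = anchor_span_min_hu,
                 diameter_sd_mm = diameter_sd_mm,
                 reference = reference, days_per_year = days_per_year,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic implant cohort
#'
#' @param spec A [cohort_spec()].
#' @return A data frame shaped like [load_study_table()] output, with the
#'   extra columns `group` and `true_corrected_hu` (the generator's truth).
#'   The attribute `"truth"` carries the generating parameters per group.
#'   Deterministic for a fixed spec; the caller's RNG state is untouched.
#' @examples
#' coh <- generate_cohort(cohort_spec(seed = 7))
#' density_trend(coh, group_map = coh[, c("id_label", "group")])
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  n <- length(groups)
  ref <- spec$reference
  with_preserved_rng(spec$seed, {
    lifespan <- round(stats::runif(n, spec$lifespan_range_days[1],
                                   spec$lifespan_range_days[2]))
    true_corr <- spec$baseline_hu[groups] +
      spec$slope_hu_per_year[groups] * lifespan / spec$days_per_year +
      stats::rnorm(n, 0, spec$residual_sd_hu)
    cv_scan <- stats::rnorm(n, spec$cv_anchor_mean_hu, spec$cv_anchor_sd_hu)
    span <- pmax(spec$anchor_span_min_hu,
                 stats::rnorm(n, spec$anchor_span_mean_hu,
                              spec$anchor_span_sd_hu))
    dv_scan <- cv_scan + span
    diam <- sample(c(16, 18, 20), n, replace = TRUE,
                   prob = c(1, 13, 16) / 30)
    diam_est <- diam + stats::rnorm(n, 0, spec$diameter_sd_mm)
    oi_sd <- pmax(10, stats::rnorm(n, 250, 120))
  })
  # invert the literal two-point correction so the pipeline's correction
  # recovers true_corr exactly from (oi_raw, cv_scan, dv_scan)
  gain <- (ref$dv_max_hu - ref$cv_mean_hu) / (dv_scan - cv_scan)
  oi_raw <- (true_corr - ref$cv_mean_hu) / gain + cv_scan

  out <- data.frame(
    id_label = sprintf("s.%d", seq_len(n)),
    diameter_measured_mm = diam,
    diameter_estimated_mm = diam_est,
    lifespan_days = as.integer(lifespan),
    oi_mean_hu = oi_raw,
    oi_sd_hu = oi_sd,
    corrected_mean_hu = true_corr,
    cv_mean_hu = cv_scan,
    dv_max_hu = dv_scan,
    included = TRUE,
    quality_flags = "",
    group = groups,
    true_corrected_hu = true_corr,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "truth") <- data.frame(
    group = names(spec$n_per_group),
    n = as.integer(spec$n_per_group),
    baseline_hu = spec$baseline_hu[names(spec$n_per_group)],
    slope_hu_per_year = spec$slope_hu_per_year[names(spec$n_per_group)],
    residual_sd_hu = spec$residual_sd_hu,
    row.names = NULL
  )
  validate_records(out)
  out
}
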