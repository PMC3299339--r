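# Hounsfield scale definition and the two-point per-scan CBCT correction.

#' Hounsfield value of a linear attenuation coefficient
#'
#' The Hounsfield scale is the affine rescaling of linear attenuation that
#' pins distilled water at standard pressure and temperature to 0 HU and air
#' to -1000 HU:
#' \deqn{HU = 1000 (\mu_x - \mu_{water}) / (\mu_{water} - \mu_{air}).}
#'
#' @param mu_x Linear attenuation coefficient(s) of the material, any
#'   consistent unit (vectorised).
#' @param mu_water,mu_air Attenuation of water and air in the same units;
#'   `mu_water` must exceed `mu_air`.
#' @return HU value(s), same length as `mu_x`.
#' @examples
#' hounsfield_from_attenuation(0.2, mu_water = 0.2, mu_air = 0)   # water: 0
#' hounsfield_from_attenuation(0, mu_water = 0.2, mu_air = 0)     # air: -1000
#' @export
hounsfield_from_attenuation <- function(mu_x, mu_water, mu_air) {
  stopifnot(is.numeric(mu_x), is.numeric(mu_water), is.numeric(mu_air))
  if (!(mu_water > mu_air)) {
    stop("non-physical calibration pair: mu_water must exceed mu_air",
         call. = FALSE)
  }
  1000 * (mu_x - mu_water) / (mu_water - mu_air)
}

#' MSCT reference anchors
#'
#' The water-calibrated reference values the per-scan CBCT correction maps
#' onto: the mean corpus-vitreum (CV) density and the maximum dedicated-volume
#' (DV) density measured on a calibrated MSCT control group. Defaults are the
#' study's ten-scan control values: CV 5.93 HU (SD 3.97) and DV max
#' 2024.67 HU (SD 103.49).
#'
#' @param cv_mean_hu,cv_sd_hu Water-like (corpus vitreum) anchor and its SD, HU.
#' @param dv_max_hu,dv_max_sd_hu Dense-bone (dedicated-volume maximum) anchor
#'   and its SD, HU.
#' @return A list of class `"msct_reference"`.
#' @export
msct_reference <- function(cv_mean_hu = 5.93, cv_sd_hu = 3.97,
                           dv_max_hu = 2024.67, dv_max_sd_hu = 103.49) {
  stopifnot(is.numeric(cv_mean_hu), is.numeric(dv_max_hu))
  if (!(dv_max_hu > cv_mean_hu)) {
    stop("reference anchors degenerate: dv_max_hu must exceed cv_mean_hu",
         call. = FALSE)
  }
  structure(list(cv_mean_hu = cv_mean_hu, cv_sd_hu = cv_sd_hu,
                 dv_max_hu = dv_max_hu, dv_max_sd_hu = dv_max_sd_hu),
            class = "msct_reference")
}

#' Build a per-scan two-point HU calibration
#'
#' Constructs the affine map that carries one CBCT acquisition's uncalibrated
#' intensity scale onto the MSCT reference scale, anchored on two regions of
#' known reference density measured on that same scan: the contralateral
#' corpus vitreum mean (water-like, low anchor) and the dedicated-volume
#' maximum (dense bone, high anchor). Each acquisition gets its own map.
#'
#' With scan anchors \eqn{(c, d)} and reference anchors \eqn{(C, D)} the map
#' is \eqn{x \mapsto g x + o} with gain \eqn{g = (D - C)/(d - c)}. The
#' default (`literal = TRUE`) intercept \eqn{o = C - g c} sends both anchors
#' exactly onto their reference values, i.e. the published correction
#' equation including its final additive reference-CV term. `literal = FALSE`
#' drops that term (\eqn{o = -g c}), which reproduces the study's printed
#' corrected column slightly more closely and pins the corpus vitreum at 0 HU
#' instead of at the reference CV mean.
#'
#' @param cv_scan_hu This scan's corpus-vitreum mean, uncalibrated HU.
#' @param dvmax_scan_hu This scan's dedicated-volume maximum, uncalibrated HU.
#' @param reference An [msct_reference()].
#' @param tol_hu Degeneracy tolerance: the scan anchors must differ by more
#'   than this many HU (default 1). Anchors closer than noise make the map
#'   meaningless; the wider the anchor spread, the more accurate the map.
#' @param literal Keep the final additive reference-CV term (default `TRUE`).
#' @return A list of class `"scan_calibration"` with elements `gain`,
#'   `offset`, the scan anchors, `reference` and `literal`.
#' @examples
#' cal <- build_calibration(cv_scan_hu = -425, dvmax_scan_hu = 1606)
#' correct_hu(-79, cal)  # implant mean of the same scan, corrected
#' @export
build_calibration <- function(cv_scan_hu, dvmax_scan_hu,
                              reference = msct_reference(),
                              tol_hu = 1, literal = TRUE) {
  stopifnot(is.numeric(cv_scan_hu), length(cv_scan_hu) == 1L,
            is.numeric(dvmax_scan_hu), length(dvmax_scan_hu) == 1L,
            inherits(reference, "msct_reference"), tol_hu > 0)
  if (dvmax_scan_hu < cv_scan_hu) {
    stop("anchor orientation error: dedicated-volume maximum (",
         dvmax_scan_hu, ") below corpus-vitreum mean (", cv_scan_hu,
         "); anchors are swapped", call. = FALSE)
  }
  if (dvmax_scan_hu - cv_scan_hu <= tol_hu) {
    stop("degenerate calibration: scan anchors differ by ",
         format(dvmax_scan_hu - cv_scan_hu), " HU ( <= tolerance ", tol_hu,
         " HU)", call. = FALSE)
  }
  gain <- (reference$dv_max_hu - reference$cv_mean_hu) /
    (dvmax_scan_hu - cv_scan_hu)
  offset <- -gain * cv_scan_hu + if (literal) reference$cv_mean_hu else 0
  structure(list(cv_scan_hu = cv_scan_hu, dvmax_scan_hu = dvmax_scan_hu,
                 reference = reference, gain = gain, offset = offset,
                 literal = literal),
            class = "scan_calibration")
}

#' @export
print.scan_calibration <- function(x, ...) {
  cat(sprintf("Two-point scan calibration: HU' = %.6g * HU %+.6g\n",
              x$gain, x$offset))
  cat(sprintf("  scan anchors  CV %.6g, DVmax %.6g HU\n",
              x$cv_scan_hu, x$dvmax_scan_hu))
  cat(sprintf("  reference     CV %.6g, DVmax %.6g HU  (%s equation)\n",
              x$reference$cv_mean_hu, x$reference$dv_max_hu,
              if (x$literal) "literal" else "no additive term"))
  invisible(x)
}

#' Apply a scan calibration to HU values
#'
#' @param value Uncalibrated HU value(s) measured on the calibrated scan
#'   (vectorised).
#' @param cal A [build_calibration()] result.
#' @return Corrected HU on the MSCT reference scale.
#' @export
correct_hu <- function(value, cal) {
  stopifnot(inherits(cal, "scan_calibration"), is.numeric(value))
  cal$gain * value + cal$offset
}

#' Apply a scan calibration voxelwise to a volume
#'
#' Every voxel is transformed by the same affine map as [correct_hu()] (the
#' scalar and voxel paths share one implementation); grid shape, spacing and
#' origin are preserved.
#'
#' @param volume A [voxel_volume()].
#' @param cal A [build_calibration()] result.
#' @return The corrected [voxel_volume()].
#' @export
correct_volume <- function(volume, cal) {
  stopifnot(inherits(volume, "voxel_volume"))
  bad <- sum(!is.finite(volume$values))
  if (bad > 0L) {
    stop("volume contains ", bad, " non-finite voxel(s); cannot calibrate",
         call. = FALSE)
  }
  volume$values[] <- correct_hu(volume$values, cal)
  volume
}
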