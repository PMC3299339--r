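# Voxel volumes, region masks, region statistics and world-coordinate crops.
#
# Coordinate convention: voxel indices are 1-based in R; the world position
# of voxel (i,j,k) is origin_mm + (c(i,j,k) - 1) * spacing_mm, i.e. origin_mm
# is the world coordinate of the CENTER of the first voxel. All geometry is
# in world millimetres.

#' Construct a voxel volume
#'
#' A 3D scalar grid of HU values with isometric or anisometric voxel spacing
#' and a world-space origin at the center of the first voxel.
#'
#' @param values Numeric 3D array of HU values.
#' @param spacing_mm Voxel edge lengths in mm; a scalar is recycled to all
#'   three axes. All components must be positive.
#' @param origin_mm World coordinate (mm) of the center of voxel (1,1,1).
#' @return A list of class `"voxel_volume"` with `values`, `spacing_mm`,
#'   `origin_mm`.
#' @export
voxel_volume <- function(values, spacing_mm = 0.25, origin_mm = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("'values' must be a 3D array", call. = FALSE)
  }
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0),
            length(origin_mm) == 3L, is.numeric(origin_mm))
  structure(list(values = values, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Voxel volume %d x %d x %d, spacing %s mm, origin (%s) mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing_mm, 4), collapse = " x "),
              paste(signif(x$origin_mm, 4), collapse = ", ")))
  cat(sprintf("  HU range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Construct a region mask over a voxel volume
#'
#' @param selector Logical 3D array, `TRUE` for selected voxels.
#' @param label Region label: `"OI"` (orbital implant), `"CV"` (contralateral
#'   corpus vitreum), `"DV"` (dedicated volume) or `"other"`.
#' @return A list of class `"region_mask"`.
#' @export
region_mask <- function(selector, label = c("other", "OI", "CV", "DV")) {
  label <- match.arg(label)
  if (!is.array(selector) || length(dim(selector)) != 3L ||
      !is.logical(selector)) {
    stop("'selector' must be a logical 3D array", call. = FALSE)
  }
  structure(list(selector = selector, label = label), class = "region_mask")
}

check_congruent <- function(volume, mask) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(mask, "region_mask"))
  if (!identical(dim(volume$values), dim(mask$selector))) {
    stop("mask shape (", paste(dim(mask$selector), collapse = "x"),
         ") does not match volume shape (",
         paste(dim(volume$values), collapse = "x"), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' World coordinates of voxel centers
#'
#' @param volume A [voxel_volume()].
#' @param mask Optional [region_mask()]; when supplied, only centers of
#'   selected voxels are returned (in array storage order).
#' @return An n x 3 matrix of world coordinates in mm.
#' @export
voxel_centers <- function(volume, mask = NULL) {
  stopifnot(inherits(volume, "voxel_volume"))
  d <- dim(volume$values)
  idx <- if (is.null(mask)) {
    arrayInd(seq_len(prod(d)), d)
  } else {
    check_congruent(volume, mask)
    which(mask$selector, arr.ind = TRUE)
  }
  sweep(sweep(idx - 1, 2, volume$spacing_mm, `*`), 2, volume$origin_mm, `+`)
}

#' Region statistics over a masked volume
#'
#' Mean, sample SD (n − 1 denominator; defined as 0 for a single voxel),
#' maximum, voxel count and physical volume of the selected voxels.
#'
#' @param volume A [voxel_volume()].
#' @param mask A congruent, non-empty [region_mask()].
#' @return A list of class `"region_stats"` with `mean_hu`, `sd_hu`,
#'   `max_hu`, `n_voxels`, `volume_mm3` and `label`.
#' @examples
#' v <- voxel_volume(array(c(0, 1000, 5, 5), c(2, 2, 1)), spacing_mm = 1)
#' m <- region_mask(array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1)))
#' region_statistics(v, m)
#' @export
region_statistics <- function(volume, mask) {
  check_congruent(volume, mask)
  vals <- volume$values[mask$selector]
  n <- length(vals)
  if (n == 0L) {
    stop("empty region mask: no voxels selected", call. = FALSE)
  }
  structure(list(
    mean_hu = mean(vals),
    sd_hu = if (n > 1L) stats::sd(vals) else 0,
    max_hu = max(vals),
    n_voxels = n,
    volume_mm3 = n * prod(volume$spacing_mm),
    label = mask$label
  ), class = "region_stats")
}

#' @export
print.region_stats <- function(x, ...) {
  cat(sprintf("Region [%s]: %d voxels (%.2f mm^3), mean %.2f HU (SD %.2f), max %.2f HU\n",
              x$label, x$n_voxels, x$volume_mm3, x$mean_hu, x$sd_hu, x$max_hu))
  invisible(x)
}

#' Crop a volume to an axis-aligned world-space box
#'
#' Returns the minimal sub-grid whose voxel centers lie inside the box (the
#' dedicated orbital volume is delineated this way, as a box bordered by the
#' orbital margins). The origin is updated so retained voxels keep their
#' world coordinates.
#'
#' @param volume A [voxel_volume()].
#' @param bounds_mm Box as `c(x0, x1, y0, y1, z0, z1)` in world mm
#'   (inclusive).
#' @return The cropped [voxel_volume()].
#' @export
crop_dedicated_volume <- function(volume, bounds_mm) {
  stopifnot(inherits(volume, "voxel_volume"),
            is.numeric(bounds_mm), length(bounds_mm) == 6L)
  b <- matrix(bounds_mm, nrow = 2L)  # column per axis: lo, hi
  if (any(b[1, ] > b[2, ])) {
    stop("malformed bounds: each lower bound must not exceed its upper bound",
         call. = FALSE)
  }
  d <- dim(volume$values)
  keep <- lapply(1:3, function(ax) {
    centers <- volume$origin_mm[ax] + (seq_len(d[ax]) - 1) * volume$spacing_mm[ax]
    which(centers >= b[1, ax] & centers <= b[2, ax])
  })
  if (any(lengths(keep) == 0L)) {
    stop("crop box does not contain any voxel centers", call. = FALSE)
  }
  first <- vapply(keep, min, integer(1))
  voxel_volume(
    volume$values[keep[[1]], keep[[2]], keep[[3]], drop = FALSE],
    spacing_mm = volume$spacing_mm,
    origin_mm = volume$origin_mm + (first - 1) * volume$spacing_mm
  )
}

#' Read / write volumes in NIfTI format
#'
#' Scalar volumes and 0/1 mask volumes are exchanged as NIfTI-1 images with a
#' diagonal affine built from the voxel spacing and origin (voxel-center
#' convention).
#'
#' @param volume A [voxel_volume()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_volume()` returns `path` invisibly; `read_volume()` returns
#'   a [voxel_volume()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing_mm
  aff <- diag(4)
  diag(aff)[1:3] <- volume$spacing_mm
  aff[1:3, 4] <- volume$origin_mm
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  voxel_volume(array(as.numeric(img), dim = dim(img)),
               spacing_mm = abs(diag(aff)[1:3]),
               origin_mm = aff[1:3, 4])
}
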