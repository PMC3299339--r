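# Digital orbital phantoms: a porous high-density implant sphere, a
# water-like contralateral corpus vitreum, a dense bone maximum, optional
# marginal spikes, Gaussian noise, and an unknown per-scan affine
# miscalibration emulating an uncalibrated CBCT intensity scale.

#' Specify a digital orbital phantom
#'
#' Defaults emulate the study's acquisition and anatomy at desk scale: a
#' 128^3 grid of 0.25 mm isometric voxels (a 32 mm cube, large enough for
#' both spheres rather than the full 16 cm field of view), an 18 mm porous
#' implant whose sub-resolution porosity is modelled as a seeded fraction of
#' implant voxels at soft-tissue density (the implants' nominal porosity is
#' about 80%), a 12 mm water-like corpus-vitreum sphere, and a small dense
#' bone focus providing the dedicated-volume maximum. The true-scale anchor
#' densities default to the MSCT control values (CV 5.93 HU, DV max
#' 2024.67 HU) so that the default [msct_reference()] is exact for the
#' phantom. The observed volume is `gain * true + offset + noise`.
#'
#' @param grid_shape Grid extents (voxels), length 3 or scalar.
#' @param spacing_mm Isometric voxel edge length, mm (default 0.25).
#' @param implant_center_mm,implant_diameter_mm Implant sphere geometry, mm;
#'   diameter from the manufactured sizes 16/18/20 by default 18.
#' @param implant_true_hu Bulk implant density on the reference scale
#'   (default 2000, below the bone maximum).
#' @param pore_fraction Fraction of implant voxels set to soft-tissue
#'   density, in \[0, 1) (default 0.8).
#' @param cv_center_mm,cv_diameter_mm,cv_true_hu Corpus-vitreum sphere;
#'   density defaults to the reference CV mean 5.93 HU.
#' @param bone_center_mm,bone_diameter_mm,bone_true_hu Dense bone focus; its
#'   density (default 2024.67 HU) is the true dedicated-volume maximum.
#' @param background_hu Soft-tissue background and pore density (default 40).
#' @param spike_count,spike_length_mm Marginal implant-material protrusions
#'   placed radially outward from the implant surface (default none).
#' @param noise_sd_hu Additive Gaussian noise SD, HU (default 30; CBCT is
#'   noisier than MSCT, but no measured magnitude is available, so this is a
#'   free parameter).
#' @param distortion_gain,distortion_offset The scan's unknown affine
#'   miscalibration (defaults 1, 0 = already on the reference scale).
#' @param seed Integer seed; the phantom is bit-reproducible for a fixed
#'   spec.
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(grid_shape = c(128, 128, 128), spacing_mm = 0.25,
                         implant_center_mm = NULL, implant_diameter_mm = 18,
                         implant_true_hu = 2000, pore_fraction = 0.8,
                         cv_center_mm = NULL, cv_diameter_mm = 12,
                         cv_true_hu = 5.93,
                         bone_center_mm = NULL, bone_diameter_mm = 4,
                         bone_true_hu = 2024.67,
                         background_hu = 40,
                         spike_count = 0, spike_length_mm = 2,
                         noise_sd_hu = 30,
                         distortion_gain = 1, distortion_offset = 0,
                         seed = 1L) {
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8),
            spacing_mm > 0,
            implant_diameter_mm > 0, cv_diameter_mm > 0, bone_diameter_mm > 0,
            pore_fraction >= 0, pore_fraction < 1,
            noise_sd_hu >= 0, distortion_gain > 0,
            spike_count >= 0, spike_length_mm >= 0)
  extent <- (grid_shape - 1) * spacing_mm
  # default layout: implant left of center, CV to its right, bone focus below
  if (is.null(implant_center_mm)) {
    implant_center_mm <- c(implant_diameter_mm / 2 + spacing_mm * 2,
                           extent[2] / 2, extent[3] / 2)
  }
  if (is.null(cv_center_mm)) {
    cv_center_mm <- c(implant_center_mm[1] + implant_diameter_mm / 2 +
                        cv_diameter_mm / 2 + 1,
                      extent[2] / 2, extent[3] / 2)
  }
  if (is.null(bone_center_mm)) {
    bone_center_mm <- c(extent[1] / 2, extent[2] / 2,
                        bone_diameter_mm / 2 + spacing_mm)
  }
  spec <- list(grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
               implant_center_mm = implant_center_mm,
               implant_diameter_mm = implant_diameter_mm,
               implant_true_hu = implant_true_hu,
               pore_fraction = pore_fraction,
               cv_center_mm = cv_center_mm, cv_diameter_mm = cv_diameter_mm,
               cv_true_hu = cv_true_hu,
               bone_center_mm = bone_center_mm,
               bone_diameter_mm = bone_diameter_mm,
               bone_true_hu = bone_true_hu,
               background_hu = background_hu,
               spike_count = as.integer(spike_count),
               spike_length_mm = spike_length_mm,
               noise_sd_hu = noise_sd_hu,
               distortion_gain = distortion_gain,
               distortion_offset = distortion_offset,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

# distance of every voxel center from a world point, as a 3D array
center_distance <- function(grid_shape, spacing_mm, point_mm) {
  ax <- lapply(1:3, function(a) (seq_len(grid_shape[a]) - 1) * spacing_mm -
                 point_mm[a])
  plane <- outer(ax[[1]]^2, ax[[2]]^2, `+`)
  arr <- array(0, grid_shape)
  for (k in seq_len(grid_shape[3])) {
    arr[, , k] <- plane + ax[[3]][k]^2
  }
  sqrt(arr)
}

#' Generate a digital orbital phantom with known ground truth
#'
#' Rasterises the spheres of a [phantom_spec()] by voxel-center membership,
#' carves seeded pores in the implant, adds optional radial surface spikes,
#' and produces both the true reference-scale volume and the observed volume
#' after the spec's affine distortion and Gaussian noise. Deterministic for a
#' fixed spec (the global RNG state is left untouched).
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `"phantom"`: `true_volume` and `observed_volume`
#'   ([voxel_volume()]s), `masks` (list of [region_mask()]s `OI`, `CV`, `DV`;
#'   the OI mask includes spike voxels, the DV mask covers the whole grid),
#'   `spike_voxels` (n x 3 index matrix) and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = 64, noise_sd_hu = 0))
#' region_statistics(ph$true_volume, ph$masks$CV)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  sp <- spec$spacing_mm
  extent <- (gs - 1) * sp
  r_oi <- spec$implant_diameter_mm / 2
  if (any(spec$implant_center_mm - r_oi < -sp / 2) ||
      any(spec$implant_center_mm + r_oi > extent + sp / 2) ||
      any(spec$cv_center_mm - spec$cv_diameter_mm / 2 < -sp / 2) ||
      any(spec$cv_center_mm + spec$cv_diameter_mm / 2 > extent + sp / 2)) {
    stop("phantom geometry error: a sphere exceeds the grid", call. = FALSE)
  }

  d_oi <- center_distance(gs, sp, spec$implant_center_mm)
  d_cv <- center_distance(gs, sp, spec$cv_center_mm)
  oi_core <- d_oi <= r_oi
  cv_sel <- d_cv <= spec$cv_diameter_mm / 2
  if (any(oi_core & cv_sel)) {
    stop("phantom geometry error: implant and corpus-vitreum regions overlap",
         call. = FALSE)
  }
  d_bone <- center_distance(gs, sp, spec$bone_center_mm)
  bone_sel <- d_bone <= spec$bone_diameter_mm / 2
  if (!any(bone_sel)) {
    stop("phantom geometry error: bone focus contains no voxel centers",
         call. = FALSE)
  }

  true_vals <- array(spec$background_hu, gs)
  true_vals[cv_sel] <- spec$cv_true_hu
  true_vals[oi_core] <- spec$implant_true_hu
  true_vals[bone_sel] <- spec$bone_true_hu

  with_preserved_rng(spec$seed, {
    # sub-resolution porosity: a seeded fraction of implant voxels at
    # soft-tissue density
    oi_idx <- which(oi_core)
    n_pore <- floor(spec$pore_fraction * length(oi_idx))
    if (n_pore > 0L) {
      true_vals[sample(oi_idx, n_pore)] <- spec$background_hu
    }

    # radial spikes of implant material beyond the nominal surface
    spike_sel <- array(FALSE, gs)
    if (spec$spike_count > 0L && spec$spike_length_mm > 0) {
      for (s in seq_len(spec$spike_count)) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        ts <- seq(0, spec$spike_length_mm, by = sp / 2)
        pts <- t(spec$implant_center_mm + outer(u, r_oi + ts))
        ijk <- round(sweep(pts, 2, sp, `/`)) + 1
        ok <- ijk[, 1] >= 1 & ijk[, 1] <= gs[1] &
          ijk[, 2] >= 1 & ijk[, 2] <= gs[2] &
          ijk[, 3] >= 1 & ijk[, 3] <= gs[3]
        spike_sel[ijk[ok, , drop = FALSE]] <- TRUE
      }
      spike_sel <- spike_sel & !oi_core & !cv_sel & !bone_sel
      true_vals[spike_sel] <- spec$implant_true_hu
    }

    noise <- if (spec$noise_sd_hu > 0) {
      array(stats::rnorm(prod(gs), 0, spec$noise_sd_hu), gs)
    } else {
      0
    }
    obs_vals <- spec$distortion_gain * true_vals + spec$distortion_offset +
      noise
  })

  oi_sel <- oi_core | spike_sel
  structure(list(
    true_volume = voxel_volume(true_vals, spacing_mm = sp),
    observed_volume = voxel_volume(obs_vals, spacing_mm = sp),
    masks = list(OI = region_mask(oi_sel, "OI"),
                 CV = region_mask(cv_sel, "CV"),
                 DV = region_mask(array(TRUE, gs), "DV")),
    spike_voxels = which(spike_sel, arr.ind = TRUE),
    spec = spec
  ), class = "phantom")
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr  # forces the promise in the caller's frame
}
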