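# Sphere geometry: three-point diameter estimation, algebraic least-squares
# fitting, surface extraction from rasterized masks, and the within/beyond
# factory-diameter split.

#' Construct a sphere
#'
#' @param center_mm World-space center, length-3, mm.
#' @param radius_mm Radius in mm, positive.
#' @return A list of class `"sphere"` with `center_mm`, `radius_mm` and
#'   `diameter_mm`.
#' @export
sphere <- function(center_mm, radius_mm) {
  stopifnot(is.numeric(center_mm), length(center_mm) == 3L,
            is.numeric(radius_mm), length(radius_mm) == 1L)
  if (!(radius_mm > 0)) stop("sphere radius must be positive", call. = FALSE)
  structure(list(center_mm = as.numeric(center_mm),
                 radius_mm = radius_mm,
                 diameter_mm = 2 * radius_mm),
            class = "sphere")
}

#' @export
print.sphere <- function(x, ...) {
  cat(sprintf("Sphere: center (%s) mm, radius %.4f mm (diameter %.4f mm)\n",
              paste(signif(x$center_mm, 6), collapse = ", "),
              x$radius_mm, x$diameter_mm))
  invisible(x)
}

#' Sphere through three surface points
#'
#' The three-point sphere-drawing construction used for implant diameter
#' estimation: the unique circle through three non-collinear points is taken
#' as a great circle, so the sphere center is the circumcenter in the points'
#' plane and the radius the circumradius. For three points picked on an
#' implant's equator this recovers the implant sphere exactly.
#'
#' @param p1,p2,p3 Length-3 numeric world coordinates in mm.
#' @param tol_mm2 Degeneracy tolerance on the triangle area (mm^2); points
#'   spanning less area are treated as collinear.
#' @return A [sphere()].
#' @examples
#' sphere_from_three_points(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0))  # unit sphere
#' @export
sphere_from_three_points <- function(p1, p2, p3, tol_mm2 = 1e-9) {
  stopifnot(length(p1) == 3L, length(p2) == 3L, length(p3) == 3L)
  a <- as.numeric(p2 - p1)
  b <- as.numeric(p3 - p1)
  ab <- cross3(a, b)
  area <- sqrt(sum(ab^2)) / 2
  if (area < tol_mm2) {
    stop("degenerate geometry: the three points are collinear or coincident ",
         "(triangle area ", format(area), " mm^2)", call. = FALSE)
  }
  # circumcenter relative to p1, in the plane spanned by a and b
  rel <- (sum(a^2) * cross3(b, ab) + sum(b^2) * cross3(ab, a)) /
    (2 * sum(ab^2))
  center <- as.numeric(p1) + rel
  sphere(center, sqrt(sum(rel^2)))
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Algebraic least-squares sphere fit
#'
#' Fits a sphere to n >= 4 points by the linearised (Kasa) normal equations:
#' minimising the residuals of \eqn{|p|^2 = 2 c \cdot p + (r^2 - |c|^2)} is a
#' linear problem in the center and a radius carrier. Exact when the points
#' lie on a sphere; robust for noisy surface samples where the three-point
#' construction is not.
#'
#' @param points An n x 3 matrix (or coercible) of world coordinates in mm,
#'   n >= 4.
#' @return A [sphere()].
#' @export
fit_sphere_least_squares <- function(points) {
  P <- as.matrix(points)
  if (ncol(P) != 3L) stop("'points' must be n x 3", call. = FALSE)
  if (nrow(P) < 4L) {
    stop("need at least 4 points for a least-squares sphere fit",
         call. = FALSE)
  }
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  qr_A <- qr(crossprod(A))
  if (qr_A$rank < 4L) {
    stop("degenerate geometry: points do not determine a sphere ",
         "(rank-deficient normal equations)", call. = FALSE)
  }
  s <- solve(qr_A, crossprod(A, b))
  center <- s[1:3]
  r2 <- s[4] + sum(center^2)
  if (!(r2 > 0)) {
    stop("degenerate geometry: non-positive fitted squared radius",
         call. = FALSE)
  }
  sphere(center, sqrt(r2))
}

#' Surface shell of a rasterized region
#'
#' Extracts boundary voxels of a mask by 6-connectivity. `"inner"` keeps
#' selected voxels with at least one unselected face neighbour, `"outer"` the
#' unselected voxels face-adjacent to the region, and `"both"` (default)
#' their union. Because inner-surface voxel centers sit up to one spacing
#' inside the continuous surface, fitting centers of the combined shell —
#' which straddles the surface — removes most of the rasterization bias in
#' diameter estimates.
#'
#' @param mask A [region_mask()].
#' @param shell `"both"`, `"inner"` or `"outer"`.
#' @return A logical 3D array selecting the shell voxels.
#' @export
surface_shell <- function(mask, shell = c("both", "inner", "outer")) {
  shell <- match.arg(shell)
  stopifnot(inherits(mask, "region_mask"))
  a <- mask$selector
  eroded <- a
  dilated <- a
  for (ax in 1:3) {
    for (k in c(-1L, 1L)) {
      nb <- shift_array(a, ax, k)
      eroded <- eroded & nb
      dilated <- dilated | nb
    }
  }
  inner <- a & !eroded
  outer <- dilated & !a
  switch(shell, inner = inner, outer = outer, both = inner | outer)
}

# Shift a 3D logical array by k voxels along axis ax, padding with FALSE
# (voxels at the grid border count as boundary).
shift_array <- function(a, ax, k) {
  d <- dim(a)
  out <- array(FALSE, d)
  n <- d[ax]
  src <- seq_len(n) - k
  ok <- src >= 1L & src <= n
  idx_dst <- rep(list(quote(expr = )), 3)
  idx_src <- idx_dst
  idx_dst[[ax]] <- which(ok)
  idx_src[[ax]] <- src[ok]
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Estimate an implant's diameter from its voxel mask
#'
#' Fits a least-squares sphere to the world-space centers of the mask's
#' surface shell voxels and reports the fitted sphere. On noiseless
#' rasterized spheres at 0.25 mm spacing the estimate is well within one
#' voxel spacing of the true diameter.
#'
#' @param volume The [voxel_volume()] the mask refers to (supplies spacing
#'   and origin).
#' @param mask The implant [region_mask()].
#' @param shell Passed to [surface_shell()].
#' @return A [sphere()].
#' @export
estimate_implant_diameter <- function(volume, mask,
                                      shell = c("both", "inner", "outer")) {
  check_congruent(volume, mask)
  sel <- surface_shell(mask, match.arg(shell))
  fit_sphere_least_squares(
    voxel_centers(volume, region_mask(sel, mask$label))
  )
}

#' Split an implant region by the factory sphere
#'
#' Partitions the masked voxels by whether their world-space centers lie
#' within the manufacturer's nominal (factory) sphere. Marginal spikes beyond
#' the factory diameter land in the `beyond` mask; the split is purely
#' geometric and carries no claim about whether such voxels are implant
#' material or imaging artefact.
#'
#' @param volume A [voxel_volume()].
#' @param mask The implant [region_mask()].
#' @param factory The factory [sphere()] (nominal diameter, assumed center).
#' @return A list with `inside` and `beyond` [region_mask()]s;
#'   `inside | beyond` equals the input mask and the two are disjoint.
#' @export
classify_against_factory_sphere <- function(volume, mask, factory) {
  check_congruent(volume, mask)
  stopifnot(inherits(factory, "sphere"))
  ctr <- voxel_centers(volume, mask)
  d2 <- colSums((t(ctr) - factory$center_mm)^2)
  inside_sel <- array(FALSE, dim(mask$selector))
  idx <- which(mask$selector)
  inside_sel[idx[d2 <= factory$radius_mm^2]] <- TRUE
  beyond_sel <- mask$selector & !inside_sel
  list(inside = region_mask(inside_sel, mask$label),
       beyond = region_mask(beyond_sel, mask$label))
}
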