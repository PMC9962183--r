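#' Signed or absolute polygon area (shoelace formula)
#'
#' @param points `n x 2` matrix of polygon vertices (closed implicitly; the
#'   last vertex connects back to the first).
#' @param signed if `TRUE`, return the signed area (positive for
#'   counterclockwise winding); default is the absolute value used for
#'   reported areas.
#' @return area in mm^2.
#' @export
polygon_area <- function(points, signed = FALSE) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("polygon needs at least 3 vertices")
  x <- points[, 1L]; y <- points[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  a <- sum(x * y2 - x2 * y) / 2
  if (signed) a else abs(a)
}

#' Perimeter of a closed polygon
#'
#' @inheritParams polygon_area
#' @return length in mm.
#' @export
polygon_perimeter <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("polygon needs at least 3 vertices")
  d <- points - points[c(2:nrow(points), 1L), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' Area centroid of a simple polygon
#'
#' @inheritParams polygon_area
#' @return length-2 numeric vector.
#' @export
polygon_centroid <- function(points) {
  points <- as.matrix(points)
  x <- points[, 1L]; y <- points[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) stop("degenerate polygon: zero area")
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

# Raw area integrals of a polygon about the coordinate origin via
# Green's-theorem edge closed forms. Signed: CCW polygons give positive A.
# Returns A, Sx = int x dA, Sy = int y dA, Ixx = int y^2 dA,
# Iyy = int x^2 dA, Ixy = int xy dA.
polygon_raw_moments <- function(points) {
  points <- as.matrix(points)
  x <- points[, 1L]; y <- points[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  cr <- x * y2 - x2 * y
  list(
    A   = sum(cr) / 2,
    Sx  = sum((x + x2) * cr) / 6,
    Sy  = sum((y + y2) * cr) / 6,
    Ixx = sum((y^2 + y * y2 + y2^2) * cr) / 12,
    Iyy = sum((x^2 + x * x2 + x2^2) * cr) / 12,
    Ixy = sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / 24
  )
}

#' Centroid and second moments of the cortical (annular) region
#'
#' Computes the exact area integrals of the region between a periosteal
#' (outer) and endosteal (inner) contour -- the cortical cross-section --
#' using per-edge Green's-theorem closed forms, and reports the second
#' moments about the cortical-region area centroid with axes parallel to
#' x (mediolateral) and y (anteroposterior): `Ix = int y^2 dA`,
#' `Iy = int x^2 dA`, `Ixy = int xy dA`.
#'
#' @param periosteal outer contour, `n x 2`, counterclockwise.
#' @param endosteal inner contour, `m x 2`, counterclockwise, strictly
#'   inside the outer contour.
#' @return list with `centroid`, `area`, `Ix`, `Iy`, `Ixy`.
#' @export
cortical_moments <- function(periosteal, endosteal) {
  mo <- polygon_raw_moments(periosteal)
  mi <- polygon_raw_moments(endosteal)
  if (mo$A <= 0 || mi$A <= 0) {
    stop("contours must be counterclockwise (positive signed area)")
  }
  if (mi$A >= mo$A) stop("endosteal contour is not smaller than periosteal")
  if (!point_in_contour(endosteal[1L, ], periosteal)) {
    stop("endosteal contour is not nested inside the periosteal contour")
  }
  A <- mo$A - mi$A
  cx <- (mo$Sx - mi$Sx) / A
  cy <- (mo$Sy - mi$Sy) / A
  # parallel-axis shift of raw moments to the centroid
  Ix <- (mo$Ixx - mi$Ixx) - A * cy^2
  Iy <- (mo$Iyy - mi$Iyy) - A * cx^2
  Ixy <- (mo$Ixy - mi$Ixy) - A * cx * cy
  list(centroid = c(cx, cy), area = A, Ix = Ix, Iy = Iy, Ixy = Ixy)
}

# Even-odd test for a single point against a contour (R fallback wrapper).
point_in_contour <- function(point, contour) {
  as.logical(points_in_polygon(point[1L], point[2L],
                               contour[, 1L], contour[, 2L]))
}

#' Principal second moments of area and principal-axis angle
#'
#' Eigenvalues of the 2D inertia tensor:
#' `Imin, Imax = (Ix + Iy)/2 -/+ sqrt(((Iy - Ix)/2)^2 + Ixy^2)`, and the
#' principal-axis angle `theta = atan2(2 Ixy, Iy - Ix) / 2`, folded into
#' `(-pi/4, pi/4]` (the tilt of the nearest principal axis relative to the
#' mediolateral x axis; rotating the section by `-theta` zeroes `Ixy`).
#' Degenerate isotropic sections (`Ix = Iy`, `Ixy = 0`) report `theta = 0`.
#'
#' @param Ix,Iy,Ixy second moments about centroidal x/y axes (mm^4).
#' @return list with `Imin`, `Imax`, `theta` (radians).
#' @export
principal_moments <- function(Ix, Iy, Ixy) {
  if (Ix <= 0 || Iy <= 0) stop("Ix and Iy must be positive")
  mean_i <- (Ix + Iy) / 2
  rad <- sqrt(((Iy - Ix) / 2)^2 + Ixy^2)
  theta <- if (Ixy == 0 && Ix == Iy) 0 else atan2(2 * Ixy, Iy - Ix) / 2
  # fold into (-pi/4, pi/4]
  while (theta > pi / 4) theta <- theta - pi / 2
  while (theta <= -pi / 4) theta <- theta + pi / 2
  list(Imin = mean_i - rad, Imax = mean_i + rad, theta = theta)
}

#' Maximum chord lengths of the periosteal contour
#'
#' `dy`/`dx` are the maximum perpendicular distances of periosteal vertices
#' from the centroidal x and y axes; `dx_theta`/`dy_theta` the same after
#' rotating the vertices about the centroid by `-theta` (into the principal
#' frame); `rmax` is the maximum radial distance from the centroid.
#'
#' @param periosteal outer contour, `n x 2`.
#' @param centroid length-2 centroid of the cortical region.
#' @param theta principal-axis angle (radians).
#' @return list with `dx`, `dy`, `dx_theta`, `dy_theta`, `rmax` (mm).
#' @export
chord_lengths <- function(periosteal, centroid, theta) {
  rel <- sweep(as.matrix(periosteal), 2L, centroid)
  dx <- max(abs(rel[, 1L]))
  dy <- max(abs(rel[, 2L]))
  ct <- cos(-theta); st <- sin(-theta)
  xr <- rel[, 1L] * ct - rel[, 2L] * st
  yr <- rel[, 1L] * st + rel[, 2L] * ct
  list(dx = dx, dy = dy,
       dx_theta = max(abs(xr)), dy_theta = max(abs(yr)),
       rmax = max(sqrt(rowSums(rel^2))))
}

#' Section moduli
#'
#' `Zx = Ix/dy`, `Zy = Iy/dx`, `Zmin = Imin/dx_theta`,
#' `Zmax = Imax/dy_theta`, `Zpol = J/rmax`.
#'
#' @param Ix,Iy,Imin,Imax,J moments (mm^4).
#' @param dx,dy,dx_theta,dy_theta,rmax chord lengths (mm).
#' @return list with `Zx`, `Zy`, `Zmin`, `Zmax`, `Zpol` (mm^3).
#' @export
section_moduli <- function(Ix, Iy, Imin, Imax, J, dx, dy, dx_theta, dy_theta,
                           rmax) {
  if (min(dx, dy, dx_theta, dy_theta, rmax) <= 0) {
    stop("all chord lengths must be positive")
  }
  list(Zx = Ix / dy, Zy = Iy / dx, Zmin = Imin / dx_theta,
       Zmax = Imax / dy_theta, Zpol = J / rmax)
}

#' All section properties of a sampled cross-section
#'
#' Computes every reported geometric/biomechanical quantity for one
#' cross-section: total, medullary and cortical areas; periosteal and
#' endosteal perimeters; radial cortical-thickness statistics; centroid;
#' centroidal and principal second moments of area; polar moment
#' `J = Ix + Iy`; chord lengths; and the five section moduli. Moments are
#' computed from the full extracted contours; the semilandmarks feed only
#' the thickness statistics (set `use_semilandmarks = TRUE` to rebuild the
#' contours from the semilandmark polygons instead, for sensitivity
#' analysis).
#'
#' @param section a `cross_section` with classified contours and sampled
#'   semilandmarks (see [sample_semilandmarks()]).
#' @param use_semilandmarks compute moments from the semilandmark polygons
#'   rather than the full contours (default `FALSE`).
#' @return a named list of class `section_properties`.
#' @export
section_properties <- function(section, use_semilandmarks = FALSE) {
  if (is.null(section$periosteal_slm)) {
    stop("section has no semilandmarks; run sample_semilandmarks() first")
  }
  peri <- if (use_semilandmarks) section$periosteal_slm else section$periosteal
  endo <- if (use_semilandmarks) section$endosteal_slm else section$endosteal
  TA <- polygon_area(peri)
  MA <- polygon_area(endo)
  CA <- TA - MA
  thick <- radial_thickness(section)
  mom <- cortical_moments(peri, endo)
  J <- mom$Ix + mom$Iy
  pr <- principal_moments(mom$Ix, mom$Iy, mom$Ixy)
  ch <- chord_lengths(peri, mom$centroid, pr$theta)
  zz <- section_moduli(mom$Ix, mom$Iy, pr$Imin, pr$Imax, J,
                       ch$dx, ch$dy, ch$dx_theta, ch$dy_theta, ch$rmax)
  structure(list(
    level = section$level, z_height = section$z_height,
    total_area = TA, medullary_area = MA, cortical_area = CA,
    periosteal_perimeter = polygon_perimeter(peri),
    endosteal_perimeter = polygon_perimeter(endo),
    thickness_min = min(thick), thickness_mean = mean(thick),
    thickness_max = max(thick),
    centroid_x = mom$centroid[1L], centroid_y = mom$centroid[2L],
    Ix = mom$Ix, Iy = mom$Iy, Ixy = mom$Ixy,
    Imin = pr$Imin, Imax = pr$Imax, theta = pr$theta, J = J,
    dx = ch$dx, dy = ch$dy, dx_theta = ch$dx_theta, dy_theta = ch$dy_theta,
    rmax = ch$rmax,
    Zx = zz$Zx, Zy = zz$Zy, Zmin = zz$Zmin, Zmax = zz$Zmax, Zpol = zz$Zpol
  ), class = "section_properties")
}

# Property columns exported to the per-specimen CSV, in order.
section_property_names <- function() {
  c("total_area", "medullary_area", "cortical_area",
    "periosteal_perimeter", "endosteal_perimeter",
    "thickness_min", "thickness_mean", "thickness_max",
    "centroid_x", "centroid_y",
    "Ix", "Iy", "Ixy", "Imin", "Imax", "theta", "J",
    "dx", "dy", "dx_theta", "dy_theta", "rmax",
    "Zx", "Zy", "Zmin", "Zmax", "Zpol")
}

#' Brute-force rasterization oracle for areas and moments
#'
#' Literal discretized-element implementation: grid cells of side
#' `cell_size` whose centres fall inside the periosteal contour and outside
#' the endosteal contour contribute `dA = cell_size^2`. Sums approximate the
#' cortical area and the centroidal second moments with O(cell_size) error.
#' Used as an independent cross-check of the exact polygon formulas, never
#' as the production path.
#'
#' @inheritParams cortical_moments
#' @param cell_size grid spacing in mm; must be at most 1/50 of the
#'   periosteal bounding-box diagonal.
#' @return list with `area`, `centroid`, `Ix`, `Iy`, `Ixy`, `J`.
#' @export
rasterize_oracle <- function(periosteal, endosteal, cell_size) {
  periosteal <- as.matrix(periosteal)
  endosteal <- as.matrix(endosteal)
  rng_x <- range(periosteal[, 1L])
  rng_y <- range(periosteal[, 2L])
  diag_len <- sqrt(diff(rng_x)^2 + diff(rng_y)^2)
  if (cell_size <= 0 || cell_size > diag_len / 50) {
    stop("cell_size must be positive and at most 1/50 of the bounding-box diagonal")
  }
  xs <- seq(rng_x[1L] + cell_size / 2, rng_x[2L], by = cell_size)
  ys <- seq(rng_y[1L] + cell_size / 2, rng_y[2L], by = cell_size)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  inside <- points_in_polygon(gx, gy, periosteal[, 1L], periosteal[, 2L]) &
    !points_in_polygon(gx, gy, endosteal[, 1L], endosteal[, 2L])
  gx <- gx[inside]; gy <- gy[inside]
  dA <- cell_size^2
  A <- length(gx) * dA
  cx <- mean(gx); cy <- mean(gy)
  Ix <- sum((gy - cy)^2) * dA
  Iy <- sum((gx - cx)^2) * dA
  Ixy <- sum((gx - cx) * (gy - cy)) * dA
  list(area = A, centroid = c(cx, cy), Ix = Ix, Iy = Iy, Ixy = Ixy,
       J = Ix + Iy)
}
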