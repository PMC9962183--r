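# Polygon primitives and section-property formulas against closed forms.

test_that("polygon area, perimeter and centroid match closed forms", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_perimeter(sq), 4)
  expect_equal(polygon_centroid(sq), c(0.5, 0.5))

  tri <- rbind(c(0, 0), c(2, 0), c(0, 2))
  expect_equal(polygon_area(tri), 2)

  # signed variant: clockwise winding is negative
  expect_lt(polygon_area(sq[4:1, ], signed = TRUE), 0)

  hexa <- circle_contour(R = 1, n = 6)
  expect_equal(polygon_perimeter(hexa), 6)

  # inscribed n-gon: area (n/2) sin(2pi/n), perimeter 2 n sin(pi/n)
  ng <- circle_contour(R = 1, n = 4096)
  expect_equal(polygon_area(ng), pi, tolerance = 1e-5)
  expect_equal(polygon_perimeter(ng), 2 * pi, tolerance = 1e-5)

  # L-shaped hexagon: 2x2 square minus its upper-right unit square
  ell <- rbind(c(0, 0), c(2, 0), c(2, 1), c(1, 1), c(1, 2), c(0, 2))
  expect_equal(polygon_area(ell), 3)
  expect_equal(polygon_centroid(ell), c(5 / 6, 5 / 6))

  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))), "at least 3")
})

test_that("cortical_moments matches annulus and rectangle closed forms", {
  peri <- circle_contour(R = 2, n = 4096)
  endo <- circle_contour(R = 1, n = 4096)
  m <- cortical_moments(peri, endo)
  expect_equal(m$area, 3 * pi, tolerance = 1e-3)
  expect_equal(m$Ix, 15 * pi / 4, tolerance = 1e-3)
  expect_equal(m$Iy, 15 * pi / 4, tolerance = 1e-3)
  expect_equal(m$Ixy, 0, tolerance = 1e-9)

  # rectangle 2 (x) by 4 (y) minus centred 1 x 2 rectangle
  rect <- function(w, h) {
    rbind(c(-w / 2, -h / 2), c(w / 2, -h / 2), c(w / 2, h / 2),
          c(-w / 2, h / 2))
  }
  m2 <- cortical_moments(rect(2, 4), rect(1, 2))
  expect_equal(m2$Ix, (2 * 4^3 - 1 * 2^3) / 12)
  expect_equal(m2$Iy, (4 * 2^3 - 2 * 1^3) / 12)
  expect_equal(m2$Ixy, 0)

  # centroidal moments are translation invariant
  shift <- c(17, -5)
  m3 <- cortical_moments(sweep(peri, 2, shift, "+"),
                         sweep(endo, 2, shift, "+"))
  expect_equal(m3$Ix, m$Ix, tolerance = 1e-9)
  expect_equal(m3$Iy, m$Iy, tolerance = 1e-9)
  expect_equal(m3$centroid, m$centroid + shift, tolerance = 1e-9)

  # nesting violations are errors
  expect_error(cortical_moments(endo, peri), "not smaller")
  expect_error(cortical_moments(peri, sweep(endo, 2, -c(5, 0))), "nested")
})

test_that("solid-ellipse raw moments match pi a b^3 / 4 forms", {
  ell <- ellipse_contour(a = 3, b = 1, n = 8192)
  m <- boneCSG:::polygon_raw_moments(ell)
  expect_equal(m$Ixx, 3 * pi / 4, tolerance = 1e-5)   # Ix = pi a b^3 / 4
  expect_equal(m$Iyy, 27 * pi / 4, tolerance = 1e-5)  # Iy = pi a^3 b / 4
  expect_equal(m$A, 3 * pi, tolerance = 1e-5)
})

test_that("principal_moments gives eigenvalues and a cross-moment-zeroing angle", {
  p <- principal_moments(2, 2, 0)
  expect_equal(c(p$Imin, p$Imax, p$theta), c(2, 2, 0))

  p <- principal_moments(1, 3, 0)
  expect_equal(c(p$Imin, p$Imax), c(1, 3))

  p <- principal_moments(2, 2, 1)
  expect_equal(c(p$Imin, p$Imax, p$theta), c(1, 3, pi / 4))

  # rotation oracle: a rotated ellipse's measured theta recovers the tilt
  # and rotating the section by -theta zeroes Ixy
  for (tilt in c(-0.6, 0.2, 0.7)) {
    peri <- ellipse_contour(3, 1.5, n = 2048, rot = tilt)
    endo <- ellipse_contour(1.5, 0.75, n = 2048, rot = tilt)
    m <- cortical_moments(peri, endo)
    pr <- principal_moments(m$Ix, m$Iy, m$Ixy)
    fold <- function(x) {
      while (x > pi / 4) x <- x - pi / 2
      while (x <= -pi / 4) x <- x + pi / 2
      x
    }
    expect_equal(pr$theta, fold(tilt), tolerance = 1e-6)
    rot <- function(pts, a) {
      cbind(pts[, 1] * cos(a) - pts[, 2] * sin(a),
            pts[, 1] * sin(a) + pts[, 2] * cos(a))
    }
    m2 <- cortical_moments(rot(peri, -pr$theta), rot(endo, -pr$theta))
    expect_lt(abs(m2$Ixy), 1e-6 * pr$Imax)
    # trace invariance under the eigendecomposition
    expect_equal(pr$Imin + pr$Imax, m$Ix + m$Iy)
  }
})

test_that("chord lengths and section moduli follow the literal pairing", {
  peri <- circle_contour(R = 2, n = 1024)
  ch <- chord_lengths(peri, c(0, 0), 0)
  expect_equal(unlist(ch), c(dx = 2, dy = 2, dx_theta = 2, dy_theta = 2,
                             rmax = 2),
               tolerance = 1e-5)

  ell <- ellipse_contour(3, 1, n = 4096)
  ch <- chord_lengths(ell, c(0, 0), 0)
  expect_equal(ch$dx, 3, tolerance = 1e-6)
  expect_equal(ch$dy, 1, tolerance = 1e-6)
  expect_equal(ch$rmax, 3, tolerance = 1e-6)

  # pre-rotated ellipse: rmax unchanged; de-rotation by theta restores dx/dy
  ell30 <- ellipse_contour(3, 1, n = 4096, rot = pi / 6)
  ch30 <- chord_lengths(ell30, c(0, 0), pi / 6)
  expect_equal(ch30$rmax, 3, tolerance = 1e-6)
  expect_equal(ch30$dx_theta, 3, tolerance = 1e-4)
  expect_equal(ch30$dy_theta, 1, tolerance = 1e-4)

  z <- section_moduli(Ix = 15 * pi / 4, Iy = 15 * pi / 4,
                      Imin = 15 * pi / 4, Imax = 15 * pi / 4,
                      J = 15 * pi / 2, dx = 2, dy = 2, dx_theta = 2,
                      dy_theta = 2, rmax = 2)
  expect_equal(z$Zx, 15 * pi / 8)
  expect_equal(z$Zpol, 15 * pi / 4)
  expect_equal(z$Zx, z$Zy)
  expect_equal(z$Zmin, z$Zmax)

  # solid ellipse a=3, b=1: Zx = (3pi/4)/1, Zy = (27pi/4)/3
  ze <- section_moduli(3 * pi / 4, 27 * pi / 4, 3 * pi / 4, 27 * pi / 4,
                       30 * pi / 4, dx = 3, dy = 1, dx_theta = 3,
                       dy_theta = 1, rmax = 3)
  expect_equal(ze$Zx, 3 * pi / 4)
  expect_equal(ze$Zy, 9 * pi / 4)
})

test_that("rasterize_oracle converges to closed forms", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  hole <- rbind(c(0.4, 0.4), c(0.6, 0.4), c(0.6, 0.6), c(0.4, 0.6)) * 1e-3 +
    0.5 - 5e-4
  r <- rasterize_oracle(sq, hole, cell_size = 1e-3)
  expect_equal(r$area, 1, tolerance = 5e-3)

  peri <- circle_contour(R = 2, n = 1024)
  endo <- circle_contour(R = 1, n = 1024)
  r <- rasterize_oracle(peri, endo, cell_size = 5e-3)
  expect_equal(r$Ix, 15 * pi / 4, tolerance = 1e-2)
  expect_equal(r$area, 3 * pi, tolerance = 1e-2)

  expect_error(rasterize_oracle(peri, endo, cell_size = 1), "1/50")
})

test_that("exact moments and raster oracle agree on random nested star pairs", {
  set.seed(42)
  for (i in 1:12) {
    peri <- star_polygon(R = 2, wobble = 0.25)
    endo <- star_polygon(R = 1, wobble = 0.2)
    m <- cortical_moments(peri, endo)
    r <- rasterize_oracle(peri, endo, cell_size = 0.01)
    expect_lt(rel_err(r$area, m$area), 0.01)
    expect_lt(rel_err(r$Ix, m$Ix), 0.01)
    expect_lt(rel_err(r$Iy, m$Iy), 0.01)
    expect_lt(rel_err(r$J, m$Ix + m$Iy), 0.01)
  }
})

test_that("scaling laws: areas s^2, moments s^4, moduli s^3", {
  set.seed(7)
  peri <- star_polygon(R = 2)
  endo <- star_polygon(R = 1)
  m1 <- cortical_moments(peri, endo)
  s <- 2.5
  m2 <- cortical_moments(peri * s, endo * s)
  expect_equal(m2$area, s^2 * m1$area, tolerance = 1e-12)
  expect_equal(m2$Ix, s^4 * m1$Ix, tolerance = 1e-12)
  expect_equal(m2$Iy, s^4 * m1$Iy, tolerance = 1e-12)
  ch1 <- chord_lengths(peri, m1$centroid, 0)
  ch2 <- chord_lengths(peri * s, m2$centroid, 0)
  expect_equal(ch2$rmax, s * ch1$rmax)
  expect_equal((m2$Ix / ch2$dy) / (m1$Ix / ch1$dy), s^3, tolerance = 1e-12)
})

test_that("section_properties satisfies the tensor identities on a real section", {
  sp <- generate_bone(tube_spec())
  sec <- sample_semilandmarks(slice_at_level(sp, 0.5))
  p <- section_properties(sec)
  expect_identical(p$J, p$Ix + p$Iy)                       # exact by formula
  expect_equal(p$Imin + p$Imax, p$Ix + p$Iy)
  expect_equal(p$cortical_area, p$total_area - p$medullary_area,
               tolerance = 1e-9)
  expect_lte(p$Imin, min(p$Ix, p$Iy))
  expect_gte(p$Imax, max(p$Ix, p$Iy))
  expect_true(p$theta > -pi / 4 && p$theta <= pi / 4)
  expect_true(all(unlist(p[c("total_area", "medullary_area",
                             "cortical_area", "Zx", "Zy", "Zmin", "Zmax",
                             "Zpol", "dx", "dy", "rmax")]) > 0))

  # in-plane 90-degree rotation: x/y quantities swap, invariants unchanged
  rot90 <- function(pts) cbind(-pts[, 2], pts[, 1])
  sec2 <- sec
  sec2$periosteal <- rot90(sec$periosteal)
  sec2$endosteal <- rot90(sec$endosteal)
  sec2$periosteal_slm <- rot90(sec$periosteal_slm)
  sec2$endosteal_slm <- rot90(sec$endosteal_slm)
  p2 <- section_properties(sec2)
  expect_equal(p2$total_area, p$total_area)
  expect_equal(p2$J, p$J, tolerance = 1e-12)
  expect_equal(p2$Imin, p$Imin, tolerance = 1e-9)
  expect_equal(p2$Imax, p$Imax, tolerance = 1e-9)
  expect_equal(p2$Zpol, p$Zpol, tolerance = 1e-9)
  expect_equal(p2$Ix, p$Iy, tolerance = 1e-9)
  expect_equal(p2$Iy, p$Ix, tolerance = 1e-9)
  expect_equal(p2$Zx, p$Zy, tolerance = 1e-9)

  # unsampled section is a precondition error
  raw <- slice_at_level(sp, 0.5)
  expect_error(section_properties(raw), "semilandmarks")
})
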