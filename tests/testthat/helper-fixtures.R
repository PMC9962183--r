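# Shared fixtures: polygonized conics, star polygons, small tube specs.

circle_contour <- function(R = 1, center = c(0, 0), n = 256) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + R * cos(th), center[2] + R * sin(th))
}

ellipse_contour <- function(a, b, center = c(0, 0), n = 256, rot = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  x <- a * cos(th)
  y <- b * sin(th)
  cbind(center[1] + x * cos(rot) - y * sin(rot),
        center[2] + x * sin(rot) + y * cos(rot))
}

# Random star-shaped polygon about the origin: smooth positive radius with
# a few low-order harmonics.
star_polygon <- function(R = 2, wobble = 0.25, n = 128, n_harm = 4) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  r <- rep(1, n)
  for (k in seq_len(n_harm)) {
    r <- r + wobble / n_harm *
      (runif(1, -1, 1) * cos(k * th) + runif(1, -1, 1) * sin(k * th))
  }
  cbind(R * r * cos(th), R * r * sin(th))
}

# Small fast tube spec: constant circular annulus, analytic truth trivial.
tube_spec <- function(R = 15, r = 10, bl = 400, n_rings = 17L,
                      n_angular = 48L, ...) {
  synthetic_bone_spec(biomechanical_length = bl, n_rings = n_rings,
                      n_angular = n_angular,
                      a_p = R, b_p = R, a_e = r, b_e = r, ...)
}

random_rotation <- function() {
  # QR of a random matrix, sign-fixed to a proper rotation
  qr_d <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

withr_local_tempfile <- function(ext = "") tempfile(fileext = ext)

withr_local_tempdir <- function() {
  d <- tempfile()
  dir.create(d)
  d
}
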