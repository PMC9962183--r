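#' Sampling configuration for diaphyseal cross-sections
#'
#' Defaults follow the standard protocol: 60 evenly spaced sections between
#' 20% (distal) and 80% (proximal) of biomechanical length, 21 equiangular
#' semilandmarks per contour.
#'
#' @param n_sections number of sections (>= 2, default 60).
#' @param range_lo,range_hi sampling range as fractions of biomechanical
#'   length, `0 < range_lo < range_hi < 1` (defaults 0.20 and 0.80).
#' @param n_semilandmarks semilandmarks per contour (>= 3, default 21).
#' @return a `sampling_config` list.
#' @export
sampling_config <- function(n_sections = 60L, range_lo = 0.20,
                            range_hi = 0.80, n_semilandmarks = 21L) {
  n_sections <- as.integer(n_sections)
  n_semilandmarks <- as.integer(n_semilandmarks)
  if (!(range_lo > 0 && range_lo < range_hi && range_hi < 1)) {
    stop("need 0 < range_lo < range_hi < 1")
  }
  if (n_sections < 2L) stop("n_sections must be at least 2")
  if (n_semilandmarks < 3L) stop("n_semilandmarks must be at least 3")
  structure(list(n_sections = n_sections, range_lo = range_lo,
                 range_hi = range_hi, n_semilandmarks = n_semilandmarks),
            class = "sampling_config")
}

#' Biomechanical length from anatomical landmarks
#'
#' The mean of the Euclidean distances from the superior femoral neck point
#' to each distal condyle point.
#'
#' @param landmarks landmark list (`neck`, `medial_condyle`,
#'   `lateral_condyle`).
#' @return length in mm.
#' @export
biomechanical_length <- function(landmarks) {
  validate_landmarks(landmarks)
  d1 <- sqrt(sum((landmarks$neck - landmarks$medial_condyle)^2))
  d2 <- sqrt(sum((landmarks$neck - landmarks$lateral_condyle)^2))
  (d1 + d2) / 2
}

#' Evenly spaced section levels
#'
#' @param config a [sampling_config()].
#' @return numeric vector of `n_sections` fractions from `range_lo` to
#'   `range_hi` inclusive.
#' @export
section_levels <- function(config = sampling_config()) {
  seq(config$range_lo, config$range_hi, length.out = config$n_sections)
}

# Intersect an oriented mesh with the plane z = z0; return a list of closed
# loops, each an n x 2 matrix of (x, y) in the section plane.
mesh_plane_loops <- function(mesh, z0) {
  v <- mesh$vertices
  f <- mesh$faces
  zv <- v[, 3L]
  # nudge the plane off any vertex to avoid degenerate point contacts
  eps <- 1e-9 * max(1, diff(range(zv)))
  while (any(abs(zv - z0) < eps)) z0 <- z0 + 2 * eps
  z1 <- zv[f[, 1L]]; z2 <- zv[f[, 2L]]; z3 <- zv[f[, 3L]]
  below <- (z1 < z0) + (z2 < z0) + (z3 < z0)
  hit <- which(below == 1L | below == 2L)
  if (length(hit) == 0L) return(list())
  segs_a <- matrix(NA_real_, length(hit), 2L)
  segs_b <- matrix(NA_real_, length(hit), 2L)
  keys_a <- character(length(hit))
  keys_b <- character(length(hit))
  edge_cross <- function(ia, ib) {
    # intersection of edge (ia, ib) with the plane, canonical direction
    swap <- ia > ib
    lo <- ifelse(swap, ib, ia); hi <- ifelse(swap, ia, ib)
    t <- (z0 - zv[lo]) / (zv[hi] - zv[lo])
    cbind(v[lo, 1L] + t * (v[hi, 1L] - v[lo, 1L]),
          v[lo, 2L] + t * (v[hi, 2L] - v[lo, 2L]),
          lo, hi)  # carry edge identity for exact matching
  }
  fa <- f[hit, 1L]; fb <- f[hit, 2L]; fc <- f[hit, 3L]
  s1 <- sign(zv[fa] - z0); s2 <- sign(zv[fb] - z0); s3 <- sign(zv[fc] - z0)
  cross12 <- s1 != s2
  cross23 <- s2 != s3
  cross31 <- s3 != s1
  pts <- vector("list", 3L)
  pts[[1L]] <- edge_cross(fa, fb)
  pts[[2L]] <- edge_cross(fb, fc)
  pts[[3L]] <- edge_cross(fc, fa)
  crossed <- cbind(cross12, cross23, cross31)
  out_a <- matrix(NA_real_, length(hit), 4L)
  out_b <- matrix(NA_real_, length(hit), 4L)
  first <- max.col(crossed, ties.method = "first")
  # second crossed edge index per face
  crossed2 <- crossed
  crossed2[cbind(seq_along(hit), first)] <- FALSE
  second <- max.col(crossed2, ties.method = "first")
  for (e in 1:3) {
    ia <- which(first == e)
    ib <- which(second == e)
    if (length(ia)) out_a[ia, ] <- pts[[e]][ia, , drop = FALSE]
    if (length(ib)) out_b[ib, ] <- pts[[e]][ib, , drop = FALSE]
  }
  # endpoints are matched by the mesh edge they lie on (exact integer key)
  key_a <- paste(out_a[, 3L], out_a[, 4L])
  key_b <- paste(out_b[, 3L], out_b[, 4L])
  assemble_loops(out_a[, 1:2, drop = FALSE], out_b[, 1:2, drop = FALSE],
                 key_a, key_b)
}

# Chain segments into closed loops; each endpoint key occurs exactly twice
# on a watertight mesh.
assemble_loops <- function(pa, pb, key_a, key_b) {
  n <- length(key_a)
  all_keys <- c(key_a, key_b)
  seg_of <- c(seq_len(n), seq_len(n))
  end_of <- c(rep(1L, n), rep(2L, n))
  by_key <- split(seq_along(all_keys), all_keys)
  if (any(lengths(by_key) != 2L)) {
    stop("open section contour: mesh is not watertight at this level")
  }
  used <- logical(n)
  loops <- list()
  for (s0 in seq_len(n)) {
    if (used[s0]) next
    loop_pts <- list(pa[s0, ])
    used[s0] <- TRUE
    cur_seg <- s0
    cur_key <- key_b[s0]
    cur_pt <- pb[s0, ]
    repeat {
      entries <- by_key[[cur_key]]
      segs <- seg_of[entries]
      ends <- end_of[entries]
      nxt <- which(segs != cur_seg | duplicated(segs))
      nxt_i <- entries[nxt[1L]]
      nseg <- seg_of[nxt_i]
      nend <- end_of[nxt_i]
      if (used[nseg]) break
      loop_pts[[length(loop_pts) + 1L]] <- cur_pt
      used[nseg] <- TRUE
      cur_seg <- nseg
      if (nend == 1L) {
        cur_key <- key_b[nseg]; cur_pt <- pb[nseg, ]
      } else {
        cur_key <- key_a[nseg]; cur_pt <- pa[nseg, ]
      }
    }
    loops[[length(loops) + 1L]] <- do.call(rbind, loop_pts)
  }
  loops[vapply(loops, nrow, integer(1)) >= 3L]
}

#' Extract and classify the cross-section at a biomechanical-length level
#'
#' Intersects the oriented specimen mesh with the plane
#' `z = z_distal + level * BL`, where the distal origin `z_distal` is the
#' condyle-landmark midpoint projected on the long axis (0 after
#' [orient_specimen()]). Loops are classified by area: the largest is the
#' periosteal contour; the largest loop strictly contained in it is the
#' endosteal contour. Loops smaller than 1% of the periosteal area are
#' discarded as mesh noise (recorded in attribute `"n_filtered"`).
#'
#' @param spec an oriented `bone_specimen`.
#' @param level fraction of biomechanical length.
#' @return a `cross_section` with `level`, `z_height`, `periosteal`,
#'   `endosteal` (both counterclockwise `n x 2` contours).
#' @export
slice_at_level <- function(spec, level) {
  if (!isTRUE(spec$oriented)) {
    stop("specimen must be oriented (orient_specimen) before sectioning")
  }
  bl <- biomechanical_length(spec$landmarks)
  z_distal <- (spec$landmarks$medial_condyle[3L] +
                 spec$landmarks$lateral_condyle[3L]) / 2
  z0 <- z_distal + level * bl
  loops <- mesh_plane_loops(spec$mesh, z0)
  if (length(loops) == 0L) {
    stop(sprintf("no cross-section at level %.3f (z = %.2f mm)", level, z0))
  }
  areas <- vapply(loops, polygon_area, numeric(1))
  ord <- order(areas, decreasing = TRUE)
  loops <- loops[ord]; areas <- areas[ord]
  keep <- areas >= 0.01 * areas[1L]
  n_filtered <- sum(!keep)
  loops <- loops[keep]; areas <- areas[keep]
  if (length(loops) < 2L) {
    stop(sprintf("no medullary cavity at level %.3f: found %d substantive loop(s)",
                 level, length(loops)))
  }
  if (length(loops) > 2L) {
    stop(sprintf("ambiguous section at level %.3f: %d substantive loops with areas %s",
                 level, length(loops),
                 paste(sprintf("%.2f", areas), collapse = ", ")))
  }
  peri <- ccw(loops[[1L]])
  endo <- ccw(loops[[2L]])
  if (!point_in_contour(endo[1L, ], peri)) {
    stop(sprintf("section at level %.3f has two loops but the smaller is not nested",
                 level))
  }
  structure(list(level = level, z_height = z0, periosteal = peri,
                 endosteal = endo, periosteal_slm = NULL,
                 endosteal_slm = NULL, ray_angles = NULL),
            class = "cross_section", n_filtered = n_filtered)
}

ccw <- function(contour) {
  if (polygon_area(contour, signed = TRUE) < 0) {
    contour[rev(seq_len(nrow(contour))), , drop = FALSE]
  } else {
    contour
  }
}

#' Area centroid of the medullary cavity
#'
#' Shoelace-weighted polygon centroid of the endosteal contour; the origin
#' of the equiangular semilandmark rays.
#'
#' @param endosteal endosteal contour, `n x 2`.
#' @return length-2 numeric vector.
#' @export
medullary_centroid <- function(endosteal) {
  polygon_centroid(endosteal)
}

# All crossings of the ray (origin, angle) with a closed contour.
# Returns sorted positive ray parameters s (distance along the unit ray).
ray_contour_crossings <- function(contour, origin, angle) {
  p <- sweep(as.matrix(contour), 2L, origin)
  q <- p[c(2:nrow(p), 1L), , drop = FALSE]
  e <- q - p
  d <- c(cos(angle), sin(angle))
  denom <- e[, 1L] * d[2L] - e[, 2L] * d[1L]       # cross(e, d)
  numer <- p[, 1L] * d[2L] - p[, 2L] * d[1L]       # cross(p, d)
  ok <- abs(denom) > 1e-14
  # p + u e = s d  =>  cross(p, d) + u cross(e, d) = 0
  # the window is slightly tolerant so a ray through a shared vertex is not
  # lost to rounding (duplicate hits are harmless: only min/max s are used)
  u <- -numer[ok] / denom[ok]
  hit <- u >= -1e-9 & u <= 1 + 1e-9
  px <- p[ok, 1L][hit] + u[hit] * e[ok, 1L][hit]
  py <- p[ok, 2L][hit] + u[hit] * e[ok, 2L][hit]
  s <- px * d[1L] + py * d[2L]
  sort(s[s > 1e-12])
}

#' Place equiangular semilandmarks on both contours
#'
#' Casts `n_semilandmarks` rays from the medullary-cavity centroid at angles
#' `2*pi*k/n` (k = 0..n-1) measured counterclockwise from +x (lateral). On
#' each ray the endosteal semilandmark is the nearest crossing of the
#' endosteal contour and the periosteal semilandmark the farthest crossing
#' of the periosteal contour, so the pair spans the full cortical wall.
#'
#' @param section a `cross_section` with classified contours.
#' @param config a [sampling_config()].
#' @return the `cross_section` with `periosteal_slm`, `endosteal_slm`
#'   (`n x 2` matrices) and `ray_angles` filled in.
#' @export
sample_semilandmarks <- function(section, config = sampling_config()) {
  n <- config$n_semilandmarks
  origin <- medullary_centroid(section$endosteal)
  angles <- 2 * pi * (seq_len(n) - 1L) / n
  peri <- matrix(NA_real_, n, 2L)
  endo <- matrix(NA_real_, n, 2L)
  for (k in seq_len(n)) {
    sp <- ray_contour_crossings(section$periosteal, origin, angles[k])
    se <- ray_contour_crossings(section$endosteal, origin, angles[k])
    if (length(sp) == 0L || length(se) == 0L) {
      stop(sprintf(
        "ray %d (%.1f deg) does not cross both contours; centroid outside a non-star-shaped contour?",
        k - 1L, angles[k] * 180 / pi))
    }
    d <- c(cos(angles[k]), sin(angles[k]))
    peri[k, ] <- origin + max(sp) * d
    endo[k, ] <- origin + min(se) * d
  }
  section$periosteal_slm <- peri
  section$endosteal_slm <- endo
  section$ray_angles <- angles
  section
}

#' Radial cortical thickness along each semilandmark ray
#'
#' Thickness on ray k is the Euclidean distance between the periosteal and
#' endosteal semilandmarks of that ray.
#'
#' @param section a `cross_section` with sampled semilandmarks.
#' @return numeric vector of `n_semilandmarks` thicknesses (mm).
#' @export
radial_thickness <- function(section) {
  if (is.null(section$periosteal_slm)) {
    stop("semilandmarks not sampled; run sample_semilandmarks() first")
  }
  sqrt(rowSums((section$periosteal_slm - section$endosteal_slm)^2))
}

#' Section a whole specimen
#'
#' Runs [slice_at_level()] and [sample_semilandmarks()] at every level of
#' the sampling configuration.
#'
#' @param spec an oriented `bone_specimen`.
#' @param config a [sampling_config()].
#' @return list of `cross_section` objects, one per level.
#' @export
section_specimen <- function(spec, config = sampling_config()) {
  lapply(section_levels(config), function(t) {
    sample_semilandmarks(slice_at_level(spec, t), config)
  })
}
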