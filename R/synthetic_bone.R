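#' Specification of a parametric synthetic femur-like bone
#'
#' Describes a tubular diaphysis whose cross-sections are concentric
#' elliptical annuli: periosteal semi-axes `a_p(t)` (mediolateral, x) and
#' `b_p(t)` (anteroposterior, y), endosteal semi-axes `a_e(t)`, `b_e(t)`,
#' all smooth functions of the normalized level `t` in [0, 1] (fraction of
#' biomechanical length; 0 = distal). Profiles may be given as constants or
#' functions. An osteoporosis mode perturbs the endosteal surface:
#' `"uniform_endosteal_expansion"` multiplies both endosteal semi-axes by
#' `f >= 1` (closed-form ground truth retained);
#' `"regional_thinning"` pushes the endosteal boundary outward by a fraction
#' `thin_depth` of the local cortical thickness, weighted toward the
#' anterior (+y) and lateral (+x) quadrants and concentrated on the
#' 20--45% level band (thickness ground truth only).
#'
#' @param biomechanical_length length in mm (default 420).
#' @param n_rings axial vertex rings (>= 16, default 33).
#' @param n_angular vertices per ring (>= 32, default 64).
#' @param a_p,b_p,a_e,b_e profile constants or functions of `t`.
#' @param osteo_mode `"none"`, `"uniform_endosteal_expansion"` or
#'   `"regional_thinning"`.
#' @param f endosteal expansion factor (>= 1; used by
#'   `uniform_endosteal_expansion`).
#' @param thin_depth fraction of local cortical thickness removed at the
#'   peak of the regional-thinning weight (0 <= thin_depth < 1).
#' @param thin_band level band `c(lo, hi)` over which regional thinning
#'   acts (default `c(0.20, 0.45)`).
#' @param seed integer seed recorded in the spec (generation itself is
#'   deterministic; the seed feeds cohort jitter).
#' @return a `synthetic_bone_spec`.
#' @export
synthetic_bone_spec <- function(biomechanical_length = 420,
                                n_rings = 33L, n_angular = 64L,
                                a_p = function(t) 14 * (1 + 0.35 * (2 * t - 1)^2),
                                b_p = function(t) 13 * (1 + 0.30 * (2 * t - 1)^2),
                                a_e = function(t) 0.62 * 14 * (1 + 0.35 * (2 * t - 1)^2),
                                b_e = function(t) 0.62 * 13 * (1 + 0.30 * (2 * t - 1)^2),
                                osteo_mode = c("none",
                                               "uniform_endosteal_expansion",
                                               "regional_thinning"),
                                f = 1, thin_depth = 0.5,
                                thin_band = c(0.20, 0.45), seed = 1L) {
  osteo_mode <- match.arg(osteo_mode)
  as_fun <- function(p) if (is.function(p)) p else function(t) rep(p, length(t))
  spec <- structure(list(
    biomechanical_length = biomechanical_length,
    n_rings = as.integer(n_rings), n_angular = as.integer(n_angular),
    a_p = as_fun(a_p), b_p = as_fun(b_p),
    a_e = as_fun(a_e), b_e = as_fun(b_e),
    osteo_mode = osteo_mode, f = f, thin_depth = thin_depth,
    thin_band = thin_band, seed = as.integer(seed)
  ), class = "synthetic_bone_spec")
  if (biomechanical_length <= 0) stop("biomechanical_length must be positive")
  if (spec$n_rings < 16L) stop("n_rings must be at least 16")
  if (spec$n_angular < 32L) stop("n_angular must be at least 32")
  if (f < 1) stop("endosteal expansion factor f must be >= 1")
  if (thin_depth < 0 || thin_depth >= 1) stop("thin_depth must be in [0, 1)")
  tt <- seq(0, 1, length.out = 101)
  ae <- spec$a_e(tt) * if (osteo_mode == "uniform_endosteal_expansion") f else 1
  be <- spec$b_e(tt) * if (osteo_mode == "uniform_endosteal_expansion") f else 1
  if (any(ae <= 0) || any(be <= 0) ||
      any(ae >= spec$a_p(tt)) || any(be >= spec$b_p(tt))) {
    stop("profiles must satisfy 0 < endosteal < periosteal at every level")
  }
  spec
}

# Effective endosteal semi-axes after uniform expansion (NULL for regional).
effective_endosteal <- function(spec, t) {
  fac <- if (spec$osteo_mode == "uniform_endosteal_expansion") spec$f else 1
  list(a = spec$a_e(t) * fac, b = spec$b_e(t) * fac)
}

# Polar radius of an axis-aligned origin-centred ellipse.
ellipse_polar_radius <- function(a, b, phi) {
  a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
}

# Angular weight of regional thinning: 1 at +x (lateral) and +y (anterior),
# 0 in the posterior-medial quadrant.
thinning_angular_weight <- function(phi) {
  pmax(0, sin(phi))^2 + pmax(0, cos(phi))^2
}

# Level weight: raised-cosine bump on the thinning band.
thinning_level_weight <- function(t, band) {
  w <- numeric(length(t))
  inside <- t >= band[1L] & t <= band[2L]
  u <- (t[inside] - band[1L]) / (band[2L] - band[1L])
  w[inside] <- 0.5 * (1 - cos(2 * pi * u))
  w
}

# Endosteal polar radius at (t, phi) for any osteo mode.
endosteal_polar_radius <- function(spec, t, phi) {
  ee <- effective_endosteal(spec, t)
  r_e <- ellipse_polar_radius(ee$a, ee$b, phi)
  if (spec$osteo_mode == "regional_thinning") {
    r_p <- ellipse_polar_radius(spec$a_p(t), spec$b_p(t), phi)
    w <- spec$thin_depth * thinning_angular_weight(phi) *
      thinning_level_weight(t, spec$thin_band)
    r_e <- r_e + w * (r_p - r_e)
  }
  r_e
}

#' Generate a watertight synthetic bone mesh from a spec
#'
#' Builds a double-walled tube: the outer wall samples the periosteal
#' ellipse profile, the inner wall the endosteal surface, and flat annular
#' end caps join them. The tube spans levels 0.05--0.95 of biomechanical
#' length so the caps sit well outside the 20--80% sampling range and never
#' contaminate sampled sections. Landmarks are synthesized as three points
#' encoding the requested biomechanical length (condyles at z = 0, neck on
#' the +z axis); no condyle or neck geometry is modelled because downstream
#' processing only consumes landmark distances.
#'
#' @param spec a [synthetic_bone_spec()].
#' @param specimen_id identifier (default derived from mode and seed).
#' @return an oriented `bone_specimen` (group `"healthy"` when
#'   `osteo_mode == "none"`, else `"osteoporosis"`).
#' @export
generate_bone <- function(spec, specimen_id = NULL) {
  stopifnot(inherits(spec, "synthetic_bone_spec"))
  bl <- spec$biomechanical_length
  nr <- spec$n_rings
  na <- spec$n_angular
  t_levels <- seq(0.05, 0.95, length.out = nr)
  phi <- 2 * pi * (seq_len(na) - 1L) / na
  zs <- t_levels * bl

  tg <- rep(t_levels, each = na)
  pg <- rep(phi, times = nr)
  r_out <- ellipse_polar_radius(spec$a_p(tg), spec$b_p(tg), pg)
  r_in <- endosteal_polar_radius(spec, tg, pg)
  zg <- rep(zs, each = na)
  outer_v <- cbind(r_out * cos(pg), r_out * sin(pg), zg)
  inner_v <- cbind(r_in * cos(pg), r_in * sin(pg), zg)
  vertices <- rbind(outer_v, inner_v)

  o_idx <- function(i, j) (i - 1L) * na + ((j - 1L) %% na) + 1L
  i_idx <- function(i, j) nr * na + o_idx(i, j)

  ring <- rep(seq_len(nr - 1L), each = na)
  ang <- rep(seq_len(na), times = nr - 1L)
  # outer wall, outward normals (CCW rings, +z up)
  a1 <- o_idx(ring, ang); b1 <- o_idx(ring, ang + 1L)
  c1 <- o_idx(ring + 1L, ang + 1L); d1 <- o_idx(ring + 1L, ang)
  outer_f <- rbind(cbind(a1, b1, c1), cbind(a1, c1, d1))
  # inner wall, normals into the cavity (reverse winding)
  a2 <- i_idx(ring, ang); b2 <- i_idx(ring, ang + 1L)
  c2 <- i_idx(ring + 1L, ang + 1L); d2 <- i_idx(ring + 1L, ang)
  inner_f <- rbind(cbind(a2, c2, b2), cbind(a2, d2, c2))
  # annular end caps
  j <- seq_len(na)
  bot <- rbind(cbind(o_idx(1L, j), i_idx(1L, j), i_idx(1L, j + 1L)),
               cbind(o_idx(1L, j), i_idx(1L, j + 1L), o_idx(1L, j + 1L)))
  top <- rbind(cbind(o_idx(nr, j), i_idx(nr, j + 1L), i_idx(nr, j)),
               cbind(o_idx(nr, j), o_idx(nr, j + 1L), i_idx(nr, j + 1L)))
  faces <- rbind(outer_f, inner_f, bot, top)
  mesh <- bone_mesh(vertices, faces)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  if (!is_watertight(mesh)) {
    stop("internal error: synthetic bone construction is not watertight")
  }
  w <- 25
  landmarks <- list(neck = c(0, 0, sqrt(bl^2 - w^2)),
                    medial_condyle = c(-w, 0, 0),
                    lateral_condyle = c(w, 0, 0),
                    group = if (spec$osteo_mode == "none") "healthy"
                            else "osteoporosis")
  if (is.null(specimen_id)) {
    specimen_id <- sprintf("synth_%s_%d", spec$osteo_mode, spec$seed)
  }
  bone_specimen(specimen_id, mesh, landmarks,
                group = landmarks$group, oriented = TRUE)
}

#' High-accuracy ellipse perimeter (Ramanujan's second approximation)
#'
#' `p = pi (a+b) (1 + 3h / (10 + sqrt(4 - 3h)))` with
#' `h = ((a-b)/(a+b))^2`; relative error below `3 h^5 / 2^17` (about 4e-11
#' at axis ratio 2:1), exact for circles.
#'
#' @param a,b semi-axes (mm).
#' @return perimeter in mm.
#' @export
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Closed-form section truth for a synthetic bone spec
#'
#' Exact elliptical-annulus values of every reported section property at a
#' given level. Available whenever the section is a concentric axis-aligned
#' elliptical annulus (`osteo_mode` `"none"` or
#' `"uniform_endosteal_expansion"`). Under `"regional_thinning"` the
#' endosteal boundary is not elliptical: only per-ray thickness truth is
#' provided, and requesting moment truth is an error.
#'
#' @param spec a [synthetic_bone_spec()].
#' @param level fraction of biomechanical length in [0, 1].
#' @param n_rays number of equiangular rays for the thickness truth
#'   (default 21).
#' @param thickness_only return only the per-ray thickness truth (the only
#'   truth defined under `regional_thinning`).
#' @return list of truth values; `thickness` is the per-ray vector.
#' @export
analytic_truth <- function(spec, level, n_rays = 21L,
                           thickness_only = FALSE) {
  stopifnot(inherits(spec, "synthetic_bone_spec"))
  angles <- 2 * pi * (seq_len(n_rays) - 1L) / n_rays
  r_p <- ellipse_polar_radius(spec$a_p(level), spec$b_p(level), angles)
  r_e <- endosteal_polar_radius(spec, level, angles)
  thickness <- r_p - r_e
  if (spec$osteo_mode == "regional_thinning") {
    if (!thickness_only) {
      stop("no closed form: regional_thinning sections are not elliptical; ",
           "use thickness_only = TRUE")
    }
    return(list(level = level, thickness = thickness,
                thickness_min = min(thickness),
                thickness_mean = mean(thickness),
                thickness_max = max(thickness)))
  }
  a_p <- spec$a_p(level); b_p <- spec$b_p(level)
  ee <- effective_endosteal(spec, level)
  a_e <- ee$a; b_e <- ee$b
  TA <- pi * a_p * b_p
  MA <- pi * a_e * b_e
  Ix <- pi / 4 * (a_p * b_p^3 - a_e * b_e^3)
  Iy <- pi / 4 * (a_p^3 * b_p - a_e^3 * b_e)
  J <- Ix + Iy
  out <- list(
    level = level,
    total_area = TA, medullary_area = MA, cortical_area = TA - MA,
    Ix = Ix, Iy = Iy, Ixy = 0,
    Imin = min(Ix, Iy), Imax = max(Ix, Iy), theta = 0, J = J,
    Zx = Ix / b_p, Zy = Iy / a_p,
    Zmin = min(Ix, Iy) / a_p, Zmax = max(Ix, Iy) / b_p,
    Zpol = J / max(a_p, b_p),
    dx = a_p, dy = b_p, rmax = max(a_p, b_p),
    periosteal_perimeter = ellipse_perimeter(a_p, b_p),
    endosteal_perimeter = ellipse_perimeter(a_e, b_e),
    thickness = thickness,
    thickness_min = min(thickness),
    thickness_mean = mean(thickness),
    thickness_max = max(thickness)
  )
  if (thickness_only) {
    out[c("level", "thickness", "thickness_min", "thickness_mean",
          "thickness_max")]
  } else {
    out
  }
}

#' Endosteal expansion factor that yields a target cortical-area ratio
#'
#' For profiles with a constant endosteal/periosteal area proportion
#' (the package defaults), returns the uniform expansion factor `f` such
#' that the osteoporotic cortical area is `ratio` times the healthy one at
#' every level.
#'
#' @param spec a healthy [synthetic_bone_spec()].
#' @param ratio target CA(osteo) / CA(healthy), in (0, 1].
#' @param level level at which the profile areas are evaluated
#'   (default 0.5; with proportional profiles the result is
#'   level-independent).
#' @return expansion factor `f >= 1`.
#' @export
expansion_for_ca_ratio <- function(spec, ratio, level = 0.5) {
  if (ratio <= 0 || ratio > 1) stop("ratio must be in (0, 1]")
  A_p <- spec$a_p(level) * spec$b_p(level)
  A_e <- spec$a_e(level) * spec$b_e(level)
  f2 <- (A_p - ratio * (A_p - A_e)) / A_e
  sqrt(f2)
}

#' Generate a synthetic two-group cohort with ground truth
#'
#' Draws `n_healthy + n_osteo` specimens from a base spec. Each specimen
#' receives an independent lognormal scale jitter (sdlog = `variation`)
#' applied to all profile radii, keeping every radius positive; all
#' osteoporotic specimens share one uniform endosteal expansion factor,
#' chosen so the analytic cortical-area ratio equals `ca_ratio` (or given
#' directly via `f`). Returns the specimens, a closed-form truth table
#' (one row per specimen x level) and the per-specimen generator
#' parameters for recovery tests.
#'
#' @param n_healthy,n_osteo group sizes (each >= 2).
#' @param variation lognormal sdlog of the per-specimen scale jitter
#'   (< 0.2).
#' @param seed integer RNG seed.
#' @param base_spec healthy [synthetic_bone_spec()] the cohort is drawn
#'   around.
#' @param ca_ratio target analytic CA(osteo)/CA(healthy) (default 0.70).
#' @param f uniform endosteal expansion factor; overrides `ca_ratio` when
#'   given.
#' @param osteo_mode `"uniform_endosteal_expansion"` (default) or
#'   `"regional_thinning"`.
#' @param thin_depth regional-thinning depth (used by
#'   `"regional_thinning"`).
#' @param levels levels at which truth rows are tabulated (default the
#'   standard 60 sampling levels).
#' @return list with `specimens` (list of `bone_specimen`), `truth`
#'   (data.frame), `params` (data.frame).
#' @export
generate_cohort <- function(n_healthy, n_osteo, variation, seed,
                            base_spec = synthetic_bone_spec(),
                            ca_ratio = 0.70, f = NULL,
                            osteo_mode = "uniform_endosteal_expansion",
                            thin_depth = 0.5,
                            levels = section_levels(sampling_config())) {
  if (n_healthy < 2L || n_osteo < 2L) stop("group sizes must be at least 2")
  if (variation < 0 || variation >= 0.2) stop("variation must be in [0, 0.2)")
  if (is.null(f)) {
    f <- if (osteo_mode == "uniform_endosteal_expansion") {
      expansion_for_ca_ratio(base_spec, ca_ratio)
    } else {
      1
    }
  }
  set.seed(seed)
  n_total <- n_healthy + n_osteo
  scales <- exp(stats::rnorm(n_total, mean = 0, sd = variation))
  groups <- c(rep("healthy", n_healthy), rep("osteoporosis", n_osteo))
  ids <- sprintf("%s_%02d", ifelse(groups == "healthy", "H", "O"),
                 c(seq_len(n_healthy), seq_len(n_osteo)))
  specimens <- vector("list", n_total)
  truth_rows <- vector("list", n_total)
  scale_profile <- function(p, s) {
    force(p); force(s)
    function(t) s * p(t)
  }
  for (i in seq_len(n_total)) {
    s <- scales[i]
    is_osteo <- groups[i] == "osteoporosis"
    spec_i <- synthetic_bone_spec(
      biomechanical_length = base_spec$biomechanical_length,
      n_rings = base_spec$n_rings, n_angular = base_spec$n_angular,
      a_p = scale_profile(base_spec$a_p, s),
      b_p = scale_profile(base_spec$b_p, s),
      a_e = scale_profile(base_spec$a_e, s),
      b_e = scale_profile(base_spec$b_e, s),
      osteo_mode = if (is_osteo) osteo_mode else "none",
      f = if (is_osteo && osteo_mode == "uniform_endosteal_expansion") f else 1,
      thin_depth = if (is_osteo) thin_depth else 0,
      seed = seed + i)
    specimens[[i]] <- generate_bone(spec_i, specimen_id = ids[i])
    thickness_only <- is_osteo && osteo_mode == "regional_thinning"
    rows <- lapply(levels, function(t) {
      tr <- analytic_truth(spec_i, t, thickness_only = thickness_only)
      tr$thickness <- NULL
      as.data.frame(tr)
    })
    df <- do.call(rbind, rows)
    df <- cbind(specimen_id = ids[i], group = groups[i], df)
    truth_rows[[i]] <- df
  }
  truth <- do.call(rbind, lapply(truth_rows, function(d) {
    # align columns across modes (thickness-only rows have fewer fields)
    all_cols <- c("specimen_id", "group", "level", "total_area",
                  "medullary_area", "cortical_area", "Ix", "Iy", "Ixy",
                  "Imin", "Imax", "theta", "J", "Zx", "Zy", "Zmin", "Zmax",
                  "Zpol", "dx", "dy", "rmax", "periosteal_perimeter",
                  "endosteal_perimeter", "thickness_min", "thickness_mean",
                  "thickness_max")
    for (cc in setdiff(all_cols, names(d))) d[[cc]] <- NA_real_
    d[all_cols]
  }))
  rownames(truth) <- NULL
  params <- data.frame(specimen_id = ids, group = groups, scale = scales,
                       f = ifelse(groups == "osteoporosis" &
                                    osteo_mode == "uniform_endosteal_expansion",
                                  f, 1),
                       osteo_mode = ifelse(groups == "osteoporosis",
                                           osteo_mode, "none"),
                       seed = seed + seq_len(n_total),
                       stringsAsFactors = FALSE)
  list(specimens = specimens, truth = truth, params = params, f = f)
}
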