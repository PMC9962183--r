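#' Load a bone specimen from an STL file plus landmark sidecar
#'
#' @param mesh_path path to a binary or ASCII STL file.
#' @param landmark_path path to the plain-text landmark sidecar
#'   (see [read_landmarks()]).
#' @param group group label, `"healthy"` or `"osteoporosis"`. If `NULL`, the
#'   `group:` entry of the landmark file is used.
#' @param specimen_id identifier; defaults to the mesh file name without
#'   extension.
#' @param units_scale multiplicative factor applied to all coordinates on
#'   load (e.g. `1000` for meshes stored in metres). Default 1 (millimetres).
#' @return a `bone_specimen`: list with `specimen_id`, `mesh`, `landmarks`,
#'   `group`.
#' @export
load_specimen <- function(mesh_path, landmark_path, group = NULL,
                          specimen_id = NULL, units_scale = 1) {
  mesh <- read_stl(mesh_path)
  lm <- read_landmarks(landmark_path)
  if (is.null(group)) group <- lm$group
  if (is.na(group) || !group %in% c("healthy", "osteoporosis")) {
    stop("group must be 'healthy' or 'osteoporosis' (got: ", group, ")")
  }
  if (units_scale != 1) {
    mesh$vertices <- mesh$vertices * units_scale
    lm$neck <- lm$neck * units_scale
    lm$medial_condyle <- lm$medial_condyle * units_scale
    lm$lateral_condyle <- lm$lateral_condyle * units_scale
  }
  if (is.null(specimen_id)) {
    specimen_id <- sub("\\.[^.]*$", "", basename(mesh_path))
  }
  bone_specimen(specimen_id, mesh, lm, group)
}

#' Construct a bone specimen
#'
#' @param specimen_id character identifier.
#' @param mesh a [bone_mesh()].
#' @param landmarks landmark list (`neck`, `medial_condyle`,
#'   `lateral_condyle`).
#' @param group `"healthy"` or `"osteoporosis"`.
#' @param oriented logical, whether the specimen is already in the canonical
#'   anatomical frame.
#' @export
bone_specimen <- function(specimen_id, mesh, landmarks, group,
                          oriented = FALSE) {
  stopifnot(inherits(mesh, "bone_mesh"))
  if (!group %in% c("healthy", "osteoporosis")) {
    stop("group must be 'healthy' or 'osteoporosis'")
  }
  validate_landmarks(landmarks)
  structure(list(specimen_id = specimen_id, mesh = mesh,
                 landmarks = landmarks, group = group,
                 oriented = isTRUE(oriented)),
            class = "bone_specimen")
}

#' @export
print.bone_specimen <- function(x, ...) {
  cat(sprintf("<bone_specimen '%s' (%s): %d vertices, %d faces, %s>\n",
              x$specimen_id, x$group, nrow(x$mesh$vertices),
              nrow(x$mesh$faces),
              if (x$oriented) "oriented" else "unoriented"))
  invisible(x)
}

#' Clean a triangle mesh
#'
#' Mirrors the standard surface-repair sequence applied to segmented bone
#' models: removes exact duplicate faces and degenerate faces, keeps only the
#' largest connected component (isolated piece removal), fills boundary holes
#' by fan triangulation, and validates the result. Non-manifold edges (an
#' edge shared by three or more faces) are reported as an error rather than
#' repaired; likewise meshes are not checked for self-intersections — both
#' are deliberate simplifications for meshes exported from segmentation
#' software, which rarely exhibit them.
#'
#' @param mesh a [bone_mesh()].
#' @return a cleaned, watertight [bone_mesh()].
#' @export
clean_mesh <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) < 4L) stop("mesh must have at least 4 faces")
  # degenerate faces
  keep <- f[, 1L] != f[, 2L] & f[, 2L] != f[, 3L] & f[, 1L] != f[, 3L]
  f <- f[keep, , drop = FALSE]
  # duplicate faces (same vertex set, any order/winding)
  sorted <- t(apply(f, 1L, sort))
  f <- f[!duplicated(sorted), , drop = FALSE]
  m <- bone_mesh(mesh$vertices, f)
  # largest connected component by face count
  comp <- mesh_vertex_components(m)
  fcomp <- comp[f[, 1L]]
  if (length(unique(fcomp[!is.na(fcomp)])) > 1L) {
    counts <- table(fcomp)
    main <- as.integer(names(counts)[which.max(counts)])
    f <- f[fcomp == main, , drop = FALSE]
  }
  # drop unreferenced vertices
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  m <- bone_mesh(mesh$vertices[used, , drop = FALSE],
                 matrix(remap[f], ncol = 3L))
  # non-manifold edges are irreparable here
  ek <- edge_keys(m$faces, nrow(m$vertices))
  cnt <- table(ek$key)
  bad <- as.numeric(names(cnt)[cnt > 2L])
  if (length(bad) > 0L) {
    n1 <- nrow(m$vertices) + 1
    stop("irreparable non-manifold edges (vertex pairs): ",
         paste(sprintf("(%d,%d)", floor(bad / n1), bad %% n1), collapse = " "))
  }
  m <- fill_holes(m)
  if (!is_watertight(m)) stop("mesh cleaning failed to produce a watertight mesh")
  m
}

# Fill boundary loops (edges used by exactly one face) by fan triangulation.
fill_holes <- function(mesh) {
  f <- mesh$faces
  n <- nrow(mesh$vertices)
  ek <- edge_keys(f, n)
  cnt <- table(ek$key)
  boundary_keys <- as.numeric(names(cnt)[cnt == 1L])
  if (length(boundary_keys) == 0L) return(mesh)
  sel <- ek$key %in% boundary_keys
  # boundary edges traversed opposite to their face direction close the loop
  from <- ek$to[sel]
  to <- ek$from[sel]
  nxt <- to
  names(nxt) <- as.character(from)
  new_faces <- list()
  visited <- character(0)
  for (start in as.character(from)) {
    if (start %in% visited) next
    loop <- as.integer(start)
    cur <- start
    repeat {
      visited <- c(visited, cur)
      nx <- nxt[[cur]]
      if (is.null(nx)) stop("open boundary chain: cannot fill hole")
      if (as.character(nx) == start) break
      loop <- c(loop, nx)
      cur <- as.character(nx)
    }
    if (length(loop) < 3L) next
    fan <- cbind(loop[1L], loop[2:(length(loop) - 1L)], loop[3:length(loop)])
    new_faces[[length(new_faces) + 1L]] <- fan
  }
  bone_mesh(mesh$vertices, rbind(f, do.call(rbind, new_faces)))
}

#' Decimate a mesh to a target face count
#'
#' Quadric-error edge collapse with manifoldness (link-condition) and
#' triangle-flip guards. When the input already has `target_faces` faces or
#' fewer it is returned unchanged with a message; no upsampling is performed.
#' The default target of 20,000 faces is the consistent mesh complexity used
#' for all specimens. Decimation that cannot reach the exact target or that
#' breaks watertightness is an error (no silent retry; regenerate or clean
#' the input instead).
#'
#' @param mesh a watertight [bone_mesh()].
#' @param target_faces target triangle count (default 20000, minimum 100).
#' @return a [bone_mesh()] with exactly `target_faces` faces (or the
#'   unchanged input when it is already at or below the target).
#' @export
decimate <- function(mesh, target_faces = 20000L) {
  target_faces <- as.integer(target_faces)
  if (target_faces < 100L) stop("target_faces must be at least 100")
  if (!is_watertight(mesh)) stop("decimate requires a watertight mesh")
  if (nrow(mesh$faces) <= target_faces) {
    message(sprintf("mesh has %d faces <= target %d; returned unchanged",
                    nrow(mesh$faces), target_faces))
    return(mesh)
  }
  if ((nrow(mesh$faces) - target_faces) %% 2L != 0L) {
    stop("target_faces differs from the input face count by an odd number; ",
         "edge collapse removes faces in pairs on a closed surface")
  }
  out <- decimate_quadric(mesh$vertices, mesh$faces, target_faces)
  res <- bone_mesh(out$vertices, out$faces)
  if (nrow(res$faces) != target_faces) {
    stop(sprintf("decimation stalled at %d faces (target %d): no valid collapses left",
                 nrow(res$faces), target_faces))
  }
  if (!is_watertight(res)) {
    stop("decimation broke watertightness; input mesh may be near-degenerate")
  }
  res
}

#' Orient a specimen into the canonical anatomical frame
#'
#' Rigid (rotation + translation, no scaling) landmark-based orientation:
#' the long axis (condyle midpoint to femoral neck point) becomes +z with the
#' proximal end at larger z; the mediolateral axis (component of the
#' medial-to-lateral condyle direction orthogonal to the long axis) becomes
#' +x; the anteroposterior axis becomes +y (right-handed). The condyle
#' midpoint is placed at the origin, so the distal biomechanical-length
#' origin is z = 0. Landmarks are transformed together with the mesh.
#'
#' @param spec a `bone_specimen`.
#' @return the oriented `bone_specimen`; the applied 4x4 transform is
#'   attached as attribute `"transform"`.
#' @export
orient_specimen <- function(spec) {
  lm <- spec$landmarks
  cmid <- (lm$medial_condyle + lm$lateral_condyle) / 2
  axis <- lm$neck - cmid
  bl <- sqrt(sum(axis^2))
  if (bl < 1e-9) stop("degenerate landmarks: neck coincides with condyle midpoint")
  u <- axis / bl
  ml <- lm$lateral_condyle - lm$medial_condyle
  ml_perp <- ml - sum(ml * u) * u
  nml <- sqrt(sum(ml_perp^2))
  if (nml < 1e-9) {
    stop("degenerate landmarks: condyle axis is collinear with the long axis")
  }
  xhat <- ml_perp / nml
  yhat <- c(u[2L] * xhat[3L] - u[3L] * xhat[2L],
            u[3L] * xhat[1L] - u[1L] * xhat[3L],
            u[1L] * xhat[2L] - u[2L] * xhat[1L])
  rot <- rbind(xhat, yhat, u)      # world -> anatomical frame
  dimnames(rot) <- NULL
  trans <- -as.vector(rot %*% cmid)
  mesh <- spec$mesh
  mesh$vertices <- transform_points(mesh$vertices, rot, trans)
  lm2 <- list(neck = as.vector(rot %*% lm$neck + trans),
              medial_condyle = as.vector(rot %*% lm$medial_condyle + trans),
              lateral_condyle = as.vector(rot %*% lm$lateral_condyle + trans),
              group = lm$group)
  out <- bone_specimen(spec$specimen_id, mesh, lm2, spec$group,
                       oriented = TRUE)
  tf <- rbind(cbind(rot, trans), c(0, 0, 0, 1))
  dimnames(tf) <- NULL
  attr(out, "transform") <- tf
  out
}

#' Apply a rigid transform to a specimen (mesh and landmarks)
#'
#' Utility used mainly for invariance testing.
#'
#' @param spec a `bone_specimen`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector.
#' @export
transform_specimen <- function(spec, rotation, translation = c(0, 0, 0)) {
  mesh <- spec$mesh
  mesh$vertices <- transform_points(mesh$vertices, rotation, translation)
  lm <- spec$landmarks
  for (key in c("neck", "medial_condyle", "lateral_condyle")) {
    lm[[key]] <- as.vector(rotation %*% lm[[key]] + translation)
  }
  bone_specimen(spec$specimen_id, mesh, lm, spec$group, oriented = FALSE)
}
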