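#' Construct a triangle mesh
#'
#' A `bone_mesh` is the package's surface-mesh container: an `n x 3` numeric
#' matrix of vertex coordinates in millimetres and an `m x 3` integer matrix
#' of 1-based vertex indices, one row per triangle.
#'
#' @param vertices numeric matrix, `n x 3`, vertex coordinates (mm).
#' @param faces integer matrix, `m x 3`, 1-based vertex index triples.
#' @return an object of class `bone_mesh`.
#' @export
bone_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces), class = "bone_mesh")
}

#' @export
print.bone_mesh <- function(x, ...) {
  cat(sprintf("<bone_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Undirected edge keys: encode sorted index pair as a double (< 2^53 safe).
edge_keys <- function(faces, n_vertices) {
  a <- c(faces[, 1L], faces[, 2L], faces[, 3L])
  b <- c(faces[, 2L], faces[, 3L], faces[, 1L])
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  list(key = as.numeric(lo) * (n_vertices + 1) + hi, from = a, to = b)
}

#' Test whether a mesh is watertight
#'
#' Watertight here means: every undirected edge is shared by exactly two
#' faces, with consistent (opposite) winding, and the mesh is a single
#' connected component with no degenerate faces.
#'
#' @param mesh a `bone_mesh`.
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) < 4L) return(FALSE)
  if (any(f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L])) {
    return(FALSE)
  }
  ek <- edge_keys(f, nrow(mesh$vertices))
  cnt <- table(ek$key)
  if (any(cnt != 2L)) return(FALSE)
  # consistent orientation: each directed edge must appear exactly once
  n <- nrow(mesh$vertices)
  dir_key <- as.numeric(ek$from) * (n + 1) + ek$to
  if (anyDuplicated(dir_key) > 0L) return(FALSE)
  length(unique(mesh_vertex_components(mesh)[as.vector(f)])) == 1L
}

# Connected components of the vertex graph (union-find).
mesh_vertex_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  f <- mesh$faces
  a <- c(f[, 1L], f[, 1L])
  b <- c(f[, 2L], f[, 3L])
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, integer(1))
}

#' Signed volume enclosed by a closed mesh
#'
#' Divergence-theorem volume; positive when face normals point outward.
#'
#' @param mesh a `bone_mesh`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  # scalar triple product p1 . (p2 x p3) / 6
  cx <- p2[, 2L] * p3[, 3L] - p2[, 3L] * p3[, 2L]
  cy <- p2[, 3L] * p3[, 1L] - p2[, 1L] * p3[, 3L]
  cz <- p2[, 1L] * p3[, 2L] - p2[, 2L] * p3[, 1L]
  sum(p1[, 1L] * cx + p1[, 2L] * cy + p1[, 3L] * cz) / 6
}

# Apply a rigid transform (3x3 rotation R, length-3 translation t) to points.
transform_points <- function(points, rotation, translation) {
  sweep(points %*% t(rotation), 2L, translation, "+")
}
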