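#' Read an STL file (binary or ASCII)
#'
#' Detects the dialect automatically: a file whose size equals
#' `84 + 50 * n_triangles` (with `n_triangles` taken from the binary header)
#' is parsed as binary STL, otherwise as ASCII. Per-triangle vertices are
#' merged into a shared vertex table by exact coordinate match after rounding
#' to 1e-6 mm, which welds the duplicated corners the format stores.
#'
#' @param path path to an `.stl` file.
#' @return a [bone_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  size <- file.info(path)$size
  if (size < 15) {
    stop(sprintf("truncated STL '%s': only %d bytes (need header)", path, size))
  }
  raw <- readBin(path, "raw", n = size)
  is_binary <- FALSE
  if (size >= 84) {
    ntri <- readBin(raw[81:84], "integer", n = 1L, size = 4L, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && size == 84 + 50 * as.numeric(ntri)) {
      is_binary <- TRUE
    }
  }
  if (is_binary) {
    tri <- read_stl_binary(raw, path)
  } else {
    tri <- read_stl_ascii(raw, path)
  }
  weld_triangle_soup(tri)
}

read_stl_binary <- function(raw, path) {
  ntri <- readBin(raw[81:84], "integer", n = 1L, size = 4L, endian = "little")
  expected <- 84 + 50 * as.numeric(ntri)
  if (length(raw) < expected) {
    stop(sprintf("truncated binary STL '%s': %d bytes, expected %.0f (offset %d)",
                 path, length(raw), expected, length(raw)))
  }
  # each 50-byte record: 12 bytes normal, 36 bytes vertices, 2 attribute bytes
  base <- 84 + 50 * (seq_len(ntri) - 1)
  vert_off <- outer(base + 12, seq_len(36), `+`)   # ntri x 36 byte offsets
  idx <- as.vector(t(vert_off))
  vals <- readBin(raw[idx], "double", n = ntri * 9L, size = 4L,
                  endian = "little")
  matrix(vals, ncol = 3L, byrow = TRUE)            # 3*ntri x 3 vertex rows
}

read_stl_ascii <- function(raw, path) {
  txt <- rawToChar(raw)
  lines <- strsplit(txt, "\r?\n")[[1]]
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L) {
    stop(sprintf("malformed ASCII STL '%s': %d vertex lines (not a multiple of 3)",
                 path, length(vlines)))
  }
  fields <- strsplit(trimws(vlines), "\\s+")
  coords <- vapply(fields, function(f) as.numeric(f[2:4]), numeric(3))
  if (anyNA(coords)) stop("unparseable vertex coordinates in ASCII STL: ", path)
  t(coords)
}

# Merge a (3*ntri) x 3 triangle-soup vertex matrix into a bone_mesh.
weld_triangle_soup <- function(tri) {
  key <- paste(round(tri[, 1L] * 1e6), round(tri[, 2L] * 1e6),
               round(tri[, 3L] * 1e6))
  uid <- !duplicated(key)
  vertices <- tri[uid, , drop = FALSE]
  index <- match(key, key[uid])
  faces <- matrix(index, ncol = 3L, byrow = TRUE)
  bone_mesh(vertices, faces)
}

#' Write a mesh as binary STL
#'
#' @param mesh a [bone_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("boneCSG binary STL", width = -80))
  writeBin(header[1:80], con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  nrm <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
               e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
               e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  rec <- t(cbind(nrm, p1, p2, p3))         # 12 floats per triangle
  attr_bytes <- as.raw(c(0L, 0L))
  for (i in seq_len(nrow(f))) {
    writeBin(rec[, i], con, size = 4L, endian = "little")
    writeBin(attr_bytes, con)
  }
  invisible(path)
}

#' Write a mesh as ASCII STL
#'
#' @inheritParams write_stl
#' @export
write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  out <- c("solid boneCSG")
  blocks <- vapply(seq_len(nrow(f)), function(i) {
    p <- v[f[i, ], , drop = FALSE]
    paste0("facet normal 0 0 0\n outer loop\n",
           paste(sprintf("  vertex %.9g %.9g %.9g", p[, 1L], p[, 2L], p[, 3L]),
                 collapse = "\n"),
           "\n endloop\nendfacet")
  }, character(1))
  writeLines(c(out, blocks, "endsolid boneCSG"), path)
  invisible(path)
}

#' Read a landmark sidecar file
#'
#' Plain-text key/value format, one entry per line:
#' `neck: x y z`, `medial_condyle: x y z`, `lateral_condyle: x y z`, and
#' optionally `group: healthy|osteoporosis`. Lines starting with `#` are
#' comments.
#'
#' @param path landmark file path.
#' @return list with `neck`, `medial_condyle`, `lateral_condyle` (numeric
#'   length-3 vectors) and `group` (character or `NA`).
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", lines))
  keys <- vapply(kv, function(m) if (length(m) == 3L) m[2L] else NA_character_,
                 character(1))
  vals <- vapply(kv, function(m) if (length(m) == 3L) m[3L] else NA_character_,
                 character(1))
  get_point <- function(key) {
    i <- match(key, keys)
    if (is.na(i)) {
      stop(sprintf("landmark file '%s' is missing required key '%s'", path, key))
    }
    p <- suppressWarnings(as.numeric(strsplit(trimws(vals[i]), "\\s+")[[1]]))
    if (length(p) != 3L || anyNA(p)) {
      stop(sprintf("landmark '%s' in '%s' is not three numbers", key, path))
    }
    p
  }
  lm <- list(neck = get_point("neck"),
             medial_condyle = get_point("medial_condyle"),
             lateral_condyle = get_point("lateral_condyle"))
  gi <- match("group", keys)
  lm$group <- if (is.na(gi)) NA_character_ else trimws(vals[gi])
  validate_landmarks(lm)
  lm
}

validate_landmarks <- function(lm) {
  pts <- rbind(lm$neck, lm$medial_condyle, lm$lateral_condyle)
  if (anyDuplicated(round(pts, 9)) > 0L) {
    stop("landmarks must be three distinct points")
  }
  d1 <- sqrt(sum((lm$neck - lm$medial_condyle)^2))
  d2 <- sqrt(sum((lm$neck - lm$lateral_condyle)^2))
  if (d1 <= 0 || d2 <= 0) stop("neck-to-condyle distances must be positive")
  invisible(lm)
}

#' Write a landmark sidecar file
#'
#' @param landmarks list with `neck`, `medial_condyle`, `lateral_condyle`
#'   and optionally `group`.
#' @param path output path.
#' @export
write_landmarks <- function(landmarks, path) {
  fmt <- function(p) paste(sprintf("%.9g", p), collapse = " ")
  lines <- c(sprintf("neck: %s", fmt(landmarks$neck)),
             sprintf("medial_condyle: %s", fmt(landmarks$medial_condyle)),
             sprintf("lateral_condyle: %s", fmt(landmarks$lateral_condyle)))
  if (!is.null(landmarks$group) && !is.na(landmarks$group)) {
    lines <- c(lines, sprintf("group: %s", landmarks$group))
  }
  writeLines(lines, path)
  invisible(path)
}
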