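#' Triangle mesh of a specimen surface
#'
#' Container for a 3D surface mesh: an `n x 3` matrix of vertex coordinates
#' (model units, typically millimetres for CT-derived scans) and an
#' `m x 3` integer matrix of faces indexing vertices (1-based, as is usual in
#' R; conversion to/from 0- or 1-based file conventions happens at the I/O
#' boundary). Optional per-vertex attributes: a numeric scalar field (used
#' e.g. to carry a distance field or an axial coordinate) and an RGB colour
#' matrix with values in 0..255.
#'
#' Validation enforces: finite coordinates, face indices in range, and no
#' face referencing the same vertex twice. Degenerate faces (repeated
#' vertex within a face) are dropped with a warning rather than treated as
#' fatal, since fossil surface scans commonly contain a few.
#'
#' @param vertices numeric matrix (or coercible) with 3 columns.
#' @param faces integer matrix with 3 columns, 1-based vertex indices; may be
#'   `NULL` or zero-row for a vertex-only (point set) mesh.
#' @param scalar optional numeric vector, one value per vertex.
#' @param color optional integer matrix `n x 3`, RGB in 0..255.
#' @param id optional character identifier carried through comparisons.
#' @return An object of class `"trimesh"`.
#' @examples
#' m <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
#' n_vertices(m)
#' @export
trimesh <- function(vertices, faces = NULL, scalar = NULL, color = NULL,
                    id = NULL) {
  vertices <- as_coord_matrix(vertices, "vertices")
  n <- nrow(vertices)
  if (n < 1L) stop("mesh has no vertices", call. = FALSE)
  if (!all(is.finite(vertices))) {
    stop("mesh vertices contain non-finite coordinates", call. = FALSE)
  }
  if (is.null(faces)) {
    faces <- matrix(integer(0), ncol = 3L)
  } else {
    faces <- matrix(as.integer(round(as.matrix(faces))), ncol = 3L)
  }
  if (nrow(faces) > 0L) {
    if (anyNA(faces) || any(faces < 1L) || any(faces > n)) {
      bad <- which(is.na(faces) | faces < 1L | faces > n, arr.ind = TRUE)
      stop(sprintf("face %d references vertex index out of range [1, %d]",
                   bad[1L, 1L], n), call. = FALSE)
    }
    degen <- faces[, 1L] == faces[, 2L] | faces[, 1L] == faces[, 3L] |
      faces[, 2L] == faces[, 3L]
    if (any(degen)) {
      warning(sprintf("dropped %d degenerate face(s) referencing a vertex twice",
                      sum(degen)), call. = FALSE)
      faces <- faces[!degen, , drop = FALSE]
    }
  }
  if (!is.null(scalar)) {
    scalar <- as.numeric(scalar)
    if (length(scalar) != n) {
      stop(sprintf("scalar field has %d values for %d vertices",
                   length(scalar), n), call. = FALSE)
    }
  }
  if (!is.null(color)) {
    color <- matrix(as.integer(round(as.matrix(color))), ncol = 3L)
    if (nrow(color) != n) {
      stop(sprintf("color field has %d rows for %d vertices",
                   nrow(color), n), call. = FALSE)
    }
    if (anyNA(color) || any(color < 0L) || any(color > 255L)) {
      stop("colors must be RGB integers in [0, 255]", call. = FALSE)
    }
    colnames(color) <- c("red", "green", "blue")
  }
  structure(
    list(vertices = vertices, faces = faces, scalar = scalar, color = color,
         id = id),
    class = "trimesh"
  )
}

as_coord_matrix <- function(x, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) == 3L) x <- matrix(x, ncol = 3L)
    else stop(sprintf("%s must have 3 columns", what), call. = FALSE)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) {
    stop(sprintf("%s must have 3 columns, got %d", what, ncol(x)),
         call. = FALSE)
  }
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' @export
print.trimesh <- function(x, ...) {
  bb <- apply(x$vertices, 2L, range)
  cat(sprintf("Triangle mesh%s: %d vertices, %d faces\n",
              if (is.null(x$id)) "" else paste0(" '", x$id, "'"),
              n_vertices(x), n_faces(x)))
  cat(sprintf("  bounding box: [%.4g, %.4g] x [%.4g, %.4g] x [%.4g, %.4g]\n",
              bb[1L, 1L], bb[2L, 1L], bb[1L, 2L], bb[2L, 2L],
              bb[1L, 3L], bb[2L, 3L]))
  if (!is.null(x$scalar)) cat("  per-vertex scalar field present\n")
  if (!is.null(x$color)) cat("  per-vertex RGB colors present\n")
  invisible(x)
}

#' Number of vertices / faces of a mesh
#' @param mesh a [trimesh()].
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' Extract the point cloud of a mesh or coordinate matrix
#'
#' The point cloud of a mesh is exactly its vertex set, in vertex order:
#' the points available to registration and distance computation are those
#' the scan resolution provides. Plain `n x 3` matrices pass through after
#' validation, so functions taking clouds accept either representation.
#'
#' @param x a `trimesh`, a landmark set, or an `n x 3` numeric matrix.
#' @return numeric matrix with 3 columns.
#' @export
as_point_cloud <- function(x) {
  pts <- if (inherits(x, "trimesh")) {
    x$vertices
  } else if (inherits(x, "landmark_set")) {
    x$points
  } else {
    as_coord_matrix(x, "point cloud")
  }
  if (nrow(pts) < 1L) stop("point cloud is empty", call. = FALSE)
  if (!all(is.finite(pts))) {
    stop("point cloud contains non-finite coordinates", call. = FALSE)
  }
  pts
}

#' Ordered landmark set
#'
#' A small ordered set of homologous points used to seed registration.
#' Pairing between two landmark sets is positional (first with first, and
#' so on); labels are documentation only, mirroring the order in which
#' homologous points are picked on each specimen.
#'
#' @param points `k x 3` numeric matrix, `k >= 3`.
#' @param labels optional character vector of length `k`.
#' @param eps minimum allowed distance between two landmarks; closer pairs
#'   are rejected as coincident.
#' @return An object of class `"landmark_set"`.
#' @export
landmark_set <- function(points, labels = NULL, eps = 1e-8) {
  points <- as_coord_matrix(points, "landmarks")
  k <- nrow(points)
  if (k < 3L) stop("at least 3 landmarks required", call. = FALSE)
  if (!all(is.finite(points))) {
    stop("landmark coordinates must be finite", call. = FALSE)
  }
  d <- stats::dist(points)
  if (any(d < eps)) {
    stop(sprintf("two landmarks coincide within epsilon %g", eps),
         call. = FALSE)
  }
  if (is.null(labels)) labels <- sprintf("lm%02d", seq_len(k))
  labels <- as.character(labels)
  if (length(labels) != k) {
    stop("one label per landmark required", call. = FALSE)
  }
  structure(list(points = points, labels = labels), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("Landmark set: %d ordered landmarks\n", nrow(x$points)))
  df <- data.frame(label = x$labels, x = x$points[, 1L], y = x$points[, 2L],
                   z = x$points[, 3L])
  print(utils::head(df, 10L), row.names = FALSE)
  if (nrow(df) > 10L) cat(sprintf("  ... and %d more\n", nrow(df) - 10L))
  invisible(x)
}

#' Read landmarks from a plain-text file
#'
#' One landmark per line: `label, x, y, z` (comma- or whitespace-separated);
#' a line of three bare numbers is accepted and auto-labelled. Lines that
#' are empty or start with `#` are skipped. Pairing between two files is by
#' line order.
#'
#' @param path file path.
#' @param eps coincidence tolerance passed to [landmark_set()].
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, eps = 1e-8) {
  if (!file.exists(path)) {
    stop(sprintf("landmark file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) < 3L) stop("at least 3 landmarks required", call. = FALSE)
  labels <- character(length(keep))
  pts <- matrix(NA_real_, length(keep), 3L)
  for (i in seq_along(keep)) {
    ln <- keep[i]
    tok <- strsplit(trimws(lines[ln]), "[,[:space:]]+")[[1L]]
    tok <- tok[nzchar(tok)]
    if (length(tok) == 3L) {
      labels[i] <- sprintf("lm%02d", i)
      xyz <- suppressWarnings(as.numeric(tok))
    } else if (length(tok) >= 4L) {
      labels[i] <- tok[1L]
      xyz <- suppressWarnings(as.numeric(tok[2L:4L]))
    } else {
      stop(sprintf("line %d: expected 'label x y z' or 'x y z'", ln),
           call. = FALSE)
    }
    if (anyNA(xyz)) {
      stop(sprintf("line %d: non-numeric coordinate", ln), call. = FALSE)
    }
    pts[i, ] <- xyz
  }
  landmark_set(pts, labels, eps = eps)
}

#' Write landmarks to a plain-text file
#' @param lm a [landmark_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  writeLines(sprintf("%s %.9g %.9g %.9g", lm$labels,
                     lm$points[, 1L], lm$points[, 2L], lm$points[, 3L]),
             path)
  invisible(path)
}

# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}
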