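#' Similarity transform (scale, rotation, translation)
#'
#' Maps a point `x` to `s * R %*% x + t`: uniform scale `s > 0`, proper
#' rotation `R` (orthonormal, `det R = +1`; reflections are excluded), and
#' translation `t` in model units. This is the transform class the
#' registration stages estimate: specimens may differ considerably in size,
#' so scale is part of the alignment, but shear is not.
#'
#' @param scale positive scalar.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric vector.
#' @return An object of class `"similarity_transform"`.
#' @export
similarity_transform <- function(scale = 1, rotation = diag(3),
                                 translation = c(0, 0, 0)) {
  scale <- as.numeric(scale)
  if (length(scale) != 1L || !is.finite(scale) || scale <= 0) {
    stop("scale must be a single positive number", call. = FALSE)
  }
  rotation <- matrix(as.numeric(rotation), 3L, 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stop("rotation matrix is not orthonormal", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > 1e-8) {
    stop("rotation matrix must have det +1 (no reflection)", call. = FALSE)
  }
  translation <- as.numeric(translation)
  if (length(translation) != 3L || !all(is.finite(translation))) {
    stop("translation must be a finite length-3 vector", call. = FALSE)
  }
  structure(list(scale = scale, rotation = rotation,
                 translation = translation),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("Similarity transform: scale %.6g\n", x$scale))
  cat("  rotation:\n")
  print(round(x$rotation, 6L))
  cat(sprintf("  translation: (%.6g, %.6g, %.6g)\n",
              x$translation[1L], x$translation[2L], x$translation[3L]))
  invisible(x)
}

#' Rotation matrix from intrinsic z-y-x Euler angles
#'
#' @param yaw,pitch,roll rotation angles in radians about the z, y, and x
#'   axes respectively; the returned matrix is `Rz(yaw) Ry(pitch) Rx(roll)`.
#' @return 3x3 rotation matrix.
#' @export
euler_rotation <- function(yaw = 0, pitch = 0, roll = 0) {
  cz <- cos(yaw); sz <- sin(yaw)
  cy <- cos(pitch); sy <- sin(pitch)
  cx <- cos(roll); sx <- sin(roll)
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  rz %*% ry %*% rx
}

#' Apply a similarity transform
#'
#' Maps every point `x -> s * R x + t`. Meshes keep their connectivity and
#' per-vertex fields; landmark sets keep order and labels.
#'
#' @param x a [trimesh()], [landmark_set()], or `n x 3` matrix.
#' @param transform a [similarity_transform()].
#' @return An object of the same type as `x`.
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "similarity_transform"))
  tf <- function(p) {
    sweep(p %*% t(transform$rotation) * transform$scale, 2L,
          transform$translation, "+")
  }
  if (inherits(x, "trimesh")) {
    x$vertices <- tf(x$vertices)
    x
  } else if (inherits(x, "landmark_set")) {
    x$points <- tf(x$points)
    x
  } else {
    tf(as_coord_matrix(x, "points"))
  }
}

#' Compose two similarity transforms
#'
#' Returns the transform equivalent to applying `inner` first, then
#' `outer`: `x -> outer(inner(x))`.
#'
#' @param outer,inner [similarity_transform()] objects.
#' @return A [similarity_transform()].
#' @export
compose_transforms <- function(outer, inner) {
  similarity_transform(
    scale = outer$scale * inner$scale,
    rotation = outer$rotation %*% inner$rotation,
    translation = outer$scale *
      as.vector(outer$rotation %*% inner$translation) + outer$translation
  )
}

#' Invert a similarity transform
#' @param transform a [similarity_transform()].
#' @return The inverse [similarity_transform()].
#' @export
invert_transform <- function(transform) {
  rinv <- t(transform$rotation)
  similarity_transform(
    scale = 1 / transform$scale,
    rotation = rinv,
    translation = -as.vector(rinv %*% transform$translation) /
      transform$scale
  )
}
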