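#' Parameters for the claw-like test specimen
#'
#' Describes a parametric ungual-like surface: a tube swept along a
#' circular arc, tapering towards the tip, with a groove indented on both
#' lateral sides (emulating medial/lateral blood grooves) and a rounded
#' bulge on the ventral proximal region (emulating a flexor tubercle).
#' All downstream stages of the package can be exercised on these surfaces
#' with known ground truth, with no scan data required.
#'
#' @param length arc length of the claw axis (model units).
#' @param curvature angle (radians) swept by the claw axis arc.
#' @param proximal_radius tube radius at the proximal end.
#' @param taper exponent of the taper law; larger values thin the distal
#'   end faster.
#' @param groove_depth fractional depth of the two lateral grooves, in
#'   `[0, 1)`.
#' @param tubercle fractional height of the ventral proximal bulge, in
#'   `[0, 1)`.
#' @param n_axial number of cross-section rings along the axis (>= 8).
#' @param n_radial number of points per ring (>= 8).
#' @param seed integer seed recorded with the parameters (the base surface
#'   is deterministic; the seed matters only for degradation noise).
#' @return An object of class `"claw_params"`.
#' @export
claw_params <- function(length = 10, curvature = pi / 2,
                        proximal_radius = 1.6, taper = 1.3,
                        groove_depth = 0.25, tubercle = 0.35,
                        n_axial = 36L, n_radial = 24L, seed = 1L) {
  if (length <= 0 || proximal_radius <= 0) {
    stop("length and proximal_radius must be positive", call. = FALSE)
  }
  if (curvature <= 0 || curvature >= 2 * pi) {
    stop("curvature must be in (0, 2*pi)", call. = FALSE)
  }
  if (taper <= 0) stop("taper must be positive", call. = FALSE)
  if (groove_depth < 0 || groove_depth >= 1 || tubercle < 0 || tubercle >= 1) {
    stop("groove_depth and tubercle must be in [0, 1)", call. = FALSE)
  }
  if (n_axial < 8L || n_radial < 8L) {
    stop("resolutions must be at least 8", call. = FALSE)
  }
  structure(list(length = length, curvature = curvature,
                 proximal_radius = proximal_radius, taper = taper,
                 groove_depth = groove_depth, tubercle = tubercle,
                 n_axial = as.integer(n_axial),
                 n_radial = as.integer(n_radial), seed = as.integer(seed)),
            class = "claw_params")
}

# wrapped angular distance
ang_diff <- function(theta, theta0) atan2(sin(theta - theta0),
                                          cos(theta - theta0))

#' Generate a watertight claw-like triangle mesh
#'
#' Builds the surface described by [claw_params()]: `n_axial` rings of
#' `n_radial` vertices along a circular arc, closed with one cap vertex at
#' each end, so the mesh is a closed manifold (Euler characteristic 2).
#' The per-vertex scalar field stores the normalised axial coordinate
#' (0 proximal, 1 distal), which the degradation stage uses to place cuts.
#' Generation is fully deterministic for fixed parameters.
#'
#' @param params a [claw_params()].
#' @return A [trimesh()] with `n_axial * n_radial + 2` vertices.
#' @export
make_claw <- function(params = claw_params()) {
  stopifnot(inherits(params, "claw_params"))
  A <- params$n_axial
  Rr <- params$n_radial
  arc_r <- params$length / params$curvature
  u <- (seq_len(A) - 1) / (A - 1)
  phi <- u * params$curvature
  # arc axis in the xz plane; dorsal/ventral along z, lateral along y
  centers <- cbind(arc_r * sin(phi), 0, arc_r * (1 - cos(phi)))
  tang <- cbind(cos(phi), 0, sin(phi))
  nrm <- cbind(-sin(phi), 0, cos(phi))   # in-plane normal (dorsal at theta=0)
  ring_r <- params$proximal_radius * (1 - 0.92 * u)^params$taper

  theta <- 2 * pi * (seq_len(Rr) - 1) / Rr
  verts <- matrix(NA_real_, A * Rr + 2L, 3L)
  axial <- numeric(A * Rr + 2L)
  groove_win <- exp(-((u - 0.55)^2) / (2 * 0.28^2))
  tub_win <- exp(-((u - 0.12)^2) / (2 * 0.10^2))
  for (i in seq_len(A)) {
    mod <- 1 -
      params$groove_depth * groove_win[i] *
        (exp(-(ang_diff(theta, pi / 2)^2) / (2 * 0.35^2)) +
         exp(-(ang_diff(theta, 3 * pi / 2)^2) / (2 * 0.35^2))) +
      params$tubercle * tub_win[i] *
        exp(-(ang_diff(theta, pi)^2) / (2 * 0.55^2))
    offset <- outer(cos(theta) * ring_r[i] * mod, nrm[i, ]) +
      outer(sin(theta) * ring_r[i] * mod, c(0, 1, 0))
    rows <- (i - 1L) * Rr + seq_len(Rr)
    verts[rows, ] <- sweep(offset, 2L, centers[i, ], "+")
    axial[rows] <- u[i]
  }
  prox_cap <- A * Rr + 1L
  tip_cap <- A * Rr + 2L
  verts[prox_cap, ] <- centers[1L, ] - 0.5 * ring_r[1L] * tang[1L, ]
  verts[tip_cap, ] <- centers[A, ] + 1.2 * ring_r[A] * tang[A, ]
  axial[prox_cap] <- 0
  axial[tip_cap] <- 1

  vid <- function(i, j) (i - 1L) * Rr + ((j - 1L) %% Rr) + 1L
  side <- vector("list", A - 1L)
  j <- seq_len(Rr)
  for (i in seq_len(A - 1L)) {
    a <- vid(i, j); b <- vid(i, j + 1L)
    c2 <- vid(i + 1L, j + 1L); d <- vid(i + 1L, j)
    side[[i]] <- rbind(cbind(a, b, c2), cbind(a, c2, d))
  }
  prox_faces <- cbind(prox_cap, vid(1L, j + 1L), vid(1L, j))
  tip_faces <- cbind(tip_cap, vid(A, j), vid(A, j + 1L))
  faces <- do.call(rbind, c(side, list(prox_faces, tip_faces)))
  trimesh(verts, faces, scalar = axial, id = "synthetic-claw")
}

#' Degradation parameters for a fragmentary target
#'
#' Describes how a pristine specimen is turned into a fragmentary target:
#' the distal fraction of the claw is cut away (missing tip), a small
#' spherical hole is punched (excavation artefact), and the surviving
#' vertices are perturbed by Gaussian noise along their normals
#' (surface-scan error). All operations are seeded and deterministic.
#'
#' @param distal_fraction fraction of the axial extent removed from the
#'   distal end, in `[0, 1)`.
#' @param hole_center axial position (fraction in `[0, 1]`) of the hole.
#' @param hole_radius radius of the spherical hole (model units); 0
#'   disables the hole.
#' @param noise_sd standard deviation of the along-normal Gaussian noise
#'   (model units); 0 disables noise.
#' @param seed integer RNG seed for the noise.
#' @return An object of class `"degradation_spec"`.
#' @export
degradation_spec <- function(distal_fraction = 0.25, hole_center = 0.15,
                             hole_radius = 0, noise_sd = 0, seed = 1L) {
  if (distal_fraction < 0 || distal_fraction >= 1) {
    stop("distal_fraction must be in [0, 1)", call. = FALSE)
  }
  if (hole_center < 0 || hole_center > 1) {
    stop("hole_center must be in [0, 1]", call. = FALSE)
  }
  if (hole_radius < 0) stop("hole_radius must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(distal_fraction = distal_fraction,
                 hole_center = hole_center, hole_radius = hole_radius,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "degradation_spec")
}

# Per-vertex axial coordinate in [0, 1]: the generator's scalar field when
# present, otherwise the normalised projection onto the first principal axis.
axial_coordinate <- function(mesh) {
  if (!is.null(mesh$scalar)) return(mesh$scalar)
  v <- sweep(mesh$vertices, 2L, colMeans(mesh$vertices))
  ax <- svd(v, nu = 0L, nv = 1L)$v[, 1L]
  p <- as.vector(v %*% ax)
  (p - min(p)) / max(max(p) - min(p), .Machine$double.eps)
}

#' Area-weighted per-vertex normals
#' @param mesh a [trimesh()] with at least one face.
#' @return `n x 3` matrix of unit normals (zero rows for unreferenced
#'   vertices).
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- matrix(0, nrow(v), 3L)
  if (nrow(f) == 0L) return(n)
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  fn <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  for (k in 1L:3L) {
    for (d in 1L:3L) {
      acc <- tapply(fn[, d], f[, k], sum)
      rows <- as.integer(names(acc))
      n[rows, d] <- n[rows, d] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  nz <- len > 0
  n[nz, ] <- n[nz, , drop = FALSE] / len[nz]
  n
}

#' Degrade a mesh into a fragmentary target
#'
#' Removes vertices beyond the distal cut (axial coordinate past
#' `1 - distal_fraction`) and inside the hole sphere, re-indexes the faces
#' (no re-triangulation of cut boundaries: the result is an open shell,
#' like a trimmed fossil scan), then perturbs the surviving vertices along
#' their normals with seeded Gaussian noise. With zero noise the surviving
#' vertex coordinates are exactly a subset of the input's.
#'
#' @param mesh a [trimesh()].
#' @param spec a [degradation_spec()].
#' @return A list: `mesh` (the degraded [trimesh()]) and `report`, a list
#'   with `removed_distal`, `removed_hole`, and `n_kept`.
#' @export
degrade <- function(mesh, spec = degradation_spec()) {
  stopifnot(inherits(mesh, "trimesh"), inherits(spec, "degradation_spec"))
  u <- axial_coordinate(mesh)
  keep <- u <= 1 - spec$distal_fraction
  removed_distal <- sum(!keep)
  removed_hole <- 0L
  if (spec$hole_radius > 0) {
    center_idx <- which.min(abs(u - spec$hole_center))
    center <- mesh$vertices[center_idx, ]
    d <- sqrt(rowSums(sweep(mesh$vertices, 2L, center)^2))
    in_hole <- d <= spec$hole_radius
    removed_hole <- sum(in_hole & keep)
    keep <- keep & !in_hole
  }
  if (sum(keep) < 3L) {
    stop("degradation would remove (nearly) all vertices", call. = FALSE)
  }
  out <- trim(mesh, keep)
  if (spec$noise_sd > 0) {
    nrm <- vertex_normals(out)
    disp <- with_seed(spec$seed, stats::rnorm(n_vertices(out), 0,
                                              spec$noise_sd))
    out$vertices <- out$vertices + disp * nrm
  }
  out$id <- paste0(mesh$id %||% "mesh", "-degraded")
  list(mesh = out,
       report = list(removed_distal = removed_distal,
                     removed_hole = removed_hole,
                     n_kept = n_vertices(out)))
}

#' Apply a known similarity transform and return the ground truth inverse
#'
#' Moves a mesh by `x -> s R x + t` and returns, alongside the transformed
#' mesh, the exact inverse transform a registration stage would have to
#' recover to re-register the moved mesh onto the original. Used to plant
#' ground truth for registration tests; real specimens likewise differ by
#' an unknown size factor and pose.
#'
#' @param mesh a [trimesh()].
#' @param scale positive scalar.
#' @param rotation length-3 numeric of Euler angles (yaw, pitch, roll,
#'   radians) or a 3x3 rotation matrix.
#' @param translation length-3 numeric vector.
#' @return A list: `mesh` (transformed) and `truth` (the inverse
#'   [similarity_transform()]).
#' @export
plant_transform <- function(mesh, scale = 1, rotation = c(0, 0, 0),
                            translation = c(0, 0, 0)) {
  stopifnot(inherits(mesh, "trimesh"))
  R <- if (is.matrix(rotation)) rotation
  else euler_rotation(rotation[1L], rotation[2L], rotation[3L])
  fwd <- similarity_transform(scale, R, translation)
  list(mesh = apply_transform(mesh, fwd), truth = invert_transform(fwd))
}

#' Sample a paired landmark set from two meshes at shared template indices
#'
#' For meshes derived from a common template (e.g. an original and its
#' degraded or transformed copy with vertex order preserved), returns two
#' ordered landmark sets sampled at the same vertex indices, ready for
#' [landmark_similarity()].
#'
#' @param mesh_a,mesh_b [trimesh()]es sharing a vertex indexing.
#' @param indices at least 3 vertex indices, valid in both meshes.
#' @return A list of two [landmark_set()]s, `a` and `b`.
#' @export
make_landmark_pair <- function(mesh_a, mesh_b, indices) {
  indices <- as.integer(indices)
  if (length(indices) < 3L) {
    stop("at least 3 landmark indices required", call. = FALSE)
  }
  if (any(indices < 1L) || any(indices > n_vertices(mesh_a)) ||
      any(indices > n_vertices(mesh_b))) {
    stop("landmark index out of range", call. = FALSE)
  }
  labels <- sprintf("lm%02d", seq_along(indices))
  list(a = landmark_set(mesh_a$vertices[indices, , drop = FALSE], labels),
       b = landmark_set(mesh_b$vertices[indices, , drop = FALSE], labels))
}
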