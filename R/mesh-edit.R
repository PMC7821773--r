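#' Trim a mesh to a vertex keep-mask
#'
#' Removes the vertices flagged `FALSE`, compacting the surviving indices
#' in order, and keeps a face only if all three of its vertices survive.
#' Surviving vertex coordinates (and scalar/color fields) are untouched;
#' the result may be an open shell. This is the programmatic counterpart
#' of interactively deleting fractured or artefactual surfaces before a
#' comparison.
#'
#' @param mesh a [trimesh()].
#' @param keep logical vector, one flag per vertex.
#' @return The trimmed [trimesh()].
#' @export
trim <- function(mesh, keep) {
  stopifnot(inherits(mesh, "trimesh"))
  keep <- as.logical(keep)
  if (length(keep) != n_vertices(mesh) || anyNA(keep)) {
    stop("keep mask must be one non-NA flag per vertex", call. = FALSE)
  }
  if (!any(keep)) stop("trim would leave an empty mesh", call. = FALSE)
  newidx <- cumsum(keep)
  f <- mesh$faces
  fkeep <- keep[f[, 1L]] & keep[f[, 2L]] & keep[f[, 3L]]
  faces <- matrix(newidx[f[fkeep, , drop = FALSE]], ncol = 3L)
  trimesh(mesh$vertices[keep, , drop = FALSE], faces,
          scalar = if (!is.null(mesh$scalar)) mesh$scalar[keep],
          color = if (!is.null(mesh$color)) {
            mesh$color[keep, , drop = FALSE]
          },
          id = mesh$id)
}

#' Select vertices by a sphere
#'
#' Flags vertices by Euclidean distance to `center`; a vertex exactly on
#' the boundary counts as inside. Useful for excising localised artefacts
#' such as circular excavation marks.
#'
#' @param mesh a [trimesh()].
#' @param center length-3 numeric sphere center.
#' @param radius positive radius.
#' @param mode `"keep-inside"` or `"keep-outside"`.
#' @return Logical keep-mask of length `n_vertices(mesh)` for [trim()].
#' @export
select_by_sphere <- function(mesh, center, radius,
                             mode = c("keep-outside", "keep-inside")) {
  stopifnot(inherits(mesh, "trimesh"))
  mode <- match.arg(mode)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  center <- as.numeric(center)
  stopifnot(length(center) == 3L)
  inside <- sqrt(rowSums(sweep(mesh$vertices, 2L, center)^2)) <= radius
  if (mode == "keep-inside") inside else !inside
}

#' Select vertices by a half-space
#'
#' Flags vertices by the sign of `(v - point) . normal`; vertices exactly
#' on the plane count as behind. Useful for planar cuts such as removing
#' everything distal of a fracture plane.
#'
#' @param mesh a [trimesh()].
#' @param point length-3 numeric point on the plane.
#' @param normal length-3 numeric plane normal (need not be unit).
#' @param mode `"keep-behind"` (against the normal, default) or
#'   `"keep-ahead"`.
#' @return Logical keep-mask for [trim()].
#' @export
select_by_plane <- function(mesh, point, normal,
                            mode = c("keep-behind", "keep-ahead")) {
  stopifnot(inherits(mesh, "trimesh"))
  mode <- match.arg(mode)
  point <- as.numeric(point); normal <- as.numeric(normal)
  stopifnot(length(point) == 3L, length(normal) == 3L)
  s <- as.vector(sweep(mesh$vertices, 2L, point) %*% normal)
  if (mode == "keep-behind") s <= 0 else s > 0
}

#' Decimate a mesh to a target vertex count
#'
#' Iterative edge collapse ordered by quadric error: each vertex carries
#' the sum of squared-distance quadrics of its incident face planes; the
#' edge whose optimal contraction point has the lowest quadric cost is
#' collapsed first (ties break to the lowest edge index), until the number
#' of referenced vertices reaches the target. Collapsed positions minimise
#' the combined quadric, so they need not be original vertices. Used to
#' reduce a higher-resolution scan to the polygon count of its comparison
#' partner.
#'
#' The returned mesh carries attribute `"fidelity"`: the maximum unsigned
#' distance from any original vertex to the decimated surface, a bound on
#' the geometric error introduced.
#'
#' @param mesh a [trimesh()] with faces.
#' @param target_vertex_count integer in `[3, n_vertices(mesh)]`; if equal
#'   to the current count the mesh is returned unchanged (with a message).
#' @return The decimated [trimesh()] with attribute `"fidelity"`.
#' @export
decimate <- function(mesh, target_vertex_count) {
  stopifnot(inherits(mesh, "trimesh"))
  target <- as.integer(target_vertex_count)
  nv <- n_vertices(mesh)
  if (target == nv) {
    message("decimate: target equals current vertex count; mesh unchanged")
    attr(mesh, "fidelity") <- 0
    return(mesh)
  }
  if (target < 3L || target > nv) {
    stop(sprintf("target vertex count must be in [3, %d]", nv),
         call. = FALSE)
  }
  if (n_faces(mesh) == 0L) {
    stop("cannot decimate a faceless mesh", call. = FALSE)
  }

  v <- mesh$vertices
  f <- mesh$faces
  quad <- vertex_quadrics(v, f)

  # edge table (undirected, lowest index first)
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(1L, 3L)])
  e <- t(apply(e, 1L, sort))
  e <- unique(e)
  ecost <- numeric(nrow(e))
  epos <- matrix(0, nrow(e), 3L)
  for (i in seq_len(nrow(e))) {
    oc <- edge_collapse_cost(quad[[e[i, 1L]]] + quad[[e[i, 2L]]],
                             v[e[i, 1L], ], v[e[i, 2L], ])
    ecost[i] <- oc$cost
    epos[i, ] <- oc$pos
  }
  face_alive <- rep(TRUE, nrow(f))
  # face-incidence count per vertex; a vertex is "referenced" while > 0
  deg <- tabulate(f, nbins = nv)
  n_ref <- sum(deg > 0L)
  edge_alive <- rep(TRUE, nrow(e))

  while (n_ref > target) {
    cand <- which(edge_alive)
    if (length(cand) == 0L) break
    i <- cand[which.min(ecost[cand])]
    u <- e[i, 1L]; w <- e[i, 2L]
    # collapse w into u at the optimal position
    v[u, ] <- epos[i, ]
    quad[[u]] <- quad[[u]] + quad[[w]]
    # remap faces that reference w; those also touching u degenerate and die
    touched_f <- which(face_alive & (f[, 1L] == w | f[, 2L] == w |
                                     f[, 3L] == w))
    for (fi in touched_f) {
      tri <- f[fi, ]
      tri[tri == w] <- u
      if (anyDuplicated(tri)) {
        face_alive[fi] <- FALSE
        for (vv in f[fi, ]) {
          deg[vv] <- deg[vv] - 1L
          if (deg[vv] == 0L) n_ref <- n_ref - 1L
        }
      } else {
        f[fi, ] <- tri
        deg[w] <- deg[w] - 1L
        deg[u] <- deg[u] + 1L
        if (deg[w] == 0L) n_ref <- n_ref - 1L
      }
    }
    # remap edges touching w, drop self-edges and duplicates, refresh costs
    touched_e <- which(edge_alive & (e[, 1L] == w | e[, 2L] == w |
                                     e[, 1L] == u | e[, 2L] == u))
    e[touched_e, ][e[touched_e, ] == w] <- u
    bad <- touched_e[e[touched_e, 1L] == e[touched_e, 2L]]
    edge_alive[bad] <- FALSE
    touched_e <- setdiff(touched_e, bad)
    if (length(touched_e) > 1L) {
      key <- paste(pmin(e[touched_e, 1L], e[touched_e, 2L]),
                   pmax(e[touched_e, 1L], e[touched_e, 2L]))
      dup <- touched_e[duplicated(key)]
      edge_alive[dup] <- FALSE
      touched_e <- setdiff(touched_e, dup)
    }
    for (j in touched_e) {
      a <- e[j, 1L]; b <- e[j, 2L]
      if (deg[a] == 0L || deg[b] == 0L) {
        edge_alive[j] <- FALSE
        next
      }
      oc <- edge_collapse_cost(quad[[a]] + quad[[b]], v[a, ], v[b, ])
      ecost[j] <- oc$cost
      epos[j, ] <- oc$pos
    }
  }

  keep <- deg > 0L
  newidx <- cumsum(keep)
  f2 <- f[face_alive, , drop = FALSE]
  out <- trimesh(v[keep, , drop = FALSE],
                 matrix(newidx[f2], ncol = 3L), id = mesh$id)
  fid <- max(c2m(mesh$vertices, out)$distances)
  attr(out, "fidelity") <- fid
  message(sprintf(
    "decimate: %d -> %d vertices; max original-vertex-to-surface distance %.4g",
    nv, n_vertices(out), fid))
  out
}

# Sum of squared-distance-to-plane quadrics of incident faces, area-weighted.
vertex_quadrics <- function(v, f) {
  n <- nrow(v)
  quad <- vector("list", n)
  zero <- matrix(0, 4L, 4L)
  for (i in seq_len(n)) quad[[i]] <- zero
  for (fi in seq_len(nrow(f))) {
    a <- v[f[fi, 1L], ]; b <- v[f[fi, 2L], ]; c2 <- v[f[fi, 3L], ]
    nr <- c((b - a)[2L] * (c2 - a)[3L] - (b - a)[3L] * (c2 - a)[2L],
            (b - a)[3L] * (c2 - a)[1L] - (b - a)[1L] * (c2 - a)[3L],
            (b - a)[1L] * (c2 - a)[2L] - (b - a)[2L] * (c2 - a)[1L])
    area2 <- sqrt(sum(nr^2))
    if (area2 == 0) next
    nr <- nr / area2
    p <- c(nr, -sum(nr * a))
    K <- (area2 / 2) * tcrossprod(p)
    for (k in 1L:3L) {
      vi <- f[fi, k]
      quad[[vi]] <- quad[[vi]] + K
    }
  }
  quad
}

# Optimal contraction position and quadric cost for one edge.
edge_collapse_cost <- function(Q, pu, pv) {
  A <- Q[1L:3L, 1L:3L]
  b <- -Q[1L:3L, 4L]
  pos <- NULL
  ok <- FALSE
  if (all(is.finite(A))) {
    r <- tryCatch(solve(A, b), error = function(e) NULL)
    if (!is.null(r) && all(is.finite(r)) &&
        rcond_3x3(A) > 1e-10) {
      pos <- r
      ok <- TRUE
    }
  }
  quad_eval <- function(p) {
    ph <- c(p, 1)
    as.numeric(ph %*% Q %*% ph)
  }
  if (!ok) {
    cands <- rbind(pu, pv, (pu + pv) / 2)
    costs <- apply(cands, 1L, quad_eval)
    j <- which.min(costs)
    return(list(pos = cands[j, ], cost = max(costs[j], 0)))
  }
  list(pos = pos, cost = max(quad_eval(pos), 0))
}

rcond_3x3 <- function(A) {
  d <- svd(A, nu = 0L, nv = 0L)$d
  if (d[1L] == 0) 0 else d[3L] / d[1L]
}

#' Reduce a higher-resolution mesh to match a lower-resolution one
#'
#' Decimates `high` to the vertex count of `low`. Upsampling is refused:
#' subdividing a low-resolution scan cannot restore surface detail the
#' scanner never captured, so if `high` does not actually have more
#' vertices than `low` this errors rather than subdividing.
#'
#' @param high the higher-resolution [trimesh()] (will be decimated).
#' @param low the lower-resolution [trimesh()] (sets the target count).
#' @return `high` decimated to `n_vertices(low)` (see [decimate()]).
#' @export
match_resolution <- function(high, low) {
  stopifnot(inherits(high, "trimesh"), inherits(low, "trimesh"))
  if (n_vertices(high) <= n_vertices(low)) {
    stop(paste("refusing to upsample: 'high' must have more vertices than",
               "'low' (increasing resolution cannot restore unscanned",
               "detail)"), call. = FALSE)
  }
  decimate(high, n_vertices(low))
}
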