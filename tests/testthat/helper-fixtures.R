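# Shared fixtures: built in code at test time, no binary files.

# single right triangle in the xy plane
unit_triangle <- function() {
  trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1L, 2L, 3L)))
}

# unit icosphere; vertex count is 10 * 4^levels + 2 (642 at levels = 3)
icosphere <- function(levels = 2L) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11),
             c(1, 11, 12), c(2, 6, 10), c(6, 12, 5), c(12, 11, 3),
             c(11, 8, 7), c(8, 2, 9), c(4, 10, 5), c(4, 5, 3),
             c(4, 3, 7), c(4, 7, 9), c(4, 9, 10), c(5, 10, 6),
             c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(levels)) {
    env <- new.env()
    mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- env[[key]]
      if (!is.null(hit)) return(hit)
      p <- v[a, ] + v[b, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      env[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- vector("list", nrow(f))
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; c2 <- f[i, 3L]
      ab <- mid(a, b); bc <- mid(b, c2); ca <- mid(c2, a)
      nf[[i]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(c2, ca, bc),
                       c(ab, bc, ca))
    }
    f <- do.call(rbind, nf)
  }
  trimesh(v, f, id = "icosphere")
}

# geometry-agnostic random mesh for I/O round trips
random_mesh <- function(n_vertices = 30L, n_faces = 40L) {
  v <- matrix(stats::rnorm(n_vertices * 3L), ncol = 3L)
  f <- t(replicate(n_faces, sample.int(n_vertices, 3L)))
  trimesh(v, f)
}

random_rotation <- function() {
  euler_rotation(stats::runif(1, -pi, pi), stats::runif(1, -pi / 2, pi / 2),
                 stats::runif(1, -pi, pi))
}

# moderate planted misalignment: the regime ICP is meant for (a landmark
# first registration leaves residual scale within ~30% and pose within ~20 deg)
moderate_similarity <- function() {
  similarity_transform(
    scale = stats::runif(1, 0.75, 1.35),
    rotation = euler_rotation(stats::runif(1, -pi / 8, pi / 8),
                              stats::runif(1, -pi / 10, pi / 10),
                              stats::runif(1, -pi / 8, pi / 8)),
    translation = stats::rnorm(3, sd = 0.4))
}

random_similarity <- function(max_angle = pi) {
  similarity_transform(
    scale = stats::runif(1, 0.5, 2),
    rotation = euler_rotation(stats::runif(1, -max_angle, max_angle),
                              stats::runif(1, -max_angle / 2, max_angle / 2),
                              stats::runif(1, -max_angle, max_angle)),
    translation = stats::rnorm(3, sd = 2))
}

# raw standardised fourth moment
kurtosis <- function(x) {
  m <- mean(x)
  mean((x - m)^4) / mean((x - m)^2)^2
}

# independent scalar point-to-triangle distance oracle: distance to the
# plane foot if its barycentric coordinates are inside, else the minimum
# point-to-segment distance over the three edges
oracle_point_triangle <- function(p, a, b, c2) {
  seg <- function(p, q, r) {
    d <- r - q
    t <- sum((p - q) * d) / sum(d * d)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (q + t * d))^2))
  }
  n <- c((b - a)[2] * (c2 - a)[3] - (b - a)[3] * (c2 - a)[2],
         (b - a)[3] * (c2 - a)[1] - (b - a)[1] * (c2 - a)[3],
         (b - a)[1] * (c2 - a)[2] - (b - a)[2] * (c2 - a)[1])
  n2 <- sum(n * n)
  if (n2 > 0) {
    foot <- p - (sum((p - a) * n) / n2) * n
    # barycentric test via edge cross products
    inside <- TRUE
    verts <- list(a, b, c2)
    for (k in 1:3) {
      q <- verts[[k]]; r <- verts[[k %% 3 + 1]]
      e <- r - q
      w <- foot - q
      cr <- c(e[2] * w[3] - e[3] * w[2], e[3] * w[1] - e[1] * w[3],
              e[1] * w[2] - e[2] * w[1])
      if (sum(cr * n) < 0) inside <- FALSE
    }
    if (inside) return(sqrt(sum((p - foot)^2)))
  }
  min(seg(p, a, b), seg(p, b, c2), seg(p, c2, a))
}

oracle_c2m <- function(points, mesh) {
  vapply(seq_len(nrow(points)), function(i) {
    min(vapply(seq_len(nrow(mesh$faces)), function(j) {
      f <- mesh$faces[j, ]
      oracle_point_triangle(points[i, ], mesh$vertices[f[1], ],
                            mesh$vertices[f[2], ], mesh$vertices[f[3], ])
    }, numeric(1)))
  }, numeric(1))
}

oracle_c2c <- function(points, ref) {
  apply(points, 1, function(p) sqrt(min(colSums((t(ref) - p)^2))))
}

# low-resolution claw pair used by the stochastic acceptance properties:
# same base shape, reference differing only in a localised feature (a more
# bulbous tubercle), target degraded (missing tip + hole + scan noise)
small_claw_pair <- function(seed) {
  target_template <- make_claw(claw_params(n_axial = 24L, n_radial = 16L))
  reference <- make_claw(claw_params(tubercle = 0.6, n_axial = 24L,
                                     n_radial = 16L))
  degraded <- degrade(target_template,
                      degradation_spec(distal_fraction = 0.3,
                                       hole_radius = 0.5, noise_sd = 0.03,
                                       seed = seed))$mesh
  list(template = target_template, reference = reference,
       degraded = degraded)
}
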