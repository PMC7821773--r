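#' Cloud-to-cloud absolute distance field
#'
#' For every point of the compared cloud, the Euclidean distance to its
#' nearest point of the reference cloud. Exact (exhaustive nearest
#' neighbour, vectorised in chunks), unsigned, asymmetric in general: the
#' maximum of the field is the directed Hausdorff distance from compared
#' to reference.
#'
#' @param compared a [trimesh()] or point cloud whose points receive
#'   distance values.
#' @param reference a [trimesh()] or point cloud measured against.
#' @return An object of class `"distance_field"`: `distances` (one
#'   non-negative value per compared point), `mode` (`"C2C"`), `n`, and the
#'   ids of both inputs.
#' @export
c2c <- function(compared, reference) {
  cmp <- as_point_cloud(compared)
  ref <- as_point_cloud(reference)
  nn <- nn_index(cmp, ref)
  new_distance_field(nn$dist, "C2C", compared, reference)
}

#' Cloud-to-mesh absolute distance field
#'
#' For every point of the compared cloud, the exact unsigned Euclidean
#' distance to the reference surface: the minimum over all reference
#' triangles of the point-to-triangle distance, where the closest point
#' may fall on a face interior, an edge, or a vertex. Never greater than
#' the cloud-to-cloud distance to the reference vertices.
#'
#' @param compared a [trimesh()] or point cloud.
#' @param reference a [trimesh()] with at least one face.
#' @return An object of class `"distance_field"` with `mode = "C2M"`.
#' @export
c2m <- function(compared, reference) {
  cmp <- as_point_cloud(compared)
  if (!inherits(reference, "trimesh") || n_faces(reference) == 0L) {
    stop("C2M needs a reference mesh with at least one face", call. = FALSE)
  }
  v <- reference$vertices
  f <- reference$faces
  A <- v[f[, 1L], , drop = FALSE]
  B <- v[f[, 2L], , drop = FALSE]
  C <- v[f[, 3L], , drop = FALSE]
  m <- nrow(f)
  n <- nrow(cmp)
  # chunk points so the expanded point x triangle arrays stay ~2e6 rows
  chunk <- max(1L, floor(2e6 / m))
  d <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    d[rows] <- point_triangle_min(cmp[rows, , drop = FALSE], A, B, C)
  }
  new_distance_field(d, "C2M", compared, reference)
}

# Minimum point-to-triangle distance per point, vectorised over all
# point x triangle pairs (closest-point region classification).
point_triangle_min <- function(P, A, B, C) {
  np <- nrow(P); m <- nrow(A)
  pi <- rep(seq_len(np), each = m)
  ti <- rep(seq_len(m), times = np)
  p <- P[pi, , drop = FALSE]
  a <- A[ti, , drop = FALSE]
  b <- B[ti, , drop = FALSE]
  c2 <- C[ti, , drop = FALSE]
  ab <- b - a; ac <- c2 - a; ap <- p - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- p - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- p - c2
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4

  q <- matrix(NA_real_, length(pi), 3L)
  todo <- rep(TRUE, length(pi))
  claim <- function(cond) {
    got <- todo & cond
    todo[got] <<- FALSE
    got
  }
  r1 <- claim(d1 <= 0 & d2 <= 0)                      # vertex A
  q[r1, ] <- a[r1, , drop = FALSE]
  r2 <- claim(d3 >= 0 & d4 <= d3)                     # vertex B
  q[r2, ] <- b[r2, , drop = FALSE]
  r3 <- claim(vc <= 0 & d1 >= 0 & d3 <= 0)            # edge AB
  t3 <- d1[r3] / (d1[r3] - d3[r3])
  q[r3, ] <- a[r3, , drop = FALSE] + t3 * ab[r3, , drop = FALSE]
  r4 <- claim(d6 >= 0 & d5 <= d6)                     # vertex C
  q[r4, ] <- c2[r4, , drop = FALSE]
  r5 <- claim(vb <= 0 & d2 >= 0 & d6 <= 0)            # edge AC
  t5 <- d2[r5] / (d2[r5] - d6[r5])
  q[r5, ] <- a[r5, , drop = FALSE] + t5 * ac[r5, , drop = FALSE]
  r6 <- claim(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0)  # edge BC
  t6 <- (d4[r6] - d3[r6]) / ((d4[r6] - d3[r6]) + (d5[r6] - d6[r6]))
  q[r6, ] <- b[r6, , drop = FALSE] +
    t6 * (c2[r6, , drop = FALSE] - b[r6, , drop = FALSE])
  r7 <- claim(rep(TRUE, length(pi)))                  # face interior
  denom <- va[r7] + vb[r7] + vc[r7]
  denom[denom == 0] <- .Machine$double.eps
  vpar <- vb[r7] / denom
  wpar <- vc[r7] / denom
  q[r7, ] <- a[r7, , drop = FALSE] + vpar * ab[r7, , drop = FALSE] +
    wpar * ac[r7, , drop = FALSE]

  d2all <- rowSums((p - q)^2)
  # safety net for degenerate (zero-area) triangles
  bad <- !is.finite(d2all)
  if (any(bad)) {
    d2all[bad] <- pmin(rowSums((p - a)^2), rowSums((p - b)^2),
                       rowSums((p - c2)^2))[bad]
  }
  sqrt(apply(matrix(d2all, nrow = m), 2L, min))
}

new_distance_field <- function(distances, mode, compared, reference) {
  if (any(!is.finite(distances)) || any(distances < 0)) {
    stop("distance field must be finite and non-negative", call. = FALSE)
  }
  id_of <- function(x) {
    if (inherits(x, "trimesh") && !is.null(x$id)) x$id else "cloud"
  }
  structure(
    list(distances = as.numeric(distances), mode = mode,
         n = length(distances), compared_id = id_of(compared),
         reference_id = id_of(reference)),
    class = "distance_field"
  )
}

#' @export
print.distance_field <- function(x, ...) {
  cat(sprintf("%s distance field: %d values ('%s' vs '%s')\n", x$mode, x$n,
              x$compared_id, x$reference_id))
  s <- field_summary(x)
  cat(sprintf("  MD = %.4f, SD = %.4f, range [%.4f, %.4f]\n",
              s$mean, s$sd, s$min, s$max))
  invisible(x)
}

#' Summary statistics of a distance field
#'
#' Mean distance (MD), standard deviation (SD, sample `n - 1`
#' denominator), minimum, maximum, and count. Lower MD and SD indicate
#' greater overall similarity between the compared surfaces. The maximum
#' doubles as the directed Hausdorff distance of the compared cloud from
#' the reference.
#'
#' @param field a `distance_field` (from [c2c()] or [c2m()]).
#' @return An object of class `"field_summary"`.
#' @export
field_summary <- function(field) {
  stopifnot(inherits(field, "distance_field"))
  d <- field$distances
  if (length(d) < 1L) stop("empty distance field", call. = FALSE)
  structure(
    list(mean = mean(d),
         sd = if (length(d) > 1L) stats::sd(d) else 0,
         min = min(d), max = max(d), n = length(d),
         directed_hausdorff = max(d),
         sd_denominator = "sample (n-1)",
         mode = field$mode),
    class = "field_summary"
  )
}

#' @export
summary.distance_field <- function(object, ...) field_summary(object)

#' @export
print.field_summary <- function(x, ...) {
  cat(sprintf("%s summary (n = %d):\n", x$mode, x$n))
  cat(sprintf("  MD = %.6f, SD = %.6f (%s)\n", x$mean, x$sd,
              x$sd_denominator))
  cat(sprintf("  range [%.6f, %.6f]; directed Hausdorff = %.6f\n",
              x$min, x$max, x$directed_hausdorff))
  invisible(x)
}

#' Histogram of a distance field
#'
#' Equal-width bins over `[0, max(distances)]` (the conventional display
#' of absolute distance distributions); the rightmost bin is closed so the
#' counts always sum to `n`.
#'
#' @param field a `distance_field`.
#' @param bins number of bins (default 256).
#' @return A list with `edges` (length `bins + 1`), `counts` (length
#'   `bins`), and `mids`.
#' @export
field_histogram <- function(field, bins = 256L) {
  stopifnot(inherits(field, "distance_field"))
  bins <- as.integer(bins)
  if (bins < 1L) stop("bins must be >= 1", call. = FALSE)
  d <- field$distances
  upper <- max(d)
  if (upper <= 0) upper <- 1
  edges <- seq(0, upper, length.out = bins + 1L)
  bin <- findInterval(d, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = bins)
  list(edges = edges, counts = counts,
       mids = (edges[-1L] + edges[-(bins + 1L)]) / 2)
}

#' Heat-map colors for a distance field
#'
#' Maps distances monotonically onto a cold-to-warm ramp
#' (blue, green, yellow, red): zero distance is the cold end (close
#' match), `saturation_max` and above is the warm end (strong variation).
#'
#' @param field a `distance_field`.
#' @param saturation_max distance mapped to the warm end; defaults to the
#'   field maximum.
#' @return A list with `rgb` (`n x 3` integer matrix, 0..255) and `hex`
#'   (character vector), suitable for attaching to the compared mesh via
#'   the `color` field and exporting to PLY.
#' @export
heatmap_colors <- function(field, saturation_max = NULL) {
  stopifnot(inherits(field, "distance_field"))
  if (is.null(saturation_max)) saturation_max <- max(field$distances)
  if (saturation_max <= 0) saturation_max <- 1
  t <- pmin(pmax(field$distances / saturation_max, 0), 1)
  ramp <- grDevices::colorRamp(c("#0000FF", "#00FF00", "#FFFF00",
                                 "#FF0000"))
  rgbm <- round(ramp(t))
  storage.mode(rgbm) <- "integer"
  colnames(rgbm) <- c("red", "green", "blue")
  list(rgb = rgbm,
       hex = grDevices::rgb(rgbm[, 1L], rgbm[, 2L], rgbm[, 3L],
                            maxColorValue = 255))
}

#' Full pairwise comparison of a target mesh against a reference
#'
#' Orchestrates the comparison workflow: optional landmark-based first
#' registration of the target onto the reference, optional ICP fine
#' alignment ("second registration"), then the absolute distance field
#' (C2M or C2C) of the aligned target's vertices against the reference,
#' with summary statistics. When ICP is on, the summary of the
#' landmark-only alignment is also recorded, so the effect of the fine
#' alignment can be judged.
#'
#' @param target the compared [trimesh()] (its vertices receive distance
#'   values).
#' @param reference the reference [trimesh()].
#' @param mode `"c2m"` (distances to the reference surface) or `"c2c"`
#'   (distances to the reference vertices).
#' @param icp run the ICP fine alignment (default `TRUE`).
#' @param landmarks_target,landmarks_reference optional paired
#'   [landmark_set()]s seeding the first registration; identity initial
#'   alignment if omitted.
#' @param max_iterations,with_scale,keep_fraction passed to [icp_align()].
#' @return An object of class `"pairwise_comparison"`: `field`, `summary`,
#'   `pre_icp_summary` (when ICP ran), `icp` (the [icp_align()] result or
#'   `NULL`), `transform` (final cumulative alignment), `mode`, and the
#'   aligned target mesh (`aligned_target`).
#' @export
pairwise_compare <- function(target, reference, mode = c("c2m", "c2c"),
                             icp = TRUE, landmarks_target = NULL,
                             landmarks_reference = NULL,
                             max_iterations = 20L, with_scale = TRUE,
                             keep_fraction = 1) {
  stopifnot(inherits(target, "trimesh"), inherits(reference, "trimesh"))
  mode <- match.arg(mode)
  init <- if (!is.null(landmarks_target) && !is.null(landmarks_reference)) {
    landmark_similarity(landmarks_target, landmarks_reference,
                        with_scale = with_scale)
  } else {
    similarity_transform()
  }
  dist_to <- function(aligned) {
    if (mode == "c2m") c2m(aligned, reference) else c2c(aligned, reference)
  }
  transform <- init
  icp_res <- NULL
  pre_icp_summary <- NULL
  if (icp) {
    pre_icp_summary <- field_summary(dist_to(apply_transform(target, init)))
    icp_res <- icp_align(target, reference, max_iterations = max_iterations,
                         with_scale = with_scale, initial = init,
                         keep_fraction = keep_fraction)
    transform <- icp_res$transform
  }
  aligned <- apply_transform(target, transform)
  field <- dist_to(aligned)
  structure(
    list(field = field, summary = field_summary(field),
         pre_icp_summary = pre_icp_summary, icp = icp_res,
         transform = transform, mode = toupper(mode),
         aligned_target = aligned),
    class = "pairwise_comparison"
  )
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Pairwise comparison (%s%s): n = %d distance values\n",
              x$mode, if (is.null(x$icp)) ", no ICP" else " + ICP", s$n))
  if (!is.null(x$pre_icp_summary)) {
    p <- x$pre_icp_summary
    cat(sprintf("  before ICP: MD = %.6f, SD = %.6f, range [%.4f, %.4f]\n",
                p$mean, p$sd, p$min, p$max))
  }
  cat(sprintf("  %s MD = %.6f, SD = %.6f, range [%.4f, %.4f]\n",
              if (is.null(x$icp)) "" else "after ICP:", s$mean, s$sd,
              s$min, s$max))
  invisible(x)
}

#' @export
summary.pairwise_comparison <- function(object, ...) object$summary

#' @export
plot.pairwise_comparison <- function(x, bins = 64L, ...) {
  h <- field_histogram(x$field, bins = bins)
  graphics::barplot(h$counts, names.arg = NULL, space = 0, border = NA,
                    col = heatmap_colors(x$field)$hex[1L],
                    xlab = "absolute distance", ylab = "count",
                    main = sprintf("%s distance distribution", x$mode), ...)
  invisible(x)
}
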