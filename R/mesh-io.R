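#' Read a triangle mesh from OBJ, PLY, or STL
#'
#' The format is inferred from the file extension unless given explicitly.
#' Dialect rules:
#' * **OBJ**: `v` and `f` records; face indices are 1-based on disk and kept
#'   1-based internally; texture/normal references in `f` records
#'   (`f 1/1/1 ...`) are dropped; polygonal faces are fan-triangulated.
#' * **PLY**: `ascii` and `binary_little_endian`; `uchar` RGB vertex colors
#'   are read when present.
#' * **STL**: binary and ascii; STL stores independent triangles, so
#'   exactly coincident vertices are welded on read (counts reported via
#'   `message`).
#'
#' @param path file path.
#' @param format one of `"obj"`, `"ply"`, `"stl"`, or `NULL` to infer from
#'   the extension.
#' @return A validated [trimesh()], with `id` set to the file base name.
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read mesh file: %s", path), call. = FALSE)
  }
  format <- infer_format(path, format)
  mesh <- switch(format,
    obj = read_obj(path),
    ply = read_ply(path),
    stl = read_stl(path),
    stop(sprintf("unsupported mesh format '%s'", format), call. = FALSE)
  )
  mesh$id <- sub("\\.[^.]*$", "", basename(path))
  mesh
}

#' Write a triangle mesh to OBJ, PLY (ascii), or STL (ascii)
#'
#' Coordinates are written with 9 significant digits, enough to round-trip
#' the geometry at single-scan precision. Per-vertex colors are written for
#' PLY (8-bit RGB); OBJ and STL carry geometry only and a warning is issued
#' if colors would be lost.
#'
#' @param mesh a [trimesh()].
#' @param path output file path.
#' @param format one of `"obj"`, `"ply"`, `"stl"`, or `NULL` to infer.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "trimesh"))
  format <- infer_format(path, format)
  switch(format,
    obj = write_obj(mesh, path),
    ply = write_ply(mesh, path),
    stl = write_stl(mesh, path),
    stop(sprintf("unsupported mesh format '%s'", format), call. = FALSE)
  )
  invisible(path)
}

infer_format <- function(path, format) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- tolower(format)
  if (!format %in% c("obj", "ply", "stl")) {
    stop(sprintf("unsupported mesh format '%s' (use obj, ply, or stl)",
                 format), call. = FALSE)
  }
  format
}

## ---- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tl <- trimws(lines)
  v_idx <- which(startsWith(tl, "v "))
  f_idx <- which(startsWith(tl, "f "))
  if (length(v_idx) == 0L) {
    stop(sprintf("empty mesh: no vertex records in %s", path), call. = FALSE)
  }
  verts <- matrix(NA_real_, length(v_idx), 3L)
  for (i in seq_along(v_idx)) {
    tok <- strsplit(tl[v_idx[i]], "[[:space:]]+")[[1L]]
    if (length(tok) < 4L) {
      stop(sprintf("line %d: vertex record needs 3 coordinates", v_idx[i]),
           call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(tok[2L:4L]))
    if (anyNA(xyz)) {
      stop(sprintf("line %d: non-numeric vertex coordinate", v_idx[i]),
           call. = FALSE)
    }
    verts[i, ] <- xyz
  }
  nv <- nrow(verts)
  face_list <- vector("list", length(f_idx))
  for (i in seq_along(f_idx)) {
    tok <- strsplit(tl[f_idx[i]], "[[:space:]]+")[[1L]][-1L]
    # keep the vertex reference, drop /texture/normal refs
    idx <- suppressWarnings(as.integer(sub("/.*$", "", tok)))
    if (anyNA(idx) || length(idx) < 3L) {
      stop(sprintf("line %d: malformed face record", f_idx[i]),
           call. = FALSE)
    }
    if (any(idx < 0L)) {
      stop(sprintf("line %d: negative (relative) face indices not supported",
                   f_idx[i]), call. = FALSE)
    }
    if (any(idx < 1L | idx > nv)) {
      stop(sprintf("line %d: face index out of range [1, %d]", f_idx[i], nv),
           call. = FALSE)
    }
    face_list[[i]] <- fan_triangulate(idx)
  }
  faces <- if (length(face_list)) do.call(rbind, face_list)
  else matrix(integer(0), ncol = 3L)
  trimesh(verts, faces)
}

fan_triangulate <- function(idx) {
  k <- length(idx)
  if (k == 3L) return(matrix(idx, ncol = 3L))
  cbind(idx[1L], idx[2L:(k - 1L)], idx[3L:k])
}

write_obj <- function(mesh, path) {
  if (!is.null(mesh$color)) {
    warning("OBJ carries geometry only; per-vertex colors not written",
            call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# OBJ exported by pairwise3d", con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  if (n_faces(mesh) > 0L) {
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L],
                       mesh$faces[, 3L]), con)
  }
}

## ---- PLY ----

ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type) {
  switch(type,
    char = , int8 = readBin(con, "integer", 1L, size = 1L, signed = TRUE,
                            endian = "little"),
    uchar = , uint8 = readBin(con, "integer", 1L, size = 1L, signed = FALSE,
                              endian = "little"),
    short = , int16 = readBin(con, "integer", 1L, size = 2L, signed = TRUE,
                              endian = "little"),
    ushort = , uint16 = readBin(con, "integer", 1L, size = 2L,
                                signed = FALSE, endian = "little"),
    int = , int32 = , uint = , uint32 =
      readBin(con, "integer", 1L, size = 4L, endian = "little"),
    float = , float32 = readBin(con, "double", 1L, size = 4L,
                                endian = "little"),
    double = , float64 = readBin(con, "double", 1L, size = 8L,
                                 endian = "little"),
    stop(sprintf("unsupported PLY property type '%s'", type), call. = FALSE)
  )
}

parse_ply_header <- function(con) {
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) {
    stop("not a PLY file (missing 'ply' magic)", call. = FALSE)
  }
  fmt <- NULL
  elements <- list()
  cur <- NULL
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("truncated PLY header", call. = FALSE)
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    if (length(tok) == 0L || tok[1L] == "comment") next
    if (tok[1L] == "format") {
      fmt <- tok[2L]
    } else if (tok[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2L], count = as.integer(tok[3L]),
                  props = list())
    } else if (tok[1L] == "property") {
      if (is.null(cur)) stop("PLY property outside element", call. = FALSE)
      p <- if (tok[2L] == "list") {
        list(name = tok[5L], list = TRUE, count_type = tok[3L],
             value_type = tok[4L])
      } else {
        list(name = tok[3L], list = FALSE, type = tok[2L])
      }
      cur$props[[p$name]] <- p
    } else if (tok[1L] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian")) {
    stop(sprintf("unsupported PLY format '%s'", fmt %||% "<missing>"),
         call. = FALSE)
  }
  list(format = fmt, elements = elements)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- parse_ply_header(con)
  ve <- hdr$elements[["vertex"]]
  fe <- hdr$elements[["face"]]
  if (is.null(ve) || ve$count < 1L) {
    stop("empty mesh: PLY has no vertices", call. = FALSE)
  }
  pnames <- names(ve$props)
  if (!all(c("x", "y", "z") %in% pnames)) {
    stop("PLY vertex element lacks x/y/z properties", call. = FALSE)
  }
  has_rgb <- all(c("red", "green", "blue") %in% pnames)

  if (hdr$format == "ascii") {
    rest <- readLines(con, warn = FALSE)
    rest <- rest[nzchar(trimws(rest))]
    if (length(rest) < ve$count + (fe$count %||% 0L)) {
      stop("truncated PLY body", call. = FALSE)
    }
    vtok <- strsplit(trimws(rest[seq_len(ve$count)]), "[[:space:]]+")
    np <- length(pnames)
    vmat <- t(vapply(vtok, function(tk) {
      if (length(tk) < np) stop("truncated PLY vertex record", call. = FALSE)
      suppressWarnings(as.numeric(tk[seq_len(np)]))
    }, numeric(np)))
    if (anyNA(vmat)) stop("non-numeric PLY vertex data", call. = FALSE)
    colnames(vmat) <- pnames
    verts <- vmat[, c("x", "y", "z"), drop = FALSE]
    color <- if (has_rgb) vmat[, c("red", "green", "blue"), drop = FALSE]
    faces <- NULL
    if (!is.null(fe) && fe$count > 0L) {
      ftok <- strsplit(trimws(rest[ve$count + seq_len(fe$count)]),
                       "[[:space:]]+")
      face_list <- lapply(seq_along(ftok), function(i) {
        tk <- suppressWarnings(as.integer(ftok[[i]]))
        if (anyNA(tk) || length(tk) < 1L || length(tk) < 1L + tk[1L]) {
          stop(sprintf("malformed PLY face record %d", i), call. = FALSE)
        }
        fan_triangulate(tk[1L + seq_len(tk[1L])] + 1L)  # 0-based on disk
      })
      faces <- do.call(rbind, face_list)
    }
  } else {
    verts <- matrix(NA_real_, ve$count, 3L)
    color <- if (has_rgb) matrix(NA_integer_, ve$count, 3L)
    for (i in seq_len(ve$count)) {
      for (p in ve$props) {
        if (p$list) stop("list property on PLY vertex unsupported",
                         call. = FALSE)
        val <- ply_read_scalar(con, p$type)
        if (length(val) == 0L) stop("truncated PLY body", call. = FALSE)
        if (p$name == "x") verts[i, 1L] <- val
        else if (p$name == "y") verts[i, 2L] <- val
        else if (p$name == "z") verts[i, 3L] <- val
        else if (has_rgb && p$name == "red") color[i, 1L] <- val
        else if (has_rgb && p$name == "green") color[i, 2L] <- val
        else if (has_rgb && p$name == "blue") color[i, 3L] <- val
      }
    }
    faces <- NULL
    if (!is.null(fe) && fe$count > 0L) {
      lp <- Filter(function(p) p$list, fe$props)
      if (length(lp) != 1L) {
        stop("PLY face element needs exactly one list property",
             call. = FALSE)
      }
      lp <- lp[[1L]]
      face_list <- vector("list", fe$count)
      for (i in seq_len(fe$count)) {
        k <- ply_read_scalar(con, lp$count_type)
        if (length(k) == 0L || is.na(k) || k < 3L) {
          stop(sprintf("malformed PLY face record %d", i), call. = FALSE)
        }
        idx <- integer(k)
        for (j in seq_len(k)) {
          v <- ply_read_scalar(con, lp$value_type)
          if (length(v) == 0L) stop("truncated PLY body", call. = FALSE)
          idx[j] <- v
        }
        face_list[[i]] <- fan_triangulate(idx + 1L)
      }
      faces <- do.call(rbind, face_list)
    }
  }
  trimesh(verts, faces, color = color)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  has_rgb <- !is.null(mesh$color)
  hdr <- c(
    "ply", "format ascii 1.0", "comment exported by pairwise3d",
    sprintf("element vertex %d", n_vertices(mesh)),
    "property double x", "property double y", "property double z",
    if (has_rgb) c("property uchar red", "property uchar green",
                   "property uchar blue"),
    sprintf("element face %d", n_faces(mesh)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  writeLines(hdr, con)
  v <- mesh$vertices
  if (has_rgb) {
    writeLines(sprintf("%.9g %.9g %.9g %d %d %d", v[, 1L], v[, 2L], v[, 3L],
                       mesh$color[, 1L], mesh$color[, 2L], mesh$color[, 3L]),
               con)
  } else {
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]), con)
  }
  if (n_faces(mesh) > 0L) {
    f <- mesh$faces - 1L  # 0-based on disk
    writeLines(sprintf("3 %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
  }
}

## ---- STL ----

read_stl <- function(path) {
  sz <- file.size(path)
  is_binary <- FALSE
  if (sz >= 84L) {
    con <- file(path, "rb")
    invisible(readBin(con, "raw", 80L))
    ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    close(con)
    if (length(ntri) == 1L && !is.na(ntri) && sz == 84 + 50 * ntri) {
      is_binary <- TRUE
    }
  }
  tris <- if (is_binary) read_stl_binary(path) else read_stl_ascii(path)
  if (nrow(tris) == 0L) {
    stop(sprintf("empty mesh: no facets in %s", path), call. = FALSE)
  }
  weld_triangles(tris)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80L))
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  # each facet: normal (3 floats) + 3 vertices (9 floats) + 2 attribute bytes
  tris <- matrix(NA_real_, 3L * ntri, 3L)
  for (i in seq_len(ntri)) {
    vals <- readBin(con, "double", 12L, size = 4L, endian = "little")
    attr_bytes <- readBin(con, "raw", 2L)
    if (length(vals) < 12L || length(attr_bytes) < 2L) {
      stop("truncated binary STL", call. = FALSE)
    }
    tris[(3L * i - 2L):(3L * i), ] <- matrix(vals[4L:12L], 3L, 3L,
                                             byrow = TRUE)
  }
  tris
}

read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- lines[startsWith(lines, "vertex")]
  if (length(vl) %% 3L != 0L) {
    stop("malformed ascii STL: vertex count not a multiple of 3",
         call. = FALSE)
  }
  if (length(vl) == 0L) return(matrix(numeric(0), ncol = 3L))
  vals <- t(vapply(strsplit(vl, "[[:space:]]+"), function(tk) {
    xyz <- suppressWarnings(as.numeric(tk[2L:4L]))
    if (anyNA(xyz)) stop("non-numeric STL vertex", call. = FALSE)
    xyz
  }, numeric(3L)))
  vals
}

# STL facets are independent triangles; weld exact coordinate duplicates.
weld_triangles <- function(tris) {
  key <- paste(tris[, 1L], tris[, 2L], tris[, 3L], sep = "|")
  first <- !duplicated(key)
  verts <- tris[first, , drop = FALSE]
  idx <- match(key, key[first])
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  message(sprintf("STL read: welded %d facet corners into %d unique vertices",
                  nrow(tris), nrow(verts)))
  trimesh(verts, faces)
}

write_stl <- function(mesh, path) {
  if (!is.null(mesh$color)) {
    warning("STL carries geometry only; per-vertex colors not written",
            call. = FALSE)
  }
  if (n_faces(mesh) == 0L) {
    stop("cannot write STL: mesh has no faces", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid pairwise3d", con)
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  nrm <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
               e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
               e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  for (i in seq_len(nrow(f))) {
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1L], nrm[i, 2L],
              nrm[i, 3L]),
      "    outer loop",
      sprintf("      vertex %.9g %.9g %.9g",
              v[f[i, ], 1L], v[f[i, ], 2L], v[f[i, ], 3L]),
      "    endloop",
      "  endfacet"
    ), con)
  }
  writeLines("endsolid pairwise3d", con)
}
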