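test_that("minimal OBJ parses with 1-based indices converted and texture refs dropped", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3"), path)
  m <- read_mesh(path)
  expect_equal(n_vertices(m), 3L)
  expect_equal(m$faces, matrix(c(1L, 2L, 3L), 1L))
  expect_equal(m$vertices[2L, ], c(1, 0, 0))

  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1/1/1 2/2/2 3/3/3"), path)
  m2 <- read_mesh(path)
  expect_equal(m2$faces, matrix(c(1L, 2L, 3L), 1L))
})

test_that("OBJ validation errors name the offending line", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 9"), path)
  expect_error(read_mesh(path), "line 4.*out of range")
  writeLines(c("# just a comment"), path)
  expect_error(read_mesh(path), "empty mesh")
  expect_error(read_mesh(tempfile(fileext = ".obj")), "cannot read")
})

test_that("meshes round-trip through OBJ, PLY, and STL", {
  set.seed(41)
  for (rep in 1:4) {
    m <- random_mesh(25L, 30L)
    for (fmt in c("obj", "ply")) {
      path <- withr::local_tempfile(fileext = paste0(".", fmt))
      write_mesh(m, path)
      back <- read_mesh(path)
      expect_equal(back$vertices, m$vertices, tolerance = 1e-8)
      expect_identical(back$faces, m$faces)
    }
  }
  # STL: connectivity is rebuilt by exact welding, so compare geometry
  sph <- icosphere(1L)
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(sph, path)
  back <- suppressMessages(read_mesh(path))
  expect_equal(n_faces(back), n_faces(sph))
  expect_equal(n_vertices(back), n_vertices(sph))
  expect_equal(sort(round(as.vector(back$vertices), 6L)),
               sort(round(as.vector(sph$vertices), 6L)))
})

test_that("a 642-vertex icosphere survives an OBJ round trip exactly", {
  sph <- icosphere(3L)
  expect_equal(n_vertices(sph), 642L)
  path <- withr::local_tempfile(fileext = ".obj")
  write_mesh(sph, path)
  back <- read_mesh(path)
  expect_equal(back$vertices, sph$vertices, tolerance = 1e-8)
  expect_identical(back$faces, sph$faces)
})

test_that("PLY colors round-trip within 8-bit quantisation; OBJ warns and drops them", {
  m <- unit_triangle()
  m$color <- rbind(c(255L, 0L, 10L), c(0L, 128L, 255L), c(17L, 200L, 3L))
  ply <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, ply)
  back <- read_mesh(ply)
  expect_true(max(abs(back$color - m$color)) <= 1L)
  obj <- withr::local_tempfile(fileext = ".obj")
  expect_warning(write_mesh(m, obj), "colors not written")
  expect_null(read_mesh(obj)$color)
})

test_that("binary little-endian PLY with uchar RGB reads correctly", {
  path <- withr::local_tempfile(fileext = ".ply")
  con <- file(path, "wb")
  writChar <- function(s) {
    writeChar(paste0(paste(s, collapse = "\n"), "\n"), con, eos = NULL)
  }
  writChar(c("ply", "format binary_little_endian 1.0",
             "element vertex 3",
             "property float x", "property float y", "property float z",
             "property uchar red", "property uchar green",
             "property uchar blue",
             "element face 1",
             "property list uchar int vertex_indices",
             "end_header"))
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  cols <- rbind(c(250L, 1L, 2L), c(3L, 4L, 5L), c(6L, 7L, 8L))
  for (i in 1:3) {
    writeBin(verts[i, ], con, size = 4L, endian = "little")
    writeBin(as.raw(cols[i, ]), con)
  }
  writeBin(as.raw(3L), con)
  writeBin(c(0L, 1L, 2L), con, size = 4L, endian = "little")
  close(con)
  m <- read_mesh(path)
  expect_equal(m$vertices, verts, tolerance = 1e-6)
  expect_equal(unname(m$color), cols)
  expect_equal(m$faces, matrix(1:3, 1L))
})

test_that("STL read welds exactly coincident vertices", {
  # two triangles sharing an edge: 6 facet corners, 4 unique vertices
  m <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
               rbind(c(1L, 2L, 3L), c(2L, 4L, 3L)))
  path <- withr::local_tempfile(fileext = ".stl")
  write_mesh(m, path)
  expect_message(back <- read_mesh(path), "welded 6 facet corners into 4")
  expect_equal(n_vertices(back), 4L)
  expect_equal(n_faces(back), 2L)
})

test_that("degenerate faces are dropped with a count, not fatal", {
  expect_warning(
    m <- trimesh(diag(3), rbind(c(1L, 2L, 3L), c(1L, 1L, 2L))),
    "1 degenerate face"
  )
  expect_equal(n_faces(m), 1L)
})

test_that("corrupt and truncated mesh files raise typed errors, never crash", {
  cases <- list(
    c("v 0 0 0", "v 1 0 0", "f 1 2"),                 # short face
    c("v 0 0 x", "v 1 0 0", "v 0 1 0", "f 1 2 3"),    # bad coordinate
    c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 -3"),   # negative index
    c("ply", "format ascii 1.0", "element vertex 5",
      "property double x", "property double y", "property double z",
      "end_header", "0 0 0"),                         # truncated ply body
    c("ply", "format big_endian 1.0", "end_header"),  # bad ply format
    c("solid x", "vertex 0 0 0", "vertex 1 0 0", "endsolid x")  # stl 2 verts
  )
  exts <- c(".obj", ".obj", ".obj", ".ply", ".ply", ".stl")
  for (i in seq_along(cases)) {
    path <- withr::local_tempfile(fileext = exts[i])
    writeLines(cases[[i]], path)
    expect_error(read_mesh(path))
  }
})

test_that("mesh_to_cloud view is exactly the vertex set and survives face deletion", {
  m <- icosphere(1L)
  cloud <- as_point_cloud(m)
  expect_identical(cloud, m$vertices)
  # deleting faces while keeping all vertices leaves the cloud unchanged
  m2 <- m
  m2$faces <- m$faces[-(1:10), , drop = FALSE]
  expect_identical(as_point_cloud(m2), cloud)
})

test_that("landmark files parse, pair by order, and reject malformed input", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("tubercle 0 0 0", "groove_m, 1, 0, 0", "groove_l 0 1 0"),
             path)
  lm <- read_landmarks(path)
  expect_equal(lm$labels, c("tubercle", "groove_m", "groove_l"))
  expect_equal(lm$points[2L, ], c(1, 0, 0))

  writeLines(c("a 0 0 0", "b 1 0 0"), path)
  expect_error(read_landmarks(path), "at least 3 landmarks")
  writeLines(c("a 0 0 0", "b 1 0 Q", "c 0 1 0"), path)
  expect_error(read_landmarks(path), "line 2.*non-numeric")
  writeLines(c("a 0 0 0", "b 0 0 0", "c 0 1 0"), path)
  expect_error(read_landmarks(path), "coincide")

  lm2 <- landmark_set(diag(3), c("x", "y", "z"))
  out <- withr::local_tempfile(fileext = ".txt")
  write_landmarks(lm2, out)
  back <- read_landmarks(out)
  expect_equal(back$points, lm2$points)
  expect_equal(back$labels, lm2$labels)
})
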