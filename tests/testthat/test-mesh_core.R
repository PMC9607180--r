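# mesh container, STL/PLY I/O, closest-point queries, vertex normals

test_that("binary STL format arithmetic and roundtrip hold for a tetrahedron", {
  m <- unit_tetrahedron()
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, path, dialect = "binary")
  expect_identical(file.size(path), 84 + 4 * 50)  # 284 bytes for 4 facets
  back <- read_stl(path)
  expect_equal(nrow(back$faces), 4L)
  expect_equal(nrow(back$vertices), 4L)  # facet corners welded
  # same mesh up to vertex ordering: compare sorted coordinates
  expect_equal(back$vertices[order(back$vertices[, 1], back$vertices[, 2], back$vertices[, 3]), ],
               m$vertices[order(m$vertices[, 1], m$vertices[, 2], m$vertices[, 3]), ],
               tolerance = 1e-6)
})

test_that("ASCII and binary STL dialects parse to the same mesh", {
  m <- unit_tetrahedron()
  pb <- withr::local_tempfile(fileext = ".stl")
  pa <- withr::local_tempfile(fileext = ".stl")
  write_stl(m, pb, "binary")
  write_stl(m, pa, "ascii")
  mb <- read_stl(pb)
  ma <- read_stl(pa)
  ord <- function(v) v[order(v[, 1], v[, 2], v[, 3]), ]
  expect_equal(ord(ma$vertices), ord(mb$vertices), tolerance = 1e-6)
  expect_equal(nrow(ma$faces), nrow(mb$faces))
})

test_that("STL read/write/read is idempotent and bit-stable", {
  withr::local_seed(11)
  m <- random_soup(40)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  p3 <- withr::local_tempfile()
  write_stl(m, p1)
  m1 <- read_stl(p1)
  write_stl(m1, p2)
  m2 <- read_stl(p2)
  expect_equal(m1$vertices, m2$vertices)
  expect_equal(m1$faces, m2$faces)
  write_stl(m1, p3)
  expect_identical(readBin(p2, "raw", file.size(p2)),
                   readBin(p3, "raw", file.size(p3)))
})

test_that("STL errors are informative", {
  expect_error(write_stl(triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)),
                         tempfile()), "empty mesh")
  # truncated binary file
  m <- unit_tetrahedron()
  p <- withr::local_tempfile()
  write_stl(m, p)
  r <- readBin(p, "raw", 200)
  writeBin(r, p)
  expect_error(read_stl(p), "truncated.*facets")
  # malformed ascii: bad vertex line
  pa <- withr::local_tempfile()
  writeLines(c("solid x", "facet normal 0 0 1", "outer loop",
               "vertex 0 0 zero", "vertex 1 0 0", "vertex 0 1 0",
               "endloop", "endfacet", "endsolid x"), pa)
  expect_error(read_stl(pa), "line 4")
})

test_that("degenerate faces are dropped with a message", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_message(m <- triangle_mesh(v, rbind(c(1, 2, 3), c(1, 1, 2))),
                 "degenerate")
  expect_equal(nrow(m$faces), 1L)
})

test_that("closest_point handles the trivial geometric cases", {
  m <- unit_tetrahedron()
  # query exactly on a vertex
  r <- closest_point(c(0, 0, 1), m)
  expect_equal(r$distance, 0)
  # orthogonal projection onto a triangle interior in the z = 0 plane
  # (query below the tetrahedron, so the z = 0 face is the closest one)
  r <- closest_point(c(0.2, 0.2, -0.5), m)
  expect_equal(r$distance, 0.5)
  expect_equal(c(r$px, r$py, r$pz), c(0.2, 0.2, 0))
  expect_error(closest_point(c(0, 0, 0), triangle_mesh(matrix(0, 1, 3),
                                                       matrix(0L, 0, 3))),
               "no faces")
})

test_that("BVH closest_point equals brute-force on random meshes", {
  withr::local_seed(42)
  for (rep in 1:5) {
    m <- random_soup(sample(50:300, 1))
    q <- matrix(runif(3 * 100, -5, 15), ncol = 3)
    a <- closest_point(q, m, method = "bvh")
    b <- closest_point(q, m, method = "brute")
    expect_lt(max(abs(a$distance - b$distance)), 1e-9)
  }
})

test_that("closest_point distance is invariant under rigid motion", {
  withr::local_seed(7)
  m <- random_soup(80)
  q <- matrix(runif(30, -5, 15), ncol = 3)
  d0 <- closest_point(q, m)$distance
  for (i in 1:3) {
    tr <- random_transform()
    d1 <- closest_point(rt_apply(tr, q), rt_apply(tr, m))$distance
    expect_lt(max(abs(d1 - d0)), 1e-9)
  }
})

test_that("on_boundary flags closest points on open-boundary edges", {
  patch <- planar_patch(5, 10)
  # query beyond the patch edge projects onto the boundary
  r <- closest_point(c(15, 5, 2), patch)
  expect_true(r$on_boundary)
  # interior projection is not a boundary hit
  r <- closest_point(c(5.1, 5.1, 2), patch)
  expect_false(r$on_boundary)
})

test_that("vertex normals: planar patch, icosphere accuracy, winding flip", {
  patch <- planar_patch(4, 6)
  n <- vertex_normals(patch)
  expect_equal(n, matrix(rep(c(0, 0, 1), each = nrow(n)), ncol = 3))
  # flipping winding flips normals
  flipped <- triangle_mesh(patch$vertices, patch$faces[, c(1, 3, 2)])
  expect_equal(vertex_normals(flipped), -n)
  # icosphere (level 3 = 1280 faces): normal within 5 degrees of radial
  s <- icosphere(3)
  expect_equal(nrow(s$faces), 1280L)
  ns <- vertex_normals(s)
  radial <- s$vertices / sqrt(rowSums(s$vertices^2))
  ang <- acos(pmin(1, rowSums(ns * radial))) * 180 / pi
  expect_lt(max(ang), 5)
})

test_that("PLY export writes a parseable ASCII file with quality and color", {
  m <- unit_tetrahedron()
  p <- withr::local_tempfile(fileext = ".ply")
  write_ply(m, p, quality = c(0, 1, 2, 3), color = cbind(255L, 0L, 0L)[rep(1, 4), ])
  lines <- readLines(p)
  expect_equal(lines[1], "ply")
  expect_true("property float quality" %in% lines)
  nv <- as.integer(sub("element vertex ", "", grep("element vertex", lines, value = TRUE)))
  expect_equal(nv, 4L)
  expect_equal(length(lines), which(lines == "end_header") + 4 + 4)
})
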