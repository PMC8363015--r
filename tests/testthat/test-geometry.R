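# Mesh ingestion, validation, spatial indexing and ray/point queries.

test_that("STL round trips preserve geometry in both encodings", {
  tmp <- withr::local_tempdir()
  # one-triangle ASCII file written by hand
  p1 <- file.path(tmp, "tri.stl")
  writeLines(c("solid tri",
               "  facet normal 0 0 1", "    outer loop",
               "      vertex 0 0 0", "      vertex 1 0 0", "      vertex 0 1 0",
               "    endloop", "  endfacet", "endsolid tri"), p1)
  m <- read_stl(p1)
  expect_equal(nrow(m$vertices), 3L)
  expect_equal(nrow(m$faces), 1L)

  # binary: icosphere at geodesic frequency 2 has 80 faces and, being a
  # closed triangulation, V = F/2 + 2 = 42 unique vertices after dedup
  ico <- geodesic_sphere(2L, 10)
  expect_equal(nrow(ico$faces), 80L)
  p2 <- file.path(tmp, "ico.stl")
  write_stl(ico, p2)
  ico2 <- read_stl(p2)
  expect_equal(nrow(ico2$vertices), 42L)
  expect_equal(nrow(ico2$faces), 80L)
  # same triangle soup within float32 precision
  soup <- function(m) m$vertices[t(m$faces), ]
  expect_equal(soup(ico2), soup(ico), tolerance = 1e-6)
  # a second round trip is exact (canonical order reached)
  p3 <- file.path(tmp, "ico3.stl")
  write_stl(ico2, p3)
  ico3 <- read_stl(p3)
  expect_identical(ico3$faces, ico2$faces)
  expect_equal(ico3$vertices, ico2$vertices, tolerance = 1e-12)
  # import scale factor
  expect_equal(read_stl(p2, scale = 2)$vertices, ico2$vertices * 2,
               tolerance = 1e-12)
})

test_that("malformed and empty STL files raise parse errors", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "bad.stl")
  writeLines(c("solid x", "  facet", "    vertex 0 0", "endsolid"), p)
  expect_error(read_stl(p), "malformed|vertex")
  expect_error(read_stl(file.path(tmp, "missing.stl")), "not found")
})

test_that("validate_mesh reports watertightness, orientation and volume", {
  ico <- geodesic_sphere(4L, 50)
  v <- validate_mesh(ico)
  expect_true(v$watertight)
  expect_true(v$oriented)
  expect_true(v$outward)
  # faceted sphere volume within 5% of (4/3) pi r^3
  expect_equal(v$signed_volume_um3, 4 / 3 * pi * 50^3, tolerance = 0.05)

  holed <- ico
  holed$faces <- holed$faces[-1, , drop = FALSE]
  expect_false(validate_mesh(holed)$watertight)

  flipped <- ico
  flipped$faces <- flipped$faces[, c(1, 3, 2)]
  expect_lt(validate_mesh(flipped)$signed_volume_um3, 0)

  # idempotent and side-effect free
  v2 <- validate_mesh(ico)
  expect_identical(v$watertight, v2$watertight)
  expect_identical(v$signed_volume_um3, v2$signed_volume_um3)
})

test_that("octree covers all triangles and degenerate queries behave", {
  expect_error(build_octree(list()), "at least")
  tri <- unit_triangle_mesh()
  idx1 <- build_octree(tri)
  expect_identical(octree_query(idx1, c(-1, -1, -1), c(2, 2, 2)), 1L)

  ico <- geodesic_sphere(8L, 40)   # 1280 triangles
  idx <- build_octree(ico, leaf_capacity = 32)
  # every triangle retrievable by querying its own bounding box
  f <- ico$faces; v <- ico$vertices
  missed <- 0L
  for (t in seq_len(nrow(f))) {
    tv <- v[f[t, ], , drop = FALSE]
    got <- octree_query(idx, apply(tv, 2, min), apply(tv, 2, max))
    if (!(t %in% got)) missed <- missed + 1L
  }
  expect_identical(missed, 0L)
  # box outside the root bounds
  expect_length(octree_query(idx, c(500, 500, 500), c(600, 600, 600)), 0L)
})

test_that("ray-triangle intersection matches the analytic oracle", {
  tri <- unit_triangle_mesh()
  idx <- build_octree(tri)
  h <- intersect_ray(c(1 / 3, 1 / 3, -1), c(0, 0, 1), idx)
  expect_equal(h$t, 1)
  expect_equal(c(h$w, h$u, h$v), rep(1 / 3, 3), tolerance = 1e-12)
  # ray parallel to the triangle plane
  h2 <- intersect_ray(c(0.2, 0.2, 1), c(1, 0, 0), idx)
  expect_true(is.na(h2$t))
  # direction must be unit length
  expect_error(intersect_ray(c(0, 0, -1), c(0, 0, 2), idx), "unit")
})

test_that("octree-accelerated intersection equals brute force on random rays", {
  ico <- geodesic_sphere(5L, 30)   # 500 triangles
  expect_equal(nrow(ico$faces), 500L)
  idx <- build_octree(ico)
  set.seed(42)
  n <- 1000
  o <- matrix(rnorm(n * 3, sd = 60), ncol = 3)
  # aim at scattered interior points so a good share of rays hit the mesh
  tgt <- matrix(rnorm(n * 3, sd = 15), ncol = 3)
  d <- tgt - o
  d <- d / sqrt(rowSums(d^2))
  h_oct <- intersect_ray(o, d, idx)
  h_bru <- intersect_ray(o, d, idx, brute = TRUE)
  expect_identical(h_oct$face, h_bru$face)
  expect_equal(h_oct$t, h_bru$t, tolerance = 0)
  expect_gt(sum(!is.na(h_oct$t)), 100)   # the comparison actually saw hits
})

test_that("point_in_volume agrees with analytic cube containment", {
  cube <- cube_mesh(1)
  expect_true(validate_mesh(cube)$watertight)
  set.seed(7)
  p <- matrix(runif(1e4 * 3, -2, 2), ncol = 3)
  # keep points away from the boundary where the answer is ill-posed
  off <- apply(abs(abs(p) - 1), 1, min) > 1e-6
  p <- p[off, , drop = FALSE]
  truth <- apply(abs(p) < 1, 1, all)
  expect_identical(point_in_volume(p, cube), truth)
  # boundary tie rule: on-surface points count as inside
  expect_true(point_in_volume(c(1, 0, 0), cube))
  # sphere sanity
  ico <- geodesic_sphere(4L, 50)
  expect_true(point_in_volume(c(0, 0, 0), ico))
  expect_false(point_in_volume(c(100, 0, 0), ico))
  expect_error(point_in_volume(c(0, 0, 0), unit_triangle_mesh()), "watertight")
})
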