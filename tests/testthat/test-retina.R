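# Photoreceptor placement, membership and Beer-Lambert absorption.

test_that("receptors on a flat patch form a hexagonal array at the requested spacing", {
  patch <- flat_patch_mesh(d = 25)
  rec <- place_receptors(patch, spacing = 2.5, apex_height = 10)
  # hex-packing estimate: area / (sqrt(3)/2 s^2) = 91 receptors +- 10%
  n_expect <- (pi * 12.5^2) / (sqrt(3) / 2 * 2.5^2)
  expect_gt(nrow(rec), 0.9 * n_expect)
  expect_lt(nrow(rec), 1.1 * n_expect)
  b <- as.matrix(rec[, c("base_x", "base_y", "base_z")])
  nn <- nn_dists(b)
  expect_equal(mean(nn), 2.5, tolerance = 0.1)
  # interior receptors have modal neighbour count 6 (within 1.2 spacing)
  d <- as.matrix(dist(b)); diag(d) <- Inf
  interior <- sqrt(rowSums(b[, 1:2]^2)) < 12.5 - 2.5
  counts <- rowSums(d[interior, ] < 1.2 * 2.5)
  expect_identical(as.integer(names(which.max(table(counts)))), 6L)
  # apices along the patch normal
  expect_equal(unname(rec$length), rep(10, nrow(rec)), tolerance = 1e-6)
})

test_that("receptor placement on the eye hits the anatomical spacing", {
  eye <- make_concentric_eye(freq = 10L)
  rec <- place_receptors(eye, spacing = 2.5, max_length = 15)
  b <- as.matrix(rec[, c("base_x", "base_y", "base_z")])
  nn <- nn_dists(b)
  expect_equal(mean(nn), 2.5, tolerance = 0.1)     # within 10% of 2.5 um
  # deterministic
  rec2 <- place_receptors(eye, spacing = 2.5, max_length = 15)
  expect_identical(rec, rec2)
  expect_error(place_receptors(eye, spacing = 100), "fewer than 3")
})

test_that("cone-shell membership honours core, overlap and bounds", {
  # two receptors with parallel axes 2.5 um apart, strongly overlapping
  rec <- receptor_set(base = rbind(c(0, 0, 0), c(2.5, 0, 0)),
                      apex = rbind(c(0, 0, 20), c(2.5, 0, 20)),
                      r_base = 2.0, r_apex = 2.0, r_core = 0.5)
  # point on the first receptor's axis inside its core is not absorbed by
  # it, and lies outside the neighbour's outer radius (2.5 > 2.0): empty
  expect_length(receptor_membership(c(0, 0, 10), rec)[[1]], 0L)
  # midway between the two axes at mid-depth: both shells contain it
  expect_identical(sort(receptor_membership(c(1.25, 0, 10), rec)[[1]]), c(1L, 2L))
  # outside the retina entirely
  expect_length(receptor_membership(c(50, 50, 50), rec)[[1]], 0L)
  # beyond apex/base planes
  expect_length(receptor_membership(c(1, 0, 25), rec)[[1]], 0L)
})

test_that("Beer-Lambert marching matches the closed form and conserves power", {
  rec <- receptor_set(matrix(c(0, 0, 0), 1, 3), matrix(c(110, 0, 0), 1, 3),
                      r_base = 5, r_apex = 5, r_core = 0)
  path <- list(segments = data.frame(x0 = 105, y0 = 1, z0 = 0,
                                     x1 = 5, y1 = 1, z1 = 0,
                                     length = 100, medium = "retina_wall"))
  cfg <- optical_config()   # alpha = 0.0067 / um
  a <- absorb_path(path, rec, cfg, step = 0.1)
  expect_equal(a[1], 1 - exp(-0.0067 * 100), tolerance = 1e-3)
  expect_lt(abs(a[1] + attr(a, "remaining") - 1), 1e-12)
  # halving the step changes the total by < 0.1%
  a2 <- absorb_path(path, rec, cfg, step = 0.05)
  expect_lt(abs(a2[1] - a[1]) / a[1], 1e-3)
  # monotonic in alpha and in path length
  cfg_hi <- optical_config(alpha = 0.02)
  expect_gt(absorb_path(path, rec, cfg_hi, step = 0.1)[1], a[1])
  short <- path
  short$segments$x0 <- 55; short$segments$length <- 50
  expect_lt(absorb_path(short, rec, cfg, step = 0.1)[1], a[1])
  # path entirely inside a non-absorbing core absorbs nothing
  rec_core <- receptor_set(matrix(c(0, 0, 0), 1, 3), matrix(c(110, 0, 0), 1, 3),
                           r_base = 5, r_apex = 5, r_core = 2)
  path_axis <- list(segments = data.frame(x0 = 105, y0 = 0, z0 = 0,
                                          x1 = 5, y1 = 0, z1 = 0,
                                          length = 100, medium = "retina_wall"))
  expect_equal(sum(absorb_path(path_axis, rec_core, cfg)), 0)
  expect_error(absorb_path(path, rec, cfg, step = -1), "> 0")
})

test_that("overlap attribution splits power without changing the total", {
  one <- receptor_set(matrix(c(0, 0, 0), 1, 3), matrix(c(110, 0, 0), 1, 3),
                      r_base = 5, r_apex = 5, r_core = 0)
  two <- receptor_set(rbind(c(0, 0, 0), c(0, 0.5, 0)),
                      rbind(c(110, 0, 0), c(110, 0.5, 0)),
                      r_base = 5, r_apex = 5, r_core = 0)
  path <- list(segments = data.frame(x0 = 105, y0 = 1, z0 = 0,
                                     x1 = 5, y1 = 1, z1 = 0,
                                     length = 100, medium = "retina_wall"))
  cfg <- optical_config()
  a1 <- absorb_path(path, one, cfg, step = 0.1)
  a2 <- absorb_path(path, two, cfg, step = 0.1)
  expect_equal(sum(a2), sum(a1), tolerance = 1e-12)
  expect_equal(a2[1], a2[2], tolerance = 1e-12)   # equal split
})

test_that("path-marched and fused traced absorption agree", {
  # dual route: trace_field(record_paths) + absorb_path marching in R vs the
  # C++ in-trace marcher used by trace_absorb
  eye <- make_concentric_eye(freq = 8L)
  rec <- place_receptors(eye, spacing = 4, max_length = 12)
  cfg <- optical_config(n_directions = 3, rays_per_beam = 40)
  ts <- trace_field(eye, cfg, record_paths = TRUE)
  tab_slow <- accumulate_absorption(ts, rec)
  tab_fast <- trace_absorb(eye, rec, cfg)
  expect_equal(unclass(tab_slow)[, ], unclass(tab_fast)[, ], tolerance = 1e-9)
})

test_that("rays that miss the eye deposit nothing", {
  eye <- make_concentric_eye(freq = 6L)
  rec <- place_receptors(eye, spacing = 4, max_length = 12)
  cfg <- optical_config()
  p <- trace_ray(c(200, 500, 0), c(-1, 0, 0), eye, cfg, rec)
  expect_identical(p$reason, "exited")
  expect_equal(sum(p$absorption), 0)
})
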