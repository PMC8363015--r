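# The parametric velvet-worm eye and the analytic reference eyes.

test_that("default velvet-worm eye meets the published geometric constraints", {
  eye <- make_velvetworm_eye()
  expect_named(eye$meshes, c("cornea", "lens", "retina_wall", "pigment_cup"))
  for (nm in c("cornea", "lens", "retina_wall")) {
    v <- validate_mesh(eye$meshes[[nm]])
    expect_true(v$watertight, info = nm)
    expect_true(v$outward, info = nm)
    # mesh resolution in the modelled reconstruction range
    expect_gte(v$n_faces, 7000)
    expect_lte(v$n_faces, 17000)
  }
  expect_true(validate_mesh(eye$meshes$pigment_cup)$watertight)
  # ~100 um eye: corneal apex at 50 um on the aperture axis
  expect_equal(max(eye$meshes$cornea$vertices[, 1]), 50, tolerance = 0.01)
  # forward direction 45 deg off the aperture axis in the horizontal plane
  expect_equal(sum(eye$forward * eye$aperture_axis), cos(pi / 4),
               tolerance = 1e-12)
  # retina abuts the lens: the retinal window (near the rear lens pole) is
  # inset into the lens volume
  win <- eye$meshes$retina_wall$vertices
  near_axis <- sqrt(win[, 2]^2 + win[, 3]^2) < 5
  win <- win[near_axis & win[, 1] > -3, , drop = FALSE]
  expect_gt(nrow(win), 3)
  expect_true(all(point_in_volume(win, eye$meshes$lens)))
  # generation is deterministic
  eye2 <- make_velvetworm_eye()
  expect_identical(eye$meshes$retina_wall$vertices,
                   eye2$meshes$retina_wall$vertices)
})

test_that("the retinal pouch deepens the forward light path", {
  eye <- make_velvetworm_eye()
  d_fwd <- ocellus:::retinal_depth(eye, eye$forward)
  d_ctr <- ocellus:::retinal_depth(eye, eye$aperture_axis)
  expect_gt(d_fwd, 1.5 * d_ctr)
  # switching the pouch off yields an azimuth-symmetric control eye:
  # back-wall radii from the retinal centre vary < 5% around the horizontal
  eye0 <- make_velvetworm_eye(eye_params(pouch_amp = 0))
  ret <- eye0$meshes$retina_wall
  idx <- build_octree(ret)
  O <- c(eye0$params$retina_centre_x, 0, 0)
  wall_r <- vapply(seq(120, 240, by = 20), function(a) {
    d <- c(cos(a * pi / 180), sin(a * pi / 180), 0)
    h <- intersect_ray(O, d, idx)
    h2 <- intersect_ray(O + d * (h$t + 1e-6), d, idx)  # farthest = back wall
    if (is.na(h2$t)) h$t else h$t + 1e-6 + h2$t
  }, numeric(1))
  expect_lt(diff(range(wall_r)) / mean(wall_r), 0.05)
})

test_that("parameter validation rejects impossible eyes", {
  expect_error(eye_params(diameter = -1), "invalid")
  expect_error(make_velvetworm_eye(eye_params(lens_back_pole = 60)),
               "behind the lens rim")
  expect_error(make_concentric_eye(radii = c(30, 40)), "decreasing")
  expect_error(make_concentric_eye(radii = c(50, 40), indices = 1.4), "match")
})

test_that("concentric reference eye is rotationally symmetric by construction", {
  eye <- make_concentric_eye(freq = 8L)
  expect_identical(eye$media$role, c("refract", "refract", "retina"))
  # mesh radii as requested
  for (i in seq_along(eye$meshes)) {
    r <- sqrt(rowSums(eye$meshes[[i]]$vertices^2))
    expect_equal(mean(r), eye$params$radii[i], tolerance = 1e-9)
  }
  # refining the mesh changes traced geometry marginally: paraxial chord
  # lengths through the shells agree across resolutions within 1%
  p1 <- trace_ray(c(200, 1, 0), c(-1, 0, 0), eye, optical_config())
  eye_f <- make_concentric_eye(freq = 16L)
  p2 <- trace_ray(c(200, 1, 0), c(-1, 0, 0), eye_f, optical_config())
  l1 <- sum(p1$segments$length[p1$segments$medium != "air"])
  l2 <- sum(p2$segments$length[p2$segments$medium != "air"])
  expect_equal(l1, l2, tolerance = 0.01)
})

test_that("eye models round-trip through STL + manifest", {
  tmp <- withr::local_tempdir()
  eye <- make_concentric_eye(freq = 4L)
  write_eye_model(eye, tmp)
  expect_true(file.exists(file.path(tmp, "eye_model.json")))
  eye2 <- read_eye_model(tmp)
  expect_identical(names(eye2$meshes), names(eye$meshes))
  expect_equal(eye2$media$index, eye$media$index)
  expect_equal(eye2$aperture_axis, eye$aperture_axis)
  soup <- function(m) m$vertices[t(m$faces), ]
  expect_equal(soup(eye2$meshes$lens), soup(eye$meshes$lens),
               tolerance = 1e-6)
  # re-traced geometry is equivalent: same path through the reread eye
  p1 <- trace_ray(c(200, 5, 0), c(-1, 0, 0), eye, optical_config())
  p2 <- trace_ray(c(200, 5, 0), c(-1, 0, 0), eye2, optical_config())
  expect_equal(p1$segments$length, p2$segments$length, tolerance = 1e-4)
})
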