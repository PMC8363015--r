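# Ray sources, hemisphere sampling, Snell refraction, tracing.

test_that("hemisphere sampling is even, deterministic and hemispheric", {
  expect_error(sample_hemisphere(0), ">= 1")
  ax <- c(0, 1, 0)
  expect_equal(sample_hemisphere(1, ax), matrix(ax, 1, 3))
  d <- sample_hemisphere(4000, c(1, 0, 0))
  expect_equal(sqrt(rowSums(d^2)), rep(1, 4000), tolerance = 1e-12)
  expect_true(all(d %*% c(1, 0, 0) >= 0))
  # area-uniform sampling has E(cos theta) = 1/2
  expect_equal(mean(d %*% c(1, 0, 0)), 0.5, tolerance = 0.01)
  # quasi-uniform lattice: nearest-neighbour spacing is tight
  ang <- acos(pmin(tcrossprod(d), 1))
  diag(ang) <- Inf
  nn <- apply(ang, 1, min)
  expect_lt(sd(nn) / mean(nn), 0.15)
  # deterministic
  expect_identical(d, sample_hemisphere(4000, c(1, 0, 0)))
})

test_that("source beams are parallel, disc-bounded and evenly spaced", {
  b1 <- make_beam(c(0, 0, -1), c(1, 2, 3), radius = 50, n_rays = 1)
  expect_equal(b1$origins[1, 1:2], c(1, 2))
  b <- make_beam(c(0, 0, -1), c(0, 0, 0), radius = 50, n_rays = 10000)
  r <- sqrt(rowSums(b$origins[, 1:2]^2))
  expect_lte(max(r), 50)
  # areal density uniform within 10% across equal-area radius bins
  bins <- cut(r^2, breaks = seq(0, 50^2, length.out = 11))
  counts <- tabulate(bins, 10)
  expect_lt(diff(range(counts)) / mean(counts), 0.1)
  # beams along d and -d are mirror images (same disc radii)
  b2 <- make_beam(c(0, 0, 1), c(0, 0, 0), radius = 50, n_rays = 500)
  b3 <- make_beam(c(0, 0, -1), c(0, 0, 0), radius = 50, n_rays = 500)
  expect_equal(sqrt(rowSums(b2$origins[, 1:2]^2)),
               sqrt(rowSums(b3$origins[, 1:2]^2)), tolerance = 1e-12)
  expect_equal(b2$origins[, 3], -b3$origins[, 3], tolerance = 1e-12)
})

test_that("Snell refraction matches closed forms and reverses exactly", {
  n_hat <- c(0, 0, 1)
  # matched indices and normal incidence leave the direction unchanged
  i <- c(sin(0.5), 0, -cos(0.5))
  expect_equal(as.numeric(refract_direction(i, n_hat, 1.33, 1.33)), i)
  expect_equal(as.numeric(refract_direction(c(0, 0, -1), n_hat, 1, 1.5)),
               c(0, 0, -1))
  # 30 deg, 1.0 -> 1.5 gives 19.47 deg
  i30 <- c(sin(pi / 6), 0, -cos(pi / 6))
  t30 <- refract_direction(i30, n_hat, 1.0, 1.5)
  expect_false(attr(t30, "tir"))
  expect_equal(asin(abs(t30[1])) * 180 / pi, 19.47, tolerance = 1e-3)
  # coplanarity
  expect_equal(t30[2], 0, tolerance = 1e-14)
  # TIR at 60 deg, 1.5 -> 1.0 (sin theta_t would be 1.30)
  i60 <- c(sin(pi / 3), 0, -cos(pi / 3))
  t60 <- refract_direction(i60, n_hat, 1.5, 1.0)
  expect_true(attr(t60, "tir"))
  # reversibility across random interfaces to 1e-10
  set.seed(11)
  for (k in 1:50) {
    i <- rnorm(3); i <- i / sqrt(sum(i^2))
    nv <- rnorm(3); nv <- nv / sqrt(sum(nv^2))
    n1 <- runif(1, 1, 1.6); n2 <- runif(1, 1, 1.6)
    tt <- refract_direction(i, nv, n1, n2)
    if (!attr(tt, "tir")) {
      back <- refract_direction(as.numeric(tt), nv, n2, n1)
      expect_equal(as.numeric(back), i, tolerance = 1e-10)
    }
  }
  expect_error(refract_direction(c(0, 0, 0), n_hat, 1, 1.5), "zero-length")
})

test_that("diffraction limit evaluates 1.22 lambda / d", {
  expect_equal(diffraction_limit(0.5, 100), 6.1e-3)
  expect_equal(diffraction_limit(0.5, 200), diffraction_limit(0.5, 100) / 2)
  expect_equal(diffraction_limit(1, 1), 1.22)
  expect_error(diffraction_limit(-1, 10), "> 0")
})

test_that("tracing handles misses, symmetry and termination bookkeeping", {
  eye <- make_concentric_eye(freq = 8L)
  cfg <- optical_config()
  # ray missing the eye: single unbounded segment, reason exited
  p <- trace_ray(c(200, 200, 0), c(0, 0, -1), eye, cfg)
  expect_identical(p$reason, "exited")
  expect_identical(nrow(p$segments), 1L)
  expect_identical(p$segments$medium, "air")
  # axial ray through the shell centre: all refractions at normal incidence,
  # path stays straight (smoothed normals remove faceting jitter)
  cfg_s <- optical_config(smooth_normals = TRUE)
  p2 <- trace_ray(c(200, 0, 0), c(-1, 0, 0), eye, cfg_s)
  expect_identical(p2$reason, "absorbed_at_pigment")
  expect_identical(p2$segments$medium,
                   c("air", "cornea", "lens", "retina_wall"))
  lat <- sqrt(p2$segments$y1^2 + p2$segments$z1^2)
  expect_lt(max(lat), 0.2)  # < 0.2 um lateral drift over a 230 um path
  # uniform index everywhere: rays are exactly straight lines
  eye1 <- make_concentric_eye(radii = c(50, 40, 30), indices = c(1, 1, 1),
                              freq = 8L)
  p3 <- trace_ray(c(200, 13, 7), c(-1, 0, 0), eye1, cfg)
  expect_equal(p3$segments$y1, rep(13, nrow(p3$segments)), tolerance = 1e-9)
  expect_equal(p3$segments$z1, rep(7, nrow(p3$segments)), tolerance = 1e-9)
})

test_that("trace_field books one beam per direction with coherent stats", {
  eye <- make_concentric_eye(freq = 6L)
  cfg <- optical_config(n_directions = 10, rays_per_beam = 100)
  ts <- trace_field(eye, cfg, record_paths = TRUE)
  expect_identical(nrow(ts$directions), 10L)
  expect_length(ts$paths, 10L)
  expect_true(all(vapply(ts$paths, length, integer(1)) == 100L))
  expect_true(all(ts$stats$n_rays == 100L))
  # power bookkeeping: everything ends somewhere
  tot <- with(ts$stats, power_exited + power_pigment + power_absorbed + power_lost)
  expect_equal(tot, rep(1, 10), tolerance = 1e-12)
})

test_that("ball-lens paraxial focus matches the closed-form back focal distance", {
  # BFD = R (2 - n) / (2 (n - 1)) = 25 um for R = 50, n = 1.5
  eye <- make_ball_lens_eye(50, 1.5, freq = 40L)
  cfg <- optical_config(n_directions = 1, rays_per_beam = 150,
                        beam_radius = 2.5, smooth_normals = TRUE)
  ts <- trace_field(eye, cfg, directions = matrix(c(1, 0, 0), 1, 3),
                    record_paths = TRUE)
  cx <- vapply(ts$paths[[1]], function(p) {
    seg <- p$segments[nrow(p$segments), ]
    a <- c(seg$x0, seg$y0, seg$z0); b <- c(seg$x1, seg$y1, seg$z1)
    h0 <- sqrt(p$segments$y0[1]^2 + p$segments$z0[1]^2)
    if (h0 < 0.75) return(NA_real_)   # near-axis crossings are ill-conditioned
    dv <- b - a
    tt <- -(a[2] * dv[2] + a[3] * dv[3]) / (dv[2]^2 + dv[3]^2)
    a[1] + tt * dv[1]
  }, numeric(1))
  bfd <- -median(cx, na.rm = TRUE) - 50
  expect_equal(bfd, 25, tolerance = 0.02)
  # n -> 1 limit: rays pass undeviated
  eye1 <- make_ball_lens_eye(50, 1.0000001, freq = 16L)
  p <- trace_ray(c(400, 10, 0), c(-1, 0, 0), eye1,
                 optical_config(smooth_normals = TRUE))
  expect_equal(p$segments$y1, rep(10, nrow(p$segments)), tolerance = 1e-3)
})
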