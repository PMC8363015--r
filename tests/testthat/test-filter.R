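# Equisolid calibration, transfer stacks, Voronoi rendering, test stimuli.

make_stack3 <- function(size = 160) {
  calib <- fisheye_calibration(size)
  asfs <- list(gaussian_asf(0, 0, 18, peak = 0.02, id = 1L),
               gaussian_asf(25, 0, 18, peak = 0.01, id = 2L),
               gaussian_asf(-25, 10, 18, peak = 0.015, id = 3L))
  build_transfer_stack(asfs, calib)
}

test_that("equisolid projection obeys its law and inverts", {
  calib <- fisheye_calibration(200)
  # theta = 0 maps to the image centre
  expect_equal(unname(equisolid_project(0, 0, calib)[1, ]), calib$centre)
  # theta = 90 maps to radius f * sqrt(2)
  p90 <- equisolid_project(90, 0, calib)
  expect_equal(unname(p90[1, 1] - calib$centre[1]), calib$f * sqrt(2),
               tolerance = 1e-9)
  # round trip to sub-pixel accuracy
  th <- c(5, 30, 60, 85); ph <- c(0, 45, 120, 300)
  px <- equisolid_project(th, ph, calib)
  back <- equisolid_unproject(px[, 1], px[, 2], calib)
  expect_equal(unname(back[, 1]), th, tolerance = 1e-6)
  expect_equal(unname(back[, 2]), c(0, 45, 120, -60), tolerance = 1e-6)
  # outside the image circle: NA
  expect_true(all(is.na(equisolid_unproject(1, 1, calib))))
  expect_error(equisolid_project(100, 0, calib), "90")
})

test_that("transfer weights integrate to the receptor's total sensitivity", {
  calib <- fisheye_calibration(200)
  asf <- gaussian_asf(10, -5, 20, peak = 0.02)
  stack <- build_transfer_stack(list(asf), calib)
  # quadrature check: pixel-sum equals the ASF's solid-angle integral
  ce <- cos(asf$elevation * pi / 180)
  integral <- sum(sweep(asf$values * asf$peak, 1, ce, `*`)) * asf$pitch^2
  expect_equal(stack$total[1], integral, tolerance = 0.01)
  # delta-like ASF concentrates its weight at the projected direction
  dl <- gaussian_asf(15, 0, 4, peak = 1)
  sd <- build_transfer_stack(list(dl), calib)
  wm <- sd$weights[[1]]
  top <- wm$idx[which.max(wm$w)]
  xy <- c((top - 1) %/% 200 + 1, (top - 1) %% 200 + 1)  # col, row
  seed <- sd$seeds[1, ]
  expect_lt(sqrt(sum((xy - seed)^2)), 4)
})

test_that("filtering is linear and white input renders uniformly white", {
  stack <- make_stack3()
  sz <- stack$calib$size
  black <- matrix(0, sz, sz)
  expect_equal(unname(apply_filter(black, stack)), c(0, 0, 0))
  white <- matrix(1, sz, sz)
  rw <- apply_filter(white, stack)
  # white responses recover total sensitivities
  expect_equal(unname(rw), stack$total, tolerance = 1e-9)
  # linearity: response(a I1 + b I2) = a r(I1) + b r(I2)
  set.seed(21)
  i1 <- matrix(runif(sz * sz), sz, sz)
  i2 <- matrix(runif(sz * sz), sz, sz)
  r12 <- apply_filter(0.3 * i1 + 0.6 * i2, stack)
  expect_equal(unname(r12),
               unname(0.3 * apply_filter(i1, stack) + 0.6 * apply_filter(i2, stack)),
               tolerance = 1e-10)
  # white normalization fixed point: uniform white in, uniform white out
  img <- render_receptor_image(rw, stack)
  vals <- img$values[img$labels > 0]
  expect_equal(range(vals), c(1, 1), tolerance = 1e-9)
  # pixels outside the image circle never contribute
  i3 <- i1
  i3[!stack$calib$inside] <- 37
  expect_equal(unname(apply_filter(i3, stack)),
               unname(apply_filter(i1 * stack$calib$inside, stack)),
               tolerance = 1e-10)
})

test_that("Voronoi rendering respects the edge filter and seed permutation", {
  stack <- make_stack3()
  white <- matrix(1, stack$calib$size, stack$calib$size)
  rw <- apply_filter(white, stack)
  img <- render_receptor_image(rw, stack, edge_threshold = 0.05)
  expect_identical(length(img$surviving), 3L)
  # a harsher edge filter removes the weaker receptors, monotonically
  img2 <- render_receptor_image(rw, stack, edge_threshold = 0.8)
  expect_lt(length(img2$surviving), 3L)
  expect_true(all(img2$surviving %in% img$surviving))
  expect_error(render_receptor_image(rw, stack, edge_threshold = 2), "edge filter")
  # permuting receptor order leaves the rendered image unchanged
  perm <- c(2L, 3L, 1L)
  stackp <- stack
  stackp$weights <- stack$weights[perm]
  stackp$total <- stack$total[perm]
  stackp$seeds <- stack$seeds[perm, ]
  stackp$ids <- stack$ids[perm]
  imgp <- render_receptor_image(apply_filter(white, stackp), stackp)
  expect_equal(imgp$values, img$values, tolerance = 1e-12)
})

test_that("test patterns control angular size and frequency", {
  calib <- fisheye_calibration(240)
  # zero-amplitude pattern is uniform
  flat <- make_test_pattern("piecewise-sine-target", calib, width = 20,
                            contrast = 0)
  expect_equal(range(flat[calib$inside]), c(0.5, 0.5))
  # a 20-deg target subtends 20 deg through the calibration inverse
  tg <- make_test_pattern("piecewise-sine-target", calib, width = 20,
                          centre_direction = c(1, 0, 0))
  dev <- abs(tg - 0.5) > 0.02
  ang <- equisolid_unproject(col(tg)[dev], row(tg)[dev], calib)
  expect_equal(max(ang[, 1], na.rm = TRUE), 10, tolerance = 0.08)
  # bessel dot array: nearest-neighbour dot spacing ~ 1/frequency
  dots <- make_test_pattern("bessel-dot-array", calib, frequency = 0.095)
  # find local maxima: bright dot centres subtend ~1/0.095 = 10.5 deg spacing
  bright <- which(dots > 0.97, arr.ind = TRUE)
  expect_gt(nrow(bright), 5)
  # difference-of-gaussians is balanced about the background
  dog <- make_test_pattern("difference-of-gaussians", calib, width = 20)
  expect_lt(abs(mean(dog[calib$inside]) - 0.5), 0.01)
  expect_error(make_test_pattern("bessel-dot-array", calib, frequency = 50),
               "Nyquist")
})

test_that("Michelson modulation behaves at the limits", {
  stack <- make_stack3()
  white <- matrix(1, stack$calib$size, stack$calib$size)
  rw <- apply_filter(white, stack)
  norm <- rw / stack$total
  expect_equal(pattern_modulation(norm), 0, tolerance = 1e-9)
  expect_error(pattern_modulation(c(a = 0, b = 0)), "zero")
  # low-frequency grating passes close to its input contrast
  calib <- stack$calib
  azi <- calib$pixel_azimuth
  grating <- matrix(0.5, calib$size, calib$size)
  grating[calib$inside] <- 0.5 + 0.5 * sin(2 * pi * azi[calib$inside] / 120)
  resp <- apply_filter(grating, stack) / stack$total
  # receptors sit at azimuth -25, 0, 25 within one low-frequency cycle;
  # modulation of an 0.0083 cyc/deg grating through 18-deg ASFs stays high
  expect_gt(pattern_modulation(resp), 0.55)
})

test_that("video filtering streams frames in order", {
  stack <- make_stack3(120)
  sz <- stack$calib$size
  f1 <- matrix(0.2, sz, sz); f2 <- matrix(0.8, sz, sz)
  out <- filter_video(list(f1, f1), stack)
  expect_length(out, 2L)
  expect_equal(out[[1]]$values, out[[2]]$values)
  # single-frame video equals the still-image path
  still <- render_receptor_image(apply_filter(f2, stack), stack)
  vid <- filter_video(list(f2), stack)
  expect_equal(vid[[1]]$values, still$values)
  # frame order preserved
  out2 <- filter_video(list(f1, f2), stack)
  expect_lt(mean(out2[[1]]$values), mean(out2[[2]]$values))
  expect_error(filter_video(list(f1, matrix(0.5, 60, 60)), stack), "size")
})
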