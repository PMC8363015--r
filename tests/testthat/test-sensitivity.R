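# Angular sensitivity functions, cut-off frequencies, viewing directions,
# field of view and the resolution map.

# absorption table with a planted per-receptor signal over sampled directions
planted_table <- function(f_list, n_dir = 800, axis = c(1, 0, 0)) {
  dirs <- sample_hemisphere(n_dir, axis)
  ang <- ocellus:::dir_to_angles(dirs)
  mat <- do.call(rbind, lapply(f_list, function(f) f(ang[, 1], ang[, 2])))
  rec <- receptor_set(matrix(rnorm(length(f_list) * 3), ncol = 3) + 10,
                      matrix(rnorm(length(f_list) * 3), ncol = 3) - 10)
  stats <- data.frame(n_rays = rep(1000L, n_dir), n_hit = 1000L,
                      n_entered_retina = 500L, power_exited = 0.5,
                      power_pigment = 0.25, power_absorbed = 0.25,
                      power_lost = 0)
  ocellus:::absorption_table(mat, dirs, stats, rec, beam_radius = 50,
                             n_rays = 1000L)
}

gauss2d <- function(azi0, elev0, fwhm, peak = 1) {
  sg <- fwhm / (2 * sqrt(2 * log(2)))
  function(a, e) peak * exp(-((a - azi0)^2 + (e - elev0)^2) / (2 * sg^2))
}

test_that("gridded ASF recovers a planted Gaussian signal", {
  set.seed(3)
  tab <- planted_table(list(gauss2d(20, -10, 18, 0.02)))
  asf <- angular_sensitivity(tab, 1L, grid_pitch = 1)
  expect_false(asf$empty)
  # peak within about half a direction-lattice spacing of the planted centre
  pk <- ocellus:::dir_to_angles(matrix(asf$peak_direction, 1, 3))
  expect_lt(abs(pk[1] - 20), 2.5)
  expect_lt(abs(pk[2] + 10), 2.5)
  # grid values non-negative, peak-normalized
  expect_gte(min(asf$values), 0)
  expect_equal(max(asf$values), 1)
  # absolute peak close to the planted amplitude
  expect_equal(asf$peak, 0.02, tolerance = 0.02)
  # reconstructed width close to the planted FWHM
  expect_equal(unname(asf_fwhm(asf)[["geometric_mean"]]), 18, tolerance = 0.1)
  # a tight cluster of nonzero samples peaks at that direction
  tabd <- planted_table(list(function(a, e) as.numeric(abs(a - 30) < 5 & abs(e) < 5)),
                        n_dir = 600)
  asfd <- angular_sensitivity(tabd, 1L)
  pkd <- ocellus:::dir_to_angles(matrix(asfd$peak_direction, 1, 3))
  expect_lt(abs(pkd[1] - 30), 6)
})

test_that("viewing direction is the thresholded weighted centroid", {
  set.seed(4)
  # symmetric single lobe: centroid = peak direction
  tab <- planted_table(list(gauss2d(30, 5, 16)))
  asf <- angular_sensitivity(tab, 1L)
  vd <- viewing_direction(asf)
  va <- ocellus:::dir_to_angles(matrix(vd, 1, 3))
  expect_lt(abs(va[1] - 30), 1.5)
  expect_lt(abs(va[2] - 5), 1.5)
  # two equal lobes at +-12 deg azimuth: centroid between them
  two <- function(a, e) gauss2d(-12, 0, 10)(a, e) + gauss2d(12, 0, 10)(a, e)
  tab2 <- planted_table(list(two))
  asf2 <- angular_sensitivity(tab2, 1L)
  va2 <- ocellus:::dir_to_angles(matrix(viewing_direction(asf2), 1, 3))
  expect_lt(abs(va2[1]), 2.5)
  # raising the threshold to ~1 converges to the peak cell
  va3 <- ocellus:::dir_to_angles(matrix(viewing_direction(asf2, 0.99), 1, 3))
  pk2 <- ocellus:::dir_to_angles(matrix(asf2$peak_direction, 1, 3))
  expect_lt(abs(va3[1] - pk2[1]), 1.5)
})

test_that("Fourier cut-off matches the Gaussian transform pair", {
  # FWHM_f = 4 ln2 / (pi w): w = 20 deg -> 0.0441 cycles/deg
  asf <- gaussian_asf(fwhm = 20)
  co <- cutoff_frequency(asf)
  expect_equal(unname(co[["horizontal"]]), 4 * log(2) / (pi * 20),
               tolerance = 0.02)
  # isotropic ASF: horizontal = vertical
  expect_equal(unname(co[["horizontal"]]), unname(co[["vertical"]]),
               tolerance = 0.01)
  # hwhm convention is exactly half
  co_h <- cutoff_frequency(asf, "hwhm")
  expect_equal(unname(co_h[["horizontal"]]), unname(co[["horizontal"]]) / 2,
               tolerance = 1e-10)
  # ASF elongated horizontally passes lower frequencies along azimuth
  sgh <- 30 / (2 * sqrt(2 * log(2))); sgv <- 10 / (2 * sqrt(2 * log(2)))
  az <- seq(-60, 60); el <- seq(-40, 40)
  V <- outer(el, az, function(e, a) exp(-a^2 / (2 * sgh^2) - e^2 / (2 * sgv^2)))
  asf2 <- gaussian_asf(); asf2$values <- V; asf2$azimuth <- az; asf2$elevation <- el
  co2 <- cutoff_frequency(asf2)
  expect_lt(co2[["horizontal"]], co2[["vertical"]])
  # too-narrow ASF is rejected with advice
  narrow <- gaussian_asf(fwhm = 1.5)
  expect_error(cutoff_frequency(narrow), "finer")
})

test_that("axis slices of the 2-D DFT equal the projection transforms", {
  # the implementation uses the projection-slice identity; verify against an
  # explicit 2-D FFT on a small asymmetric grid
  set.seed(9)
  V <- matrix(runif(30 * 40), 30, 40)
  F2 <- fft(V)
  expect_equal(Mod(F2[1, ]), Mod(fft(colSums(V))), tolerance = 1e-10)
  expect_equal(Mod(F2[, 1]), Mod(fft(rowSums(V))), tolerance = 1e-10)
})

test_that("field of view follows the 5% relative-absorption criterion", {
  set.seed(5)
  tab <- planted_table(list(gauss2d(0, 0, 25, 0.02), gauss2d(40, 0, 25, 0.01),
                            gauss2d(-40, 0, 25, 0.01), gauss2d(0, 30, 25, 0.01),
                            gauss2d(0, -30, 25, 0.01)))
  fov <- field_of_view(tab, threshold = 0.05)
  expect_true(any(fov$mask))
  # horizontal extent exceeds vertical (lobes at +-40 vs +-30)
  expect_gt(fov$extent[["horizontal"]], fov$extent[["vertical"]])
  # threshold -> 0 admits every direction with any absorption
  fov0 <- field_of_view(tab, threshold = 1e-12)
  expect_gte(sum(fov0$mask), sum(fov$mask))
  # one receptor hot in a tight cluster: the field collapses around it
  one <- planted_table(list(function(a, e) as.numeric(abs(a - 10) < 5 & abs(e) < 5)),
                       n_dir = 600)
  fov1 <- field_of_view(one)
  expect_gte(sum(fov1$mask), 1L)
  expect_lte(sum(fov1$mask), 5L)
})

test_that("effective pupil area reflects delivered beam fraction", {
  set.seed(6)
  tab <- planted_table(list(gauss2d(0, 0, 20)))
  # stats were planted with half the rays reaching the retina
  a <- effective_pupil_area(tab)
  expect_equal(a, rep(0.5 * pi * 50^2, ncol(tab)))
  expect_equal(effective_pupil_area(tab, c(1, 0, 0)), 0.5 * pi * 50^2)
})

test_that("resolution map is invariant to receptor order", {
  set.seed(8)
  fl <- list(gauss2d(10, 0, 18, 0.02), gauss2d(-15, 5, 22, 0.015),
             gauss2d(30, -8, 20, 0.018))
  tab <- planted_table(fl)
  m1 <- resolution_map(tab)
  # permute receptor rows
  perm <- c(3L, 1L, 2L)
  tabp <- ocellus:::absorption_table(unclass(tab)[perm, ],
                                     attr(tab, "directions"),
                                     attr(tab, "stats"),
                                     {
                                       r <- attr(tab, "receptors")[perm, ]
                                       r$id <- r$id[order(order(perm))] * 0L + attr(tab, "receptors")$id[perm]
                                       r
                                     },
                                     50, 1000L)
  m2 <- resolution_map(tabp)
  o1 <- m1$receptors[order(m1$receptors$id), ]
  o2 <- m2$receptors[order(m2$receptors$id), ]
  expect_equal(o1$cutoff_h, o2$cutoff_h, tolerance = 1e-12)
  expect_equal(o1$fwhm_gm, o2$fwhm_gm, tolerance = 1e-12)
  # viewing directions of mapped receptors lie inside the field of view
  expect_true(all(m1$receptors$in_fov))
})
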