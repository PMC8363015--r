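#' Optical configuration
#'
#' Collects the refractive indices, source-beam geometry, sampling counts and
#' absorption parameters used throughout a run.  Defaults are the standard
#' conditions for the velvet-worm eye model: air 1.0, cornea 1.4, lens 1.44,
#' retina 1.36 (microvillar rhabdom), a 50 um parallel beam of 10000 rays,
#' 4000 incident directions over a hemisphere, and a photopigment absorption
#' coefficient of 0.0067 per um.  A measured lens index of 1.485 has also
#' been reported for this eye; pass `n_lens = 1.485` to use it.
#'
#' @param n_air,n_cornea,n_lens,n_retina refractive indices (all >= 1).
#' @param beam_radius source beam radius, um.
#' @param rays_per_beam rays per parallel bundle.
#' @param n_directions incident directions spanning the visual hemisphere.
#' @param alpha photopigment absorption coefficient, 1/um.
#' @param wavelength wavelength for the diffraction helper, um.
#' @param step Beer-Lambert marching step inside the retina, um.
#' @param tir `"reflect"` continues totally internally reflected rays as
#'   specular reflections (with an event cap); `"terminate"` kills them.
#' @param max_events cap on surface interactions per ray.
#' @param smooth_normals interpolate vertex normals at hits instead of using
#'   per-face geometric normals.
#' @return an object of class `optical_config`.
#' @export
optical_config <- function(n_air = 1.0, n_cornea = 1.4, n_lens = 1.44,
                           n_retina = 1.36, beam_radius = 50,
                           rays_per_beam = 10000L, n_directions = 4000L,
                           alpha = 0.0067, wavelength = 0.5, step = 0.25,
                           tir = c("reflect", "terminate"), max_events = 50L,
                           smooth_normals = FALSE) {
  tir <- match.arg(tir)
  idx <- c(n_air, n_cornea, n_lens, n_retina)
  if (any(idx < 1)) stop("refractive indices must be >= 1")
  if (alpha < 0) stop("alpha must be >= 0")
  if (rays_per_beam < 1 || n_directions < 1) stop("counts must be >= 1")
  if (step <= 0) stop("step must be > 0")
  structure(list(n_air = n_air, n_cornea = n_cornea, n_lens = n_lens,
                 n_retina = n_retina, beam_radius = beam_radius,
                 rays_per_beam = as.integer(rays_per_beam),
                 n_directions = as.integer(n_directions), alpha = alpha,
                 wavelength = wavelength, step = step, tir = tir,
                 max_events = as.integer(max_events),
                 smooth_normals = isTRUE(smooth_normals)),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  indices: air %.3f | cornea %.3f | lens %.3f | retina %.3f\n",
              x$n_air, x$n_cornea, x$n_lens, x$n_retina))
  cat(sprintf("  beam: %d rays, radius %.1f um | %d directions | alpha %.4f /um | step %.2f um\n",
              x$rays_per_beam, x$beam_radius, x$n_directions, x$alpha, x$step))
  invisible(x)
}

#' Deterministic even sampling of a hemisphere of directions
#'
#' Fibonacci-lattice construction: `n` unit directions, quasi-uniform in
#' solid angle, all within 90 degrees of `axis`.  Deterministic for fixed
#' `n` (no random numbers).
#'
#' @param n number of directions (>= 1).
#' @param axis unit vector at the pole of the hemisphere.
#' @return an n x 3 matrix of unit directions.
#' @export
sample_hemisphere <- function(n, axis = c(1, 0, 0)) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  if (n == 1L) return(matrix(axis, 1, 3))
  i <- seq_len(n) - 0.5
  cosz <- 1 - i / n                      # uniform in cos(theta) over (0, 1)
  sinz <- sqrt(pmax(0, 1 - cosz^2))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  local <- cbind(sinz * cos(phi), sinz * sin(phi), cosz)
  local %*% t(rotation_to_z(axis))
}

# rotation matrix R with R %*% (0,0,1) = axis
rotation_to_z <- function(axis) {
  z <- c(0, 0, 1)
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  c2 <- sum(z * axis)
  if (sum(v^2) < 1e-18) {
    if (c2 > 0) return(diag(3))
    return(diag(c(1, -1, -1)))           # antiparallel: rotate pi about x
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c2)
}

#' Construct a parallel source beam
#'
#' Rays share one propagation direction and originate on a disc perpendicular
#' to it, evenly spaced by a deterministic sunflower (Fermat spiral) layout.
#' The disc is placed on the far side of `aim_point` against the propagation
#' direction, at `standoff` (so the whole beam starts outside the scene).
#'
#' @param direction unit propagation direction of the rays.
#' @param aim_point point the beam axis passes through (um).
#' @param radius beam radius (um).
#' @param n_rays number of rays.
#' @param standoff axial distance of the disc from `aim_point` (um).
#' @return list with `origins` (n x 3), `direction`, `radius`, `n_rays`.
#' @export
make_beam <- function(direction, aim_point = c(0, 0, 0), radius = 50,
                      n_rays = 10000L, standoff = 200) {
  if (radius <= 0) stop("radius must be > 0")
  n_rays <- as.integer(n_rays)
  if (n_rays < 1L) stop("n_rays must be >= 1")
  d <- as.numeric(direction); d <- d / sqrt(sum(d^2))
  centre <- as.numeric(aim_point) - d * standoff
  if (n_rays == 1L) {
    return(list(origins = matrix(centre, 1, 3), direction = d,
                radius = radius, n_rays = 1L))
  }
  k <- seq_len(n_rays)
  r <- radius * sqrt((k - 0.5) / n_rays)
  golden <- pi * (3 - sqrt(5))
  th <- golden * (k - 1)
  # orthonormal frame perpendicular to d
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(d[2] * ref[3] - d[3] * ref[2],
         d[3] * ref[1] - d[1] * ref[3],
         d[1] * ref[2] - d[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  origins <- cbind(centre[1] + r * (cos(th) * u[1] + sin(th) * v[1]),
                   centre[2] + r * (cos(th) * u[2] + sin(th) * v[2]),
                   centre[3] + r * (cos(th) * u[3] + sin(th) * v[3]))
  list(origins = origins, direction = d, radius = radius, n_rays = n_rays)
}

#' Refract a direction across an interface (Snell's law)
#'
#' The surface normal may point to either side; it is re-oriented against
#' the incident ray internally.  Returns the transmitted unit direction, or
#' the reflected direction with attribute `tir = TRUE` when total internal
#' reflection occurs (`(n1/n2) sin(theta_i) > 1`).
#'
#' @param incident unit incident direction.
#' @param normal unit surface normal.
#' @param n1,n2 refractive indices before/after the interface.
#' @return unit direction with logical attribute `"tir"`.
#' @export
refract_direction <- function(incident, normal, n1, n2) {
  i <- as.numeric(incident); nv <- as.numeric(normal)
  li <- sqrt(sum(i^2)); ln <- sqrt(sum(nv^2))
  if (li < 1e-12 || ln < 1e-12) stop("zero-length vector")
  i <- i / li; nv <- nv / ln
  ci <- -sum(i * nv)
  if (ci < 0) { nv <- -nv; ci <- -ci }
  eta <- n1 / n2
  k <- 1 - eta^2 * (1 - ci^2)
  if (k < 0) {
    out <- i + 2 * ci * nv               # total internal reflection
    out <- out / sqrt(sum(out^2))
    attr(out, "tir") <- TRUE
    return(out)
  }
  out <- eta * i + (eta * ci - sqrt(k)) * nv
  out <- out / sqrt(sum(out^2))
  attr(out, "tir") <- FALSE
  out
}

#' Diffraction-limited angular resolution
#'
#' First-minimum (Rayleigh) half-angle `1.22 * wavelength / aperture` of a
#' circular aperture, used as a sanity check that geometric optics suffices:
#' for a 100 um aperture at 500 nm this is about 0.0061 rad (0.35 deg), far
#' below the ~10 deg angular sensitivities modelled here.
#'
#' @param wavelength wavelength (same length unit as `aperture`).
#' @param aperture aperture diameter.
#' @return angle in radians.
#' @export
diffraction_limit <- function(wavelength, aperture) {
  if (any(wavelength <= 0) || any(aperture <= 0))
    stop("wavelength and aperture must be > 0")
  1.22 * wavelength / aperture
}
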