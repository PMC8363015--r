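# From the receptor x direction absorption table to angular sensitivity
# functions (ASFs), viewing directions, Fourier cut-off frequencies, field
# of view, effective pupil area and the whole-field resolution map.
#
# Angular coordinates are head-frame: azimuth = angle in the horizontal
# (x-y) plane from the aperture axis (+x) toward anterior (+y), elevation =
# angle above the horizontal plane.  Directions are outward unit vectors
# (where light comes from); a receptor's viewing direction lives on the same
# hemisphere as the source directions.

dir_to_angles <- function(dirs) {
  dirs <- as.matrix(dirs)
  cbind(azimuth = atan2(dirs[, 2], dirs[, 1]) * 180 / pi,
        elevation = asin(pmin(1, pmax(-1, dirs[, 3]))) * 180 / pi)
}

angles_to_dir <- function(azimuth, elevation) {
  a <- azimuth * pi / 180; e <- elevation * pi / 180
  cbind(cos(e) * cos(a), cos(e) * sin(a), sin(e))
}

# mean angular spacing (deg) of n quasi-uniform directions on a hemisphere
lattice_spacing_deg <- function(n) sqrt(2 * pi / n) * 180 / pi

#' Angular sensitivity function of one receptor
#'
#' Interpolates the receptor's scattered per-direction absorption samples
#' onto a regular azimuth x elevation grid (default 1 degree pitch) by
#' moving-least-squares local-linear interpolation; grid cells beyond the
#' hull of the sampled directions are zero and values are clipped at zero.
#'
#' @param table an `absorption_table` from [trace_absorb()].
#' @param receptor_id receptor id (row of the table).
#' @param grid_pitch grid pitch in degrees.
#' @param pad window padding beyond the nonzero samples (deg).
#' @param normalize `"peak"` stores values scaled to a peak of 1,
#'   `"absolute"` keeps absorbed beam-power fractions.
#' @return an object of class `angular_sensitivity`: `values` (elevation x
#'   azimuth matrix), `azimuth`, `elevation` (cell centres, deg), `peak`
#'   (absolute peak), `peak_direction`, `empty` flag, `pitch`.
#' @export
angular_sensitivity <- function(table, receptor_id, grid_pitch = 1,
                                pad = 8, normalize = c("peak", "absolute")) {
  stopifnot(inherits(table, "absorption_table"))
  normalize <- match.arg(normalize)
  r <- match(receptor_id, attr(table, "receptors")$id)
  if (is.na(r)) stop("receptor ", receptor_id, " not in table")
  dirs <- attr(table, "directions")
  vals <- as.numeric(table[r, ])
  ang <- dir_to_angles(dirs)
  peak <- max(vals)
  if (peak <= 0) {
    return(structure(list(values = matrix(0, 1, 1), azimuth = 0, elevation = 0,
                          peak = 0, peak_direction = c(NA, NA, NA),
                          receptor_id = receptor_id, empty = TRUE,
                          pitch = grid_pitch, normalize = normalize),
                     class = "angular_sensitivity"))
  }
  n_above_half <- sum(vals >= 0.5 * peak)
  nz <- vals >= 0.01 * peak
  az_rng <- range(ang[nz, 1]) + c(-pad, pad)
  el_rng <- range(ang[nz, 2]) + c(-pad, pad)
  az_rng <- pmax(pmin(az_rng, 180), -180)
  el_rng <- pmax(pmin(el_rng, 90), -90)
  az <- seq(az_rng[1], az_rng[2], by = grid_pitch)
  el <- seq(el_rng[1], el_rng[2], by = grid_pitch)
  # local metric: compress azimuth by cos(elevation) at the sample peak
  e0 <- ang[which.max(vals), 2]
  ce <- max(cos(e0 * pi / 180), 0.2)
  g <- expand.grid(az = az, el = el)
  h <- lattice_spacing_deg(nrow(dirs))
  v <- cpp_mls_interp(ang[, 1] * ce, ang[, 2], vals,
                      g$az * ce, g$el, 7L, h, 2 * h)
  v <- pmax(v, 0)
  V <- matrix(v, nrow = length(el), ncol = length(az), byrow = TRUE)
  pk <- max(V)
  ij <- which(V == pk, arr.ind = TRUE)[1, ]
  pk_dir <- angles_to_dir(az[ij[2]], el[ij[1]])[1, ]
  if (normalize == "peak" && pk > 0) V <- V / pk
  structure(list(values = V, azimuth = az, elevation = el,
                 peak = pk, peak_direction = pk_dir,
                 receptor_id = receptor_id, empty = FALSE,
                 pitch = grid_pitch, normalize = normalize,
                 n_above_half = n_above_half),
            class = "angular_sensitivity")
}

#' @export
print.angular_sensitivity <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("<angular_sensitivity: receptor %s, empty (no absorption)>\n",
                x$receptor_id))
    return(invisible(x))
  }
  f <- asf_fwhm(x)
  cat(sprintf("<angular_sensitivity: receptor %s, peak %.3g, FWHM %.1f x %.1f deg>\n",
              x$receptor_id, x$peak, f[["horizontal"]], f[["vertical"]]))
  invisible(x)
}

#' @export
plot.angular_sensitivity <- function(x, ...) {
  if (x$empty) stop("empty ASF")
  image(x$azimuth, x$elevation, t(x$values), xlab = "azimuth (deg)",
        ylab = "elevation (deg)", col = hcl.colors(64, "inferno"),
        main = paste("receptor", x$receptor_id), ...)
  invisible(x)
}

#' Viewing direction of a receptor
#'
#' Weighted centroid of the gridded angular sensitivity restricted to cells
#' at or above `threshold` of the peak (default 30%); weights are the cell
#' values times the cell solid angle.
#'
#' @param asf an `angular_sensitivity`.
#' @param threshold fraction of peak included in the centroid.
#' @return outward unit vector (length 3).
#' @export
viewing_direction <- function(asf, threshold = 0.30) {
  stopifnot(inherits(asf, "angular_sensitivity"))
  if (asf$empty || max(asf$values) <= 0) stop("empty angular sensitivity")
  V <- asf$values
  keep <- V >= threshold * max(V)
  idx <- which(keep, arr.ind = TRUE)
  az <- asf$azimuth[idx[, 2]]
  el <- asf$elevation[idx[, 1]]
  w <- V[keep] * cos(el * pi / 180)
  d <- angles_to_dir(az, el)
  v <- colSums(d * w) / sum(w)
  v / sqrt(sum(v^2))
}

#' Spatial full width at half maximum of an ASF
#'
#' Width of the angular sensitivity at half its peak, measured through the
#' peak cell along the horizontal (azimuth, corrected by cos(elevation)) and
#' vertical (elevation) grid axes, with linear interpolation at the
#' half-maximum crossings.
#'
#' @param asf an `angular_sensitivity`.
#' @return named vector `c(horizontal=, vertical=, geometric_mean=)`, deg.
#' @export
asf_fwhm <- function(asf) {
  stopifnot(inherits(asf, "angular_sensitivity"))
  if (asf$empty) stop("empty angular sensitivity")
  V <- asf$values
  ij <- which(V == max(V), arr.ind = TRUE)[1, ]
  ce <- cos(asf$elevation[ij[1]] * pi / 180)
  wh <- line_fwhm(V[ij[1], ], asf$pitch) * ce
  wv <- line_fwhm(V[, ij[2]], asf$pitch)
  c(horizontal = wh, vertical = wv, geometric_mean = sqrt(wh * wv))
}

line_fwhm <- function(y, pitch) {
  p <- which.max(y)
  half <- y[p] / 2
  # right crossing
  r <- p
  while (r < length(y) && y[r + 1] >= half) r <- r + 1
  xr <- if (r == length(y)) r else r + (y[r] - half) / (y[r] - y[r + 1])
  l <- p
  while (l > 1 && y[l - 1] >= half) l <- l - 1
  xl <- if (l == 1) l else l - (y[l] - half) / (y[l] - y[l - 1])
  (xr - xl) * pitch
}

#' Cut-off spatial frequency of a receptor from its ASF
#'
#' Discrete Fourier transform of the gridded angular sensitivity; along the
#' horizontal and vertical frequency axes through the origin the cut-off is
#' the full width at half maximum of the modulus, in cycles/degree.  The
#' axis slices are computed by the projection-slice identity (1-D transforms
#' of the axis projections), which is exactly the 2-D transform on the axes.
#' `convention = "hwhm"` returns the half width instead (the two conventions
#' differ by exactly 2x).
#'
#' @param asf an `angular_sensitivity` on a regular grid.
#' @param convention `"fwhm"` (default) or `"hwhm"`.
#' @param nfft zero-padded transform length.
#' @return named vector `c(horizontal=, vertical=)` in cycles/degree:
#'   `horizontal` is the cut-off for modulation along the horizontal
#'   (azimuth) direction, `vertical` along elevation.
#' @export
cutoff_frequency <- function(asf, convention = c("fwhm", "hwhm"), nfft = 4096L) {
  stopifnot(inherits(asf, "angular_sensitivity"))
  convention <- match.arg(convention)
  if (asf$empty) stop("empty angular sensitivity")
  f <- asf_fwhm(asf)
  if (min(f[1:2]) < 2 * asf$pitch)
    stop("ASF narrower than 2 grid cells; use a finer grid_pitch")
  V <- asf$values
  ij <- which(V == max(V), arr.ind = TRUE)[1, ]
  ce <- cos(asf$elevation[ij[1]] * pi / 180)
  fh <- halfmax_freq(colSums(V), asf$pitch * ce, nfft)
  fv <- halfmax_freq(rowSums(V), asf$pitch, nfft)
  k <- if (convention == "fwhm") 2 else 1
  c(horizontal = k * fh, vertical = k * fv)
}

halfmax_freq <- function(y, pitch, nfft) {
  n <- max(nfft, length(y))
  mod <- Mod(fft(c(y, rep(0, n - length(y)))))
  half <- mod[1] / 2
  i <- 1
  while (i < length(mod) && mod[i + 1] >= half) i <- i + 1
  xi <- i + (mod[i] - half) / (mod[i] - mod[i + 1])   # 1-based bin of crossing
  (xi - 1) / (n * pitch)
}

#' Field of view from an absorption table
#'
#' A direction is inside the field of view iff the maximum over receptors of
#' its absorption relative to that receptor's own peak reaches `threshold`
#' (default 5%); at the field edge this reduces to the most peripheral
#' receptors falling below 5% of their peak.  Angular extents are measured
#' through the direction of peak summed absorption: the horizontal extent is
#' the azimuth range of in-field directions within an elevation band about
#' the peak, and conversely for the vertical extent (plus one direction-
#' lattice spacing, since each sample stands for a cell of the hemisphere).
#'
#' @param table an `absorption_table`.
#' @param threshold fraction of per-receptor peak absorption.
#' @param band half-width (deg) of the plane band used for the extents.
#' @return list of class `fov`: `mask` (logical per direction), `extent`
#'   (named: horizontal, vertical, deg), `peak_direction`, `threshold`.
#' @export
field_of_view <- function(table, threshold = 0.05, band = 6) {
  stopifnot(inherits(table, "absorption_table"))
  dirs <- attr(table, "directions")
  peaks <- apply(table, 1, max)
  rel <- table / ifelse(peaks > 0, peaks, 1)
  mask <- apply(rel, 2, max) >= threshold
  ssum <- colSums(table)
  pk <- which.max(ssum)
  ang <- dir_to_angles(dirs)
  h <- lattice_spacing_deg(nrow(dirs))
  inh <- mask & abs(ang[, 2] - ang[pk, 2]) <= band
  inv <- mask & abs((ang[, 1] - ang[pk, 1]) * cos(ang[, 2] * pi / 180)) <= band
  ext_h <- if (any(inh)) diff(range(ang[inh, 1])) + h else 0
  ext_v <- if (any(inv)) diff(range(ang[inv, 2])) + h else 0
  structure(list(mask = mask,
                 extent = c(horizontal = ext_h, vertical = ext_v),
                 peak_direction = dirs[pk, ], threshold = threshold),
            class = "fov")
}

#' @export
print.fov <- function(x, ...) {
  cat(sprintf("<fov: %.0f deg horizontal x %.0f deg vertical (%d/%d directions in field)>\n",
              x$extent[["horizontal"]], x$extent[["vertical"]],
              sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Effective pupil area per viewing direction
#'
#' The fraction of the parallel source beam that enters the eye and reaches
#' the retinal volume, times the beam disc area: the area of the external
#' aperture actually delivering light for that direction.
#'
#' @param traces a `trace_set` or `absorption_table`.
#' @param direction optional outward direction (unit vector); when given,
#'   the nearest traced direction is used and a scalar returned.
#' @return area(s) in um^2.
#' @export
effective_pupil_area <- function(traces, direction = NULL) {
  st <- if (inherits(traces, "absorption_table")) attr(traces, "stats") else traces$stats
  dirs <- if (inherits(traces, "absorption_table")) attr(traces, "directions") else traces$directions
  br <- if (inherits(traces, "absorption_table")) attr(traces, "beam_radius") else traces$beam_radius
  area <- st$n_entered_retina / st$n_rays * pi * br^2
  if (is.null(direction)) return(area)
  d <- as.numeric(direction); d <- d / sqrt(sum(d^2))
  cosang <- dirs %*% d
  i <- which.max(cosang)
  if (cosang[i] < cos(10 * pi / 180))
    stop("direction not traced (nearest sample > 10 deg away)")
  area[i]
}

#' Resolution map of the entire visual field
#'
#' Assembles, for every receptor with nonzero absorption, the viewing
#' direction, horizontal and vertical cut-off frequencies, ASF width; and
#' per traced direction the effective pupil area and relative summed
#' absorption; plus the field-of-view mask.
#'
#' @param table an `absorption_table`.
#' @param grid_pitch ASF grid pitch (deg).
#' @param convention cut-off convention, see [cutoff_frequency()].
#' @param fov_threshold field-of-view criterion (fraction of peak).
#' @param min_peak receptors whose peak absorption is below this fraction of
#'   the strongest receptor's peak are skipped (too dim to grid reliably).
#' @param min_samples minimum number of direction samples at or above half
#'   the receptor's peak for its ASF width to count as resolved; narrower
#'   functions are below the direction-lattice resolution and their width
#'   and cut-off are reported as NA.
#' @return an object of class `resolution_map`: `receptors` data.frame (id,
#'   view_x/y/z, azimuth, elevation, cutoff_h, cutoff_v, fwhm_h, fwhm_v,
#'   fwhm_gm, peak_absorption, in_fov), `directions` data.frame (direction,
#'   pupil_area_um2, relative_absorption, in_fov), `fov`, `convention`.
#' @export
resolution_map <- function(table, grid_pitch = 1,
                           convention = c("fwhm", "hwhm"),
                           fov_threshold = 0.05, min_peak = 0.01,
                           min_samples = 4L) {
  stopifnot(inherits(table, "absorption_table"))
  convention <- match.arg(convention)
  rec <- attr(table, "receptors")
  dirs <- attr(table, "directions")
  fov <- field_of_view(table, fov_threshold)
  peaks <- apply(table, 1, max)
  keep <- peaks >= min_peak * max(peaks)
  rows <- which(keep)
  out <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    r <- rows[k]
    asf <- angular_sensitivity(table, rec$id[r], grid_pitch)
    vd <- viewing_direction(asf)
    resolved <- asf$n_above_half >= min_samples
    co <- if (resolved) {
      tryCatch(cutoff_frequency(asf, convention),
               error = function(e) c(horizontal = NA_real_, vertical = NA_real_))
    } else c(horizontal = NA_real_, vertical = NA_real_)
    fw <- asf_fwhm(asf)
    if (!resolved) fw[] <- NA_real_
    va <- dir_to_angles(matrix(vd, 1, 3))
    out[[k]] <- data.frame(id = rec$id[r], view_x = vd[1], view_y = vd[2],
                           view_z = vd[3], azimuth = va[1, 1],
                           elevation = va[1, 2],
                           cutoff_h = co[["horizontal"]],
                           cutoff_v = co[["vertical"]],
                           fwhm_h = fw[["horizontal"]],
                           fwhm_v = fw[["vertical"]],
                           fwhm_gm = fw[["geometric_mean"]],
                           peak_absorption = peaks[r])
  }
  rdf <- do.call(rbind, out)
  # a receptor is in the field when its viewing direction is
  rdf$in_fov <- vapply(seq_len(nrow(rdf)), function(i) {
    d <- c(rdf$view_x[i], rdf$view_y[i], rdf$view_z[i])
    any(fov$mask & (dirs %*% d > cos(1.5 * lattice_spacing_deg(nrow(dirs)) * pi / 180)))
  }, logical(1))
  ssum <- colSums(table)
  ddf <- data.frame(dir_x = dirs[, 1], dir_y = dirs[, 2], dir_z = dirs[, 3],
                    pupil_area_um2 = effective_pupil_area(table),
                    relative_absorption = ssum / max(ssum),
                    in_fov = fov$mask)
  structure(list(receptors = rdf, directions = ddf, fov = fov,
                 convention = convention, grid_pitch = grid_pitch),
            class = "resolution_map")
}

#' @export
print.resolution_map <- function(x, ...) {
  r <- x$receptors
  ok <- is.finite(r$cutoff_h) & is.finite(r$cutoff_v)
  cat(sprintf("<resolution_map: %d receptors (%s convention)>\n",
              nrow(r), x$convention))
  cat(sprintf("  cut-off cycles/deg: horizontal %.3f-%.3f, vertical %.3f-%.3f\n",
              min(r$cutoff_h[ok]), max(r$cutoff_h[ok]),
              min(r$cutoff_v[ok]), max(r$cutoff_v[ok])))
  cat(sprintf("  field of view: %.0f x %.0f deg\n",
              x$fov$extent[["horizontal"]], x$fov$extent[["vertical"]]))
  best <- r[which.max(pmax(r$cutoff_h, r$cutoff_v)), ]
  cat(sprintf("  peak cut-off %.3f cycles/deg at azimuth %.0f, elevation %.0f deg\n",
              max(best$cutoff_h, best$cutoff_v), best$azimuth, best$elevation))
  invisible(x)
}

#' @export
plot.resolution_map <- function(x, what = c("cutoff_h", "cutoff_v", "fwhm_gm",
                                            "peak_absorption"), ...) {
  what <- match.arg(what)
  r <- x$receptors
  # orthographic projection from the lateral (aperture-axis) viewpoint
  px <- r$view_y; py <- r$view_z
  val <- r[[what]]
  cols <- hcl.colors(64, "viridis")[
    pmax(1, pmin(64, 1 + round(63 * (val - min(val, na.rm = TRUE)) /
                                 max(1e-12, diff(range(val, na.rm = TRUE))))))]
  plot(px, py, col = cols, pch = 16, asp = 1, xlab = "y (anterior ->)",
       ylab = "z (up ->)", main = what, ...)
  th <- seq(0, 2 * pi, length.out = 181)
  lines(cos(th), sin(th), col = "grey60")
  invisible(x)
}

#' Export a resolution map to CSV
#'
#' Writes two files: `<stem>_receptors.csv`, `<stem>_directions.csv`.
#'
#' @param x a `resolution_map`.
#' @param stem output path stem.
#' @return invisibly, the paths written.
#' @export
write_resolution_map <- function(x, stem) {
  stopifnot(inherits(x, "resolution_map"))
  p1 <- paste0(stem, "_receptors.csv")
  p2 <- paste0(stem, "_directions.csv")
  write.csv(x$receptors, p1, row.names = FALSE)
  write.csv(x$directions, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
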