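# Eye image filters: from angular sensitivities to per-receptor pixel-weight
# maps over a calibrated equisolid-angle fisheye image, receptor responses,
# and Voronoi-rendered "what the eye sees" images.

#' Equisolid-angle fisheye calibration
#'
#' The projection law is r = 2 f sin(theta/2) from the image centre, where
#' theta is the angle from the camera axis; at theta = 90 deg the radius is
#' f * sqrt(2) (the image circle).  Equal solid angles occupy equal image
#' areas, so the per-pixel solid angle is the constant 1/f^2 inside the
#' circle.  The camera axis defaults to the eye's aperture axis (+x) with
#' image up = +z and image right = +y (anterior).
#'
#' @param size image side length in pixels (square canvas).
#' @param axis camera (optical) axis, outward unit vector.
#' @param up world direction rendered as image up.
#' @param centre image centre in pixels (x, y); default the canvas centre.
#' @param radius image-circle radius at theta = 90 deg (pixels).
#' @return an object of class `fisheye_calibration`; includes cached
#'   per-pixel direction angles used by the filter builders.
#' @export
fisheye_calibration <- function(size = 360L, axis = c(1, 0, 0),
                                up = c(0, 0, 1), centre = NULL,
                                radius = NULL) {
  size <- as.integer(size)
  axis <- as.numeric(axis); axis <- axis / sqrt(sum(axis^2))
  up <- as.numeric(up)
  up <- up - sum(up * axis) * axis
  if (sum(up^2) < 1e-12) stop("up must not be parallel to axis")
  up <- up / sqrt(sum(up^2))
  right <- c(up[2] * axis[3] - up[3] * axis[2],
             up[3] * axis[1] - up[1] * axis[3],
             up[1] * axis[2] - up[2] * axis[1])
  if (is.null(centre)) centre <- c((size + 1) / 2, (size + 1) / 2)
  if (is.null(radius)) radius <- size / 2 - 0.5
  f <- radius / sqrt(2)
  # cached pixel angles (x = column, y = row, y down)
  px <- matrix(rep(seq_len(size), each = size), size, size)   # column index
  py <- matrix(rep(seq_len(size), times = size), size, size)  # row index
  dx <- px - centre[1]; dy <- centre[2] - py
  r <- sqrt(dx^2 + dy^2)
  inside <- r <= radius + 1e-9
  theta <- 2 * asin(pmin(r / (2 * f), 1))
  phi <- atan2(dy, dx)
  st <- sin(theta)
  dirs <- cbind(cos(theta)[inside],
                (st * cos(phi))[inside],
                (st * sin(phi))[inside])
  world <- dirs[, 1, drop = FALSE] %*% rbind(axis) +
    dirs[, 2, drop = FALSE] %*% rbind(right) +
    dirs[, 3, drop = FALSE] %*% rbind(up)
  ang <- dir_to_angles(world)
  azi <- matrix(NA_real_, size, size); ele <- matrix(NA_real_, size, size)
  azi[inside] <- ang[, 1]; ele[inside] <- ang[, 2]
  structure(list(size = size, centre = centre, f = f, radius = radius,
                 axis = axis, up = up, right = right,
                 inside = inside, pixel_azimuth = azi, pixel_elevation = ele,
                 solid_angle_deg2 = (180 / pi)^2 / f^2),
            class = "fisheye_calibration")
}

#' @export
print.fisheye_calibration <- function(x, ...) {
  cat(sprintf("<fisheye_calibration: %dx%d px, f = %.2f px, equisolid r = 2f sin(theta/2)>\n",
              x$size, x$size, x$f))
  invisible(x)
}

#' Equisolid projection and its inverse
#'
#' `equisolid_project` maps spherical angles (theta from the camera axis,
#' phi counter-clockwise from image right) to pixel coordinates;
#' `equisolid_unproject` inverts it for in-circle pixels (NA outside).
#'
#' @param theta angle from the camera axis, degrees (0..90).
#' @param phi azimuth in the image plane, degrees.
#' @param calib a [fisheye_calibration()].
#' @return `equisolid_project`: matrix with columns `x`, `y` (pixels);
#'   `equisolid_unproject`: matrix with columns `theta`, `phi` (degrees).
#' @export
equisolid_project <- function(theta, phi, calib) {
  stopifnot(inherits(calib, "fisheye_calibration"))
  if (any(theta < 0 | theta > 90)) stop("theta must be in [0, 90] deg")
  r <- 2 * calib$f * sin(theta * pi / 360)
  cbind(x = calib$centre[1] + r * cos(phi * pi / 180),
        y = calib$centre[2] - r * sin(phi * pi / 180))
}

#' @rdname equisolid_project
#' @param x,y pixel coordinates.
#' @export
equisolid_unproject <- function(x, y, calib) {
  stopifnot(inherits(calib, "fisheye_calibration"))
  dx <- x - calib$centre[1]; dy <- calib$centre[2] - y
  r <- sqrt(dx^2 + dy^2)
  out <- cbind(theta = 2 * asin(pmin(r / (2 * calib$f), 1)) * 180 / pi,
               phi = atan2(dy, dx) * 180 / pi)
  out[r > calib$radius + 1e-9, ] <- NA_real_
  out
}

# pixel coordinates of outward directions (NA behind the camera plane)
dir_to_pixel <- function(dirs, calib) {
  if (is.null(dim(dirs))) dirs <- matrix(dirs, ncol = 3, byrow = TRUE)
  dirs <- as.matrix(dirs)
  a <- dirs %*% calib$axis
  u <- dirs %*% calib$right
  v <- dirs %*% calib$up
  theta <- acos(pmin(1, pmax(-1, a))) * 180 / pi
  phi <- atan2(v, u) * 180 / pi
  bad <- theta > 90
  theta[bad] <- NA_real_
  cbind(x = calib$centre[1] + 2 * calib$f * sin(theta * pi / 360) * cos(phi * pi / 180),
        y = calib$centre[2] - 2 * calib$f * sin(theta * pi / 360) * sin(phi * pi / 180))
}

# bilinear sample of an ASF grid at scattered (azimuth, elevation)
asf_sample <- function(asf, azi, ele) {
  az <- asf$azimuth; el <- asf$elevation
  V <- asf$values
  if (asf$normalize == "peak") V <- V * asf$peak
  p <- asf$pitch
  fi <- (ele - el[1]) / p + 1
  fj <- (azi - az[1]) / p + 1
  i0 <- floor(fi); j0 <- floor(fj)
  ok <- i0 >= 1 & j0 >= 1 & i0 < length(el) & j0 < length(az)
  out <- numeric(length(azi))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]
  wi <- fi[ok] - i0; wj <- fj[ok] - j0
  ne <- length(el)
  v00 <- V[cbind(i0, j0)]; v10 <- V[cbind(i0 + 1, j0)]
  v01 <- V[cbind(i0, j0 + 1)]; v11 <- V[cbind(i0 + 1, j0 + 1)]
  out[ok] <- (1 - wi) * (1 - wj) * v00 + wi * (1 - wj) * v10 +
    (1 - wi) * wj * v01 + wi * wj * v11
  out
}

#' Build the eye's transfer stack over a calibrated fisheye canvas
#'
#' Each receptor's absolute angular sensitivity is resampled onto the pixel
#' grid through the inverse equisolid projection and weighted by the
#' per-pixel solid angle (constant under the equisolid law), giving a
#' pixel-weight map whose sum equals the receptor's total angular
#' sensitivity integral.
#'
#' @param asfs list of `angular_sensitivity` objects (one per receptor).
#' @param calib a [fisheye_calibration()] sharing the hemisphere convention
#'   of the ASFs (head frame; aperture-axis camera).
#' @return an object of class `transfer_stack`: per-receptor sparse weight
#'   maps (`idx` linear pixel indices, `w` weights), `total` sensitivities,
#'   `seeds` (projected viewing directions, pixels), `ids`, `calib`.
#' @export
build_transfer_stack <- function(asfs, calib) {
  stopifnot(inherits(calib, "fisheye_calibration"))
  asfs <- asfs[!vapply(asfs, `[[`, logical(1), "empty")]
  if (!length(asfs)) stop("no non-empty angular sensitivities supplied")
  n <- length(asfs)
  azi <- calib$pixel_azimuth; ele <- calib$pixel_elevation
  inside_idx <- which(calib$inside)
  a_in <- azi[inside_idx]; e_in <- ele[inside_idx]
  weights <- vector("list", n)
  total <- numeric(n)
  seeds <- matrix(NA_real_, n, 2)
  ids <- integer(n)
  om <- calib$solid_angle_deg2
  for (k in seq_len(n)) {
    asf <- asfs[[k]]
    ids[k] <- asf$receptor_id
    sel <- a_in >= asf$azimuth[1] & a_in <= asf$azimuth[length(asf$azimuth)] &
      e_in >= asf$elevation[1] & e_in <= asf$elevation[length(asf$elevation)]
    idx <- inside_idx[sel]
    w <- asf_sample(asf, a_in[sel], e_in[sel]) * om
    nz <- w > 0
    weights[[k]] <- list(idx = idx[nz], w = w[nz])
    total[k] <- sum(w[nz])
    vd <- viewing_direction(asf)
    seeds[k, ] <- dir_to_pixel(vd, calib)
  }
  structure(list(weights = weights, total = total, seeds = seeds, ids = ids,
                 calib = calib),
            class = "transfer_stack")
}

#' @export
print.transfer_stack <- function(x, ...) {
  cat(sprintf("<transfer_stack: %d receptors on a %d px equisolid canvas>\n",
              length(x$ids), x$calib$size))
  invisible(x)
}

#' Receptor responses to an image
#'
#' `response_r = sum_p weight_r(p) * image(p)`: linear in the image.  Pixels
#' outside the calibrated image circle never contribute.
#'
#' @param image numeric matrix (rows x columns, values typically 0..1) or a
#'   3-channel array (converted to luminance).
#' @param stack a `transfer_stack`.
#' @return named numeric vector of per-receptor responses.
#' @export
apply_filter <- function(image, stack) {
  stopifnot(inherits(stack, "transfer_stack"))
  img <- as_luminance(image)
  sz <- stack$calib$size
  if (nrow(img) != sz || ncol(img) != sz)
    stop(sprintf("image is %dx%d but calibration expects %dx%d",
                 nrow(img), ncol(img), sz, sz))
  out <- vapply(stack$weights, function(wm) sum(wm$w * img[wm$idx]), numeric(1))
  names(out) <- stack$ids
  out
}

as_luminance <- function(image) {
  if (length(dim(image)) == 3L) {
    ch <- dim(image)[3]
    if (ch >= 3)
      image <- 0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
    else image <- image[, , 1]
  }
  as.matrix(image)
}

#' Render receptor responses as a Voronoi cell image
#'
#' The output canvas shares the input calibration; each receptor paints the
#' Voronoi cell of its projected viewing direction.  Cells whose receptor's
#' total sensitivity (response to uniform white) is below `edge_threshold`
#' of the maximum are removed (field edge), and per-receptor white gains
#' `1 / response_to_white` make a uniform white input render uniformly
#' white.
#'
#' @param responses vector from [apply_filter()] on the same stack.
#' @param stack a `transfer_stack`.
#' @param edge_threshold edge-filter fraction of the maximum total
#'   sensitivity.
#' @return an object of class `receptor_image`: `values` (matrix, 0 outside
#'   the circle / removed cells), `labels`, `gains`, `surviving`, `calib`.
#' @export
render_receptor_image <- function(responses, stack, edge_threshold = 0.05) {
  stopifnot(inherits(stack, "transfer_stack"))
  keep <- stack$total >= edge_threshold * max(stack$total) &
    is.finite(stack$seeds[, 1])
  if (!any(keep)) stop("all cells removed by the edge filter")
  gains <- ifelse(stack$total > 0, 1 / stack$total, 0)
  cal <- stack$calib
  lab <- cpp_voronoi_label(stack$seeds[keep, , drop = FALSE], cal$size, cal$size,
                           cal$centre[1], cal$centre[2], cal$radius)
  vals <- responses[keep] * gains[keep]
  img <- matrix(0, cal$size, cal$size)
  nz <- lab > 0
  img[nz] <- vals[lab[nz]]
  structure(list(values = img, labels = lab, gains = gains,
                 surviving = which(keep), calib = cal),
            class = "receptor_image")
}

#' @export
print.receptor_image <- function(x, ...) {
  cat(sprintf("<receptor_image: %d surviving cells on %d px canvas, range %.3f..%.3f>\n",
              length(x$surviving), x$calib$size,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.receptor_image <- function(x, ...) {
  v <- pmin(pmax(x$values, 0), max(1, max(x$values)))
  image(t(v)[, nrow(v):1], col = gray(seq(0, 1, length.out = 256)),
        asp = 1, axes = FALSE, ...)
  invisible(x)
}

#' Generate spherical test stimuli rendered through the calibration
#'
#' Stimuli are defined on the direction sphere and rendered through the
#' equisolid projection, so angular size and angular frequency (not pixel
#' frequency) are controlled.
#'
#' Kinds: `"bessel-dot-array"` - a hexagonal array of Bessel-profile dots
#' with nearest-neighbour angular spacing `1/frequency`; `"piecewise-sine-
#' target"` - one full sine period (dark and bright flank) across a circular
#' window of diameter `width`, continuous with the 0.5 background;
#' `"difference-of-gaussians"` - a balanced centre-surround spot of overall
#' diameter `width`.
#'
#' @param kind stimulus type.
#' @param calib a [fisheye_calibration()].
#' @param frequency angular frequency (cycles/deg) for the dot array.
#' @param width target angular diameter (deg) for the targets.
#' @param centre_direction outward unit vector at the stimulus centre.
#' @param contrast amplitude (1 = full contrast about the 0.5 background).
#' @return image matrix (size x size) in [0, 1].
#' @export
make_test_pattern <- function(kind = c("bessel-dot-array", "piecewise-sine-target",
                                       "difference-of-gaussians"),
                              calib, frequency = 0.095, width = 20,
                              centre_direction = NULL, contrast = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(calib, "fisheye_calibration"))
  if (frequency <= 0 || width <= 0) stop("frequency and width must be > 0")
  sz <- calib$size
  img <- matrix(0.5, sz, sz)
  inside <- which(calib$inside)
  dirs <- angles_to_dir(calib$pixel_azimuth[inside], calib$pixel_elevation[inside])
  if (kind == "bessel-dot-array") {
    s <- 1 / frequency                      # dot spacing, deg
    # grid Nyquist: two pixels per dot radius at the circle edge
    px_per_deg <- calib$radius / 90
    if (s / 2 < 2 / px_per_deg)
      stop("frequency above the canvas Nyquist limit; use a larger canvas")
    centres <- hex_dirs_on_sphere(s, calib$axis)
    r0 <- s / 2
    best <- rep(180, length(inside))
    for (i in seq_len(nrow(centres))) {
      ca <- pmin(1, pmax(-1, dirs %*% centres[i, ]))
      best <- pmin(best, acos(ca) * 180 / pi)
    }
    prof <- ifelse(best < r0, besselJ(2.404826 * best / r0, 0), 0)
    img[inside] <- 0.5 + 0.5 * contrast * prof
  } else {
    c0 <- if (is.null(centre_direction)) calib$axis else {
      v <- as.numeric(centre_direction); v / sqrt(sum(v^2))
    }
    # horizontal tangent at the stimulus centre (in the head horizontal plane)
    th <- c(-c0[2], c0[1], 0)
    if (sum(th^2) < 1e-12) th <- c(0, 1, 0)
    th <- th / sqrt(sum(th^2))
    ca <- pmin(1, pmax(-1, dirs %*% c0))
    ps <- acos(ca) * 180 / pi               # angular distance to centre
    u <- asin(pmin(1, pmax(-1, dirs %*% th))) * 180 / pi  # horizontal offset
    if (kind == "piecewise-sine-target") {
      sel <- ps <= width / 2
      img[inside][sel] <- 0.5 + 0.5 * contrast * sin(2 * pi * u[sel] / width)
    } else {
      sc <- width / 6; ss <- width / 3
      k <- (sc / ss)^2                      # balances centre and surround
      val <- contrast * (exp(-ps^2 / (2 * sc^2)) - k * exp(-ps^2 / (2 * ss^2)))
      img[inside] <- pmin(1, pmax(0, 0.5 + val))
    }
  }
  img
}

# hexagonal grid of directions on the sphere around `axis`, spacing s (deg)
hex_dirs_on_sphere <- function(s, axis) {
  delta <- s * pi / 180
  chart <- hex_lattice(pi / 2, delta)      # cover the hemisphere
  th <- sqrt(rowSums(chart^2))
  psi <- atan2(chart[, 2], chart[, 1])
  loc <- cbind(sin(th) * cos(psi), sin(th) * sin(psi), cos(th))
  loc %*% t(rotation_to_z(as.numeric(axis)))
}

#' Michelson modulation of receptor responses over a region
#'
#' `(max - min) / (max + min)` of (typically white-normalized) responses of
#' the receptors in `region`.
#'
#' @param responses named response vector from [apply_filter()].
#' @param region receptor ids to include.
#' @return Michelson fraction in [0, 1].
#' @export
pattern_modulation <- function(responses, region = names(responses)) {
  v <- responses[as.character(region)]
  if (!length(v) || all(is.na(v))) stop("empty region")
  if (all(v == 0)) stop("all responses zero")
  (max(v) - min(v)) / (max(v) + min(v))
}

#' Filter a sequence of frames through the eye
#'
#' Applies the transfer stack and Voronoi rendering to each frame in order,
#' streaming one frame at a time.
#'
#' @param frames list of image matrices (shared calibration geometry).
#' @param stack a `transfer_stack`.
#' @param edge_threshold see [render_receptor_image()].
#' @return list of `receptor_image` objects, in frame order.
#' @export
filter_video <- function(frames, stack, edge_threshold = 0.05) {
  stopifnot(is.list(frames), length(frames) >= 1)
  d0 <- dim(as_luminance(frames[[1]]))
  lapply(frames, function(fr) {
    if (!identical(dim(as_luminance(fr)), d0))
      stop("frame size changed mid-stream")
    render_receptor_image(apply_filter(fr, stack), stack, edge_threshold)
  })
}

#' Read an image file (PNG or TIFF)
#'
#' @param path image path; `.png`, `.tif`/`.tiff` are supported.
#' @return numeric array as returned by the decoder.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return(png::readPNG(path))
  if (ext %in% c("tif", "tiff")) return(tiff::readTIFF(path))
  if (ext %in% c("jpg", "jpeg"))
    stop("JPEG is not supported; convert to PNG or TIFF")
  stop("unsupported image format: ", ext)
}

#' Write a matrix or receptor image to PNG
#'
#' @param x numeric matrix in [0, 1] or a `receptor_image`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  if (inherits(x, "receptor_image")) x <- x$values
  x <- pmin(pmax(as.matrix(x), 0), 1)
  png::writePNG(x, path)
  invisible(path)
}
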