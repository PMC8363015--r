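# Synthetic eye models: a parametric velvet-worm-like eye plus analytically
# tractable reference eyes (ball lens, concentric shells) used as oracles.

#' Geodesic sphere mesh
#'
#' Subdivided icosahedron with geodesic frequency `freq`: 20 * freq^2 faces,
#' vertices projected to the unit sphere, consistently oriented outward.
#'
#' @param freq geodesic frequency (>= 1).
#' @param radius sphere radius (um).
#' @param centre length-3 centre.
#' @param label mesh label.
#' @return a [triangle_mesh()].
#' @export
geodesic_sphere <- function(freq = 16L, radius = 1, centre = c(0, 0, 0),
                            label = "sphere") {
  freq <- as.integer(freq)
  stopifnot(freq >= 1L)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  verts <- list(); faces <- list()
  key_env <- new.env(hash = TRUE, parent = emptyenv())
  nv <- 0L
  get_vid <- function(p) {
    key <- paste(sprintf("%.9f", p), collapse = ",")
    id <- key_env[[key]]
    if (is.null(id)) {
      nv <<- nv + 1L
      verts[[nv]] <<- p
      key_env[[key]] <- nv
      id <- nv
    }
    id
  }
  for (t in seq_len(nrow(f))) {
    A <- v[f[t, 1], ]; B <- v[f[t, 2], ]; C <- v[f[t, 3], ]
    # barycentric grid of (freq+1)(freq+2)/2 points on the face
    vid <- matrix(NA_integer_, freq + 1L, freq + 1L)
    for (i in 0:freq) for (j in 0:(freq - i)) {
      p <- ((freq - i - j) * A + i * B + j * C) / freq
      p <- p / sqrt(sum(p^2))
      vid[i + 1L, j + 1L] <- get_vid(p)
    }
    for (i in 0:(freq - 1L)) for (j in 0:(freq - 1L - i)) {
      faces[[length(faces) + 1L]] <-
        c(vid[i + 1L, j + 1L], vid[i + 2L, j + 1L], vid[i + 1L, j + 2L])
      if (i + j < freq - 1L)
        faces[[length(faces) + 1L]] <-
          c(vid[i + 2L, j + 1L], vid[i + 2L, j + 2L], vid[i + 1L, j + 2L])
    }
  }
  vm <- do.call(rbind, verts)
  vm <- vm * radius
  vm <- sweep(vm, 2, as.numeric(centre), `+`)
  m <- triangle_mesh(vm, do.call(rbind, faces), label = label)
  orient_outward(m)
}

orient_outward <- function(mesh) {
  if (mesh_signed_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

# Closed surface of revolution about the x axis.  `profile` is an m x 2
# matrix of (x, r) with r = 0 at the first and last point (the poles).
revolve_mesh <- function(profile, n_seg = 64L, label = "other") {
  m <- nrow(profile)
  stopifnot(m >= 3L, abs(profile[1, 2]) < 1e-12, abs(profile[m, 2]) < 1e-12)
  ang <- 2 * pi * (seq_len(n_seg) - 1L) / n_seg
  verts <- matrix(profile[1, c(1, 2, 2)] * c(1, 0, 0), 1, 3)
  ring_ids <- vector("list", m)
  ring_ids[[1]] <- rep(1L, n_seg)
  nv <- 1L
  for (i in 2:(m - 1L)) {
    ring <- cbind(profile[i, 1], profile[i, 2] * cos(ang), profile[i, 2] * sin(ang))
    verts <- rbind(verts, ring)
    ring_ids[[i]] <- nv + seq_len(n_seg)
    nv <- nv + n_seg
  }
  verts <- rbind(verts, c(profile[m, 1], 0, 0))
  ring_ids[[m]] <- rep(nv + 1L, n_seg)
  faces <- list()
  nxt <- function(k) if (k == n_seg) 1L else k + 1L
  for (i in 1:(m - 1L)) {
    a <- ring_ids[[i]]; b <- ring_ids[[i + 1L]]
    for (k in seq_len(n_seg)) {
      k2 <- nxt(k)
      if (i == 1L) {
        faces[[length(faces) + 1L]] <- c(a[1], b[k], b[k2])
      } else if (i == m - 1L) {
        faces[[length(faces) + 1L]] <- c(a[k], b[1], a[k2])
      } else {
        faces[[length(faces) + 1L]] <- c(a[k], b[k], b[k2])
        faces[[length(faces) + 1L]] <- c(a[k], b[k2], a[k2])
      }
    }
  }
  m2 <- triangle_mesh(verts, do.call(rbind, faces), label = label)
  orient_outward(m2)
}

#' Parameters of the synthetic velvet-worm eye
#'
#' All lengths in um for a 100 um eye and scaled linearly with
#' `diameter / 100`.  The generator encodes the published qualitative
#' constraints of the real eye - a smooth protruding cornea with its own
#' radius of curvature, a homogeneous biconvex lens directly behind it, a
#' retina abutting the lens with no vitreous gap, and a deep posterior pouch
#' serving the forward visual field - with every free dimension an explicit,
#' documented parameter.
#'
#' @param diameter outer eye diameter (um); the corneal apex sits at
#'   `diameter / 2` on the aperture axis.
#' @param cornea_radius radius of curvature of the corneal bulge (um).
#' @param cornea_thickness corneal shell thickness (um).
#' @param cornea_arc angular extent (deg) of the corneal cap about its own
#'   centre of curvature.
#' @param cup_half_angle opening half-angle (deg, from the eye origin) of
#'   the surrounding screening-pigment cup; rays outside it are occluded.
#' @param cup_radius inner radius (um) of the pigment cup.
#' @param lens_arc angular extent (deg) of the front lens surface about the
#'   corneal centre of curvature.
#' @param lens_back_pole x position of the rear lens pole (um).
#' @param retina_centre_x x position of the retinal shape centre (um).
#' @param retina_rho0 base radial extent of the retina about its centre (um).
#' @param pouch_amp fractional radial deepening at the pouch centre.
#' @param pouch_sigma angular width (deg) of the pouch bump.
#' @param central_amp,central_sigma fractional radial extension and angular
#'   width (deg) of the central back wall (opposite the aperture axis);
#'   pushes the laterally-viewing receptors away from the nodal region
#'   without thickening the absorbing layer elsewhere.
#' @param pouch_azimuth azimuth (deg) of the pouch centre in the horizontal
#'   plane; defaults to opposite the forward viewing direction
#'   (`180 + forward_angle`), where rays from the forward field land.
#' @param flatten vertical flattening coefficient (fraction of radius removed
#'   at the vertical poles).
#' @param window_inset depth (um) by which the retinal window is inset into
#'   the lens so the two volumes overlap rather than sharing coincident
#'   surfaces.
#' @param forward_angle angle (deg) between the aperture axis and the
#'   forward (acute-zone) viewing direction, in the horizontal plane.
#' @param receptor_spacing nominal receptor centre spacing (um).
#' @param receptor_r_base,receptor_r_apex,receptor_r_core receptor outer
#'   radii at base and apex and non-absorbing core radius (um); the wide,
#'   overlapping defaults emulate interdigitating microvilli and keep the
#'   deep pouch interior covered by absorbing material.
#' @param retina_coverage,retina_coverage_v horizontal and vertical angular
#'   radii (deg) of the receptor-bearing retinal cap about the central back
#'   direction; the wall beyond it is bare screening pigment (perikaryal
#'   region).  The smaller vertical coverage makes the vertical field of
#'   view narrower than the horizontal one.
#' @param freq_retina geodesic frequency of the retina mesh.
#' @param n_seg azimuthal segments of the revolved cornea/lens/cup meshes.
#' @return a list of class `eye_params`.
#' @export
eye_params <- function(diameter = 100, cornea_radius = 40,
                       cornea_thickness = 4, cornea_arc = 95,
                       cup_half_angle = 66, cup_radius = 58,
                       lens_arc = 85, lens_back_pole = 0,
                       retina_centre_x = -5, retina_rho0 = 14,
                       pouch_amp = 2.5, pouch_sigma = 26,
                       pouch_azimuth = -125, central_amp = 0,
                       central_sigma = 25, flatten = 0.14,
                       window_inset = 0.25, forward_angle = 45,
                       receptor_spacing = 2.5, retina_coverage = 105,
                       retina_coverage_v = 88,
                       receptor_r_base = 3.0, receptor_r_apex = 2.2,
                       receptor_r_core = 0.5, freq_retina = 20L,
                       n_seg = 96L) {
  p <- list(diameter = diameter, cornea_radius = cornea_radius,
            cornea_thickness = cornea_thickness, cornea_arc = cornea_arc,
            cup_half_angle = cup_half_angle, cup_radius = cup_radius,
            lens_arc = lens_arc, lens_back_pole = lens_back_pole,
            retina_centre_x = retina_centre_x, retina_rho0 = retina_rho0,
            pouch_amp = pouch_amp, pouch_sigma = pouch_sigma,
            pouch_azimuth = if (is.null(pouch_azimuth)) 180 + forward_angle
                            else pouch_azimuth,
            central_amp = central_amp, central_sigma = central_sigma,
            flatten = flatten, window_inset = window_inset,
            forward_angle = forward_angle,
            receptor_spacing = receptor_spacing,
            retina_coverage = retina_coverage,
            receptor_r_base = receptor_r_base,
            receptor_r_apex = receptor_r_apex,
            receptor_r_core = receptor_r_core,
            retina_coverage_v = retina_coverage_v,
            freq_retina = as.integer(freq_retina), n_seg = as.integer(n_seg))
  if (p$diameter <= 0 || p$pouch_amp < 0 || p$cornea_radius <= 0)
    stop("invalid eye parameters")
  class(p) <- "eye_params"
  p
}

sphere_arc <- function(R, th0, th1, n) {
  th <- seq(th0, th1, length.out = n)
  cbind(R * cos(th), R * sin(th))
}

sweep_x <- function(profile, dx) {
  profile[, 1] <- profile[, 1] + dx
  profile
}

#' Generate the synthetic velvet-worm eye
#'
#' Builds four watertight meshes: a protruding corneal shell, a homogeneous
#' biconvex lens whose external and internal curvatures both contribute to
#' focusing, a retinal volume whose front face is inset slightly into the
#' lens (no vitreous gap) and whose back wall carries a deep pouch opposite
#' the forward viewing direction, and a surrounding screening-pigment cup
#' open only over the optical aperture.  Generation is fully deterministic.
#'
#' @param params an [eye_params()] list.
#' @return an object of class `eye_model` with elements `meshes` (named list
#'   of [triangle_mesh()]), `media` (data.frame: label, role, priority,
#'   index, window_from), `aperture_axis`, `forward`, `params`.
#' @export
make_velvetworm_eye <- function(params = eye_params()) {
  stopifnot(inherits(params, "eye_params"))
  s <- params$diameter / 100
  apex_x <- 50 * s
  R_co <- params$cornea_radius * s
  cc_x <- apex_x - R_co                       # corneal centre of curvature
  R_ci <- R_co - params$cornea_thickness * s
  th_co <- params$cornea_arc * pi / 180

  # cornea: outer cap + rim annulus + inner cap, about (cc_x, 0, 0)
  n_arc <- 40L
  prof_co <- rbind(sweep_x(sphere_arc(R_co, 0, th_co, n_arc), cc_x),
                   sweep_x(sphere_arc(R_ci, th_co, 0, n_arc), cc_x))
  cornea <- revolve_mesh(prof_co, n_seg = params$n_seg, label = "cornea")

  # lens: front cap just inside the cornea (overlapping it by window_inset),
  # rear cap through the shared rim to the back pole
  R_lf <- R_ci + params$window_inset * s
  th_lf <- params$lens_arc * pi / 180
  x_rim <- cc_x + R_lf * cos(th_lf); r_rim <- R_lf * sin(th_lf)
  x_lb <- params$lens_back_pole * s
  a <- x_rim - x_lb
  if (a <= 0) stop("lens_back_pole must lie behind the lens rim")
  R_lb <- (a^2 + r_rim^2) / (2 * a)
  xc <- x_lb + R_lb
  psi_rim <- acos(pmin(1, pmax(-1, (x_rim - xc) / R_lb)))
  psi <- seq(psi_rim, pi, length.out = 36L)
  prof_le <- rbind(sweep_x(sphere_arc(R_lf, 0, th_lf, 30L), cc_x),
                   cbind(xc + R_lb * cos(psi), R_lb * sin(psi)))
  lens <- revolve_mesh(prof_le, n_seg = params$n_seg, label = "lens")

  # screening-pigment cup: spherical shell open over the aperture cone
  th_cup <- params$cup_half_angle * pi / 180
  cup_in <- params$cup_radius * s; cup_out <- cup_in + 1.4 * s
  prof_cup <- rbind(sphere_arc(cup_in, pi, th_cup, 48L),
                    sphere_arc(cup_out, th_cup, pi, 48L))
  cup <- revolve_mesh(prof_cup, n_seg = params$n_seg, label = "pigment_cup")

  # retina: deformed geodesic sphere about (retina_centre_x, 0, 0)
  fwd_ang <- params$forward_angle * pi / 180
  forward <- c(cos(fwd_ang), sin(fwd_ang), 0)
  pz <- (if (is.null(params$pouch_azimuth)) 180 + params$forward_angle
         else params$pouch_azimuth) * pi / 180
  pouch_dir <- c(cos(pz), sin(pz), 0)
  O_ret <- c(params$retina_centre_x * s, 0, 0)
  base_sph <- geodesic_sphere(params$freq_retina, 1, c(0, 0, 0), "retina_wall")
  w <- base_sph$vertices
  rho0 <- params$retina_rho0 * s
  psi_p <- acos(pmin(1, pmax(-1, w %*% pouch_dir)))
  sig <- params$pouch_sigma * pi / 180
  psi_c <- acos(pmin(1, pmax(-1, w %*% c(-1, 0, 0))))
  sigc <- params$central_sigma * pi / 180
  camp <- if (is.null(params$central_amp)) 0 else params$central_amp
  rho_back <- rho0 * (1 + params$pouch_amp * exp(-(psi_p / sig)^2) +
                        camp * exp(-(psi_c / sigc)^2)) *
    (1 - params$flatten * w[, 3]^2)
  # window: distance from O_ret to the rear lens surface, inset into the lens
  oc <- O_ret - c(xc, 0, 0)
  b_half <- as.numeric(w %*% oc)
  cc <- sum(oc^2) - R_lb^2
  disc <- b_half^2 - cc
  t_near <- ifelse(disc >= 0, -b_half - sqrt(pmax(disc, 0)), NA_real_)
  px <- O_ret[1] + t_near * w[, 1]
  is_window <- !is.na(t_near) & t_near > 0 & px <= (x_rim - 1.0 * s)
  rho <- as.numeric(rho_back)
  rho[is_window] <- pmin(rho[is_window],
                         t_near[is_window] + params$window_inset * s)
  verts <- sweep(w * rho, 2, O_ret, `+`)
  # clamp inside the pigment cup and outside the cornea's inner shell
  rad <- sqrt(rowSums(verts^2))
  lim <- cup_in - 0.6 * s
  over <- rad > lim
  verts[over, ] <- verts[over, ] * (lim / rad[over])
  retina <- triangle_mesh(verts, base_sph$faces, label = "retina_wall")
  retina <- orient_outward(retina)

  media <- data.frame(
    label = c("cornea", "lens", "retina_wall", "pigment_cup"),
    role = c("refract", "refract", "retina", "absorber"),
    priority = c(1L, 2L, 3L, 0L),
    index = c(NA_real_, NA_real_, NA_real_, NA_real_),
    window_from = c(NA, NA, "lens", NA),
    stringsAsFactors = FALSE)
  structure(list(meshes = list(cornea = cornea, lens = lens,
                               retina_wall = retina, pigment_cup = cup),
                 media = media,
                 aperture_axis = c(1, 0, 0), forward = forward,
                 params = params, kind = "velvetworm"),
            class = "eye_model")
}

#' Ball-lens reference eye
#'
#' A single homogeneous spherical lens in air with a distant absorbing
#' detector shell.  The paraxial back focal distance is known in closed form,
#' `BFD = R (2 - n) / (2 (n - 1))`, making this the oracle geometry for
#' validating refraction tracing.
#'
#' @param radius lens radius (um).
#' @param n_lens lens refractive index (> 1).
#' @param detector_radius radius of the absorbing shell (um).
#' @param freq geodesic frequency of the lens mesh.
#' @return an `eye_model`.
#' @export
make_ball_lens_eye <- function(radius = 50, n_lens = 1.5,
                               detector_radius = 4 * radius, freq = 26L) {
  stopifnot(radius > 0, n_lens > 1)
  lens <- geodesic_sphere(freq, radius, c(0, 0, 0), "lens")
  det <- geodesic_sphere(8L, detector_radius, c(0, 0, 0), "retina_wall")
  # the detector is transparent on entry (index 1, same as air) and absorbs
  # rays leaving its interior, so it captures every ray after the lens
  media <- data.frame(label = c("lens", "retina_wall"),
                      role = c("refract", "retina"),
                      priority = c(2L, 1L),
                      index = c(n_lens, 1.0),
                      window_from = c(NA, NA),
                      stringsAsFactors = FALSE)
  structure(list(meshes = list(lens = lens, retina_wall = det), media = media,
                 aperture_axis = c(1, 0, 0), forward = c(1, 0, 0),
                 params = list(radius = radius, n_lens = n_lens,
                               detector_radius = detector_radius),
                 kind = "ball_lens"),
            class = "eye_model")
}

#' Concentric-shell reference eye
#'
#' Nested concentric spheres (cornea, lens, retina by default) with full
#' rotational symmetry about any axis through the centre; used for
#' end-to-end symmetry checks of the tracing and sensitivity pipeline.
#'
#' @param radii strictly decreasing sphere radii (um), outermost first.
#' @param indices matching refractive indices; the innermost sphere is the
#'   retinal volume.
#' @param freq geodesic frequency of the sphere meshes.
#' @return an `eye_model`.
#' @export
make_concentric_eye <- function(radii = c(50, 40, 30),
                                indices = c(1.4, 1.44, 1.36), freq = 16L) {
  if (length(radii) < 2L || any(diff(radii) >= 0))
    stop("radii must be strictly decreasing")
  if (length(indices) != length(radii))
    stop("indices must match radii")
  n <- length(radii)
  labels <- c("cornea", "lens", "retina_wall")
  if (n > 3) labels <- c(paste0("shell", seq_len(n - 2)), "lens", "retina_wall")
  labels <- labels[seq_len(n)]
  labels[n] <- "retina_wall"
  meshes <- lapply(seq_len(n), function(i)
    geodesic_sphere(freq, radii[i], c(0, 0, 0), labels[i]))
  names(meshes) <- labels
  media <- data.frame(label = labels,
                      role = c(rep("refract", n - 1L), "retina"),
                      priority = seq_len(n),
                      index = indices,
                      window_from = c(rep(NA, n - 1L), labels[n - 1L]),
                      stringsAsFactors = FALSE)
  structure(list(meshes = meshes, media = media,
                 aperture_axis = c(1, 0, 0), forward = c(1, 0, 0),
                 params = list(radii = radii, indices = indices),
                 kind = "concentric"),
            class = "eye_model")
}

#' @export
print.eye_model <- function(x, ...) {
  cat(sprintf("<eye_model '%s'>\n", x$kind))
  for (nm in names(x$meshes)) {
    m <- x$meshes[[nm]]
    cat(sprintf("  %-12s %6d faces\n", nm, nrow(m$faces)))
  }
  cat(sprintf("  aperture axis (%.2f, %.2f, %.2f) | forward (%.2f, %.2f, %.2f)\n",
              x$aperture_axis[1], x$aperture_axis[2], x$aperture_axis[3],
              x$forward[1], x$forward[2], x$forward[3]))
  invisible(x)
}

eye_bounding_radius <- function(eye) {
  max(vapply(eye$meshes, function(m) max(sqrt(rowSums(m$vertices^2))), numeric(1)))
}

eye_centroid <- function(eye) {
  allv <- do.call(rbind, lapply(eye$meshes, `[[`, "vertices"))
  colMeans(allv)
}

# retinal light-path depth (um) for an outward field direction `view_dir`:
# total chord length through the retinal volume of the central ray arriving
# from that direction (through the eye origin)
retinal_depth <- function(eye, view_dir) {
  stopifnot(inherits(eye, "eye_model"))
  ret <- eye$meshes$retina_wall
  d <- as.numeric(view_dir); d <- d / sqrt(sum(d^2))
  idx <- build_octree(ret)
  R <- 4 * eye_bounding_radius(eye)
  ts <- numeric(0)
  t0 <- 0
  for (i in 1:32) {
    h <- intersect_ray(d * (R - t0 - 1e-6), -d, idx)$t
    if (is.na(h)) break
    t0 <- t0 + 1e-6 + h
    ts <- c(ts, t0)
  }
  if (length(ts) < 2) return(0)
  # successive hit pairs bound the inside chords
  sum(ts[seq(2, length(ts), by = 2)] - ts[seq(1, length(ts) - 1, by = 2)])
}

#' Write an eye model to disk (STL meshes + JSON manifest)
#'
#' @param eye an `eye_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eye_model <- function(eye, dir) {
  stopifnot(inherits(eye, "eye_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(eye$meshes)) {
    f <- file.path(dir, paste0(nm, ".stl"))
    write_stl(eye$meshes[[nm]], f)
    files[nm] <- basename(f)
  }
  manifest <- list(kind = eye$kind, unit = "um",
                   meshes = as.list(files),
                   media = eye$media,
                   aperture_axis = eye$aperture_axis,
                   forward = eye$forward,
                   params = eye$params[!vapply(eye$params, is.null, logical(1))])
  jsonlite::write_json(manifest, file.path(dir, "eye_model.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read an eye model written by [write_eye_model()]
#'
#' @param dir directory containing `eye_model.json` and the STL meshes.
#' @return an `eye_model`.
#' @export
read_eye_model <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "eye_model.json"), simplifyVector = TRUE)
  meshes <- lapply(names(man$meshes), function(nm)
    read_stl(file.path(dir, man$meshes[[nm]]), label = nm))
  names(meshes) <- names(man$meshes)
  media <- as.data.frame(man$media, stringsAsFactors = FALSE)
  media$window_from <- as.character(media$window_from)
  media$window_from[media$window_from %in% c("NA", "")] <- NA
  params <- man$params
  if (identical(man$kind, "velvetworm")) class(params) <- "eye_params"
  structure(list(meshes = meshes, media = media,
                 aperture_axis = as.numeric(man$aperture_axis),
                 forward = as.numeric(man$forward),
                 params = params, kind = man$kind),
            class = "eye_model")
}
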