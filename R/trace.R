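# Multi-surface ray tracing through an eye model.
#
# Volume membership along a ray is tracked by crossing parity over the
# watertight meshes; where volumes deliberately overlap (the lens is inset
# into the cornea, the retinal window into the lens) the medium is the
# highest-priority volume containing the segment, which makes coincident or
# interpenetrating boundaries numerically robust.  Rays refract by Snell's
# law at every index step, reflect specularly on total internal reflection
# (with an event cap), and terminate on screening pigment: the retina mesh
# absorbs rays arriving from any medium other than its window medium, and
# absorbs all rays leaving the retinal volume.

role_code <- c(refract = 0L, retina = 1L, absorber = 2L)

resolve_media <- function(eye, config) {
  med <- eye$media
  idx <- med$index
  lookup <- c(cornea = config$n_cornea, lens = config$n_lens,
              retina_wall = config$n_retina)
  for (i in seq_len(nrow(med))) {
    if (is.na(idx[i])) {
      idx[i] <- if (med$label[i] %in% names(lookup)) lookup[[med$label[i]]] else config$n_air
    }
  }
  wf <- integer(nrow(med))
  for (i in seq_len(nrow(med))) {
    w <- med$window_from[i]
    wf[i] <- if (is.na(w)) -2L else (match(w, med$label) - 1L)
  }
  list(role = unname(role_code[med$role]), index = idx,
       priority = as.integer(med$priority), window_from = wf)
}

build_scene <- function(eye, config, receptors = NULL,
                        leaf_capacity = 32L, max_depth = 10L) {
  stopifnot(inherits(eye, "eye_model"), inherits(config, "optical_config"))
  cmb <- combine_meshes(eye$meshes)
  mm <- resolve_media(eye, config)
  ptr <- cpp_scene_build(cmb$vertices, cmb$faces, cmb$mesh_id,
                         mm$role, mm$index, mm$priority, mm$window_from,
                         config$n_air, as.integer(leaf_capacity),
                         as.integer(max_depth), config$smooth_normals)
  if (!is.null(receptors)) {
    stopifnot(inherits(receptors, "receptor_set"))
    cpp_scene_set_receptors(ptr,
                            as.matrix(receptors[, c("base_x", "base_y", "base_z")]),
                            as.matrix(receptors[, c("apex_x", "apex_y", "apex_z")]),
                            receptors$r_base, receptors$r_apex, receptors$r_core,
                            config$alpha, config$step)
  }
  list(ptr = ptr, labels = cmb$labels, eye = eye, config = config,
       n_receptors = if (is.null(receptors)) 0L else nrow(receptors))
}

#' Trace a single ray through an eye model
#'
#' Records the full piecewise-linear path: contiguous segments with their
#' media, the surface events (refraction, total internal reflection, no-op
#' index matches, termination), and the termination reason.
#'
#' @param origin ray origin (um), outside all eye volumes.
#' @param direction unit propagation direction.
#' @param eye an `eye_model`.
#' @param config an [optical_config()].
#' @param receptors optional `receptor_set`; when given, Beer-Lambert
#'   absorption is marched along retinal segments and reported per receptor.
#' @return an object of class `ray_path`: list with `segments` (data.frame
#'   x0..z1, length, medium label), `events`, `reason` (one of `"exited"`,
#'   `"absorbed_at_pigment"`, `"tir_terminated"`, `"max_events"`),
#'   `power_remaining`, and `absorption` (per-receptor, if receptors given).
#' @export
trace_ray <- function(origin, direction, eye, config = optical_config(),
                      receptors = NULL) {
  sc <- build_scene(eye, config, receptors)
  d <- as.numeric(direction); d <- d / sqrt(sum(d^2))
  res <- cpp_trace_beam(sc$ptr, matrix(as.numeric(origin), 1, 3), d, 1.0,
                        config$max_events, TRUE,
                        if (config$tir == "terminate") 1L else 0L)
  p <- res$paths[[1]]
  as_ray_path(p, sc$labels, res$absorption)
}

as_ray_path <- function(p, labels, absorption = NULL) {
  seg <- as.data.frame(p$segments)
  if (nrow(seg)) {
    seg$length <- sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2 + (seg$z1 - seg$z0)^2)
    seg$medium <- c("air", labels)[seg$medium + 1]
  }
  ev <- as.data.frame(p$events)
  if (nrow(ev)) {
    ev$kind <- c("refract", "tir_reflect", "index_match", "terminate")[ev$kind + 1]
    ev$mesh <- labels[ev$mesh]
  }
  reasons <- c("exited", "absorbed_at_pigment", "tir_terminated", "max_events")
  structure(list(segments = seg, events = ev,
                 reason = reasons[p$reason],
                 power_remaining = p$power_remaining,
                 absorption = absorption),
            class = "ray_path")
}

#' @export
print.ray_path <- function(x, ...) {
  cat(sprintf("<ray_path: %d segments, %d events, reason '%s'>\n",
              nrow(x$segments), nrow(x$events), x$reason))
  invisible(x)
}

#' Trace parallel beams from directions spanning the visual field
#'
#' One parallel bundle of `config$rays_per_beam` rays (radius
#' `config$beam_radius`) is traced for each incident direction.  Directions
#' are outward unit vectors (where the light comes from); each beam
#' propagates along the negated direction and is aimed at the eye centroid
#' from a plane tangent to a sphere of twice the eye's bounding radius.
#'
#' @param eye an `eye_model`.
#' @param config an [optical_config()].
#' @param directions optional n x 3 matrix of outward unit directions;
#'   defaults to [sample_hemisphere()] of `config$n_directions` about the
#'   aperture axis.
#' @param receptors optional `receptor_set` to accumulate absorption into
#'   (see [trace_absorb()] for the common fused call).
#' @param record_paths keep every ray path (memory-heavy; only sensible for
#'   small runs).
#' @param progress print progress every ~10%.
#' @return an object of class `trace_set`: `directions`, per-beam `stats`
#'   (rays hitting the eye, rays reaching the retinal volume, power sums),
#'   `beam_radius`, `n_rays`, the `eye`, and optionally `paths` and an
#'   `absorption` matrix (receptor x direction).
#' @export
trace_field <- function(eye, config = optical_config(), directions = NULL,
                        receptors = NULL, record_paths = FALSE,
                        progress = FALSE) {
  if (is.null(directions))
    directions <- sample_hemisphere(config$n_directions, eye$aperture_axis)
  directions <- as.matrix(directions)
  sc <- build_scene(eye, config, receptors)
  centroid <- eye_centroid(eye)
  standoff <- 2 * eye_bounding_radius(eye)
  nd <- nrow(directions)
  nrec <- sc$n_receptors
  absorb <- if (nrec > 0) matrix(0, nrec, nd) else NULL
  stats <- data.frame(n_rays = integer(nd), n_hit = integer(nd),
                      n_entered_retina = integer(nd),
                      power_exited = numeric(nd), power_pigment = numeric(nd),
                      power_absorbed = numeric(nd), power_lost = numeric(nd))
  paths <- if (record_paths) vector("list", nd) else NULL
  tirm <- if (config$tir == "terminate") 1L else 0L
  for (i in seq_len(nd)) {
    beam <- make_beam(-directions[i, ], centroid, config$beam_radius,
                      config$rays_per_beam, standoff)
    res <- cpp_trace_beam(sc$ptr, beam$origins, beam$direction,
                          1 / beam$n_rays, config$max_events, record_paths, tirm)
    if (nrec > 0) absorb[, i] <- res$absorption
    stats[i, ] <- list(res$n_rays, res$n_hit, res$n_entered_retina,
                       res$power_exited, res$power_pigment,
                       res$power_absorbed, res$power_lost)
    if (record_paths)
      paths[[i]] <- lapply(res$paths, as_ray_path, labels = sc$labels)
    if (progress && (i %% max(1, nd %/% 10) == 0))
      message(sprintf("traced %d / %d directions", i, nd))
  }
  structure(list(directions = directions, stats = stats,
                 beam_radius = config$beam_radius,
                 n_rays = config$rays_per_beam, eye = eye, config = config,
                 paths = paths, absorption = absorb,
                 receptor_ids = if (nrec > 0) receptors$id else NULL),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set: %d directions x %d rays (beam radius %.1f um)>\n",
              nrow(x$directions), x$n_rays, x$beam_radius))
  cat(sprintf("  mean fraction of rays reaching retina: %.3f\n",
              mean(x$stats$n_entered_retina / x$stats$n_rays)))
  if (!is.null(x$absorption))
    cat(sprintf("  absorption accumulated for %d receptors\n", nrow(x$absorption)))
  invisible(x)
}

#' Trace the visual field and accumulate receptor absorption in one pass
#'
#' Fused version of [trace_field()] + [accumulate_absorption()]: traces every
#' beam and marches Beer-Lambert absorption into the receptors without
#' retaining per-ray paths, so large runs stay within constant memory.
#'
#' @inheritParams trace_field
#' @param receptors a `receptor_set` from [place_receptors()].
#' @return an `absorption_table`: receptor x direction matrix of absorbed
#'   beam-power fractions, with the trace metadata attached as attributes
#'   (`directions`, `stats`, `beam_radius`, `n_rays`, `receptors`).
#' @export
trace_absorb <- function(eye, receptors, config = optical_config(),
                         directions = NULL, progress = FALSE) {
  stopifnot(inherits(receptors, "receptor_set"))
  ts <- trace_field(eye, config, directions, receptors,
                    record_paths = FALSE, progress = progress)
  absorption_table(ts$absorption, ts$directions, ts$stats, receptors,
                   beam_radius = ts$beam_radius, n_rays = ts$n_rays)
}
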