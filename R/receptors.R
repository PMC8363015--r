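# Photoreceptor geometry and Beer-Lambert absorption.
#
# Receptors are absorbing truncated cones with a non-absorbing central core
# (cylinder), base on the back retinal wall, apex at the lens-facing retinal
# surface.  Neighbouring cones overlap at depth, emulating interdigitating
# microvilli; absorbed power at a marching step is split equally among all
# receptors containing that step.

#' Construct a receptor set
#'
#' @param base n x 3 matrix of base centres (um, on the back retinal wall).
#' @param apex n x 3 matrix of apex points (um, toward the lens).
#' @param r_base outer cone radius at the base (um).
#' @param r_apex outer cone radius at the apex (um).
#' @param r_core non-absorbing core (cylinder) radius (um).
#' @return a data.frame of class `receptor_set`.
#' @export
receptor_set <- function(base, apex, r_base = 2.0, r_apex = 0.5, r_core = 0.5) {
  base <- as.matrix(base); apex <- as.matrix(apex)
  stopifnot(ncol(base) == 3L, ncol(apex) == 3L, nrow(base) == nrow(apex))
  n <- nrow(base)
  r_base <- rep_len(r_base, n); r_apex <- rep_len(r_apex, n)
  r_core <- rep_len(r_core, n)
  len <- sqrt(rowSums((base - apex)^2))
  if (any(len <= 0)) stop("apex must differ from base")
  if (any(r_base <= r_core) || any(r_core < 0))
    stop("need r_base > r_core >= 0")
  out <- data.frame(id = seq_len(n),
                    base_x = base[, 1], base_y = base[, 2], base_z = base[, 3],
                    apex_x = apex[, 1], apex_y = apex[, 2], apex_z = apex[, 3],
                    r_base = r_base, r_apex = r_apex, r_core = r_core,
                    length = len)
  class(out) <- c("receptor_set", "data.frame")
  out
}

#' @export
print.receptor_set <- function(x, ...) {
  cat(sprintf("<receptor_set: %d receptors, mean length %.1f um, base radius %.2f um>\n",
              nrow(x), mean(x$length), mean(x$r_base)))
  invisible(as.data.frame(x))
}

#' Place photoreceptors on a retinal surface
#'
#' Base centres are laid out in an approximately hexagonal pattern with mean
#' nearest-neighbour distance close to `spacing`.  For a closed (watertight)
#' retina mesh, a hexagonal lattice in an azimuthal-equidistant angular chart
#' about the retina's interior centre is projected radially onto the back
#' (pigment-side) wall; a second pass rescales the lattice so the realized
#' mean spacing matches the request.  Receptor apices are found by casting
#' from each base toward the lens: the exit point through the lens-facing
#' retinal surface.  For an open, roughly planar patch the lattice is laid
#' in the best-fit plane and apices sit at `apex_height` along its normal.
#' Placement is deterministic.
#'
#' @param x an `eye_model` or a retina-wall [triangle_mesh()].
#' @param spacing target receptor centre spacing (um).
#' @param r_base,r_apex,r_core receptor radii (um), see [receptor_set()].
#' @param lens_point interior point the apices point toward (defaults to the
#'   lens centroid for an `eye_model`; required direction reference for a
#'   closed bare mesh, defaulting to the mesh centroid offset along +x).
#' @param max_length cap on receptor length (um).
#' @param apex_height receptor length for open planar patches (um).
#' @param coverage angular radius (deg) of the receptor-bearing retinal cap,
#'   measured about the central back direction; wall outside it is bare
#'   screening pigment.  Defaults to the eye's `retina_coverage` parameter
#'   when placing on an `eye_model`, otherwise unlimited.
#' @return a `receptor_set`.
#' @export
place_receptors <- function(x, spacing = 2.5, r_base = NULL, r_apex = NULL,
                            r_core = NULL, lens_point = NULL,
                            max_length = Inf, apex_height = 4 * spacing,
                            coverage = NULL) {
  if (spacing <= 0) stop("spacing must be > 0")
  if (inherits(x, "eye_model")) {
    mesh <- x$meshes$retina_wall
    if (is.null(mesh)) stop("eye model has no retina_wall mesh")
    if (is.null(lens_point)) lens_point <- colMeans(x$meshes$lens$vertices)
    if (is.null(coverage))
      coverage <- c(x$params$retina_coverage, x$params$retina_coverage_v)
    if (is.null(r_base)) r_base <- x$params$receptor_r_base
    if (is.null(r_apex)) r_apex <- x$params$receptor_r_apex
    if (is.null(r_core)) r_core <- x$params$receptor_r_core
  } else if (inherits(x, "triangle_mesh")) {
    mesh <- x
  } else stop("x must be an eye_model or triangle_mesh")
  if (is.null(coverage)) coverage <- 180
  coverage <- rep_len(coverage, 2L)
  if (is.null(r_base)) r_base <- 2.0
  if (is.null(r_apex)) r_apex <- 0.5
  if (is.null(r_core)) r_core <- 0.5
  val <- validate_mesh(mesh)
  rec <- if (val$watertight) {
    place_on_closed(mesh, spacing, lens_point, max_length, coverage)
  } else {
    place_on_patch(mesh, spacing, apex_height)
  }
  if (nrow(rec$base) < 3L)
    stop("spacing too large for this retina: fewer than 3 receptors")
  receptor_set(rec$base, rec$apex, r_base, r_apex, r_core)
}

hex_lattice <- function(extent, delta) {
  ny <- ceiling(extent / (delta * sqrt(3) / 2)) + 1L
  nx <- ceiling(extent / delta) + 1L
  pts <- list()
  for (row in -ny:ny) {
    y <- row * delta * sqrt(3) / 2
    off <- if (row %% 2 == 0) 0 else delta / 2
    xs <- (-nx:nx) * delta + off
    pts[[length(pts) + 1L]] <- cbind(xs, y)
  }
  p <- do.call(rbind, pts)
  p[p[, 1]^2 + p[, 2]^2 <= extent^2, , drop = FALSE]
}

mean_nn_dist <- function(p) {
  n <- nrow(p)
  if (n < 2) return(NA_real_)
  d2 <- as.matrix(dist(p))
  diag(d2) <- Inf
  mean(apply(d2, 1, min))
}

place_on_closed <- function(mesh, spacing, lens_point, max_length,
                            coverage = 180) {
  O <- colMeans(mesh$vertices)
  if (is.null(lens_point)) lens_point <- O + c(1, 0, 0) * 1e3
  idx <- build_octree(mesh)
  cvec <- O - lens_point
  cdir <- if (sqrt(sum(cvec^2)) > 1e-9) cvec / sqrt(sum(cvec^2)) else c(-1, 0, 0)
  # chart frame: e1 horizontal, e2 toward vertical, pole at cdir
  e1 <- c(-cdir[2], cdir[1], 0)
  if (sum(e1^2) < 1e-12) e1 <- c(1, 0, 0)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(cdir[2] * e1[3] - cdir[3] * e1[2],
          cdir[3] * e1[1] - cdir[1] * e1[3],
          cdir[1] * e1[2] - cdir[2] * e1[1])

  cast_far <- function(dirs) {
    # farthest intersection along each direction from O
    n <- nrow(dirs)
    t_far <- rep(NA_real_, n)
    face <- rep(NA_integer_, n)
    org <- matrix(rep(O, each = n), n, 3)
    t0 <- rep(0, n)
    active <- rep(TRUE, n)
    for (it in 1:24) {
      if (!any(active)) break
      h <- intersect_ray(org[active, , drop = FALSE] +
                           dirs[active, , drop = FALSE] * (t0[active] + 1e-6),
                         dirs[active, , drop = FALSE], idx)
      got <- !is.na(h$t)
      ia <- which(active)
      t_far[ia[got]] <- t0[ia[got]] + 1e-6 + h$t[got]
      face[ia[got]] <- h$face[got]
      t0[ia[got]] <- t_far[ia[got]]
      active[ia[!got]] <- FALSE
    }
    list(t = t_far, face = face)
  }
  nrm_all <- face_normals(mesh)
  on_back <- function(pts, faces) {
    # back (pigment) wall faces away from the lens
    nrm <- nrm_all[faces, , drop = FALSE]
    tolens <- sweep(-pts, 2, lens_point, `+`)
    tolens <- tolens / pmax(sqrt(rowSums(tolens^2)), 1e-12)
    rowSums(nrm * tolens) < 0.5
  }

  # probe pass: mean back-surface radius sets the chart scale
  probe <- sample_hemisphere(512, cdir)
  extra <- sample_hemisphere(256, -cdir)  # cover beyond the hemisphere too
  probe <- rbind(probe, extra)
  pf <- cast_far(probe)
  ok <- !is.na(pf$t)
  pts <- sweep(probe[ok, , drop = FALSE] * pf$t[ok], 2, O, `+`)
  bk <- on_back(pts, pf$face[ok])
  if (!any(bk)) stop("no back retinal surface found")
  rbar <- mean(pf$t[ok][bk])
  thmax <- max(acos(pmin(1, (probe[ok, , drop = FALSE][bk, ] %*% cdir))))

  covh <- min(thmax, coverage[1] * pi / 180)
  covv <- min(thmax, coverage[2] * pi / 180)
  gen <- function(delta) {
    chart <- hex_lattice(min(max(covh, covv) + 2 * delta, pi * 0.98), delta)
    chart <- chart[(chart[, 1] / covh)^2 + (chart[, 2] / covv)^2 <= 1, ,
                   drop = FALSE]
    th <- sqrt(rowSums(chart^2))
    psi <- atan2(chart[, 2], chart[, 1])
    dirs <- outer(sin(th) * cos(psi), e1) + outer(sin(th) * sin(psi), e2) +
      outer(cos(th), cdir)
    cf <- cast_far(dirs)
    ok <- !is.na(cf$t)
    pts <- sweep(dirs[ok, , drop = FALSE] * cf$t[ok], 2, O, `+`)
    keep <- on_back(pts, cf$face[ok])
    pts[keep, , drop = FALSE]
  }
  delta <- spacing / rbar
  base <- gen(delta)
  got <- mean_nn_dist(base)
  if (is.finite(got) && got > 0) {
    delta <- delta * spacing / got       # one correction pass
    base <- gen(delta)
  }

  # apices: cast from each base toward the lens, take the retinal exit point
  dl <- sweep(-base, 2, lens_point, `+`)
  dl <- dl / pmax(sqrt(rowSums(dl^2)), 1e-12)
  h <- intersect_ray(base + dl * 1e-4, dl, idx)
  len <- pmin(ifelse(is.na(h$t), max_length, h$t + 1e-4), max_length)
  # rim points misclassified as back wall yield no usable inward cast; drop
  ok <- is.finite(len) & len > 1.0
  list(base = base[ok, , drop = FALSE], apex = (base + dl * len)[ok, , drop = FALSE])
}

place_on_patch <- function(mesh, spacing, apex_height) {
  v <- mesh$vertices
  ctr <- colMeans(v)
  sv <- svd(sweep(v, 2, ctr))
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]; nrm <- sv$v[, 3]
  uv <- cbind((sweep(v, 2, ctr) %*% e1)[, 1], (sweep(v, 2, ctr) %*% e2)[, 1])
  ext <- max(sqrt(rowSums(uv^2)))
  cand <- hex_lattice(ext, spacing)
  # keep lattice points inside some triangle of the projected mesh
  f <- mesh$faces
  inside <- rep(FALSE, nrow(cand))
  for (t in seq_len(nrow(f))) {
    a <- uv[f[t, 1], ]; b <- uv[f[t, 2], ]; cc <- uv[f[t, 3], ]
    d <- (b[2] - cc[2]) * (a[1] - cc[1]) + (cc[1] - b[1]) * (a[2] - cc[2])
    if (abs(d) < 1e-12) next
    l1 <- ((b[2] - cc[2]) * (cand[, 1] - cc[1]) + (cc[1] - b[1]) * (cand[, 2] - cc[2])) / d
    l2 <- ((cc[2] - a[2]) * (cand[, 1] - cc[1]) + (a[1] - cc[1]) * (cand[, 2] - cc[2])) / d
    l3 <- 1 - l1 - l2
    inside <- inside | (l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9)
  }
  p2 <- cand[inside, , drop = FALSE]
  base <- sweep(p2[, 1, drop = FALSE] %*% t(e1) + p2[, 2, drop = FALSE] %*% t(e2),
                2, ctr, `+`)
  apex <- sweep(base, 2, nrm * apex_height, `+`)
  list(base = base, apex = apex)
}

#' Which receptors' absorbing shells contain given points
#'
#' Exact truncated-cone-shell containment: a point belongs to a receptor if
#' it lies between apex and base, within the outer cone radius at its depth,
#' and outside the non-absorbing core.  Overlapping receptors may all claim
#' one point.
#'
#' @param points length-3 vector or n x 3 matrix (um).
#' @param receptors a `receptor_set`.
#' @return list (one element per point) of integer receptor ids.
#' @export
receptor_membership <- function(points, receptors) {
  stopifnot(inherits(receptors, "receptor_set"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  res <- cpp_cone_membership(as.matrix(points),
                             as.matrix(receptors[, c("base_x", "base_y", "base_z")]),
                             as.matrix(receptors[, c("apex_x", "apex_y", "apex_z")]),
                             receptors$r_base, receptors$r_apex, receptors$r_core)
  lapply(res, function(i) receptors$id[i])
}

#' March Beer-Lambert absorption along one ray path
#'
#' Retinal segments of the path are marched in steps of at most `step` um;
#' at each step whose midpoint lies inside at least one receptor's absorbing
#' shell, the remaining power is attenuated by `exp(-alpha * ds)` and the
#' absorbed amount credited, split equally among the containing receptors.
#' Absorbed plus remaining power equals the input power to within 1e-12.
#'
#' @param path a `ray_path` from [trace_ray()] (or any object with a
#'   `segments` data.frame containing retinal segments).
#' @param receptors a `receptor_set`.
#' @param config an [optical_config()] (supplies `alpha`).
#' @param step marching step (um).
#' @param power input ray power.
#' @param retina_label medium label of retinal segments.
#' @return numeric vector of per-receptor absorbed power, with attributes
#'   `remaining` and `absorbed_total`.
#' @export
absorb_path <- function(path, receptors, config = optical_config(),
                        step = config$step, power = 1.0,
                        retina_label = "retina_wall") {
  if (step <= 0) stop("step must be > 0")
  stopifnot(inherits(receptors, "receptor_set"))
  seg <- path$segments
  seg <- seg[seg$medium == retina_label & seg$length > 0, , drop = FALSE]
  out <- numeric(nrow(receptors))
  absorbed <- 0
  for (i in seq_len(nrow(seg))) {
    a <- c(seg$x0[i], seg$y0[i], seg$z0[i])
    b <- c(seg$x1[i], seg$y1[i], seg$z1[i])
    L <- seg$length[i]
    d <- (b - a) / L
    ns <- ceiling(L / step)
    ds <- L / ns
    f <- exp(-config$alpha * ds)
    mids <- sweep(outer((seq_len(ns) - 0.5) * ds, d), 2, a, `+`)
    mem <- receptor_membership(mids, receptors)
    for (k in seq_len(ns)) {
      ids <- mem[[k]]
      if (length(ids)) {
        dA <- power * (1 - f)
        power <- power * f
        out[ids] <- out[ids] + dA / length(ids)
        absorbed <- absorbed + dA
      }
    }
  }
  attr(out, "remaining") <- power
  attr(out, "absorbed_total") <- absorbed
  out
}

absorption_table <- function(mat, directions, stats, receptors,
                             beam_radius, n_rays) {
  mat <- as.matrix(mat)
  structure(mat, class = c("absorption_table", "matrix", "array"),
            directions = directions, stats = stats, receptors = receptors,
            beam_radius = beam_radius, n_rays = n_rays)
}

#' @export
print.absorption_table <- function(x, ...) {
  cat(sprintf("<absorption_table: %d receptors x %d directions>\n",
              nrow(x), ncol(x)))
  cat(sprintf("  beam: %d rays, radius %.1f um | total absorbed fraction: mean %.4f, max %.4f\n",
              attr(x, "n_rays"), attr(x, "beam_radius"),
              mean(colSums(x)), max(colSums(x))))
  invisible(x)
}

#' Accumulate per-receptor absorption over a traced field
#'
#' Builds the receptor x direction absorption table for a [trace_field()]
#' result.  If the trace retained per-ray paths they are marched directly
#' (reference path); otherwise the beams are re-traced with the receptors
#' attached, which is deterministic and yields identical paths.
#'
#' @param traces a `trace_set`.
#' @param receptors a `receptor_set`.
#' @param config an [optical_config()]; defaults to the trace's own.
#' @return an `absorption_table` (receptor x direction matrix, entries are
#'   fractions of each beam's input power).
#' @export
accumulate_absorption <- function(traces, receptors, config = NULL) {
  stopifnot(inherits(traces, "trace_set"), inherits(receptors, "receptor_set"))
  if (is.null(config)) config <- traces$config
  if (!is.null(traces$absorption) &&
      identical(traces$receptor_ids, receptors$id)) {
    return(absorption_table(traces$absorption, traces$directions, traces$stats,
                            receptors, traces$beam_radius, traces$n_rays))
  }
  if (!is.null(traces$paths)) {
    nd <- nrow(traces$directions)
    mat <- matrix(0, nrow(receptors), nd)
    for (i in seq_len(nd)) {
      for (p in traces$paths[[i]])
        mat[, i] <- mat[, i] + absorb_path(p, receptors, config,
                                           power = 1 / traces$n_rays)
    }
    return(absorption_table(mat, traces$directions, traces$stats, receptors,
                            traces$beam_radius, traces$n_rays))
  }
  trace_absorb(traces$eye, receptors, config, directions = traces$directions)
}
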