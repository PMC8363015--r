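#' Build an octree spatial index over one or more meshes
#'
#' Triangles are partitioned into an octree (axis-aligned, centre-split);
#' each triangle is stored in every leaf its bounding box overlaps, so the
#' union of leaf lists always covers all triangles.  The index accelerates
#' ray queries but never changes their result.
#'
#' @param meshes a [triangle_mesh()] or list of them.
#' @param leaf_capacity maximum triangles per leaf before subdivision.
#' @param max_depth maximum tree depth.
#' @return an object of class `spatial_index`.
#' @export
build_octree <- function(meshes, leaf_capacity = 32L, max_depth = 10L) {
  if (inherits(meshes, "triangle_mesh")) meshes <- list(meshes)
  if (length(meshes) < 1L) stop("octree requires at least one triangle")
  stopifnot(all(vapply(meshes, inherits, logical(1), "triangle_mesh")))
  cmb <- combine_meshes(meshes)
  if (nrow(cmb$faces) < 1L) stop("octree requires at least one triangle")
  ptr <- cpp_octree_build(cmb$vertices, cmb$faces, cmb$mesh_id,
                          as.integer(leaf_capacity), as.integer(max_depth))
  structure(list(ptr = ptr, vertices = cmb$vertices, faces = cmb$faces,
                 mesh_id = cmb$mesh_id, labels = cmb$labels,
                 leaf_capacity = as.integer(leaf_capacity),
                 max_depth = as.integer(max_depth)),
            class = "spatial_index")
}

combine_meshes <- function(meshes) {
  nv <- 0L
  verts <- vector("list", length(meshes))
  faces <- vector("list", length(meshes))
  ids <- vector("list", length(meshes))
  for (i in seq_along(meshes)) {
    m <- meshes[[i]]
    verts[[i]] <- m$vertices
    faces[[i]] <- m$faces + nv
    ids[[i]] <- rep(i, nrow(m$faces))
    nv <- nv + nrow(m$vertices)
  }
  list(vertices = do.call(rbind, verts),
       faces = do.call(rbind, faces),
       mesh_id = as.integer(unlist(ids)),
       labels = vapply(meshes, function(m) m$label, character(1)))
}

# rebuild the external pointer if the object was serialized/restored
index_ptr <- function(index) {
  p <- index$ptr
  if (is.null(p) || isTRUE(tryCatch(identical(cpp_octree_stats(p)$n_triangles, 0L),
                                    error = function(e) TRUE))) {
    p <- cpp_octree_build(index$vertices, index$faces, index$mesh_id,
                          index$leaf_capacity, index$max_depth)
  }
  p
}

#' @export
print.spatial_index <- function(x, ...) {
  st <- cpp_octree_stats(index_ptr(x))
  cat(sprintf("<spatial_index: %d triangles over %d mesh(es), %d nodes (%d leaves)>\n",
              st$n_triangles, length(x$labels), st$n_nodes, st$n_leaves))
  invisible(x)
}

#' Retrieve triangles whose leaves overlap an axis-aligned box
#'
#' @param index a `spatial_index`.
#' @param lo,hi numeric length-3 box corners (um).
#' @return sorted integer vector of 1-based triangle indices.
#' @export
octree_query <- function(index, lo, hi) {
  stopifnot(inherits(index, "spatial_index"))
  cpp_octree_query_box(index_ptr(index), as.numeric(lo), as.numeric(hi))
}

#' Nearest ray-surface intersection
#'
#' Finds the minimum-t Moller-Trumbore intersection of each ray with the
#' indexed triangles.  Hits closer than `tmin` are excluded
#' (self-intersection guard).  The octree is an accelerator only: with
#' `brute = TRUE` the same answer is computed by scanning all triangles.
#'
#' @param origin numeric length 3 or n x 3 matrix of ray origins (um).
#' @param direction matching unit direction(s).
#' @param index a `spatial_index` from [build_octree()].
#' @param tmin self-intersection guard (um).
#' @param brute bypass the octree (reference path).
#' @return a data.frame with one row per ray: `t`, `x`, `y`, `z` (hit point),
#'   `nx`, `ny`, `nz` (face normal), `u`, `v`, `w` (barycentric coordinates),
#'   `face`, `mesh`, `label`; `t` is `NA` for rays with no hit.
#' @export
intersect_ray <- function(origin, direction, index, tmin = 1e-9, brute = FALSE) {
  stopifnot(inherits(index, "spatial_index"))
  if (is.null(dim(origin))) origin <- matrix(origin, ncol = 3, byrow = TRUE)
  if (is.null(dim(direction))) direction <- matrix(direction, ncol = 3, byrow = TRUE)
  origin <- as.matrix(origin); direction <- as.matrix(direction)
  if (nrow(direction) == 1L && nrow(origin) > 1L)
    direction <- direction[rep(1L, nrow(origin)), , drop = FALSE]
  nn <- sqrt(rowSums(direction^2))
  if (any(abs(nn - 1) > 1e-8)) stop("directions must be unit vectors")
  h <- cpp_intersect(index_ptr(index), origin, direction, tmin, brute)
  f <- h[, "face"]
  ok <- !is.na(f)
  n <- nrow(h)
  out <- data.frame(t = h[, "t"], x = NA_real_, y = NA_real_, z = NA_real_,
                    nx = NA_real_, ny = NA_real_, nz = NA_real_,
                    u = NA_real_, v = NA_real_, w = NA_real_,
                    face = as.integer(f), mesh = as.integer(h[, "mesh"]),
                    label = rep(NA_character_, n))
  if (any(ok)) {
    p <- origin[ok, , drop = FALSE] + direction[ok, , drop = FALSE] * h[ok, "t"]
    out$x[ok] <- p[, 1]; out$y[ok] <- p[, 2]; out$z[ok] <- p[, 3]
    fam <- triangle_mesh(index$vertices, index$faces)
    nrm <- face_normals(fam)[f[ok], , drop = FALSE]
    out$nx[ok] <- nrm[, 1]; out$ny[ok] <- nrm[, 2]; out$nz[ok] <- nrm[, 3]
    out$u[ok] <- h[ok, "u"]; out$v[ok] <- h[ok, "v"]
    out$w[ok] <- 1 - h[ok, "u"] - h[ok, "v"]
    out$label[ok] <- index$labels[out$mesh[ok]]
  }
  out
}
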