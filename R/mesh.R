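#' Triangle mesh objects
#'
#' A `triangle_mesh` is the package's basic geometry container: a matrix of
#' 3D vertex positions (micrometres), an integer matrix of 1-based vertex
#' triples (faces), and a volume label (`"cornea"`, `"lens"`, `"retina_wall"`,
#' `"receptor"` or any other name).
#'
#' @param vertices numeric matrix, n x 3, vertex positions in um.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param label character volume name.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, label = "other") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) < 1L) stop("mesh has no faces")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces, label = as.character(label)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("<triangle_mesh '%s': %d vertices, %d faces>\n",
              x$label, nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox um: x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
      a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

edge_use_counts <- function(mesh) {
  f <- mesh$faces
  i <- c(f[, 1], f[, 2], f[, 3])
  j <- c(f[, 2], f[, 3], f[, 1])
  und <- paste(pmin(i, j), pmax(i, j))
  dird <- paste(i, j)
  list(undirected = table(und), directed = table(dird))
}

#' Validate a triangle mesh
#'
#' Report-only checks used before tracing: watertightness (every undirected
#' edge shared by exactly two faces), consistent outward orientation (each
#' directed edge used once and the signed volume positive), bounding box and
#' signed volume.
#'
#' @param mesh a [triangle_mesh()].
#' @return a list of class `mesh_validation` with elements `watertight`,
#'   `oriented`, `outward` (signed volume > 0), `signed_volume_um3`, `bbox`,
#'   `n_vertices`, `n_faces`.  Serializable with [jsonlite::toJSON()].
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  ec <- edge_use_counts(mesh)
  watertight <- all(ec$undirected == 2L)
  consistent <- all(ec$directed == 1L)
  vol <- mesh_signed_volume(mesh)
  bb <- apply(mesh$vertices, 2, range)
  dimnames(bb) <- list(c("min", "max"), c("x", "y", "z"))
  structure(list(label = mesh$label,
                 watertight = watertight,
                 oriented = consistent,
                 outward = watertight && consistent && vol > 0,
                 signed_volume_um3 = vol,
                 bbox = bb,
                 n_vertices = nrow(mesh$vertices),
                 n_faces = nrow(mesh$faces)),
            class = "mesh_validation")
}

#' @export
print.mesh_validation <- function(x, ...) {
  cat(sprintf("<mesh_validation '%s'>\n", x$label))
  cat(sprintf("  watertight: %s | oriented: %s | outward: %s\n",
              x$watertight, x$oriented, x$outward))
  cat(sprintf("  signed volume: %.1f um^3 | %d vertices, %d faces\n",
              x$signed_volume_um3, x$n_vertices, x$n_faces))
  invisible(x)
}

#' Test whether points lie inside a watertight mesh volume
#'
#' Crossing-parity containment test along a fixed oblique ray direction.
#' Points within `tol` of the surface are counted inside (documented tie
#' rule for boundary points).
#'
#' @param points numeric vector of length 3 or an n x 3 matrix (um).
#' @param mesh a watertight [triangle_mesh()].
#' @param tol boundary tolerance in um.
#' @return logical vector.
#' @export
point_in_volume <- function(points, mesh, tol = 1e-9) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  val <- validate_mesh(mesh)
  if (!val$watertight) stop("point_in_volume requires a watertight mesh")
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  xp <- cpp_octree_build(mesh$vertices, mesh$faces,
                         rep(1L, nrow(mesh$faces)), 32L, 10L)
  cnt <- cpp_crossing_counts(xp, points)[, 1]
  inside <- (cnt %% 2L) == 1L
  if (tol > 0) {
    # boundary tie rule: on-surface points count as inside
    near <- cpp_min_tri_dist(xp, points) <= tol
    inside <- inside | near
  }
  inside
}
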