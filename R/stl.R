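#' Read a triangle mesh from an STL file
#'
#' Reads binary or ASCII STL (auto-detected).  STL stores one vertex triple
#' per facet; vertices are deduplicated by exact coordinate match so shared
#' vertices are merged, while the face count is preserved.  STL carries no
#' units; coordinates are taken as micrometres, optionally multiplied by
#' `scale` on import.
#'
#' @param path file path.
#' @param label volume label for the resulting mesh.
#' @param scale multiplicative scale factor applied to coordinates.
#' @return a [triangle_mesh()].
#' @export
read_stl <- function(path, label = "other", scale = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  if (sz < 15) stop("malformed STL (file too short): ", path)
  raw <- readBin(path, "raw", n = sz)
  head_txt <- rawToChar(raw[1:min(80, sz)])
  is_ascii <- grepl("^\\s*solid", head_txt)
  if (is_ascii && sz >= 84) {
    # some binary files also start with "solid": cross-check the face count
    n_declared <- readBin(raw[81:84], "integer", size = 4, endian = "little")
    if (sz == 84 + 50 * n_declared) is_ascii <- FALSE
  }
  tri <- if (is_ascii) parse_stl_ascii(raw, path) else parse_stl_binary(raw, path)
  if (nrow(tri) == 0) stop("empty mesh in STL file: ", path)
  tri <- tri * scale
  # exact-coordinate dedup
  key <- paste(sprintf("%.17g", tri[, 1]), sprintf("%.17g", tri[, 2]),
               sprintf("%.17g", tri[, 3]))
  uk <- !duplicated(key)
  verts <- tri[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces, label = label)
}

parse_stl_binary <- function(raw, path) {
  if (length(raw) < 84) stop("malformed STL (missing binary header) in ", path)
  n <- readBin(raw[81:84], "integer", size = 4, endian = "little")
  if (n < 0 || length(raw) < 84 + 50 * n)
    stop(sprintf("malformed binary STL in %s: %d facets declared but file has %d bytes",
                 path, n, length(raw)))
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  # each 50-byte record: 12 float32 (normal + 3 vertices) + uint16 attribute
  off <- 84 + (seq_len(n) - 1L) * 50L
  byte_idx <- rep(off, each = 36L) + rep(13:48, times = n)   # vertex bytes only
  vals <- readBin(raw[byte_idx], "numeric", size = 4, n = 9L * n, endian = "little")
  matrix(vals, ncol = 3, byrow = TRUE)
}

parse_stl_ascii <- function(raw, path) {
  lines <- strsplit(rawToChar(raw), "\r?\n")[[1]]
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) %% 3 != 0)
    stop(sprintf("malformed ASCII STL in %s: vertex count %d not a multiple of 3 (near line %d)",
                 path, length(vl), if (length(vl)) vl[length(vl)] else 0L))
  if (length(vl) == 0) return(matrix(numeric(0), ncol = 3))
  txt <- sub("^\\s*vertex\\s+", "", lines[vl])
  vals <- suppressWarnings(lapply(strsplit(trimws(txt), "\\s+"), as.numeric))
  bad <- which(vapply(vals, function(v) length(v) != 3 || anyNA(v), logical(1)))
  if (length(bad))
    stop(sprintf("malformed ASCII STL in %s at line %d: '%s'",
                 path, vl[bad[1]], lines[vl[bad[1]]]))
  do.call(rbind, vals)
}

#' Write a triangle mesh to an STL file
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @param ascii write ASCII STL instead of binary.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(f)
  nrm <- face_normals(mesh)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", mesh$label), con)
    for (i in seq_len(n)) {
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g",
                           v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", mesh$label), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", paste("ocellus mesh", mesh$label)))[1:80]
    writeBin(header, con)
    writeBin(as.integer(n), con, size = 4, endian = "little")
    # interleave: normal, v1, v2, v3 per facet as float32 + 2 attribute bytes
    for (i in seq_len(n)) {
      writeBin(as.numeric(c(nrm[i, ], t(v[f[i, ], ]))), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
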