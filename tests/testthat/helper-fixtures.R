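# Small geometry fixtures built in code.

unit_triangle_mesh <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                rbind(c(1, 2, 3)), label = "tri")
}

# axis-aligned cube [-s, s]^3 as 12 consistently oriented triangles
cube_mesh <- function(s = 1) {
  v <- as.matrix(expand.grid(x = c(-s, s), y = c(-s, s), z = c(-s, s)))
  f <- rbind(c(1, 3, 2), c(2, 3, 4),    # z = -s
             c(5, 6, 7), c(6, 8, 7),    # z = +s
             c(1, 2, 5), c(2, 6, 5),    # y = -s
             c(3, 7, 4), c(4, 7, 8),    # y = +s
             c(1, 5, 3), c(3, 5, 7),    # x = -s
             c(2, 4, 6), c(4, 8, 6))    # x = +s
  orient <- triangle_mesh(v, f, label = "cube")
  if (ocellus:::mesh_signed_volume(orient) < 0)
    orient$faces <- orient$faces[, c(1, 3, 2)]
  orient
}

# flat circular retina patch of diameter d in the z = 0 plane (open mesh)
flat_patch_mesh <- function(d = 25, n_ring = 48) {
  th <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
  v <- rbind(c(0, 0, 0), cbind(d / 2 * cos(th), d / 2 * sin(th), 0))
  f <- cbind(1, 1 + seq_len(n_ring), 1 + c(seq_len(n_ring)[-1], 1))
  triangle_mesh(v, f, label = "patch")
}

# synthetic Gaussian angular-sensitivity object (peak-normalized grid)
gaussian_asf <- function(azi0 = 0, elev0 = 0, fwhm = 20, peak = 1,
                         half_window = 40, pitch = 1, id = 1L) {
  az <- seq(azi0 - half_window, azi0 + half_window, by = pitch)
  el <- seq(elev0 - half_window, elev0 + half_window, by = pitch)
  sg <- fwhm / (2 * sqrt(2 * log(2)))
  V <- outer(el, az, function(e, a)
    exp(-((a - azi0)^2 + (e - elev0)^2) / (2 * sg^2)))
  structure(list(values = V, azimuth = az, elevation = el, peak = peak,
                 peak_direction = ocellus:::angles_to_dir(azi0, elev0)[1, ],
                 receptor_id = id, empty = FALSE, pitch = pitch,
                 normalize = "peak"),
            class = "angular_sensitivity")
}

nn_dists <- function(p) {
  d <- as.matrix(dist(p))
  diag(d) <- Inf
  apply(d, 1, min)
}
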