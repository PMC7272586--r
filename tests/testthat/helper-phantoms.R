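# Geometric phantoms with known structure, shared across test files.

# solid block with one carved spherical void (diameter in voxels)
carved_void <- function(n = 41L, diameter = 20, voxel_um = 1) {
  m <- array(TRUE, rep(n, 3L))
  cc <- (n + 1) / 2
  coords <- seq_len(n)
  d2 <- outer(outer((coords - cc)^2, (coords - cc)^2, "+"),
              (coords - cc)^2, "+")
  m[d2 <= (diameter / 2)^2] <- FALSE
  binary_network(m, voxel_um)
}

# square lattice of parallel fibers along z: centre spacing s, diameter d
# (both in voxels); diagonal gap pore is analytically s*sqrt(2) - d
fiber_lattice <- function(n = 128L, spacing = 16, diameter = 4,
                          voxel_um = 1) {
  m <- array(FALSE, rep(n, 3L))
  xy <- seq_len(n) - 1
  centres <- seq(0, n - 1, by = spacing)
  for (fx in centres) for (fy in centres) {
    ix <- which(abs(xy - fx) <= diameter / 2)
    iy <- which(abs(xy - fy) <= diameter / 2)
    for (i in ix) for (j in iy)
      if ((xy[i] - fx)^2 + (xy[j] - fy)^2 <= (diameter / 2)^2)
        m[i, j, ] <- TRUE
  }
  binary_network(m, voxel_um)
}

# straight cylinder along z, axis deliberately off voxel centres
solid_cylinder <- function(diameter, n = NULL, nz = 50L, voxel_um = 1) {
  if (is.null(n)) n <- ceiling(diameter) + 20L
  m <- array(FALSE, c(n, n, nz))
  cx <- n / 2 + 0.31
  cy <- n / 2 + 0.57
  for (j in seq_len(n)) for (i in seq_len(n))
    if ((i - cx)^2 + (j - cy)^2 <= (diameter / 2)^2) m[i, j, ] <- TRUE
  binary_network(m, voxel_um)
}

# 2D parallel stripes: fiber width w, gap g (pixels)
stripe_pattern <- function(w = 14L, g = 18L, n = 256L, voxel_um = 1,
                           as_image = FALSE) {
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n)) if (((i - 1) %% (w + g)) < w) m[i, ] <- TRUE
  if (as_image) image_volume(ifelse(m, 1, 0.1), voxel_um)
  else binary_network(m, voxel_um)
}

# small Mikado network for property checks
small_mikado <- function(n_fibers = 15L, seed = 1L, edge_um = 13.92,
                         voxel_um = 0.29, dim3 = TRUE) {
  generate_fiber_network(fiber_network_spec(
    dimensionality = if (dim3) 3 else 2, edge_um = edge_um,
    voxel_um = voxel_um, fiber_diameter_um = 2.4 * voxel_um,
    n_fibers = n_fibers, noise_sd = 0.02, seed = seed))
}
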