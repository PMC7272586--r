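#' Specification of a synthetic 3D invasion assay
#'
#' Emulates the acquisition layout of a 3D collagen invasion assay: a grid
#' of epifluorescence nucleus z-stacks (default 11 x 11 positions with
#' 4 um z-spacing) over one well. Nuclei sit at the matrix surface with
#' probability `surface_fraction` and otherwise at an exponentially
#' distributed depth below it, reproducing the point-mass-plus-tail shape
#' of measured cumulative depth curves. Each nucleus is rendered as a 3D
#' Gaussian blob; the returned truth table carries the exact positions and
#' depths.
#'
#' @param grid_shape integer vector (stacks per side), default `c(11, 11)`.
#' @param z_step_um z-spacing between planes, um.
#' @param n_cells total number of nuclei across the grid.
#' @param surface_z_um z-position of the matrix surface, um.
#' @param surface_fraction fraction of cells adherent at the surface.
#' @param tail_scale_um exponential scale of invasion depths, um.
#' @param stack_px lateral stack size in pixels.
#' @param xy_um_per_px lateral pixel size, um.
#' @param depth_um_total total imaged depth below (and margin above) the
#'   surface, um.
#' @param nucleus_sigma_um Gaussian blob sigma per axis, um.
#' @param intensity blob peak intensity (background is 0).
#' @param noise_sd Gaussian noise sd.
#' @param seed integer seed.
#' @return An object of class `invasion_stack_spec`.
#' @export
invasion_stack_spec <- function(grid_shape = c(11L, 11L), z_step_um = 4,
                                n_cells = 500L, surface_z_um = 20,
                                surface_fraction = 0.6,
                                tail_scale_um = 50, stack_px = 64L,
                                xy_um_per_px = 1.3,
                                depth_um_total = 300,
                                nucleus_sigma_um = c(4, 4, 4),
                                intensity = 1, noise_sd = 0.05,
                                seed = 1L) {
  if (z_step_um <= 0) stop("z-spacing must be positive")
  if (n_cells < 1) stop("cell count must be >= 1")
  if (surface_fraction < 0 || surface_fraction > 1)
    stop("surface_fraction must be in [0, 1]")
  if (tail_scale_um < 0) stop("depths must be >= 0")
  structure(list(grid_shape = as.integer(grid_shape),
                 z_step_um = z_step_um, n_cells = as.integer(n_cells),
                 surface_z_um = surface_z_um,
                 surface_fraction = surface_fraction,
                 tail_scale_um = tail_scale_um,
                 stack_px = as.integer(stack_px),
                 xy_um_per_px = xy_um_per_px,
                 depth_um_total = depth_um_total,
                 nucleus_sigma_um = rep(nucleus_sigma_um, length.out = 3),
                 intensity = intensity, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "invasion_stack_spec")
}

#' Generate gridded invasion z-stacks with a ground-truth nucleus table
#'
#' @param spec an [invasion_stack_spec()].
#' @return A list with `stacks` (named list of [image_volume()], one per
#'   grid position, z as the third axis) and `truth` (data.frame: `id`,
#'   `grid_x`, `grid_y`, `x_um`, `y_um`, `z_um`, `depth_um`).
#' @export
generate_invasion_stacks <- function(spec) {
  stopifnot(inherits(spec, "invasion_stack_spec"))
  with_seed(spec$seed, {
    n <- spec$n_cells
    ngrid <- prod(spec$grid_shape)
    at_surface <- stats::runif(n) < spec$surface_fraction
    depth <- ifelse(at_surface, 0,
                    stats::rexp(n, rate = 1 / spec$tail_scale_um))
    depth <- pmin(depth, spec$depth_um_total - spec$surface_z_um -
                    2 * spec$z_step_um)
    gpos <- sample.int(ngrid, n, replace = TRUE)
    fov <- spec$stack_px * spec$xy_um_per_px
    margin <- 2 * spec$nucleus_sigma_um[1]
    truth <- data.frame(
      id = seq_len(n),
      grid_x = ((gpos - 1L) %% spec$grid_shape[1]) + 1L,
      grid_y = ((gpos - 1L) %/% spec$grid_shape[1]) + 1L,
      x_um = stats::runif(n, margin, fov - margin),
      y_um = stats::runif(n, margin, fov - margin),
      z_um = spec$surface_z_um + depth,
      depth_um = depth)

    n_planes <- max(2L, ceiling(spec$depth_um_total / spec$z_step_um))
    dims <- c(spec$stack_px, spec$stack_px, n_planes)
    spacing <- c(spec$xy_um_per_px, spec$xy_um_per_px, spec$z_step_um)
    stacks <- vector("list", ngrid)
    names(stacks) <- sprintf("pos_%02d_%02d",
                             ((seq_len(ngrid) - 1L) %% spec$grid_shape[1]) + 1L,
                             ((seq_len(ngrid) - 1L) %/% spec$grid_shape[1]) + 1L)
    for (g in seq_len(ngrid)) {
      img <- array(0, dims)
      sel <- gpos == g
      if (any(sel)) {
        ctr <- cbind(truth$x_um[sel], truth$y_um[sel], truth$z_um[sel])
        img <- add_blobs_cpp(img, as.integer(dims), spacing, ctr,
                             spec$nucleus_sigma_um, spec$intensity)
      }
      if (spec$noise_sd > 0)
        img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
      dim(img) <- dims
      stacks[[g]] <- image_volume(img, spacing)
    }
    list(stacks = stacks, truth = truth)
  })
}
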