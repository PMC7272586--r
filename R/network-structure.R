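#' Segment a fibrous-network image into fiber and fluid phases
#'
#' Global Otsu thresholding or a local-mean threshold with offset; the
#' foreground (above threshold) is the fiber phase.
#'
#' @param image an [image_volume()].
#' @param method `"global-otsu"` (default) or `"local-mean-offset"`.
#' @param offset intensity offset above the local mean (local method).
#' @param window_um window size for the local mean, um.
#' @return A [binary_network()].
#' @export
binarize_network <- function(image, method = c("global-otsu",
                                               "local-mean-offset"),
                             offset = 0, window_um = 5) {
  stopifnot(inherits(image, "image_volume"))
  method <- match.arg(method)
  x <- image$data
  rng <- range(x)
  if (diff(rng) == 0)
    stop("constant image: no two-phase segmentation possible")
  if (method == "global-otsu") {
    # Otsu only uses the intensity histogram, so flattening the volume to
    # a matrix is exact
    norm <- (x - rng[1]) / diff(rng)
    thr <- EBImage::otsu(matrix(norm, nrow = dim(x)[1]), range = c(0, 1),
                         levels = 256L)
    mask <- norm > thr
  } else {
    sig <- pmax(1, window_um / image$voxel_size_um / 2)
    local_mean <- gauss_blur_cpp(x, as.integer(dim(x)), sig)
    mask <- x > local_mean + offset
  }
  dim(mask) <- dim(x)
  binary_network(mask, image$voxel_size_um)
}

# distance from each phase voxel to the nearest out-of-phase voxel centre.
# The volume boundary is always "solid": for the fluid phase the outside
# is out-of-phase (pad_phase = FALSE), so pores may not extend outside the
# imaged field; for the fiber phase the outside continues the solid
# (pad_phase = TRUE), so fibrils crossing a face are not artificially
# thinned there.
phase_edt <- function(mask_phase, spacing, pad_phase = FALSE) {
  nd <- length(dim(mask_phase))
  padded <- array(pad_phase, dim(mask_phase) + 2L)
  idx <- lapply(dim(mask_phase), function(n) 1 + seq_len(n))
  if (nd == 2L) padded[idx[[1]], idx[[2]]] <- mask_phase
  else padded[idx[[1]], idx[[2]], idx[[3]]] <- mask_phase
  d <- edt_cpp(padded, as.integer(dim(padded)), spacing)
  d <- if (nd == 2L) d[idx[[1]], idx[[2]]] else d[idx[[1]], idx[[2]],
                                                  idx[[3]]]
  d[!mask_phase] <- 0
  array(d, dim(mask_phase))
}

# inscribed-sphere radius at each voxel of the phase: distance to the
# nearest out-of-phase voxel centre minus half the finest voxel edge, so
# that every voxel centre within the radius is guaranteed in-phase.
inscribed_radius <- function(mask_phase, spacing, pad_phase = FALSE) {
  r <- phase_edt(mask_phase, spacing, pad_phase) - min(spacing) / 2
  r[!mask_phase | r < 0] <- 0
  array(r, dim(mask_phase))
}

#' Pore-size analysis by residual sphere fitting
#'
#' Fits maximal inscribed spheres into the fluid phase of a binarized
#' network. One analysis step consists of (1) the Euclidean distance
#' transform of the fluid phase (anisotropic voxel sizes respected, volume
#' faces solid); (2) every fluid voxel as a candidate center, ranked by
#' decreasing distance with lexicographic voxel order as tie-break; (3)
#' greedy acceptance of every candidate whose center is not inside an
#' already-accepted sphere (accepted spheres may overlap). Each residual step then deletes the
#' accepted spheres from the fluid phase and repeats on the residual
#' space, capturing the smaller interstitial pores between the primary
#' ones. The sample pore size is the median of the pore-diameter
#' distribution pooled over all steps, with each pore weighted by the
#' fluid volume it newly covers; equivalently, the median over fluid
#' voxels of the diameter of the largest accepted sphere containing each
#' voxel. The volume weighting makes the estimate consistent with the
#' local-thickness definition of pore size and insensitive to the long
#' tail of voxel-scale interstitial spheres that any space-covering
#' scheme produces.
#'
#' @param binary a [binary_network()].
#' @param residual_steps number of residual steps after the primary one,
#'   or `"auto"` (default for 3D): keep adding steps while a step newly
#'   covers at least `min_new_fraction` of the fluid volume, up to
#'   `max_steps`.
#' @param max_steps cap on residual steps in `"auto"` mode.
#' @param min_new_fraction stopping fraction in `"auto"` mode.
#' @param min_diameter_vox resolution floor: accepted spheres smaller
#'   than this many voxels in diameter are space-covering artifacts below
#'   the resolution limit of the image and are excluded from the reported
#'   pore set (they still count as covered space for the residual steps).
#' @return A `pore_set`: data.frame with columns `x_um`, `y_um` (and
#'   `z_um` in 3D), `diameter_um`, `volume_um3` (newly covered fluid
#'   volume), `step` (0 = primary), with the sample median in
#'   `attr(, "median_pore_um")`.
#' @export
pore_size_spheres <- function(binary, residual_steps = "auto",
                              max_steps = 5L, min_new_fraction = 0.01,
                              min_diameter_vox = 2) {
  stopifnot(inherits(binary, "binary_network"))
  dims <- dim(binary$mask)
  nd <- length(dims)
  spacing <- binary$voxel_size_um
  fluid <- !binary$mask
  if (!any(fluid)) stop("empty fluid phase")
  auto <- identical(residual_steps, "auto")
  n_steps <- if (auto) max_steps else as.integer(residual_steps)
  vox_vol <- prod(spacing)
  fluid_vol <- sum(fluid) * vox_vol

  res <- list()
  for (step in 0:n_steps) {
    if (!any(fluid)) break
    r <- inscribed_radius(fluid, spacing)
    cand <- which(fluid)
    cand <- cand[order(-r[cand], cand)]
    g <- greedy_spheres_cpp(as.numeric(r), as.integer(cand - 1L),
                            as.integer(dims), spacing, fluid)
    if (length(g$index) == 0L) break
    xyz <- voxel_coords_um(g$index, dims, spacing)
    df <- data.frame(x_um = xyz[, 1], y_um = xyz[, 2])
    if (nd == 3L) df$z_um <- xyz[, 3]
    df$diameter_um <- 2 * g$radius
    df$volume_um3 <- g$n_new * vox_vol
    df$step <- step
    df$voxel_index <- g$index
    vol_step <- sum(df$volume_um3)
    df <- df[df$diameter_um >= min_diameter_vox * min(spacing), ,
             drop = FALSE]
    res[[step + 1L]] <- df
    if (auto && step > 0 && vol_step < min_new_fraction * fluid_vol)
      break
    fluid <- fluid & !as.logical(g$covered)
    dim(fluid) <- dims
  }
  pores <- do.call(rbind, res)
  if (is.null(pores) || nrow(pores) == 0L)
    stop("no pores at or above the resolution floor")
  structure(pores,
            median_pore_um = weighted_median(pores$diameter_um,
                                             pores$volume_um3),
            class = c("pore_set", "data.frame"))
}

# median of the distribution with masses w at values x (interpolation-free:
# the smallest x whose cumulative mass reaches half the total)
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1]]
}

#' @export
print.pore_set <- function(x, ...) {
  cat(sprintf("<pore_set> %d pores over %d step(s); median diameter %.3f um\n",
              nrow(x), length(unique(x$step)),
              attr(x, "median_pore_um")))
  invisible(x)
}

#' Brute-force local-thickness map
#'
#' For every voxel of the chosen phase, the diameter of the largest sphere
#' that is fully contained in the phase and contains that voxel, computed
#' by exhaustively painting the inscribed sphere of every phase voxel in
#' decreasing-radius order. This is the independent verifier for
#' [pore_size_spheres()]; its cost grows with the total painted volume, so
#' it is intended for moderate grids.
#'
#' The "oracle median pore diameter" of a sample is the median of this map
#' over the phase voxels (a volume-weighted pore-size distribution).
#'
#' @param binary a [binary_network()].
#' @param phase `"fluid"` (pores) or `"fiber"` (thickness).
#' @return Numeric array of local-thickness diameters (um), zero outside
#'   the phase.
#' @export
local_thickness_oracle <- function(binary, phase = c("fluid", "fiber")) {
  stopifnot(inherits(binary, "binary_network"))
  phase <- match.arg(phase)
  m <- phase_mask(binary, phase)
  if (!any(m)) stop("chosen phase is empty")
  dims <- dim(m)
  r <- inscribed_radius(m, binary$voxel_size_um,
                        pad_phase = phase == "fiber")
  ord <- which(m)
  ord <- ord[order(-r[ord], ord)]
  lt <- local_thickness_cpp(as.numeric(r), as.integer(ord - 1L),
                            as.integer(dims), binary$voxel_size_um)
  array(lt, dims)
}

#' Fiber-thickness analysis on the medial axis
#'
#' Runs the thickness estimate on the fiber phase rather than the fluid
#' phase: measurement points are the medial-axis voxels of the fiber
#' phase (the ridge of the Euclidean distance transform, i.e. in-phase
#' local maxima of the distance map, distributed along each fibril), and
#' the local diameter at each point is twice the Euclidean distance to
#' the fluid phase. A single analysis step is used — no residual steps —
#' and volume faces continue the fiber phase so fibrils leaving the field
#' are not artificially thinned. The voxel size is the effective
#' resolution floor of the estimate.
#'
#' @param binary a [binary_network()].
#' @return A `thickness_set`: data.frame of measurement points (`x_um`,
#'   `y_um`, optionally `z_um`, `diameter_um`) with `mean_um` and `sd_um`
#'   attributes.
#' @export
structure_thickness <- function(binary) {
  stopifnot(inherits(binary, "binary_network"))
  dims <- dim(binary$mask)
  nd <- length(dims)
  spacing <- binary$voxel_size_um
  if (!any(binary$mask)) stop("empty fiber phase")
  d <- phase_edt(binary$mask, spacing, pad_phase = TRUE)
  ridge <- local_maxima_cpp(d, as.integer(dims))
  idx <- which(as.logical(ridge))
  xyz <- voxel_coords_um(idx, dims, spacing)
  df <- data.frame(x_um = xyz[, 1], y_um = xyz[, 2])
  if (nd == 3L) df$z_um <- xyz[, 3]
  df$diameter_um <- 2 * d[idx]
  structure(df, mean_um = mean(df$diameter_um),
            sd_um = stats::sd(df$diameter_um),
            class = c("thickness_set", "data.frame"))
}

#' @export
print.thickness_set <- function(x, ...) {
  cat(sprintf("<thickness_set> %d measurement points; %.4f +/- %.4f um\n",
              nrow(x), attr(x, "mean_um"), attr(x, "sd_um")))
  invisible(x)
}

#' 2D pore and bundle-thickness analysis of an actin region
#'
#' The 2D variant of the pore-size algorithm applied to cut-out actin
#' fiber bundle regions: binarize within the region, fit pore disks with
#' exactly one residual step, and measure bundle thickness on the medial
#' axis of the actin phase. Pixels outside the region mask are treated as
#' solid so pores never leak outside the cut-out.
#'
#' @param image an [image_volume()] (2D).
#' @param region logical matrix, `TRUE` inside the region of interest.
#' @param method passed to [binarize_network()].
#' @return A list with `pores` (a `pore_set`) and `thickness` (a
#'   `thickness_set`).
#' @export
analyze_actin_region <- function(image, region = NULL,
                                 method = "global-otsu") {
  stopifnot(inherits(image, "image_volume"))
  if (length(dim(image$data)) != 2L)
    stop("analyze_actin_region expects a 2D image")
  if (is.null(region)) region <- array(TRUE, dim(image$data))
  if (!any(region)) stop("empty region mask")
  bin <- binarize_network(image, method = method)
  fiber <- bin$mask
  fiber[!region] <- TRUE  # outside the region counts as solid for pores
  pore_bin <- binary_network(fiber, image$voxel_size_um)
  pores <- pore_size_spheres(pore_bin, residual_steps = 1L)
  fib_only <- bin$mask & region
  if (!any(fib_only)) stop("no fiber phase inside region")
  thick <- structure_thickness(binary_network(fib_only,
                                              image$voxel_size_um))
  list(pores = pores, thickness = thick)
}
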