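#' Specification of a synthetic nucleus subvolume
#'
#' A rotated solid ellipsoid with semi-axes `a >= b >= c`, optionally with
#' a speckled interior texture (multiplicative log-normal speckle of
#' adjustable contrast emulating chromatin granularity), rendered into an
#' isotropic voxel grid with Gaussian noise.
#'
#' @param semi_axes_um semi-axes (a, b, c), um, sorted decreasing.
#' @param angles_rad rotation angles (z-y-z Euler), radians.
#' @param voxel_um voxel size, um.
#' @param texture `"uniform"` or `"speckled"`.
#' @param contrast speckle contrast parameter (sd of log-intensity).
#' @param noise_sd additive Gaussian noise sd.
#' @param seed integer seed.
#' @return An object of class `nucleus_volume_spec`.
#' @export
nucleus_volume_spec <- function(semi_axes_um = c(8, 5, 3),
                                angles_rad = c(0, 0, 0), voxel_um = 0.5,
                                texture = c("uniform", "speckled"),
                                contrast = 0.3, noise_sd = 0.02,
                                seed = 1L) {
  texture <- match.arg(texture)
  s <- sort(as.numeric(semi_axes_um), decreasing = TRUE)
  if (any(s <= 0)) stop("semi-axes must satisfy a >= b >= c > 0")
  structure(list(semi_axes_um = s, angles_rad = angles_rad,
                 voxel_um = voxel_um, texture = texture,
                 contrast = contrast, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "nucleus_volume_spec")
}

euler_zyz <- function(a) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                             sin(t), 0, cos(t)), 3, 3)
  rz(a[1]) %*% ry(a[2]) %*% rz(a[3])
}

#' Generate a synthetic nucleus subvolume with ground-truth mask
#'
#' @param spec a [nucleus_volume_spec()].
#' @return list with `image` ([image_volume()]), `mask` (logical array
#'   ground truth) and `centre_um`.
#' @export
generate_nucleus_volume <- function(spec) {
  stopifnot(inherits(spec, "nucleus_volume_spec"))
  pad <- 3
  ext <- 2 * (max(spec$semi_axes_um) + pad)
  nvox <- ceiling(ext / spec$voxel_um)
  dims <- rep(nvox, 3L)
  spacing <- rep(spec$voxel_um, 3L)
  centre <- (dims - 1) * spacing / 2
  rot <- euler_zyz(spec$angles_rad)
  mask <- raster_ellipsoid_cpp(as.integer(dims), spacing, centre,
                               spec$semi_axes_um, rot)
  mask <- array(as.logical(mask), dims)
  with_seed(spec$seed, {
    img <- array(0.1, dims)
    inside <- rep(1, sum(mask))
    if (spec$texture == "speckled") {
      speck <- array(stats::rnorm(prod(dims)), dims)
      speck <- gauss_blur_cpp(speck, as.integer(dims), rep(1.5, 3))
      speck <- speck / stats::sd(speck)
      inside <- exp(spec$contrast * speck[mask])
      inside <- inside / mean(inside)
    }
    img[mask] <- 0.1 + inside
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    dim(img) <- dims
    list(image = image_volume(img, spacing), mask = mask,
         centre_um = centre)
  })
}

#' Segment one nucleus from a subvolume
#'
#' Otsu threshold within the subvolume, then the connected component
#' containing the seed point, with interior holes filled (any background
#' component not touching the subvolume border is absorbed into the
#' mask).
#'
#' @param subvolume an [image_volume()].
#' @param seed_point voxel index (1-based, length 3) inside the nucleus.
#' @return logical array mask.
#' @export
segment_nucleus <- function(subvolume, seed_point) {
  stopifnot(inherits(subvolume, "image_volume"))
  x <- subvolume$data
  dims <- dim(x)
  seed_point <- as.integer(seed_point)
  if (any(seed_point < 1L) || any(seed_point > dims))
    stop("seed point outside subvolume")
  rng <- range(x)
  if (diff(rng) == 0) stop("uniform subvolume: nothing to segment")
  norm <- (x - rng[1]) / diff(rng)
  thr <- EBImage::otsu(matrix(norm, nrow = dims[1]), range = c(0, 1),
                       levels = 256L)
  fg <- array(norm > thr, dims)
  lab <- label_components_cpp(fg, as.integer(dims), 6L)
  seed_lab <- lab[seed_point[1], seed_point[2], seed_point[3]]
  if (seed_lab == 0L) stop("seed point falls in background after thresholding")
  mask <- array(lab == seed_lab, dims)
  # fill interior holes: background components not touching the border
  bg <- label_components_cpp(!mask, as.integer(dims), 6L)
  border_labs <- unique(c(bg[1, , ], bg[dims[1], , ], bg[, 1, ],
                          bg[, dims[2], ], bg[, , 1], bg[, , dims[3]]))
  hole <- !mask & !(bg %in% border_labs)
  mask | array(hole, dims)
}

#' Ellipsoid-equivalent shape metrics of a nucleus mask
#'
#' Axis lengths come from the eigen-decomposition of the voxel-coordinate
#' covariance: for a uniform solid ellipsoid the variance along a
#' principal axis of semi-length `a` is `a^2/5` in 3D (`a^2/4` in 2D), so
#' axis length `= 2 * sqrt(5 * lambda)` in 3D returns the true axis
#' lengths of an ideal ellipsoid in any orientation. Volume is the voxel
#' count times the voxel volume.
#'
#' @param mask logical array (2D or 3D).
#' @param voxel_size_um per-axis voxel size, um.
#' @return list of class `nucleus_shape`: `minor_um`, `major_um`,
#'   `axes_um` (sorted decreasing), `aspect_ratio`, `volume_um3`,
#'   `low_confidence` (mask thinner than 2 voxels on some principal
#'   axis).
#' @export
shape_metrics <- function(mask, voxel_size_um) {
  if (!any(mask)) stop("empty mask")
  dims <- dim(mask)
  nd <- length(dims)
  voxel_size_um <- rep(as.numeric(voxel_size_um), length.out = nd)
  idx <- which(mask)
  coords <- voxel_coords_um(idx, dims, voxel_size_um)
  cf <- if (nd == 3L) 5 else 4  # uniform solid ellipsoid variance factor
  cv <- stats::cov(coords)
  # add the voxel's own second moment so single-voxel-thin masks are finite
  diag(cv) <- diag(cv) + voxel_size_um^2 / 12
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  axes <- 2 * sqrt(cf * pmax(ev, 0))
  vol <- length(idx) * prod(voxel_size_um)
  structure(list(minor_um = axes[nd], major_um = axes[1], axes_um = axes,
                 aspect_ratio = axes[1] / axes[nd],
                 volume_um3 = vol,
                 low_confidence = axes[nd] < 2 * max(voxel_size_um)),
            class = "nucleus_shape")
}

#' @export
print.nucleus_shape <- function(x, ...) {
  cat(sprintf(paste0("<nucleus_shape> minor %.2f um, major %.2f um, ",
                     "aspect %.2f, volume %.1f um^3%s\n"),
              x$minor_um, x$major_um, x$aspect_ratio, x$volume_um3,
              if (x$low_confidence) " (low confidence)" else ""))
  invisible(x)
}

#' Chromatin intensity-variation score
#'
#' A deliberately simple texture surrogate: the coefficient of variation
#' of background-subtracted intensities inside the nucleus mask. It is
#' zero for a uniform nucleus, strictly increasing in speckle contrast,
#' and invariant to global intensity rescaling — sufficient to rank
#' chromatin condensation states, but not a reconstruction of any
#' published chromatin-heterogeneity algorithm.
#'
#' @param subvolume an [image_volume()].
#' @param mask logical array from [segment_nucleus()].
#' @param background background level to subtract; default is the median
#'   intensity outside the mask.
#' @return dimensionless variation score.
#' @export
chromatin_variation <- function(subvolume, mask, background = NULL) {
  stopifnot(inherits(subvolume, "image_volume"))
  if (!any(mask)) stop("empty mask")
  x <- subvolume$data
  if (is.null(background))
    background <- if (all(mask)) 0 else stats::median(x[!mask])
  v <- x[mask] - background
  m <- mean(v)
  if (m <= 0) stop("non-positive mean intensity inside mask")
  stats::sd(v) / m
}
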