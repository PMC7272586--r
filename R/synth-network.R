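#' Specification of a synthetic fibrous network
#'
#' Describes a two-phase fibrous network to be rendered as a voxel image:
#' straight random chords (a Mikado model) of Gaussian-distributed
#' diameter, dilated to their physical thickness, blurred with a separable
#' Gaussian point-spread function and corrupted with noise. Either the
#' number of fibers or a target median pore diameter is given; in the
#' latter case [calibrate_fiber_count()] resolves the count against the
#' brute-force local-thickness oracle.
#'
#' Defaults emulate confocal acquisitions of collagen matrices: large
#' cubes (150 um edge) for pore-size analysis and small high-resolution
#' cubes (25 um edge, 0.05 um voxels) for fibril-thickness analysis. The
#' voxel sizes are package defaults, not measured values.
#'
#' @param dimensionality 2 or 3.
#' @param edge_um physical edge length of the (square/cubic) field, um.
#' @param voxel_um voxel size, um (scalar, isotropic; anisotropic grids
#'   can be analyzed but are not generated).
#' @param fiber_diameter_um mean fiber diameter, um.
#' @param fiber_diameter_sd_um standard deviation of fiber diameter, um.
#' @param n_fibers number of chords; mutually exclusive with
#'   `target_pore_um`.
#' @param target_pore_um target median pore diameter, um; resolved to a
#'   fiber count by [calibrate_fiber_count()].
#' @param psf_sigma_um per-axis Gaussian PSF sigma, um.
#' @param noise_sd Gaussian noise standard deviation on the unit-intensity
#'   image.
#' @param poisson_noise if `TRUE`, apply Poisson photon noise before the
#'   Gaussian read noise.
#' @param seed integer seed; all randomness in the generator is drawn from
#'   a private stream seeded with it.
#' @return An object of class `fiber_network_spec`.
#' @export
fiber_network_spec <- function(dimensionality = 3, edge_um = 37.12,
                               voxel_um = 0.29, fiber_diameter_um = 0.7,
                               fiber_diameter_sd_um = 0, n_fibers = NULL,
                               target_pore_um = NULL,
                               psf_sigma_um = voxel_um,
                               noise_sd = 0.03, poisson_noise = FALSE,
                               seed = 1L) {
  if (!dimensionality %in% c(2, 3)) stop("dimensionality must be 2 or 3")
  if (voxel_um <= 0) stop("voxel size must be positive")
  if (fiber_diameter_um < 2 * voxel_um)
    stop("fiber diameter must span at least 2 voxels after rasterization")
  if (is.null(n_fibers) == is.null(target_pore_um))
    stop("exactly one of n_fibers and target_pore_um must be set")
  if (!is.null(target_pore_um) && target_pore_um >= edge_um)
    stop("target pore diameter exceeds the volume edge: infeasible")
  if (!is.null(n_fibers) && n_fibers < 0) stop("n_fibers must be >= 0")
  psf_sigma_um <- rep(as.numeric(psf_sigma_um),
                      length.out = dimensionality)
  structure(list(dimensionality = as.integer(dimensionality),
                 edge_um = edge_um, voxel_um = voxel_um,
                 fiber_diameter_um = fiber_diameter_um,
                 fiber_diameter_sd_um = fiber_diameter_sd_um,
                 n_fibers = n_fibers, target_pore_um = target_pore_um,
                 psf_sigma_um = psf_sigma_um, noise_sd = noise_sd,
                 poisson_noise = poisson_noise, seed = as.integer(seed)),
            class = "fiber_network_spec")
}

# evaluate expr under a private RNG stream so generators do not disturb
# (or depend on) the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                          envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# sample a chord through the field: a point inside plus a uniform random
# direction, extended to the bounding box
sample_chords <- function(n, edge, nd) {
  p0 <- matrix(stats::runif(n * 3, 0, edge), n, 3)
  if (nd == 2L) p0[, 3] <- 0
  if (nd == 3L) {
    z <- stats::runif(n, -1, 1)
    th <- stats::runif(n, 0, 2 * pi)
    r <- sqrt(pmax(0, 1 - z^2))
    dir <- cbind(r * cos(th), r * sin(th), z)
  } else {
    th <- stats::runif(n, 0, pi)
    dir <- cbind(cos(th), sin(th), 0)
  }
  half <- 2 * edge  # long enough to always cross the box
  list(p0 = p0 - half * dir, p1 = p0 + half * dir)
}

#' Generate a synthetic fibrous network image with ground truth
#'
#' Renders the Mikado chords of a [fiber_network_spec()] into a binary
#' fiber mask (the exact, pre-blur ground truth), then produces the
#' intensity image by PSF blurring and adding noise. Deterministic for a
#' fixed seed.
#'
#' @param spec a [fiber_network_spec()]; its fiber count must be resolved
#'   (use [calibrate_fiber_count()] for pore-targeted specs).
#' @return A list with `image` ([image_volume()]) and `truth`
#'   ([binary_network()]).
#' @export
generate_fiber_network <- function(spec) {
  stopifnot(inherits(spec, "fiber_network_spec"))
  if (is.null(spec$n_fibers))
    stop("fiber count unresolved; run calibrate_fiber_count() first")
  nd <- spec$dimensionality
  nvox <- max(2L, round(spec$edge_um / spec$voxel_um))
  dims <- rep(nvox, nd)
  spacing <- rep(spec$voxel_um, nd)
  with_seed(spec$seed, {
    n <- spec$n_fibers
    if (n > 0) {
      ch <- sample_chords(n, spec$edge_um, nd)
      diam <- stats::rnorm(n, spec$fiber_diameter_um,
                           spec$fiber_diameter_sd_um)
      diam <- pmax(diam, 2 * spec$voxel_um)
      mask <- raster_fibers_cpp(as.integer(dims), spacing,
                                ch$p0[, seq_len(3), drop = FALSE],
                                ch$p1[, seq_len(3), drop = FALSE],
                                diam / 2)
    } else {
      mask <- array(FALSE, dims)
    }
    img <- array(as.numeric(mask), dims)
    sig <- spec$psf_sigma_um / spacing
    if (any(sig > 0)) img <- gauss_blur_cpp(img, as.integer(dims), sig)
    if (spec$poisson_noise) {
      photons <- 200
      img <- stats::rpois(length(img), img * photons) / photons
      dim(img) <- dims
    }
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    dim(img) <- dims
    list(image = image_volume(img, spacing),
         truth = binary_network(array(as.logical(mask), dims), spacing))
  })
}

#' Resolve a target median pore diameter to a fiber count
#'
#' Bisection on the number of fibers against the brute-force
#' local-thickness oracle ([local_thickness_oracle()]): at each trial
#' count a network is rendered with the spec's seed and the oracle median
#' pore diameter of its ground-truth binary is compared to the target.
#' Stops when the oracle median is within `tol` (relative) of the target.
#'
#' @param spec a [fiber_network_spec()] with `target_pore_um` set.
#' @param tol relative tolerance on the oracle median (default 5%).
#' @param max_iter maximum bisection iterations.
#' @return The resolved spec (`n_fibers` set, `target_pore_um` kept for
#'   reference) with the achieved oracle median in
#'   `attr(, "oracle_median_um")`.
#' @export
calibrate_fiber_count <- function(spec, tol = 0.05, max_iter = 30L) {
  stopifnot(inherits(spec, "fiber_network_spec"))
  if (is.null(spec$target_pore_um))
    stop("spec has no target pore diameter")
  target <- spec$target_pore_um
  if (target >= spec$edge_um) stop("infeasible target pore diameter")

  eval_count <- function(n) {
    s <- spec
    s$n_fibers <- as.integer(n)
    s$target_pore_um <- NULL
    net <- generate_fiber_network(s)
    lt <- local_thickness_oracle(net$truth, phase = "fluid")
    stats::median(lt[!net$truth$mask])
  }

  # initial guess from the mean chord spacing of a Poisson line/fiber
  # process: pore diameter scales ~ n^(-1/(d-1)) for chords crossing a
  # d-dimensional box
  nd <- spec$dimensionality
  n0 <- max(4, round(if (nd == 3L) (2 * spec$edge_um / target)^2
                     else 2 * spec$edge_um / target))
  lo <- NULL; hi <- NULL  # lo: count with median > target (too sparse)
  n <- n0
  m <- eval_count(n)
  for (i in seq_len(20)) {
    if (abs(m - target) / target <= tol) break
    if (m > target) { lo <- c(n, m); n2 <- if (is.null(hi)) n * 2 else
      round((n + hi[1]) / 2) }
    else { hi <- c(n, m); n2 <- if (is.null(lo)) max(2, round(n / 2)) else
      round((n + lo[1]) / 2) }
    if (!is.null(lo) && !is.null(hi) && hi[1] - lo[1] <= 1) break
    n <- n2
    m <- eval_count(n)
    if (i >= max_iter) break
  }
  if (abs(m - target) / target > tol) {
    # fall back to the better bracket end
    cand <- rbind(lo, hi, c(n, m))
    best <- cand[which.min(abs(cand[, 2] - target)), ]
    n <- best[1]; m <- best[2]
    if (abs(m - target) / target > tol)
      stop(sprintf(paste0("calibration failed to bracket target %.3g um ",
                          "(best oracle median %.3g um)"), target, m))
  }
  out <- spec
  out$n_fibers <- as.integer(n)
  attr(out, "oracle_median_um") <- m
  out
}
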