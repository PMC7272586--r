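#' Intensity image volume with physical voxel size
#'
#' The common currency of all imaging stages: a 2D or 3D numeric array of
#' intensities together with the physical voxel size per axis, in
#' micrometres. Confocal acquisitions are typically anisotropic (coarser in
#' z), so the voxel size is always carried per axis and every reported
#' length is in micrometres, never in voxels.
#'
#' @param data numeric array (2D matrix or 3D array) of intensities.
#' @param voxel_size_um numeric vector of per-axis voxel edge lengths in
#'   micrometres; length must match the dimensionality of `data`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, voxel_size_um) {
  if (!is.array(data)) data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(2L, 3L)) stop("image_volume: data must be 2D or 3D")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, nd)
  if (length(voxel_size_um) != nd)
    stop("image_volume: voxel_size_um must have one entry per axis")
  if (any(!is.finite(voxel_size_um)) || any(voxel_size_um <= 0))
    stop("image_volume: voxel sizes must be positive")
  structure(list(data = data, voxel_size_um = voxel_size_um),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %s voxels, voxel size %s um, extent %s um\n",
              paste(d, collapse = " x "),
              paste(signif(x$voxel_size_um, 4), collapse = " x "),
              paste(signif(d * x$voxel_size_um, 4), collapse = " x ")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Two-phase segmentation of a fibrous network
#'
#' A binary grid separating the fiber phase (collagen fibrils or actin
#' bundles, `TRUE`) from the fluid phase (`FALSE`), with the physical voxel
#' size attached. All pore-size and thickness estimates operate on this
#' representation.
#'
#' @param mask logical array; `TRUE` marks the fiber phase.
#' @param voxel_size_um per-axis voxel size in micrometres.
#' @return An object of class `binary_network`.
#' @export
binary_network <- function(mask, voxel_size_um) {
  if (!is.array(mask)) mask <- as.array(mask)
  if (!is.logical(mask)) stop("binary_network: mask must be logical")
  nd <- length(dim(mask))
  if (!nd %in% c(2L, 3L)) stop("binary_network: mask must be 2D or 3D")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, nd)
  if (length(voxel_size_um) != nd || any(voxel_size_um <= 0))
    stop("binary_network: invalid voxel sizes")
  structure(list(mask = mask, voxel_size_um = voxel_size_um),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %s voxels, fiber fraction %.3f\n",
              paste(dim(x$mask), collapse = " x "), mean(x$mask)))
  invisible(x)
}

phase_mask <- function(binary, phase = c("fluid", "fiber")) {
  phase <- match.arg(phase)
  if (phase == "fiber") binary$mask else !binary$mask
}

#' Write an image volume as multi-page TIFF plus sidecar JSON
#'
#' Intensities are rescaled to \[0, 1\] for 16-bit TIFF storage; the scale
#' and the voxel size are recorded in a sidecar `<file>.json` so that
#' [read_image_volume()] restores physical units.
#'
#' @param x an [image_volume()].
#' @param file output TIFF path.
#' @return `file`, invisibly.
#' @export
write_image_volume <- function(x, file) {
  stopifnot(inherits(x, "image_volume"))
  d <- dim(x$data)
  lo <- min(x$data); hi <- max(x$data)
  scale <- if (hi > lo) hi - lo else 1
  norm <- (x$data - lo) / scale
  pages <- if (length(d) == 2L) list(t(norm)) else
    lapply(seq_len(d[3]), function(k) t(norm[, , k]))
  tiff::writeTIFF(pages, file, bits.per.sample = 16L)
  meta <- list(voxel_size_um = x$voxel_size_um,
               intensity_offset = lo, intensity_scale = scale)
  jsonlite::write_json(meta, paste0(file, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read an image volume written by [write_image_volume()]
#'
#' @param file TIFF path with sidecar `<file>.json`.
#' @return An [image_volume()].
#' @export
read_image_volume <- function(file) {
  pages <- tiff::readTIFF(file, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  arr <- vapply(pages, function(p) t(p), matrix(0, ncol(pages[[1]]),
                                                nrow(pages[[1]])))
  if (length(dim(arr)) == 3L && dim(arr)[3] == 1L) arr <- arr[, , 1]
  data <- arr * meta$intensity_scale + meta$intensity_offset
  image_volume(data, meta$voxel_size_um)
}

# physical coordinates (um) of voxel indices (1-based), origin at first
# voxel centre
voxel_coords_um <- function(idx, dims, spacing) {
  nd <- length(dims)
  out <- matrix(0, length(idx), nd)
  rem <- idx - 1L
  for (ax in seq_len(nd)) {
    out[, ax] <- (rem %% dims[ax]) * spacing[ax]
    rem <- rem %/% dims[ax]
  }
  out
}
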