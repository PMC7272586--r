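#' Detect nuclei in gridded z-stacks
#'
#' Band-pass blob detection at the nucleus scale: a difference-of-Gaussians
#' filter (inner sigma = expected radius / sqrt(3), the blob-optimal
#' scale; outer sigma 1.6x larger), 3D local maxima of the response, a
#' robust response threshold at `k_mad` median absolute deviations above
#' the median response, intensity-weighted subvoxel centroid refinement,
#' and duplicate suppression within one nucleus radius. Two nuclei closer
#' than the merge radius collapse into one detection — a documented
#' limitation of any single-scale detector.
#'
#' @param stacks list of [image_volume()] (one per grid position) or a
#'   single volume.
#' @param nucleus_radius_um expected nucleus radius, um.
#' @param k_mad detection threshold in MADs above the median filter
#'   response; the default of 10 (about 6.7 Gaussian sd) keeps the
#'   expected number of false maxima below one per multi-million-voxel
#'   acquisition.
#' @return data.frame of detections: `id`, `stack`, `x_um`, `y_um`,
#'   `z_um`.
#' @export
detect_nuclei <- function(stacks, nucleus_radius_um = 6, k_mad = 10) {
  if (inherits(stacks, "image_volume")) stacks <- list(stacks)
  if (length(stacks) == 0L) stop("no stacks supplied")
  if (is.null(names(stacks)))
    names(stacks) <- sprintf("stack_%03d", seq_along(stacks))
  zs <- vapply(stacks, function(s) s$voxel_size_um[3], 1.0)
  if (length(unique(round(zs, 9))) != 1L)
    stop("stacks must share a uniform z spacing")
  out <- list()
  nid <- 0L
  for (sn in names(stacks)) {
    vol <- stacks[[sn]]
    dims <- dim(vol$data)
    spacing <- vol$voxel_size_um
    s1 <- (nucleus_radius_um / sqrt(3)) / spacing
    s2 <- 1.6 * s1
    dog <- gauss_blur_cpp(vol$data, as.integer(dims), s1) -
      gauss_blur_cpp(vol$data, as.integer(dims), s2)
    thr <- stats::median(dog) + k_mad * stats::mad(dog)
    resp <- dog
    resp[resp < thr] <- 0
    mx <- which(as.logical(local_maxima_cpp(resp, as.integer(dims))) &
                  resp > 0)
    if (length(mx) == 0L) next
    mx <- mx[order(-dog[mx])]
    # duplicate suppression within one nucleus radius
    pos <- voxel_coords_um(mx, dims, spacing)
    keep <- rep(TRUE, length(mx))
    for (i in seq_along(mx)) {
      if (!keep[i]) next
      if (i < length(mx)) {
        later <- (i + 1):length(mx)
        d2 <- colSums((t(pos[later, , drop = FALSE]) - pos[i, ])^2)
        keep[later][d2 < nucleus_radius_um^2] <- FALSE
      }
    }
    mx <- mx[keep]
    pos <- pos[keep, , drop = FALSE]
    # subvoxel refinement: intensity-weighted centroid in a local window
    win <- pmax(1L, round(nucleus_radius_um / spacing))
    for (i in seq_along(mx)) {
      v <- arrayInd(mx[i], dims)
      rng <- lapply(1:3, function(a)
        max(1L, v[a] - win[a]):min(dims[a], v[a] + win[a]))
      sub <- vol$data[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
      sub <- pmax(sub - min(sub), 0)
      w <- sum(sub)
      if (w > 0) {
        for (a in 1:3) {
          coords <- (rng[[a]] - 1) * spacing[a]
          marg <- apply(sub, a, sum)
          pos[i, a] <- sum(coords * marg) / w
        }
      }
    }
    nid <- nid + seq_len(nrow(pos))
    out[[sn]] <- data.frame(id = nid, stack = sn, x_um = pos[, 1],
                            y_um = pos[, 2], z_um = pos[, 3])
    nid <- max(nid)
  }
  if (length(out) == 0L)
    return(data.frame(id = integer(), stack = character(),
                      x_um = numeric(), y_um = numeric(),
                      z_um = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Estimate the matrix surface from detected nucleus positions
#'
#' The adherent (non-invasive) cell layer dominates the z histogram, so
#' the surface is found as the mode of the z histogram with bin width
#' equal to the z spacing (bins anchored at the shallowest record, which
#' makes the estimate exactly equivariant under z shifts); the returned
#' surface is the median z of the records in the modal bin. Ties between
#' equally tall bins are broken toward the shallower (smaller z) one.
#'
#' @param records data.frame with a `z_um` column.
#' @param z_step_um histogram bin width (the acquisition z-spacing), um.
#' @return list with `z0_um` and `bin_um`.
#' @export
estimate_surface <- function(records, z_step_um = 4) {
  if (nrow(records) < 10L)
    stop("too few records to estimate a surface (need >= 10)")
  z <- records$z_um
  bin <- floor((z - min(z)) / z_step_um + 0.5)
  counts <- table(bin)
  modal <- as.numeric(names(counts)[which.max(counts)])
  list(z0_um = stats::median(z[bin == modal]), bin_um = z_step_um)
}

#' Classify invasive cells by depth below the surface
#'
#' Depth is measured positive downward from the surface (`depth = z - z0`)
#' and a cell is invasive iff it lies strictly deeper than the threshold
#' (default 8 um); cells at or above the threshold are non-invasive,
#' which absorbs small surface roughness into the adherent class.
#'
#' @param records data.frame with `z_um`.
#' @param z0_um surface position (from [estimate_surface()]), um.
#' @param threshold_um invasion depth threshold, um.
#' @return `records` with `depth_um` and logical `invasive` columns.
#' @export
classify_invasive <- function(records, z0_um, threshold_um = 8) {
  records$depth_um <- records$z_um - z0_um
  records$invasive <- records$depth_um > threshold_um
  records
}

#' Summarize invasiveness per condition
#'
#' Computes, per replicate, the percentage of invasive cells and the mean
#' invasion depth of the invasive cells only (the adherent surface layer
#' is excluded from the depth statistic), then reports mean and sd across
#' replicates.
#'
#' @param records classified records (see [classify_invasive()]).
#' @param replicate optional column name identifying replicate wells;
#'   `NULL` treats all records as one replicate.
#' @return list with `n_cells`, `percent_invasive` (mean, sd),
#'   `invasion_depth_um` (mean, sd) and the per-replicate table.
#' @export
summarize_invasion <- function(records, replicate = NULL) {
  if (nrow(records) == 0L) stop("no cells to summarize")
  rep_key <- if (is.null(replicate)) rep("all", nrow(records)) else
    as.character(records[[replicate]])
  groups <- split(records, rep_key)
  per <- do.call(rbind, lapply(names(groups), function(g) {
    r <- groups[[g]]
    data.frame(replicate = g, n = nrow(r),
               percent_invasive = 100 * mean(r$invasive),
               invasion_depth_um = if (any(r$invasive))
                 mean(r$depth_um[r$invasive]) else NA_real_)
  }))
  rownames(per) <- NULL
  list(n_cells = nrow(records),
       percent_invasive = c(mean = mean(per$percent_invasive),
                            sd = stats::sd(per$percent_invasive)),
       invasion_depth_um = c(mean = mean(per$invasion_depth_um,
                                         na.rm = TRUE),
                             sd = stats::sd(per$invasion_depth_um,
                                            na.rm = TRUE)),
       per_replicate = per)
}

#' Empirical cumulative distribution of invasion depth
#'
#' Right-continuous ECDF of `depth_um`: the probability for cells to lie
#' at a given depth or above it (shallower), evaluable on any depth grid.
#'
#' @param records data.frame with `depth_um`.
#' @return A function of class `ecdf`.
#' @export
cumulative_depth <- function(records) {
  if (nrow(records) == 0L) stop("no records")
  stats::ecdf(records$depth_um)
}

#' Deepest fraction of invasive cells
#'
#' Returns the `ceiling(fraction * n)` invasive records of greatest depth;
#' records tied with the boundary depth are all included, so the subset
#' may exceed the nominal size.
#'
#' @param records classified records.
#' @param fraction fraction of invasive cells to keep (default 10%).
#' @return Subset of `records`.
#' @export
deepest_fraction <- function(records, fraction = 0.10) {
  inv <- records[records$invasive, , drop = FALSE]
  if (nrow(inv) < 10L) stop("too few invasive records (need >= 10)")
  k <- ceiling(fraction * nrow(inv))
  cut <- sort(inv$depth_um, decreasing = TRUE)[k]
  inv[inv$depth_um >= cut, , drop = FALSE]
}
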