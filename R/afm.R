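#' Hertz force for a spherical indenter
#'
#' The spherical-contact Hertz model `F = (4/3) E / (1 - nu^2) sqrt(R)
#' delta^(3/2)` for a rigid sphere of radius `R` indenting an elastic
#' half-space by depth `delta`. Units: E in Pa, R and delta in um, force
#' returned in nN.
#'
#' @param delta_um indentation depth(s), um; values <= 0 return 0.
#' @param E_Pa Young's modulus, Pa.
#' @param nu Poisson ratio (0.5 = incompressible).
#' @param R_um indenter bead radius, um.
#' @return Force in nN.
#' @export
hertz_force <- function(delta_um, E_Pa, nu, R_um) {
  d <- pmax(delta_um, 0) * 1e-6
  f_n <- (4 / 3) * E_Pa / (1 - nu^2) * sqrt(R_um * 1e-6) * d^1.5
  f_n * 1e9
}

#' Specification of a synthetic AFM force-distance curve
#'
#' Generates Hertzian approach/retract force-position curves: zero force
#' (plus a linear baseline and noise) before the contact point `z0`, the
#' Hertz spherical-contact force beyond it, sampled on a regular position
#' grid until the force setpoint is reached. Optional spike artifacts
#' emulate disturbed curves (dirt, dead cells) that the residual-RMS
#' filter must reject.
#'
#' @param E_Pa Young's modulus, Pa (> 0).
#' @param nu Poisson ratio, in \[0, 0.5\].
#' @param R_um bead radius, um.
#' @param z0_um contact-point position, um (measured along the approach
#'   axis; z increases toward/into the sample).
#' @param setpoint_nN maximum force setpoint, nN.
#' @param baseline_nN baseline force offset, nN.
#' @param baseline_slope_nN_um baseline slope, nN per um.
#' @param noise_sd_pN Gaussian force noise sd, pN.
#' @param spike_prob per-sample probability of a spike artifact.
#' @param spike_nN spike amplitude, nN.
#' @param dz_um position sampling step, um.
#' @param protocol protocol tag: `"matrix"`, `"cytoskeleton"` or
#'   `"nucleus"`.
#' @param repeat_index repeat number (nucleus protocol measures one point
#'   several times).
#' @param seed integer seed.
#' @return An object of class `force_curve_spec`.
#' @export
force_curve_spec <- function(E_Pa, nu = 0.5, R_um = 3, z0_um = 2,
                             setpoint_nN = 5, baseline_nN = 0,
                             baseline_slope_nN_um = 0, noise_sd_pN = 0,
                             spike_prob = 0, spike_nN = 2,
                             dz_um = 0.005,
                             protocol = c("nucleus", "cytoskeleton",
                                          "matrix"),
                             repeat_index = 1L, seed = 1L) {
  protocol <- match.arg(protocol)
  if (E_Pa <= 0) stop("E must be > 0")
  if (nu < 0 || nu > 0.5) stop("nu must be in [0, 0.5]")
  if (R_um <= 0) stop("R must be > 0")
  if (setpoint_nN <= 3 * noise_sd_pN * 1e-3)
    stop("setpoint at or below the noise floor")
  structure(list(E_Pa = E_Pa, nu = nu, R_um = R_um, z0_um = z0_um,
                 setpoint_nN = setpoint_nN, baseline_nN = baseline_nN,
                 baseline_slope_nN_um = baseline_slope_nN_um,
                 noise_sd_pN = noise_sd_pN, spike_prob = spike_prob,
                 spike_nN = spike_nN, dz_um = dz_um, protocol = protocol,
                 repeat_index = as.integer(repeat_index),
                 seed = as.integer(seed)),
            class = "force_curve_spec")
}

#' Generate a synthetic force-distance curve
#'
#' @param spec a [force_curve_spec()].
#' @return An object of class `force_curve`: list with `approach` and
#'   `retract` data.frames (`z_um`, `F_nN`), plus probe metadata
#'   (`R_um`, `setpoint_nN`, `protocol`, `repeat_index`).
#' @export
generate_force_curve <- function(spec) {
  stopifnot(inherits(spec, "force_curve_spec"))
  # indentation needed to reach the setpoint
  dmax <- (spec$setpoint_nN * 1e-9 /
             ((4 / 3) * spec$E_Pa / (1 - spec$nu^2) *
                sqrt(spec$R_um * 1e-6)))^(2 / 3) * 1e6
  z <- seq(0, spec$z0_um + dmax, by = spec$dz_um)
  f_model <- hertz_force(z - spec$z0_um, spec$E_Pa, spec$nu, spec$R_um) +
    spec$baseline_nN + spec$baseline_slope_nN_um * z
  with_seed(spec$seed, {
    noisy <- function(f) {
      if (spec$noise_sd_pN > 0)
        f <- f + stats::rnorm(length(f), 0, spec$noise_sd_pN * 1e-3)
      if (spec$spike_prob > 0) {
        sp <- stats::runif(length(f)) < spec$spike_prob
        f[sp] <- f[sp] + spec$spike_nN
      }
      f
    }
    approach <- data.frame(z_um = z, F_nN = noisy(f_model))
    retract <- data.frame(z_um = rev(z), F_nN = noisy(rev(f_model)))
    structure(list(approach = approach, retract = retract,
                   R_um = spec$R_um, setpoint_nN = spec$setpoint_nN,
                   protocol = spec$protocol,
                   repeat_index = spec$repeat_index,
                   true_E_Pa = spec$E_Pa, true_z0_um = spec$z0_um),
              class = "force_curve")
  })
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(paste0("<force_curve> %s protocol, R = %g um, setpoint ",
                     "%g nN, %d + %d samples\n"), x$protocol, x$R_um,
              x$setpoint_nN, nrow(x$approach), nrow(x$retract)))
  invisible(x)
}

#' Write a force curve in the package's tabular text format
#'
#' Self-describing TSV: `# key: value` header lines (bead_radius_um,
#' setpoint_nN, protocol, repeat) followed by columns `segment`, `z_um`,
#' `F_nN`.
#'
#' @param curve a `force_curve`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_force_curve <- function(curve, file) {
  stopifnot(inherits(curve, "force_curve"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# bead_radius_um: %.17g", curve$R_um),
               sprintf("# setpoint_nN: %.17g", curve$setpoint_nN),
               sprintf("# protocol: %s", curve$protocol),
               sprintf("# repeat: %d", curve$repeat_index),
               "segment\tz_um\tF_nN"), con)
  seg <- rbind(cbind(segment = "approach",
                     format(curve$approach, digits = 17)),
               cbind(segment = "retract",
                     format(curve$retract, digits = 17)))
  utils::write.table(seg, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Parse a force curve from the tabular text format
#'
#' @param file path written by [write_force_curve()] (or converted from an
#'   instrument export).
#' @return A `force_curve`.
#' @export
parse_force_curve <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2L) stop("no data rows in force-curve file")
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("segment", "z_um", "F_nN") %in% names(tab)))
    stop("force-curve file must have columns segment, z_um, F_nN")
  bad <- which(!tab$segment %in% c("approach", "retract"))
  if (length(bad))
    stop(sprintf("unknown segment label at data row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  segs <- lapply(split(tab, tab$segment), function(s)
    data.frame(z_um = s$z_um, F_nN = s$F_nN))
  for (nm in names(segs)) {
    dz <- diff(segs[[nm]]$z_um)
    if (length(dz) && !(all(dz >= 0) || all(dz <= 0)))
      stop(sprintf("%s segment is not monotone in position", nm))
  }
  if (is.null(segs$approach) || is.null(segs$retract))
    stop("force-curve file must contain approach and retract segments")
  structure(list(approach = segs$approach, retract = segs$retract,
                 R_um = as.numeric(meta$bead_radius_um),
                 setpoint_nN = as.numeric(meta$setpoint_nN),
                 protocol = if (is.null(meta$protocol)) NA_character_ else
                   meta$protocol,
                 repeat_index = if (is.null(meta[["repeat"]])) 1L else
                   as.integer(meta[["repeat"]])),
            class = "force_curve")
}

segment_data <- function(curve, segment = c("approach", "retract")) {
  segment <- match.arg(segment)
  s <- curve[[segment]]
  s[order(s$z_um), , drop = FALSE]  # analyze in increasing-z order
}

#' Estimate the contact point of a force curve
#'
#' Piecewise model: a flat baseline before the contact point and a
#' Hertz-shaped rise after it. For each candidate contact point on a
#' coarse grid the baseline and the Hertz amplitude are fitted linearly
#' and the total squared residual is evaluated; the minimizer is then
#' refined by golden-section search between its grid neighbours.
#'
#' @param curve a `force_curve`.
#' @param segment `"approach"` or `"retract"`.
#' @param n_grid number of coarse grid candidates.
#' @return contact-point position `z0_um`.
#' @export
estimate_contact_point <- function(curve, segment = "approach",
                                   n_grid = 200L) {
  s <- segment_data(curve, segment)
  if (nrow(s) < 50L) stop("segment too short for contact-point estimation")
  pre <- s$F_nN[seq_len(max(10L, nrow(s) %/% 10L))]
  if (max(s$F_nN) < mean(pre) + 5 * max(stats::sd(pre), 1e-12))
    stop("no contact detected: force never exceeds baseline + 5 sd")
  sse <- function(z0) piecewise_fit(s, z0)$sse
  zr <- range(s$z_um)
  grid <- seq(zr[1], zr[2] - (zr[2] - zr[1]) * 0.05,
              length.out = n_grid)
  vals <- vapply(grid, sse, 1.0)
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  stats::optimize(sse, c(lo, hi))$minimum
}

# linear fit of F = a + b * (z - z0)_+^(3/2); returns coefficients and SSE
piecewise_fit <- function(s, z0) {
  x <- pmax(s$z_um - z0, 0)^1.5
  fit <- stats::lm.fit(cbind(1, x), s$F_nN)
  list(a = fit$coefficients[1], b = fit$coefficients[2],
       sse = sum(fit$residuals^2), residuals = fit$residuals)
}

#' Fit the Hertz model to a force curve
#'
#' Least-squares fit of `F = (4/3) E / (1 - nu^2) sqrt(R) (z - z0)^(3/2)`
#' plus a constant baseline. The contact point is a free parameter refined
#' jointly (grid search plus local optimization) unless supplied. The fit
#' window is either the full indentation part or — for the nucleus
#' protocol — only the topmost 10% of the force range of the indentation
#' part, which isolates the deep-indentation response dominated by the
#' nucleus; window `"top10-depth"` anchors the 10% on indentation depth
#' instead.
#'
#' @param curve a `force_curve`.
#' @param segment `"approach"` or `"retract"`.
#' @param window `"full"`, `"top10"` (topmost 10% of the force range) or
#'   `"top10-depth"`.
#' @param R_um bead radius; default from curve metadata.
#' @param nu Poisson ratio used in the conversion (default 0.5,
#'   incompressible).
#' @param z0_um optional fixed contact point, um.
#' @return An object of class `hertz_fit`: `E_Pa`, `nu`, `z0_um`,
#'   `window`, `rms_pN`, `n_points`, `accepted` (NA until
#'   [rms_filter()]).
#' @export
hertz_fit <- function(curve, segment = c("approach", "retract"),
                      window = c("full", "top10", "top10-depth"),
                      R_um = NULL, nu = 0.5, z0_um = NULL) {
  segment <- match.arg(segment)
  window <- match.arg(window)
  if (is.null(R_um)) R_um <- curve$R_um
  if (is.null(R_um) || is.na(R_um)) stop("bead radius unknown")
  s <- segment_data(curve, segment)
  if (is.null(z0_um)) z0_um <- estimate_contact_point(curve, segment)
  base <- piecewise_fit(s, z0_um)
  contact <- s$z_um > z0_um
  f0 <- base$a  # baseline offset
  find_window <- function() {
    if (window == "full") return(which(contact))
    ind <- which(contact)
    if (window == "top10") {
      fr <- s$F_nN[ind] - f0
      which(contact & (s$F_nN - f0) >= 0.9 * max(fr))
    } else {
      dmax <- max(s$z_um[ind] - z0_um)
      which(contact & (s$z_um - z0_um) >= 0.9 * dmax)
    }
  }
  win <- find_window()
  if (length(win) < 10L)
    stop("fewer than 10 samples in the fit window")
  x <- (s$z_um[win] - z0_um)^1.5
  f <- s$F_nN[win] - f0
  b <- sum(x * f) / sum(x * x)  # through the origin after baseline removal
  resid <- f - b * x
  # b is nN / um^(3/2); convert to Pa
  E <- b * 1e-9 / 1e-6^1.5 * (1 - nu^2) * 3 / 4 / sqrt(R_um * 1e-6)
  structure(list(E_Pa = E, nu = nu, z0_um = z0_um, segment = segment,
                 window = window, R_um = R_um,
                 rms_pN = sqrt(mean(resid^2)) * 1e3,
                 n_points = length(win), accepted = NA),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf(paste0("<hertz_fit> E = %.2f Pa (nu = %.2f, R = %g um), ",
                     "z0 = %.3f um, %s/%s, RMS %.1f pN, n = %d%s\n"),
              x$E_Pa, x$nu, x$R_um, x$z0_um, x$segment, x$window,
              x$rms_pN, x$n_points,
              if (is.na(x$accepted)) "" else
                if (x$accepted) ", accepted" else ", rejected"))
  invisible(x)
}

#' Residual-RMS curve filter
#'
#' Quality gate on Hertz fits: a fit is accepted iff its residual root
#' mean square is at or below the threshold (default 150 pN), rejecting
#' curves disturbed by artifacts. The same threshold is applied to every
#' curve regardless of condition.
#'
#' @param fit a `hertz_fit`.
#' @param threshold_pN RMS threshold, pN.
#' @return The fit with its `accepted` flag set.
#' @export
rms_filter <- function(fit, threshold_pN = 150) {
  stopifnot(inherits(fit, "hertz_fit"))
  fit$accepted <- fit$rms_pN <= threshold_pN
  fit
}

protocol_defaults <- function(protocol) {
  switch(protocol,
         matrix = list(segment = "retract", window = "full",
                       R_um = 22.5, setpoint_nN = 5),
         cytoskeleton = list(segment = "approach", window = "full",
                             R_um = 3, setpoint_nN = 0.5),
         nucleus = list(segment = "approach", window = "top10",
                        R_um = 3, setpoint_nN = 5),
         stop("unknown protocol: ", protocol))
}

#' Run an AFM probing protocol over grouped curves
#'
#' Applies the protocol-specific Hertz fit (matrix: retract segment, full
#' window, 45 um bead; cytoskeleton: approach, full window, 6 um bead;
#' nucleus: approach, topmost-10% force window, 6 um bead) to every curve,
#' filters by residual RMS, and aggregates accepted fits to one modulus
#' per cell (mean over accepted points/repeats). Cells whose fits are all
#' rejected are excluded and reported in `excluded`.
#'
#' @param curves_by_cell named list; each element is a list of
#'   `force_curve` objects for one cell (or one matrix location).
#' @param protocol `"matrix"`, `"cytoskeleton"` or `"nucleus"`.
#' @param nu Poisson ratio.
#' @param rms_threshold_pN acceptance threshold, pN.
#' @return list with `per_cell` (data.frame `cell`, `E_Pa`, `n_accepted`,
#'   `n_total`), `fits` (all fits), `excluded` (cell names).
#' @export
run_protocol <- function(curves_by_cell,
                         protocol = c("nucleus", "cytoskeleton",
                                      "matrix"),
                         nu = 0.5, rms_threshold_pN = 150) {
  protocol <- match.arg(protocol)
  pd <- protocol_defaults(protocol)
  if (is.null(names(curves_by_cell)))
    names(curves_by_cell) <- sprintf("cell_%03d",
                                     seq_along(curves_by_cell))
  fits <- list()
  rows <- list()
  excluded <- character()
  for (cell in names(curves_by_cell)) {
    cf <- lapply(curves_by_cell[[cell]], function(cv) {
      ft <- tryCatch(
        hertz_fit(cv, segment = pd$segment, window = pd$window,
                  R_um = if (is.null(cv$R_um) || is.na(cv$R_um))
                    pd$R_um else cv$R_um, nu = nu),
        error = function(e) structure(
          list(E_Pa = NA_real_, nu = nu, z0_um = NA_real_,
               segment = pd$segment, window = pd$window, R_um = pd$R_um,
               rms_pN = Inf, n_points = 0L, accepted = NA,
               error = conditionMessage(e)), class = "hertz_fit"))
      rms_filter(ft, rms_threshold_pN)
    })
    fits[[cell]] <- cf
    ok <- vapply(cf, function(f) isTRUE(f$accepted), TRUE)
    if (!any(ok)) {
      excluded <- c(excluded, cell)
      next
    }
    rows[[cell]] <- data.frame(
      cell = cell,
      E_Pa = mean(vapply(cf[ok], function(f) f$E_Pa, 1.0)),
      n_accepted = sum(ok), n_total = length(ok))
  }
  per_cell <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell = character(), E_Pa = numeric(),
               n_accepted = integer(), n_total = integer())
  rownames(per_cell) <- NULL
  list(per_cell = per_cell, fits = fits, excluded = excluded,
       protocol = protocol)
}
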