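#' Pipeline configuration
#'
#' A single structured configuration driving an end-to-end run
#' (simulate -> analyze -> report). Stage parameter blocks default to the
#' study's analysis constants: the 8 um invasion threshold, the 150 pN
#' residual-RMS threshold, protocol bead radii of 22.5 um (matrix) and
#' 3 um (cells), automatic residual steps for 3D pores and exactly one
#' for 2D actin. A seed is mandatory whenever a synthetic stage is
#' enabled.
#'
#' @param stages character vector of stages to run, a subset of
#'   `c("matrix", "invasion", "afm", "stats")`.
#' @param seed global integer seed.
#' @param matrix list of [fiber_network_spec()] arguments.
#' @param invasion list of [invasion_stack_spec()] arguments plus
#'   `threshold_um`.
#' @param afm list with `E_Pa` (named per condition), `n_cells`,
#'   `repeats`, `protocol`, `noise_sd_pN`, `rms_threshold_pN`.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("matrix", "invasion", "afm",
                                       "stats"),
                            seed = 1L,
                            matrix = list(edge_um = 18.56,
                                          voxel_um = 0.29,
                                          n_fibers = 60),
                            invasion = list(grid_shape = c(3L, 3L),
                                            n_cells = 200L,
                                            threshold_um = 8),
                            afm = list(E_Pa = c(control = 157.7,
                                                treated = 95.0),
                                       n_cells = 8L, repeats = 5L,
                                       protocol = "nucleus",
                                       noise_sd_pN = 10,
                                       rms_threshold_pN = 150),
                            out_dir = tempfile("confinometry_run_")) {
  if (length(stages) == 0L) stop("no stages selected")
  stages <- match.arg(stages, c("matrix", "invasion", "afm", "stats"),
                      several.ok = TRUE)
  if (is.null(seed)) stop("a seed is required when synthetic stages run")
  structure(list(stages = stages, seed = as.integer(seed),
                 matrix = matrix, invasion = invasion, afm = afm,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' The round trip `read_pipeline_config(write_pipeline_config(cfg))` is
#' lossless.
#'
#' @param config a [pipeline_config()].
#' @param file YAML path.
#' @return `file` (write) or the config (read).
#' @export
write_pipeline_config <- function(config, file) {
  stopifnot(inherits(config, "pipeline_config"))
  raw <- unclass(config)
  # yaml serializes named atomic vectors as plain sequences; named lists
  # keep their keys
  if (!is.null(names(raw$afm$E_Pa)))
    raw$afm$E_Pa <- as.list(raw$afm$E_Pa)
  yaml::write_yaml(raw, file)
  invisible(file)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(file) {
  raw <- yaml::read_yaml(file)
  if (is.list(raw$afm$E_Pa)) raw$afm$E_Pa <- unlist(raw$afm$E_Pa)
  pipeline_config(stages = unlist(raw$stages), seed = raw$seed,
                  matrix = raw$matrix, invasion = raw$invasion,
                  afm = raw$afm, out_dir = raw$out_dir)
}

pipeline_log <- function(con, stage, msg, params = NULL) {
  line <- sprintf("[%s] %s%s", stage, msg,
                  if (is.null(params)) "" else paste0(" | ",
                    paste(names(params), unlist(params), sep = "=",
                          collapse = " ")))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the selected stages in dependency order, writes every stage's
#' outputs (CSV/JSON) under the configured output directory, and returns
#' a manifest recording inputs, parameters, output files and their MD5
#' hashes. Reruns with an identical configuration and seed produce
#' identical outputs for the seeded stages. A stage failure aborts the
#' run with the failing stage named; outputs of completed stages are
#' preserved.
#'
#' @param config a [pipeline_config()].
#' @return The manifest (list), invisibly written to
#'   `manifest.json` as well.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(out, "run.log"), "w")
  on.exit(close(logcon))
  outputs <- character()
  results <- list()

  run_stage <- function(stage, fn) {
    pipeline_log(logcon, stage, "start")
    res <- tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
    pipeline_log(logcon, stage, "done")
    res
  }

  if ("matrix" %in% config$stages) {
    results$matrix <- run_stage("matrix", function() {
      args <- config$matrix
      args$seed <- config$seed
      spec <- do.call(fiber_network_spec, args)
      net <- generate_fiber_network(spec)
      bin <- binarize_network(net$image)
      pores <- pore_size_spheres(net$truth)
      thick <- structure_thickness(net$truth)
      f <- file.path(out, "pores.csv")
      utils::write.csv(as.data.frame(pores), f, row.names = FALSE)
      f2 <- file.path(out, "thickness.csv")
      utils::write.csv(as.data.frame(thick), f2, row.names = FALSE)
      f3 <- file.path(out, "matrix_summary.json")
      jsonlite::write_json(list(
        median_pore_um = attr(pores, "median_pore_um"),
        mean_thickness_um = attr(thick, "mean_um"),
        sd_thickness_um = attr(thick, "sd_um"),
        n_pores = nrow(pores), n_points = nrow(thick),
        segmentation_jaccard = jaccard(bin$mask, net$truth$mask)),
        f3, auto_unbox = TRUE, digits = NA)
      outputs <<- c(outputs, f, f2, f3)
      list(median_pore_um = attr(pores, "median_pore_um"),
           mean_thickness_um = attr(thick, "mean_um"))
    })
  }

  if ("invasion" %in% config$stages) {
    results$invasion <- run_stage("invasion", function() {
      args <- config$invasion
      thr <- args$threshold_um %||% 8
      args$threshold_um <- NULL
      args$seed <- config$seed + 1L
      spec <- do.call(invasion_stack_spec, args)
      sim <- generate_invasion_stacks(spec)
      det <- detect_nuclei(sim$stacks)
      surf <- estimate_surface(det, spec$z_step_um)
      cls <- classify_invasive(det, surf$z0_um, thr)
      summ <- summarize_invasion(cls)
      f <- file.path(out, "nuclei.csv")
      utils::write.csv(cls, f, row.names = FALSE)
      ec <- cumulative_depth(cls)
      grid <- seq(0, max(cls$depth_um), length.out = 100)
      f2 <- file.path(out, "ecdf.csv")
      utils::write.csv(data.frame(depth_um = grid, cum_prob = ec(grid)),
                       f2, row.names = FALSE)
      f3 <- file.path(out, "invasion_summary.json")
      jsonlite::write_json(list(
        n_cells = summ$n_cells,
        percent_invasive = unname(summ$percent_invasive["mean"]),
        invasion_depth_um = unname(summ$invasion_depth_um["mean"]),
        surface_z_um = surf$z0_um, threshold_um = thr),
        f3, auto_unbox = TRUE, digits = NA)
      outputs <<- c(outputs, f, f2, f3)
      list(percent_invasive = unname(summ$percent_invasive["mean"]),
           surface_z_um = surf$z0_um, records = cls)
    })
  }

  if ("afm" %in% config$stages) {
    results$afm <- run_stage("afm", function() {
      a <- config$afm
      rows <- list()
      k <- 0L
      for (cond in names(a$E_Pa)) {
        cells <- list()
        for (ci in seq_len(a$n_cells)) {
          k <- k + 1L
          curves <- lapply(seq_len(a$repeats), function(ri)
            generate_force_curve(force_curve_spec(
              E_Pa = a$E_Pa[[cond]], protocol = a$protocol,
              noise_sd_pN = a$noise_sd_pN,
              seed = config$seed + 1000L * k + ri,
              repeat_index = ri)))
          cells[[sprintf("%s_cell_%02d", cond, ci)]] <- curves
        }
        pr <- run_protocol(cells, protocol = a$protocol,
                           rms_threshold_pN = a$rms_threshold_pN)
        pr$per_cell$condition <- cond
        rows[[cond]] <- pr$per_cell
      }
      fits <- do.call(rbind, rows)
      f <- file.path(out, "fits.csv")
      utils::write.csv(fits, f, row.names = FALSE)
      outputs <<- c(outputs, f)
      fits
    })
  }

  if ("stats" %in% config$stages) {
    results$stats <- run_stage("stats", function() {
      if (is.null(results$afm)) stop("stats stage requires the afm stage")
      fits <- results$afm
      tab <- condition_table(fits$condition, fits$cell, "E_Pa",
                             fits$E_Pa)
      conds <- unique(fits$condition)
      comp <- if (length(conds) >= 2L)
        data.frame(metric = "E_Pa", treated = conds[-1],
                   control = conds[1]) else NULL
      rep <- build_report(tab, comp)
      f <- file.path(out, "report.json")
      jsonlite::write_json(list(descriptives = rep$descriptives,
                                comparisons = rep$comparisons,
                                note = rep$note),
                           f, auto_unbox = TRUE, digits = NA)
      f2 <- file.path(out, "report.csv")
      utils::write.csv(rep$descriptives, f2, row.names = FALSE)
      outputs <<- c(outputs, f, f2)
      rep
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("confinometry")),
    seed = config$seed, stages = config$stages,
    parameters = unclass(config)[c("matrix", "invasion", "afm")],
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$results <- results
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

jaccard <- function(a, b) sum(a & b) / sum(a | b)
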