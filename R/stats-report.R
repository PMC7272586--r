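#' Mann-Whitney U test for condition comparison
#'
#' Two-sided rank-sum comparison as used for all condition contrasts:
#' exact p by enumeration when both samples are small (min(n, m) <= 8)
#' and tie-free, otherwise the tie-corrected normal approximation with
#' continuity correction. Backed by [stats::wilcox.test()]; `U` is the
#' number of (x, y) pairs with x > y (+ half the ties).
#'
#' @param x,y numeric samples (each non-empty).
#' @param method `"auto"` (the rule above), `"exact"` or `"normal"`.
#' @return list with `U`, `p`, `method`.
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  ties <- any(duplicated(c(x, y)))
  exact <- switch(method,
                  auto = min(length(x), length(y)) <= 8L && !ties,
                  exact = TRUE, normal = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal")
}

#' Significance label at the 5/1/0.1% levels
#'
#' @param p p-value in \[0, 1\].
#' @return `"***"` (p < 0.001), `"**"` (p < 0.01), `"*"` (p < 0.05) or
#'   `"n.s."`; the comparisons are strict, so p = 0.05 is `"n.s."`.
#' @export
significance_label <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  vapply(p, function(pi)
    if (pi < 0.001) "***" else if (pi < 0.01) "**" else
      if (pi < 0.05) "*" else "n.s.", "")
}

#' Fold change between condition means
#'
#' Treated over control, rounded half-up to two decimals (so 1.515
#' reports as 1.52).
#'
#' @param treated_mean,control_mean condition means (control non-zero).
#' @return dimensionless ratio, two decimals.
#' @export
fold_change <- function(treated_mean, control_mean) {
  if (any(control_mean == 0)) stop("zero control mean")
  r <- treated_mean / control_mean
  floor(r * 100 + 0.5) / 100  # half-up, matching how ratios are printed
}

#' Assemble a tidy per-condition measurement table
#'
#' Rows of (condition, id, metric, value); duplicate (condition, id,
#' metric) triples are rejected so each cell contributes one value per
#' metric.
#'
#' @param condition,id,metric,value equal-length vectors.
#' @return data.frame of class `condition_table`.
#' @export
condition_table <- function(condition, id, metric, value) {
  df <- data.frame(condition = as.character(condition),
                   id = as.character(id), metric = as.character(metric),
                   value = as.numeric(value))
  key <- paste(df$condition, df$id, df$metric, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (condition, id, metric) triples")
  class(df) <- c("condition_table", "data.frame")
  df
}

#' Build a condition summary report
#'
#' Per (metric, condition) descriptives (mean, sd, n) and the requested
#' pairwise Mann-Whitney comparisons with significance labels and fold
#' changes of the means. No multiple-testing correction is applied; each
#' comparison is reported at its nominal level.
#'
#' @param table a [condition_table()].
#' @param comparisons data.frame with columns `metric`, `treated`,
#'   `control` naming the requested contrasts; `NULL` for descriptives
#'   only.
#' @return list of class `condition_report` with `descriptives` and
#'   `comparisons` data.frames.
#' @export
build_report <- function(table, comparisons = NULL) {
  stopifnot(inherits(table, "condition_table"))
  parts <- split(table, list(table$metric, table$condition), drop = TRUE)
  desc <- do.call(rbind, lapply(parts, function(p)
    data.frame(metric = p$metric[1], condition = p$condition[1],
               n = nrow(p), mean = mean(p$value),
               sd = stats::sd(p$value))))
  desc <- desc[order(desc$metric, desc$condition), ]
  rownames(desc) <- NULL
  comp <- NULL
  if (!is.null(comparisons) && nrow(comparisons)) {
    comp <- do.call(rbind, lapply(seq_len(nrow(comparisons)),
                                  function(i) {
      cm <- comparisons[i, ]
      sel <- table$metric == cm$metric
      if (!any(sel)) stop("unknown metric: ", cm$metric)
      xt <- table$value[sel & table$condition == cm$treated]
      xc <- table$value[sel & table$condition == cm$control]
      if (!length(xt) || !length(xc))
        stop(sprintf("no data for comparison %s: %s vs %s", cm$metric,
                     cm$treated, cm$control))
      mw <- mann_whitney_u(xt, xc)
      data.frame(metric = cm$metric, treated = cm$treated,
                 control = cm$control, U = mw$U, p = mw$p,
                 label = significance_label(mw$p),
                 fold_change = fold_change(mean(xt), mean(xc)))
    }))
    rownames(comp) <- NULL
  }
  structure(list(descriptives = desc, comparisons = comp,
                 note = "no multiple-testing correction applied"),
            class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  cat("<condition_report>\n")
  print(x$descriptives, digits = 4)
  if (!is.null(x$comparisons)) {
    cat("\ncomparisons:\n")
    print(x$comparisons, digits = 4)
  }
  cat("note:", x$note, "\n")
  invisible(x)
}
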