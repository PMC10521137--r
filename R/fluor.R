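#' Corrected total nuclear fluorescence
#'
#' `CTNF = integrated density - area * mean background fluorescence`: the
#' summed intensity over the circled cell minus the background expected over
#' the same area. Negative values (background brighter than the cell) are
#' returned as-is; use [cell_fluor_metrics()] to have them flagged.
#'
#' @param integrated_density Summed pixel intensity over the selection.
#' @param area Selection area (pixels^2 or um^2; must be > 0).
#' @param background_mean Mean background fluorescence per unit area.
#' @return Numeric CTNF, vectorized over the inputs.
#' @examples
#' ctnf(1000, 50, 4)  # 800
#' @export
ctnf <- function(integrated_density, area, background_mean) {
  if (anyNA(integrated_density) || anyNA(area) || anyNA(background_mean)) {
    stop("ctnf requires integrated_density, area and background_mean")
  }
  if (any(area <= 0)) stop("area must be positive")
  integrated_density - area * background_mean
}

#' Per-cell fluorescence metrics
#'
#' Adds the corrected total nuclear fluorescence and the
#' nuclear/cytoplasmic mean-intensity ratio to a table of per-cell
#' measurements.
#'
#' @param records A `data.frame` with columns `integrated_density`, `area`,
#'   `background_mean`, `nuclear_mean`, `cytoplasmic_mean` (e.g. from
#'   [simulate_cell_fluorescence()]).
#' @return `records` with added columns `ctnf`, `ctnf_negative` and
#'   `nc_ratio` (`NA` where the cytoplasmic mean is zero).
#' @export
cell_fluor_metrics <- function(records) {
  req <- c("integrated_density", "area", "background_mean",
           "nuclear_mean", "cytoplasmic_mean")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  records$ctnf <- ctnf(records$integrated_density, records$area,
                       records$background_mean)
  records$ctnf_negative <- records$ctnf < 0
  records$nc_ratio <- ifelse(records$cytoplasmic_mean > 0,
                             records$nuclear_mean / records$cytoplasmic_mean,
                             NA_real_)
  records
}

#' Nuclear/cytoplasmic ratios with a two-group comparison
#'
#' Computes the per-cell nuclear/cytoplasmic mean-intensity ratio, excludes
#' cells with zero cytoplasmic signal (with a warning), and compares the two
#' groups with a two-sided t test: Welch's unequal-variance test by default,
#' Student's pooled test on request.
#'
#' @param records A `data.frame` with columns `group`, `nuclear_mean`,
#'   `cytoplasmic_mean`; exactly two groups with at least two usable cells
#'   each.
#' @param test `"welch"` (default) or `"student"`.
#' @return A list of class `nc_comparison`: `records` (with `nc_ratio`),
#'   `group_medians`, `group_n`, `statistic`, `p_value`, `test`.
#' @export
nc_ratio_and_compare <- function(records, test = c("welch", "student")) {
  test <- match.arg(test)
  req <- c("group", "nuclear_mean", "cytoplasmic_mean")
  if (!all(req %in% names(records))) {
    stop("records must have columns ", paste(req, collapse = ", "))
  }
  bad <- records$cytoplasmic_mean <= 0
  if (any(bad)) {
    warning("excluding ", sum(bad), " cell(s) with non-positive cytoplasmic mean")
    records <- records[!bad, , drop = FALSE]
  }
  records$nc_ratio <- records$nuclear_mean / records$cytoplasmic_mean
  groups <- unique(records$group)
  if (length(groups) != 2) stop("exactly two groups are required")
  sizes <- table(records$group)
  if (any(sizes < 2)) stop("each group needs at least two cells")
  x <- records$nc_ratio[records$group == groups[1]]
  y <- records$nc_ratio[records$group == groups[2]]
  tt <- stats::t.test(x, y, var.equal = (test == "student"),
                      alternative = "two.sided")
  structure(list(
    records = records,
    group_medians = stats::setNames(c(stats::median(x), stats::median(y)),
                                    as.character(groups)),
    group_n = stats::setNames(as.integer(c(length(x), length(y))),
                              as.character(groups)),
    statistic = unname(tt$statistic),
    p_value = tt$p.value,
    test = test
  ), class = "nc_comparison")
}

#' @export
print.nc_comparison <- function(x, ...) {
  cat("Nuclear/cytoplasmic ratio comparison (", x$test, " t test)\n", sep = "")
  cat(sprintf("  groups: %s (n=%d, median %.3f) vs %s (n=%d, median %.3f)\n",
              names(x$group_n)[1], x$group_n[1], x$group_medians[1],
              names(x$group_n)[2], x$group_n[2], x$group_medians[2]))
  cat(sprintf("  t = %.3f, p = %.3g\n", x$statistic, x$p_value))
  invisible(x)
}
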