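#' Summarize one biological replicate's fork distances
#'
#' The replicate-level statistic carried into group comparisons is the
#' median fork distance over retained probes.
#'
#' @param condition Condition id.
#' @param replicate Replicate id.
#' @param distances Per-probe fork distances (bp); `NA`s (non-retained
#'   probes) are dropped.
#' @param fired_origins Optional fired-origin count for the replicate.
#' @return A one-row `data.frame` with columns `condition`, `replicate`,
#'   `n_probes`, `median_distance`, `fired_origins`.
#' @export
condition_summary <- function(condition, replicate, distances,
                              fired_origins = NA_integer_) {
  d <- distances[!is.na(distances)]
  data.frame(condition = as.character(condition),
             replicate = as.character(replicate),
             n_probes = length(d),
             median_distance = if (length(d)) stats::median(d) else NA_real_,
             fired_origins = as.integer(fired_origins),
             stringsAsFactors = FALSE)
}

#' Compare fork-distance medians across conditions
#'
#' Ordinary one-way ANOVA on the replicate medians, followed by all
#' pairwise group comparisons with a family-wise correction: Tukey's HSD by
#' default, or pooled-variance t tests with a Sidak or Bonferroni
#' adjustment. For g groups the table has g(g-1)/2 pairwise rows.
#'
#' @param summaries A `data.frame` of replicate summaries (rows from
#'   [condition_summary()], or any frame with columns `condition` and
#'   `median_distance`).
#' @param method Multiple-comparison correction: `"tukey"` (default),
#'   `"sidak"` or `"bonferroni"`.
#' @return A list of class `condition_comparison`:
#'   \describe{
#'     \item{anova}{`data.frame` with `F`, `df_between`, `df_within`, `p`;}
#'     \item{group_means}{`data.frame` with `condition`, `n`, `mean`;}
#'     \item{pairwise}{`data.frame` with `group1`, `group2`, `diff`,
#'       `p_adj`;}
#'     \item{method, n_comparisons}{bookkeeping.}
#'   }
#' @export
compare_conditions <- function(summaries,
                               method = c("tukey", "sidak", "bonferroni")) {
  method <- match.arg(method)
  req <- c("condition", "median_distance")
  if (!all(req %in% names(summaries))) {
    stop("summaries must have columns condition and median_distance")
  }
  df <- summaries[!is.na(summaries$median_distance), , drop = FALSE]
  sizes <- table(df$condition)
  single <- names(sizes)[sizes < 2]
  if (length(single) > 0) {
    warning("excluding condition(s) with a single replicate: ",
            paste(single, collapse = ", "))
    df <- df[!df$condition %in% single, , drop = FALSE]
  }
  groups <- unique(df$condition)
  g <- length(groups)
  if (g < 2) stop("need at least two conditions with >= 2 replicates each")
  df$condition <- factor(df$condition, levels = groups)

  fit <- stats::aov(median_distance ~ condition, data = df)
  sm <- summary(fit)[[1]]
  anova_tab <- data.frame(F = sm[["F value"]][1],
                          df_between = sm[["Df"]][1],
                          df_within = sm[["Df"]][2],
                          p = sm[["Pr(>F)"]][1])
  means <- stats::aggregate(median_distance ~ condition, data = df, FUN = mean)
  group_means <- data.frame(condition = as.character(means$condition),
                            n = as.integer(sizes[as.character(means$condition)]),
                            mean = means$median_distance,
                            stringsAsFactors = FALSE)

  m <- g * (g - 1) / 2
  if (method == "tukey") {
    tk <- stats::TukeyHSD(fit)$condition
    parts <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- data.frame(
      group1 = vapply(parts, `[`, "", 2L),
      group2 = vapply(parts, `[`, "", 1L),
      diff = -tk[, "diff"],
      p_adj = tk[, "p adj"],
      stringsAsFactors = FALSE
    )
  } else {
    mse <- sm[["Mean Sq"]][2]
    dfw <- sm[["Df"]][2]
    mu <- stats::setNames(group_means$mean, group_means$condition)
    nn <- stats::setNames(group_means$n, group_means$condition)
    pairs <- utils::combn(as.character(groups), 2)
    p_raw <- diff_est <- numeric(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      diff_est[j] <- mu[a] - mu[b]
      se <- sqrt(mse * (1 / nn[a] + 1 / nn[b]))
      p_raw[j] <- 2 * stats::pt(-abs(diff_est[j] / se), dfw)
    }
    p_adj <- if (method == "bonferroni") pmin(1, p_raw * m) else
      1 - (1 - p_raw)^m
    pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                           diff = diff_est, p_adj = p_adj,
                           stringsAsFactors = FALSE)
  }
  rownames(pairwise) <- NULL
  structure(list(anova = anova_tab, group_means = group_means,
                 pairwise = pairwise, method = method,
                 n_comparisons = as.integer(m)),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("One-way ANOVA on replicate median fork distances\n")
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g\n", x$anova$df_between,
              x$anova$df_within, x$anova$F, x$anova$p))
  cat(sprintf("  %d pairwise comparisons (%s-adjusted)\n",
              x$n_comparisons, x$method))
  print(x$pairwise, ...)
  invisible(x)
}
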