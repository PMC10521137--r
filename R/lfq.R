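#' Complete an LFQ table and convert zero intensities to 1
#'
#' Missing (protein, sample, replicate) rows are first added with intensity
#' 0 — every protein then has the full replicate structure — and every zero
#' intensity is replaced by 1 so that downstream ratios are defined.
#' Idempotent; raw intensities are expected, before control normalization.
#'
#' @param table Long-format `data.frame` with columns `protein`, `sample`,
#'   `replicate`, `intensity` (all intensities >= 0).
#' @param complete Add missing protein x sample x replicate rows as zeros
#'   before imputing (default `TRUE`). The replicate grid per sample is
#'   taken from the replicates observed in that sample.
#' @return The table with zeros imputed to 1, sorted by protein, sample,
#'   replicate.
#' @export
impute_zeros <- function(table, complete = TRUE) {
  check_lfq_table(table)
  if (any(table$intensity < 0)) stop("intensities must be >= 0")
  if (complete) {
    grids <- lapply(split(table$replicate, table$sample), unique)
    full <- do.call(rbind, lapply(names(grids), function(s) {
      expand.grid(protein = unique(table$protein), sample = s,
                  replicate = sort(grids[[s]]),
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    }))
    key <- function(d) paste(d$protein, d$sample, d$replicate, sep = "\r")
    missing <- full[!key(full) %in% key(table), , drop = FALSE]
    if (nrow(missing) > 0) {
      missing$intensity <- 0
      table <- rbind(table[, c("protein", "sample", "replicate", "intensity")],
                     missing)
    }
  }
  table$intensity[table$intensity == 0] <- 1
  table <- table[order(table$protein, table$sample, table$replicate), ,
                 drop = FALSE]
  rownames(table) <- NULL
  table
}

check_lfq_table <- function(table) {
  req <- c("protein", "sample", "replicate", "intensity")
  if (!all(req %in% names(table))) {
    stop("LFQ table must have columns ", paste(req, collapse = ", "))
  }
  key <- paste(table$protein, table$sample, table$replicate)
  if (anyDuplicated(key)) {
    stop("duplicated (protein, sample, replicate) rows in LFQ table")
  }
  invisible(table)
}

#' Normalize LFQ intensities to an endogenously biotinylated control
#'
#' Divides every protein's intensity by the control protein's intensity in
#' the same sample and replicate, cancelling per-run capture and loading
#' differences. The control maps to 1 everywhere. Zeros must have been
#' imputed first ([impute_zeros()]).
#'
#' @param table Long-format LFQ table (zeros imputed).
#' @param control_id Control protein id (e.g. the acetyl-CoA carboxylase
#'   Acc1 in yeast).
#' @return The table with an added `normalized` column.
#' @export
normalize_to_control <- function(table, control_id = "ACC1") {
  check_lfq_table(table)
  ctrl <- table[table$protein == control_id, , drop = FALSE]
  if (nrow(ctrl) == 0) stop("control protein '", control_id, "' not in table")
  key <- paste(table$sample, table$replicate)
  ckey <- paste(ctrl$sample, ctrl$replicate)
  i <- match(key, ckey)
  if (anyNA(i)) {
    bad <- unique(key[is.na(i)])
    stop("control protein '", control_id,
         "' missing from sample/replicate: ", paste(bad, collapse = ", "))
  }
  if (any(ctrl$intensity <= 0)) {
    stop("control protein has non-positive intensity; impute zeros first")
  }
  table$normalized <- table$intensity / ctrl$intensity[i]
  table
}

#' Dual-axis enrichment scores for the three-sample design
#'
#' Per protein and sample class, the arithmetic mean of the normalized
#' intensities over replicates; then two log-ratio coordinates:
#' `x = log(avg sample3 / avg sample2)` (treatment vs no treatment, both
#' tagged) and `y = log(avg sample3 / avg sample1)` (tag vs no tag, both
#' treated). The control protein sits exactly at (0, 0).
#'
#' @param table Normalized table from [normalize_to_control()].
#' @param log_base Logarithm base (default 2).
#' @return A `data.frame` of class `lfq_enrichment` with columns `protein`,
#'   `avg_sample1`, `avg_sample2`, `avg_sample3`, `x_enrichment`,
#'   `y_enrichment`; attribute `log_base`.
#' @export
enrichment_scores <- function(table, log_base = 2) {
  if (is.null(table$normalized)) {
    stop("table must be normalized first (normalize_to_control)")
  }
  want <- c("sample1", "sample2", "sample3")
  if (!all(want %in% unique(table$sample))) {
    stop("table must contain sample classes ", paste(want, collapse = ", "))
  }
  avg <- stats::aggregate(normalized ~ protein + sample, data = table,
                          FUN = mean)
  wide <- stats::reshape(avg, idvar = "protein", timevar = "sample",
                         direction = "wide")
  names(wide) <- sub("^normalized\\.", "avg_", names(wide))
  for (s in paste0("avg_", want)) {
    if (any(!is.finite(wide[[s]])) || any(wide[[s]] <= 0)) {
      stop("non-positive per-sample average; impute zeros before normalizing")
    }
  }
  out <- data.frame(
    protein = wide$protein,
    avg_sample1 = wide$avg_sample1,
    avg_sample2 = wide$avg_sample2,
    avg_sample3 = wide$avg_sample3,
    x_enrichment = log(wide$avg_sample3 / wide$avg_sample2, base = log_base),
    y_enrichment = log(wide$avg_sample3 / wide$avg_sample1, base = log_base),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$protein), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "log_base") <- log_base
  class(out) <- c("lfq_enrichment", "data.frame")
  out
}

#' Flag proximity-labelling hits
#'
#' A protein is a hit when it exceeds both enrichment thresholds: enriched
#' by the tag (y axis) and further enhanced by the treatment (x axis) —
#' the upper-right quadrant of the enrichment scatter.
#'
#' @param results An `lfq_enrichment` frame from [enrichment_scores()].
#' @param x_threshold,y_threshold Finite thresholds in log units
#'   (defaults 1 and 1, i.e. two-fold in base 2).
#' @return `results` with a logical `hit` column; thresholds recorded as
#'   attributes `x_threshold`, `y_threshold`.
#' @export
classify_hits <- function(results, x_threshold = 1, y_threshold = 1) {
  stopifnot(is.numeric(x_threshold), is.numeric(y_threshold))
  results$hit <- results$x_enrichment > x_threshold &
    results$y_enrichment > y_threshold
  attr(results, "x_threshold") <- x_threshold
  attr(results, "y_threshold") <- y_threshold
  results
}

#' One-call LFQ enrichment analysis
#'
#' Composes [impute_zeros()], [normalize_to_control()],
#' [enrichment_scores()] and [classify_hits()].
#'
#' @inheritParams impute_zeros
#' @inheritParams normalize_to_control
#' @inheritParams enrichment_scores
#' @inheritParams classify_hits
#' @return An `lfq_enrichment` frame with hit flags.
#' @export
lfq_enrichment <- function(table, control_id = "ACC1", log_base = 2,
                           x_threshold = 1, y_threshold = 1) {
  table <- impute_zeros(table)
  table <- normalize_to_control(table, control_id)
  res <- enrichment_scores(table, log_base)
  classify_hits(res, x_threshold, y_threshold)
}
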