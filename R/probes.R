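#' Build oriented origin-centred probes
#'
#' For each active origin two probes are defined, one per side, each spanning
#' `probe_half_width` bp and binned at `probe_bin` bp. The upstream probe's
#' axis is reversed so that on both probes the coordinate reads "distance
#' from the origin", increasing away from it; a read end exactly at the
#' origin position contributes distance 0 on both sides. Probes that would
#' extend past a chromosome end are built over the available range and
#' flagged `truncated`; truncated probes are excluded from distance
#' statistics by default.
#'
#' @param ends A [read_ends()] object.
#' @param active Active origin catalogue (`origin_id`, `chrom`, `pos`), e.g.
#'   from [call_active_origins()].
#' @param params A [fork_params()].
#' @param layout Optional [genome_layout()]; required to flag probes
#'   truncated at chromosome ends.
#' @param strand_mode `"total"` (default) uses both strands;
#'   `"leading"` restricts each side to the strand its fork is expected to
#'   label (plus downstream of the origin, minus upstream).
#'
#' @return A list of `fork_probe` objects. Each probe carries `origin_id`,
#'   `chrom`, `origin_pos`, `side`, `bin`, `distance` (bin midpoints),
#'   `raw`, and placeholders `smoothed`, `peaks`, `retained`,
#'   `fork_distance` filled by [smooth_probe()], [detect_peaks()] and
#'   [fork_distance()].
#' @export
build_probes <- function(ends, active, params = fork_params(), layout = NULL,
                         strand_mode = c("total", "leading")) {
  stopifnot(inherits(ends, "read_ends"), inherits(params, "fork_params"))
  strand_mode <- match.arg(strand_mode)
  hw <- params$probe_half_width
  bin <- params$probe_bin
  n_bins <- hw %/% bin
  centres <- (seq_len(n_bins) - 0.5) * bin
  probes <- vector("list", 2L * nrow(active))
  for (i in seq_len(nrow(active))) {
    chr <- active$chrom[i]
    ori <- active$pos[i]
    sub <- ends[ends$chrom == chr, , drop = FALSE]
    len <- if (!is.null(layout)) chrom_length(layout, chr) else NA_integer_
    for (s in c("upstream", "downstream")) {
      if (s == "downstream") {
        sel <- sub$pos >= ori & sub$pos < ori + hw
        d <- sub$pos[sel] - ori
        expected_strand <- "+"
        truncated <- !is.na(len) && (ori + hw > len)
      } else {
        sel <- sub$pos > ori - hw & sub$pos <= ori
        d <- ori - sub$pos[sel]
        expected_strand <- "-"
        truncated <- ori - hw < 0
      }
      cnt <- sub$count[sel]
      if (strand_mode == "leading") {
        keep <- sub$strand[sel] == expected_strand
        d <- d[keep]; cnt <- cnt[keep]
      }
      raw <- numeric(n_bins)
      if (length(d) > 0) {
        b <- pmin(d %/% bin + 1L, n_bins)
        acc <- rowsum(as.numeric(cnt), b)
        raw[as.integer(rownames(acc))] <- acc[, 1]
      }
      probe <- structure(list(
        origin_id = active$origin_id[i], chrom = chr, origin_pos = ori,
        side = s, bin = bin, distance = centres, raw = raw,
        smoothed = NULL, peaks = NULL, retained = NA,
        truncated = truncated, fork_distance = NA_real_
      ), class = "fork_probe")
      probes[[2L * (i - 1L) + match(s, c("upstream", "downstream"))]] <- probe
    }
  }
  probes
}

#' Loess-smooth a probe's binned signal
#'
#' Local polynomial regression with tricube weights over the
#' `loess_neighbours` nearest bins (span = neighbours / bins) at the stated
#' polynomial order, evaluated at every bin midpoint. An all-zero probe is
#' returned all-zero without fitting.
#'
#' @param probe A `fork_probe` from [build_probes()].
#' @param params A [fork_params()].
#' @return The probe with its `smoothed` vector filled in.
#' @export
smooth_probe <- function(probe, params = fork_params()) {
  stopifnot(inherits(probe, "fork_probe"))
  probe$smoothed <- loess_knn(probe$raw, probe$distance,
                              params$loess_neighbours, params$loess_order)
  probe
}

# k-nearest-neighbour tricube local polynomial fit, evaluated at the data
# positions themselves.
loess_knn <- function(y, x, neighbours, order) {
  n <- length(y)
  if (n < neighbours + 1L) {
    stop("need at least loess_neighbours + 1 bins (have ", n, ")")
  }
  if (all(y == 0)) return(numeric(n))
  fit <- stats::loess(y ~ x, data = data.frame(x = x, y = y),
                      span = neighbours / n, degree = order,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  as.numeric(stats::predict(fit, newdata = data.frame(x = x)))
}

#' Detect peaks on a smoothed probe and set its retention flag
#'
#' Peaks are local maxima of the smoothed signal with topographic prominence
#' at least `peak_prominence_fraction` times the smoothed maximum and
#' pairwise separation at least `peak_min_separation` bp. Probes with more
#' than one peak contain a second origin and are dropped from distance
#' statistics (`retained = FALSE`).
#'
#' @param probe A smoothed `fork_probe`.
#' @param params A [fork_params()].
#' @return The probe with `peaks` (a `data.frame` of `distance`, `height`,
#'   `prominence`) and `retained` filled in.
#' @export
detect_peaks <- function(probe, params = fork_params()) {
  stopifnot(inherits(probe, "fork_probe"))
  if (is.null(probe$smoothed)) stop("probe must be smoothed first")
  sm <- probe$smoothed
  if (max(sm) <= 0) {
    probe$peaks <- data.frame(distance = numeric(), height = numeric(),
                              prominence = numeric())
    probe$retained <- TRUE
    return(probe)
  }
  pk <- find_peaks(sm,
                   min_prominence = params$peak_prominence_fraction * max(sm),
                   min_distance = ceiling(params$peak_min_separation / probe$bin))
  probe$peaks <- data.frame(distance = probe$distance[pk$index],
                            height = pk$height, prominence = pk$prominence)
  probe$retained <- nrow(probe$peaks) <= 1L
  probe
}

#' Fork distance of a retained probe
#'
#' The distance from the origin of the maximum of the smoothed signal —
#' the modal fork position within the probe. Undefined (`NA`) for all-zero,
#' non-retained or truncated probes. Ties at the maximum report the smallest
#' distance, with a message.
#'
#' @param probe A smoothed `fork_probe` with peaks detected.
#' @return Distance in bp, or `NA_real_`.
#' @export
fork_distance <- function(probe) {
  stopifnot(inherits(probe, "fork_probe"))
  if (is.null(probe$smoothed) || is.na(probe$retained)) {
    stop("probe must be smoothed and have peaks detected first")
  }
  sm <- probe$smoothed
  if (!isTRUE(probe$retained) || isTRUE(probe$truncated) || max(sm) <= 0) {
    return(NA_real_)
  }
  i <- which(sm == max(sm))
  if (length(i) > 1L) {
    message("tie at smoothed maximum for probe ", probe$origin_id, "/",
            probe$side, "; reporting the smallest distance")
  }
  probe$distance[i[1L]]
}

#' Run the smooth / peak-call / distance stages over a probe list
#'
#' @param probes List of `fork_probe` from [build_probes()].
#' @param params A [fork_params()].
#' @return The probe list with `smoothed`, `peaks`, `retained` and
#'   `fork_distance` populated.
#' @export
process_probes <- function(probes, params = fork_params()) {
  lapply(probes, function(p) {
    p <- smooth_probe(p, params)
    p <- detect_peaks(p, params)
    p$fork_distance <- fork_distance(p)
    p
  })
}

#' Tabulate processed probes
#'
#' @param probes List of processed `fork_probe` objects.
#' @return A `data.frame` with one row per probe: `origin_id`, `chrom`,
#'   `side`, `truncated`, `n_peaks`, `retained`, `fork_distance`.
#' @export
probe_table <- function(probes) {
  do.call(rbind, lapply(probes, function(p) {
    data.frame(origin_id = p$origin_id, chrom = p$chrom, side = p$side,
               truncated = p$truncated,
               n_peaks = if (is.null(p$peaks)) NA_integer_ else nrow(p$peaks),
               retained = p$retained, fork_distance = p$fork_distance,
               stringsAsFactors = FALSE)
  }))
}

#' Aligned probe matrix for heat-map rendering
#'
#' Stacks the smoothed probe vectors into a matrix (one row per probe,
#' columns = distance bins) ordered by decreasing fork distance, the usual
#' presentation for origin-aligned fork profiles.
#'
#' @param probes List of processed `fork_probe` objects.
#' @param retained_only Drop non-retained and truncated probes first
#'   (default `TRUE`).
#' @return A numeric matrix with row names `origin_id/side` and column names
#'   the bin midpoints.
#' @export
aligned_probe_matrix <- function(probes, retained_only = TRUE) {
  if (retained_only) {
    probes <- Filter(function(p) isTRUE(p$retained) && !isTRUE(p$truncated),
                     probes)
  }
  if (length(probes) == 0) return(matrix(numeric(), nrow = 0, ncol = 0))
  m <- do.call(rbind, lapply(probes, function(p) p$smoothed))
  rownames(m) <- vapply(probes, function(p) paste0(p$origin_id, "/", p$side), "")
  colnames(m) <- probes[[1]]$distance
  ord <- order(-vapply(probes, function(p) {
    ifelse(is.na(p$fork_distance), -Inf, p$fork_distance)
  }, numeric(1)))
  m[ord, , drop = FALSE]
}

#' Genome-wide peak detection and fired-origin count
#'
#' Computes the running-window signal per chromosome, Loess-smooths it with
#' the probe smoothing parameters, and counts peaks using the probe peak
#' criteria (prominence relative to the per-chromosome smoothed maximum).
#' Since every fired origin launches two divergent forks, the fired-origin
#' count is the genome-wide peak count divided by two.
#'
#' @param ends A [read_ends()] object.
#' @param layout A [genome_layout()].
#' @param params A [fork_params()].
#' @param window,step Running-window size and step in bp for the genome-wide
#'   signal (defaults 1000 and 100).
#' @return `count_genome_peaks` returns a `data.frame` of peaks (`chrom`,
#'   `pos`, `height`, `prominence`); `count_fired_origins` returns the
#'   integer fired-origin count (peak count %/% 2, with a warning when the
#'   peak count is odd) carrying the peak count as attribute `peak_count`.
#' @export
count_genome_peaks <- function(ends, layout, params = fork_params(),
                               window = 1000L, step = 100L) {
  stopifnot(inherits(ends, "read_ends"), inherits(layout, "genome_layout"))
  ws <- windowed_signal(ends, layout, window = window, step = step)
  out <- list()
  for (chr in layout$chrom) {
    sub <- ws[ws$chrom == chr, , drop = FALSE]
    if (nrow(sub) < params$loess_neighbours + 1L) next
    y <- sub$raw
    mid <- (sub$start + sub$end) / 2
    sm <- loess_knn(y, mid, params$loess_neighbours, params$loess_order)
    if (max(sm) <= 0) next
    pk <- find_peaks(sm,
                     min_prominence = params$peak_prominence_fraction * max(sm),
                     min_distance = ceiling(params$peak_min_separation / step))
    if (nrow(pk) > 0) {
      out[[chr]] <- data.frame(chrom = chr, pos = mid[pk$index],
                               height = pk$height, prominence = pk$prominence,
                               stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), pos = numeric(),
                      height = numeric(), prominence = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @rdname count_genome_peaks
#' @export
count_fired_origins <- function(ends, layout, params = fork_params(),
                                window = 1000L, step = 100L) {
  pk <- count_genome_peaks(ends, layout, params, window = window, step = step)
  n_peaks <- nrow(pk)
  if (n_peaks %% 2L == 1L) {
    warning("odd genome-wide peak count (", n_peaks,
            "); flooring the fired-origin count")
  }
  structure(n_peaks %/% 2L, peak_count = n_peaks)
}
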