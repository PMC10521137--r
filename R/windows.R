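#' Running-window break-end signal with reads-per-million normalization
#'
#' Sums read-end multiplicities in running windows along each chromosome and
#' scales counts to reads per million. Window starts are placed every `step`
#' bp from position 0; a window covers `[start, start + window)` and the last
#' window on a chromosome may overhang its end. With `step == window` the
#' windows tile the chromosome, so raw counts conserve the total retained
#' multiplicity and normalized values sum to 1e6 under the default
#' denominator.
#'
#' @param ends A [read_ends()] object (after masking/deduplication).
#' @param layout A [genome_layout()].
#' @param window Window size in bp (default 1000).
#' @param step Step between window starts in bp (default 100); must satisfy
#'   `window >= step >= 1`.
#' @param denominator `"retained"` (default): normalize by the total retained
#'   multiplicity in `ends`; `"mapped"`: normalize by `total_mapped`.
#' @param total_mapped Total mapped read count, required when
#'   `denominator = "mapped"`.
#' @param strand Optionally restrict to `"+"` or `"-"` ends before windowing
#'   (the denominator is still computed from the unrestricted input so that
#'   per-strand tracks are comparable).
#'
#' @return A `data.frame` of class `windowed_signal` with columns `chrom`,
#'   `start`, `end`, `raw`, `rpm`; attributes `window`, `step`,
#'   `denominator_policy`, `denominator`.
#' @export
windowed_signal <- function(ends, layout, window = 1000L, step = 100L,
                            denominator = c("retained", "mapped"),
                            total_mapped = NULL, strand = NULL) {
  stopifnot(inherits(ends, "read_ends"), inherits(layout, "genome_layout"))
  denominator <- match.arg(denominator)
  window <- as.integer(window); step <- as.integer(step)
  if (step < 1L || window < step) stop("require window >= step >= 1")
  denom <- if (denominator == "retained") {
    total_reads(ends)
  } else {
    if (is.null(total_mapped)) stop("total_mapped required for denominator = 'mapped'")
    as.numeric(total_mapped)
  }
  if (!is.null(strand)) {
    strand <- match.arg(strand, c("+", "-"))
    ends <- ends[ends$strand == strand, , drop = FALSE]
  }
  pieces <- lapply(seq_len(nrow(layout)), function(i) {
    chr <- layout$chrom[i]
    len <- layout$length[i]
    starts <- seq.int(0L, max(0L, len - 1L), by = step)
    sub <- ends[ends$chrom == chr, , drop = FALSE]
    raw <- window_counts(sub$pos, sub$count, starts, window)
    data.frame(chrom = chr, start = starts, end = starts + window,
               raw = raw, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (denom <= 0) {
    if (total_reads(ends) > 0 || denom < 0) {
      warning("normalization denominator is 0; normalized values set to 0")
    } else if (denom == 0) {
      warning("no reads retained; normalized values set to 0")
    }
    out$rpm <- rep(0, nrow(out))
  } else {
    out$rpm <- out$raw * 1e6 / denom
  }
  rownames(out) <- NULL
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "denominator_policy") <- denominator
  attr(out, "denominator") <- denom
  class(out) <- c("windowed_signal", "data.frame")
  out
}

# Weighted count of positions falling in [start, start + window) for each
# window start, via cumulative sums over the sorted positions.
window_counts <- function(pos, count, starts, window) {
  if (length(pos) == 0) return(numeric(length(starts)))
  ord <- order(pos)
  pos <- pos[ord]
  cum <- cumsum(as.numeric(count[ord]))
  upto <- function(x) {          # total multiplicity at positions < x
    i <- findInterval(x - 0.5, pos)
    ifelse(i == 0, 0, cum[pmax(i, 1)])
  }
  upto(starts + window) - upto(starts)
}
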