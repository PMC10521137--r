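#' Read an origin catalogue from BED
#'
#' Origins (e.g. budding-yeast ARS sites) are stored as BED intervals; the
#' origin position is taken as the interval midpoint, and the BED name column
#' supplies the origin id when present.
#'
#' @param path BED file path (>= 3 columns).
#' @return A `data.frame` with columns `origin_id`, `chrom`, `pos`.
#' @export
read_origin_catalogue <- function(path) {
  bed <- read_bed3(path)
  out <- data.frame(
    origin_id = if (!is.null(bed$label)) bed$label else
      sprintf("ori%03d", seq_len(nrow(bed))),
    chrom = bed$chrom,
    pos = as.integer(floor((bed$start + bed$end) / 2)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$origin_id)) stop("origin ids must be unique")
  out
}

#' Score candidate origins and retain the active subset
#'
#' Each origin is scored by the total read-end multiplicity in the activity
#' window centred on it (computed on the reference condition's reads).
#' Origins are ranked by score and the bottom `activity_filter_fraction`
#' removed, so the retained count is `ceiling((1 - fraction) * n)`. Ties at
#' the cut boundary are broken by retaining the earlier-coordinate origin.
#'
#' @param ends A [read_ends()] object for the reference condition.
#' @param catalogue A `data.frame` with columns `origin_id`, `chrom`, `pos`.
#' @param params A [fork_params()].
#' @return The catalogue subset of active origins, with an added
#'   `activity_score` column, ordered by chromosome and position.
#' @examples
#' # 5 origins scoring 10, 20, 30, 40, 50 with fraction 0.40: the three
#' # top-scoring origins are retained.
#' @export
call_active_origins <- function(ends, catalogue, params = fork_params()) {
  stopifnot(inherits(ends, "read_ends"), inherits(params, "fork_params"))
  if (nrow(catalogue) == 0) stop("origin catalogue is empty")
  if (anyDuplicated(catalogue$origin_id)) stop("origin ids must be unique")
  half <- params$activity_window / 2
  score <- vapply(seq_len(nrow(catalogue)), function(i) {
    sub <- ends[ends$chrom == catalogue$chrom[i], , drop = FALSE]
    lo <- catalogue$pos[i] - half
    hi <- catalogue$pos[i] + half
    sum(sub$count[sub$pos >= lo & sub$pos < hi])
  }, numeric(1))
  n <- nrow(catalogue)
  keep_n <- ceiling((1 - params$activity_filter_fraction) * n)
  if (length(unique(score)) == 1L && n > 1L) {
    warning("all origin activity scores are equal; retaining ",
            keep_n, " origins in coordinate order")
  }
  ord <- order(-score, catalogue$chrom, catalogue$pos)
  keep <- sort(ord[seq_len(keep_n)])
  out <- catalogue[keep, , drop = FALSE]
  out$activity_score <- score[keep]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
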