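#' Stranded single-nucleotide read ends
#'
#' The central TrAEL-seq container: one row per unique (chromosome, position,
#' strand) triple with a multiplicity count. Positions are zero-based and mark
#' the last nucleotide 5' of the strand break, i.e. each mapped read is
#' truncated to a single base.
#'
#' @param chrom Character chromosome names.
#' @param pos Zero-based positions (non-negative integers).
#' @param strand `"+"` or `"-"`.
#' @param count Multiplicities (positive integers), default 1.
#'
#' @return A `data.frame` of class `read_ends` with columns `chrom`, `pos`,
#'   `strand`, `count`, aggregated over identical triples and sorted by
#'   coordinate.
#' @export
read_ends <- function(chrom = character(), pos = integer(),
                      strand = character(), count = 1L) {
  n <- length(pos)
  chrom <- as.character(chrom)
  strand <- as.character(strand)
  count <- rep_len(as.integer(count), n)
  if (length(chrom) != n || length(strand) != n) {
    stop("chrom, pos and strand must have equal length")
  }
  if (n > 0) {
    if (any(!strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(pos < 0) || any(pos != floor(pos))) {
      stop("positions must be non-negative integers")
    }
    if (any(count < 1L)) stop("multiplicity must be >= 1")
  }
  df <- data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
                   count = count, stringsAsFactors = FALSE)
  df <- aggregate_ends(df)
  class(df) <- c("read_ends", "data.frame")
  df
}

# Collapse identical (chrom, pos, strand) triples, summing counts;
# output sorted by chrom, pos, strand.
aggregate_ends <- function(df) {
  if (nrow(df) == 0) return(df)
  key <- paste(df$chrom, df$pos, df$strand, sep = "\r")
  cnt <- rowsum(df$count, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- df[first, c("chrom", "pos", "strand"), drop = FALSE]
  out$count <- as.integer(cnt[match(key[first], rownames(cnt)), 1])
  ord <- order(out$chrom, out$pos, out$strand)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

total_reads <- function(ends) {
  if (nrow(ends) == 0) return(0L)
  sum(ends$count)
}

#' Extract 5'-most break-adjacent positions from mapped reads
#'
#' Each BED6 interval is truncated to one nucleotide at its 5' end: the
#' interval start for plus-strand reads, `end - 1` for minus-strand reads.
#' Identical (chromosome, position, strand) triples are aggregated into a
#' multiplicity count.
#'
#' @param reads A `data.frame` with BED6 columns `chrom`, `start`, `end`,
#'   optionally `name` and `score`, and `strand`, zero-based half-open
#'   (e.g. from [read_bed6()]).
#' @return A [read_ends()] object.
#' @examples
#' reads <- data.frame(chrom = "chrI", start = 100L, end = 175L,
#'                     name = ".", score = 0L, strand = "+")
#' extract_read_ends(reads)  # single end at chrI:100:+
#' @export
extract_read_ends <- function(reads) {
  req <- c("chrom", "start", "end", "strand")
  if (!all(req %in% names(reads))) {
    stop("reads must have columns ", paste(req, collapse = ", "))
  }
  if (nrow(reads) == 0) return(read_ends())
  if (any(reads$end <= reads$start)) {
    stop("zero- or negative-length read interval encountered")
  }
  ok <- reads$strand %in% c("+", "-")
  if (any(!ok)) {
    warning(sum(!ok), " read(s) without a usable strand were rejected")
    reads <- reads[ok, , drop = FALSE]
    if (nrow(reads) == 0) return(read_ends())
  }
  pos <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  read_ends(reads$chrom, pos, reads$strand)
}

#' Filter read ends against an exclusion mask and optionally collapse
#' duplicates
#'
#' Ends whose position falls inside any mask interval (union semantics over
#' possibly overlapping intervals) are removed; this mirrors discarding reads
#' that map to non-single-copy regions (rDNA, 2-micron plasmid, mtDNA,
#' sub-telomeres, transposons). With `dedup = TRUE` multiplicities are
#' collapsed to 1, an explicit positional de-duplication stage. Both
#' operations are idempotent.
#'
#' @param ends A [read_ends()] object.
#' @param mask `NULL`, or a `data.frame` with columns `chrom`, `start`, `end`
#'   (zero-based half-open; e.g. from [read_bed3()]), or a
#'   `GenomicRanges::GRanges`.
#' @param dedup Collapse multiplicities to 1?
#' @return A filtered [read_ends()] object.
#' @export
filter_and_deduplicate <- function(ends, mask = NULL, dedup = FALSE) {
  stopifnot(inherits(ends, "read_ends"))
  out <- ends
  if (!is.null(mask) && nrow(out) > 0) {
    gr_mask <- as_mask_granges(mask)
    if (length(gr_mask) > 0) {
      gr_ends <- GenomicRanges::GRanges(
        seqnames = out$chrom,
        ranges = IRanges::IRanges(start = out$pos + 1L, width = 1L)
      )
      hit <- IRanges::overlapsAny(gr_ends, gr_mask, ignore.strand = TRUE)
      out <- out[!hit, , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  if (isTRUE(dedup) && nrow(out) > 0) out$count <- rep(1L, nrow(out))
  class(out) <- c("read_ends", "data.frame")
  out
}

as_mask_granges <- function(mask) {
  if (inherits(mask, "GRanges")) return(mask)
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(mask))) {
    stop("mask must have columns chrom, start, end")
  }
  if (nrow(mask) == 0) {
    return(GenomicRanges::GRanges())
  }
  if (any(mask$end <= mask$start)) stop("mask intervals must satisfy start < end")
  GenomicRanges::GRanges(
    seqnames = mask$chrom,
    ranges = IRanges::IRanges(start = mask$start + 1L, end = mask$end)
  )
}
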