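#' Genome layout
#'
#' A minimal description of the reference genome: one row per chromosome with
#' its length in base pairs. All coordinates in the package are zero-based and
#' half-open, matching the BED convention.
#'
#' @param chrom Character vector of chromosome names (must be unique).
#' @param length Integer vector of chromosome lengths in bp (all > 0).
#'
#' @return A `data.frame` of class `genome_layout` with columns `chrom` and
#'   `length`.
#' @examples
#' genome_layout(c("chrI", "chrII"), c(500000L, 500000L))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != base::length(length)) {
    stop("`chrom` and `length` must have equal length")
  }
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0) || any(length != floor(length))) {
    stop("chromosome lengths must be positive integers")
  }
  out <- data.frame(chrom = chrom, length = as.integer(length),
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Read or write a two-column chromosome-sizes file
#'
#' The standard `chrom.sizes` format: tab-separated, chromosome name then
#' length, no header.
#'
#' @param path File path.
#' @param layout A [genome_layout()].
#' @return `read_chrom_sizes` returns a [genome_layout()];
#'   `write_chrom_sizes` returns `path` invisibly.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chromosome-sizes file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_layout(df$chrom, df$length)
}

#' @rdname read_chrom_sizes
#' @export
write_chrom_sizes <- function(layout, path) {
  stopifnot(inherits(layout, "genome_layout"))
  utils::write.table(layout[, c("chrom", "length")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) stop("chromosome not in layout: ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  layout$length[i]
}
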