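#' Read BED files into data frames
#'
#' Plain tab-separated BED readers (zero-based, half-open). `read_bed6`
#' expects at least six columns (chrom, start, end, name, score, strand);
#' `read_bed3` at least three, with an optional fourth used as interval label.
#'
#' @param path File path.
#' @return A `data.frame`; `read_bed6` has columns `chrom`, `start`, `end`,
#'   `name`, `score`, `strand`; `read_bed3` has `chrom`, `start`, `end` and,
#'   when present, `label`.
#' @export
read_bed6 <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("expected >= 6 BED columns in ", path)
  df <- df[, 1:6]
  names(df) <- c("chrom", "start", "end", "name", "score", "strand")
  df$chrom <- as.character(df$chrom)
  df$strand <- as.character(df$strand)
  df
}

#' @rdname read_bed6
#' @export
read_bed3 <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("expected >= 3 BED columns in ", path)
  out <- df[, 1:3]
  names(out) <- c("chrom", "start", "end")
  out$chrom <- as.character(out$chrom)
  if (ncol(df) >= 4) out$label <- as.character(df[[4]])
  out
}

#' Read and write read ends as BED6
#'
#' Each end is stored as a single-nucleotide interval `[pos, pos + 1)` with
#' its multiplicity in the score column.
#'
#' @param ends A [read_ends()] object.
#' @param path File path.
#' @return `write_read_ends_bed` returns `path` invisibly;
#'   `read_read_ends_bed` returns a [read_ends()] object.
#' @export
write_read_ends_bed <- function(ends, path) {
  stopifnot(inherits(ends, "read_ends"))
  bed <- data.frame(chrom = ends$chrom, start = ends$pos,
                    end = ends$pos + 1L, name = "end", score = ends$count,
                    strand = ends$strand, stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_read_ends_bed
#' @export
read_read_ends_bed <- function(path) {
  bed <- read_bed6(path)
  if (nrow(bed) == 0) return(read_ends())
  if (any(bed$end - bed$start != 1L)) {
    stop("read-end BED must contain single-nucleotide intervals")
  }
  count <- suppressWarnings(as.integer(bed$score))
  count[is.na(count) | count < 1L] <- 1L
  read_ends(bed$chrom, bed$start, bed$strand, count)
}

#' Write a windowed signal track as bedGraph
#'
#' Four columns (chrom, start, end, value), fixed-format floats; a
#' `track type=bedGraph` header line is included. The normalized
#' reads-per-million value is exported by default.
#'
#' @param signal A [windowed_signal()] result.
#' @param path File path.
#' @param value `"rpm"` or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(signal, path, value = c("rpm", "raw")) {
  value <- match.arg(value)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('track type=bedGraph name="traelkit windowed signal"', con)
  df <- data.frame(signal$chrom, signal$start, signal$end,
                   sprintf("%.6f", signal[[value]]))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
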