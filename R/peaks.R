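#' Local maxima with topographic prominence
#'
#' Finds interior local maxima of a numeric vector (plateaus report their
#' middle sample; boundary samples are never peaks), computes each peak's
#' topographic prominence — its height above the higher of the two minima
#' separating it from taller terrain on either side — and then applies a
#' prominence threshold followed by a greedy minimum-separation filter that
#' keeps higher peaks first.
#'
#' @param x Numeric vector.
#' @param min_prominence Minimum prominence to keep a peak (default 0).
#' @param min_distance Minimum index separation between kept peaks
#'   (default 0).
#' @return A `data.frame` with columns `index`, `height`, `prominence`,
#'   ordered by index.
#' @export
find_peaks <- function(x, min_prominence = 0, min_distance = 0) {
  empty <- data.frame(index = integer(), height = numeric(),
                      prominence = numeric())
  n <- length(x)
  if (n < 3) return(empty)
  r <- rle(x)
  k <- length(r$values)
  if (k < 3) return(empty)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  idx <- integer(0)
  for (j in 2:(k - 1)) {
    if (r$values[j] > r$values[j - 1] && r$values[j] > r$values[j + 1]) {
      idx <- c(idx, run_start[j] + (r$lengths[j] - 1L) %/% 2L)
    }
  }
  if (length(idx) == 0) return(empty)

  prom <- vapply(idx, function(i) peak_prominence(x, i), numeric(1))
  keep <- prom >= min_prominence
  idx <- idx[keep]; prom <- prom[keep]
  if (length(idx) > 1 && min_distance > 0) {
    ord <- order(-x[idx], idx)
    kept <- integer(0)
    for (i in ord) {
      if (all(abs(idx[i] - idx[kept]) >= min_distance)) kept <- c(kept, i)
    }
    kept <- sort(kept)
    idx <- idx[kept]; prom <- prom[kept]
  }
  data.frame(index = idx, height = x[idx], prominence = prom)
}

# Height of x[i] above the higher of the two minima separating it from
# taller terrain (or the vector boundary) on each side.
peak_prominence <- function(x, i) {
  h <- x[i]
  left_min <- h
  j <- i - 1L
  while (j >= 1L && x[j] <= h) {
    if (x[j] < left_min) left_min <- x[j]
    j <- j - 1L
  }
  right_min <- h
  j <- i + 1L
  while (j <= length(x) && x[j] <= h) {
    if (x[j] < right_min) right_min <- x[j]
    j <- j + 1L
  }
  h - max(left_min, right_min)
}
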