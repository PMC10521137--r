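# Shared fixtures, built in code.

# A single-chromosome layout sized to hold `n` origins spaced `spacing` bp,
# the first at `offset`; returns list(layout, origins).
spaced_origins <- function(n, spacing = 60000L, offset = 40000L,
                           chrom = "chrI") {
  pos <- offset + spacing * (seq_len(n) - 1L)
  layout <- genome_layout(chrom, max(pos) + offset)
  list(layout = layout,
       origins = data.frame(origin_id = sprintf("ori%03d", seq_len(n)),
                            chrom = chrom, pos = pos,
                            stringsAsFactors = FALSE))
}

# Multi-chromosome version: `per_chrom` origins on each of `n_chrom`
# chromosomes.
multi_chrom_origins <- function(n_chrom = 3L, per_chrom = 10L,
                                spacing = 60000L, offset = 40000L) {
  pieces <- lapply(seq_len(n_chrom), function(k) {
    s <- spaced_origins(per_chrom, spacing, offset,
                        chrom = paste0("chr", k))
    s$origins$origin_id <- sprintf("c%do%02d", k, seq_len(per_chrom))
    s
  })
  layout <- do.call(rbind, lapply(pieces, `[[`, "layout"))
  layout <- genome_layout(layout$chrom, layout$length)
  origins <- do.call(rbind, lapply(pieces, `[[`, "origins"))
  rownames(origins) <- NULL
  list(layout = layout, origins = origins)
}

# Bare fork_probe around a signal vector, for direct smoothing/peak tests.
make_probe <- function(raw, bin = 100L, side = "downstream",
                       truncated = FALSE) {
  structure(list(origin_id = "oriT", chrom = "chrT", origin_pos = 0L,
                 side = side, bin = bin,
                 distance = (seq_along(raw) - 0.5) * bin,
                 raw = as.numeric(raw), smoothed = NULL, peaks = NULL,
                 retained = NA, truncated = truncated,
                 fork_distance = NA_real_),
            class = "fork_probe")
}

# Brute-force peak oracle: strict local maxima plus prominence computed by
# whole-vector scans (no walking loop), no separation filter.
brute_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  idx <- which(vapply(seq_len(n), function(i) {
    i > 1 && i < n && x[i] > x[i - 1] && x[i] > x[i + 1]
  }, logical(1)))
  prom <- vapply(idx, function(i) {
    higher_left <- which(x[seq_len(i - 1)] > x[i])
    L <- if (length(higher_left)) max(higher_left) + 1L else 1L
    left_min <- min(x[L:(i - 1)])
    right_side <- if (i < n) x[(i + 1):n] else numeric(0)
    higher_right <- which(right_side > x[i])
    R <- if (length(higher_right)) i + min(higher_right) - 1L else n
    right_min <- min(x[(i + 1):R])
    x[i] - max(left_min, right_min)
  }, numeric(1))
  keep <- prom >= min_prominence
  data.frame(index = idx[keep], height = x[idx[keep]],
             prominence = prom[keep])
}

# Long-format LFQ table from an intensity matrix: rows = proteins, one
# column per sample/replicate combination given in `design` (data.frame with
# sample, replicate).
lfq_from_matrix <- function(m, design) {
  stopifnot(ncol(m) == nrow(design))
  do.call(rbind, lapply(seq_len(nrow(design)), function(j) {
    data.frame(protein = rownames(m), sample = design$sample[j],
               replicate = design$replicate[j], intensity = m[, j],
               stringsAsFactors = FALSE)
  }))
}

std_design <- function(n_rep = 3L) {
  data.frame(sample = rep(paste0("sample", 1:3), each = n_rep),
             replicate = rep(seq_len(n_rep), 3L))
}
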