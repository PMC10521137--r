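#' Default desk-scale genome and origin catalogue
#'
#' Two 500-kb chromosomes carrying five origins each, spaced 90 kb apart and
#' at least 70 kb from chromosome ends — comfortably separated for
#' single-peak probes and small enough for fast simulation.
#'
#' @return `default_trael_layout()` returns a [genome_layout()];
#'   `default_trael_origins()` a `data.frame` with columns `origin_id`,
#'   `chrom`, `pos`.
#' @export
default_trael_layout <- function() {
  genome_layout(c("chrI", "chrII"), c(500000L, 500000L))
}

#' @rdname default_trael_layout
#' @export
default_trael_origins <- function() {
  pos <- c(70000L, 160000L, 250000L, 340000L, 430000L)
  out <- data.frame(
    chrom = rep(c("chrI", "chrII"), each = length(pos)),
    pos = rep(pos, 2L),
    stringsAsFactors = FALSE
  )
  out$origin_id <- sprintf("ori%03d", seq_len(nrow(out)))
  out[, c("origin_id", "chrom", "pos")]
}

# Normal(mean, sd) truncated at zero, by rejection; sd = 0 returns the mean.
rtruncnorm_pos <- function(n, mean, sd) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0)
  guard <- 0L
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
    guard <- guard + 1L
    if (guard > 1000L) stop("truncated-normal rejection failed to converge")
  }
  out
}

#' Simulate a TrAEL-like replication-fork experiment
#'
#' Generates stranded single-nucleotide read ends around replication forks
#' with full ground truth. Each origin fires independently; a fired origin
#' places one leftward and one rightward fork at distances drawn from a
#' truncated Normal, and each fork emits a fixed number of read ends
#' scattered with Gaussian positional noise. Strand labels follow the
#' leading-strand preference of the assay: rightward forks emit plus-strand
#' reads with probability `leading_fraction`, leftward forks mirrored.
#' Uniform background reads and exact-copy duplicates are added last.
#'
#' @param layout A [genome_layout()].
#' @param params A [fork_sim_params()]; origin positions must lie within
#'   chromosome bounds.
#' @param probe_half_width Probe half-width (bp) used only to flag origin
#'   pairs closer than twice this value in the truth metadata, since such
#'   pairs violate the downstream single-peak-per-probe assumption.
#'
#' @return A list with elements
#'   \describe{
#'     \item{ends}{a [read_ends()] object;}
#'     \item{truth}{a list with `origins` (one row per fired origin: `origin_id`,
#'       `chrom`, `pos`, `fired`, `fork_left`, `fork_right`, `dist_left`,
#'       `dist_right`), `counts` (`fork_reads`, `background_reads`,
#'       `duplicate_reads`, `total_reads`) and `warnings` (character).}
#'   }
#' @examples
#' sim <- simulate_trael_experiment(default_trael_layout(),
#'   fork_sim_params(default_trael_origins(), seed = 7))
#' head(sim$ends)
#' sim$truth$counts
#' @export
simulate_trael_experiment <- function(layout, params,
                                      probe_half_width = 20000L) {
  stopifnot(inherits(layout, "genome_layout"),
            inherits(params, "fork_sim_params"))
  ori <- params$origins
  ori <- ori[order(ori$chrom, ori$pos), , drop = FALSE]
  rownames(ori) <- NULL
  len <- chrom_length(layout, ori$chrom)
  if (any(ori$pos < 0) || any(ori$pos >= len)) {
    stop("origin positions must lie within chromosome bounds")
  }

  warnings <- character()
  for (chr in unique(ori$chrom)) {
    p <- sort(ori$pos[ori$chrom == chr])
    if (length(p) > 1 && any(diff(p) < 2 * probe_half_width)) {
      warnings <- c(warnings, paste0(
        "origins on ", chr, " closer than twice the probe half-width (",
        2 * probe_half_width, " bp); probes may contain more than one origin"))
    }
  }

  set.seed(params$seed)
  n <- nrow(ori)
  fired <- stats::runif(n) < params$firing_prob
  dist_left <- dist_right <- fork_left <- fork_right <- rep(NA_real_, n)
  nf <- sum(fired)
  if (nf > 0) {
    dist_left[fired] <- rtruncnorm_pos(nf, params$distance_mean, params$distance_sd)
    dist_right[fired] <- rtruncnorm_pos(nf, params$distance_mean, params$distance_sd)
    fork_left[fired] <- ori$pos[fired] - dist_left[fired]
    fork_right[fired] <- ori$pos[fired] + dist_right[fired]
  }

  chrom <- character(0); pos <- numeric(0); strand <- character(0)
  rpf <- params$reads_per_fork
  for (i in which(fired)) {
    for (side in c("left", "right")) {
      centre <- if (side == "left") fork_left[i] else fork_right[i]
      p <- centre + stats::rnorm(rpf, 0, params$noise_sd)
      lead <- stats::runif(rpf) < params$leading_fraction
      s <- if (side == "right") ifelse(lead, "+", "-") else ifelse(lead, "-", "+")
      chrom <- c(chrom, rep(ori$chrom[i], rpf))
      pos <- c(pos, p)
      strand <- c(strand, s)
    }
  }
  n_fork <- length(pos)

  # uniform background per chromosome
  n_bg_total <- 0L
  for (k in seq_len(nrow(layout))) {
    lam <- layout$length[k] / 1000 * params$background_rate
    n_bg <- if (lam > 0) stats::rpois(1, lam) else 0L
    if (n_bg > 0) {
      chrom <- c(chrom, rep(layout$chrom[k], n_bg))
      pos <- c(pos, stats::runif(n_bg, 0, layout$length[k]))
      strand <- c(strand, sample(c("+", "-"), n_bg, replace = TRUE))
      n_bg_total <- n_bg_total + n_bg
    }
  }

  if (length(pos) > 0) {
    pos <- floor(pos)
    lim <- chrom_length(layout, chrom)
    pos <- pmin(pmax(pos, 0), lim - 1)
  }

  # exact-copy duplicates of emitted reads
  n_base <- length(pos)
  dup_idx <- integer(0)
  if (n_base > 0 && params$duplicate_rate > 0) {
    dup_idx <- which(stats::runif(n_base) < params$duplicate_rate)
  }
  n_dup <- length(dup_idx)
  if (n_dup > 0) {
    chrom <- c(chrom, chrom[dup_idx])
    pos <- c(pos, pos[dup_idx])
    strand <- c(strand, strand[dup_idx])
  }

  ends <- read_ends(chrom, pos, strand)
  truth_orig <- data.frame(origin_id = ori$origin_id, chrom = ori$chrom,
                           pos = ori$pos, fired = fired,
                           fork_left = fork_left, fork_right = fork_right,
                           dist_left = dist_left, dist_right = dist_right,
                           stringsAsFactors = FALSE)
  # the truth lists fired origins only (both fork positions and distances)
  truth_orig <- truth_orig[truth_orig$fired, , drop = FALSE]
  rownames(truth_orig) <- NULL
  list(
    ends = ends,
    truth = list(
      origins = truth_orig,
      counts = list(fork_reads = n_fork, background_reads = n_bg_total,
                    duplicate_reads = n_dup,
                    total_reads = n_fork + n_bg_total + n_dup),
      warnings = warnings
    )
  )
}

#' Write a simulated TrAEL experiment to disk
#'
#' Read ends go to BED6, the per-origin truth table to TSV and the chromosome
#' sizes to a two-column TSV, under a common file prefix.
#'
#' @param sim Result of [simulate_trael_experiment()].
#' @param layout The [genome_layout()] used for the simulation.
#' @param prefix Output path prefix.
#' @return Named character vector of the files written, invisibly.
#' @export
write_trael_simulation <- function(sim, layout, prefix) {
  paths <- c(ends = paste0(prefix, ".ends.bed"),
             truth = paste0(prefix, ".truth.tsv"),
             chrom_sizes = paste0(prefix, ".chrom.sizes"))
  write_read_ends_bed(sim$ends, paths[["ends"]])
  write_tsv(sim$truth$origins, paths[["truth"]])
  write_chrom_sizes(layout, paths[["chrom_sizes"]])
  invisible(paths)
}
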