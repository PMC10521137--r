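#' Fork-progression analysis parameters
#'
#' Bundles every tunable of the origin-centred fork analysis. Defaults follow
#' common practice for budding-yeast TrAEL-seq: a 10-kb activity window
#' centred on each candidate origin with the bottom 40% of activity scores
#' filtered out; 20-kb oriented probes on each side of an active origin,
#' binned at 100 bp; Loess smoothing with 15 nearest neighbours and a
#' second-order local polynomial; peaks defined as local maxima with
#' topographic prominence at least half the probe maximum and pairwise
#' separation of at least 2 kb.
#'
#' @param activity_window Width in bp of the window centred on each candidate
#'   origin used to score its activity (default 10000).
#' @param activity_filter_fraction Fraction of lowest-scoring origins removed
#'   (default 0.40; must be in `[0, 1)`).
#' @param probe_half_width Probe extent in bp on each side of the origin
#'   (default 20000; must exceed `activity_window / 2`).
#' @param probe_bin Bin width in bp for probe signal (default 100).
#' @param loess_neighbours Number of nearest bins used by the local fit
#'   (default 15; must be at least `loess_order + 1`).
#' @param loess_order Local polynomial order (default 2).
#' @param peak_prominence_fraction Minimum peak prominence as a fraction of
#'   the smoothed profile maximum (default 0.5; in `(0, 1]`).
#' @param peak_min_separation Minimum distance between peaks in bp
#'   (default 2000).
#' @param reference_condition Condition id used to score origin activity and
#'   order aligned probes (default `"reference"`).
#'
#' @return A list of class `fork_params`.
#' @export
fork_params <- function(activity_window = 10000L,
                        activity_filter_fraction = 0.40,
                        probe_half_width = 20000L,
                        probe_bin = 100L,
                        loess_neighbours = 15L,
                        loess_order = 2L,
                        peak_prominence_fraction = 0.5,
                        peak_min_separation = 2000L,
                        reference_condition = "reference") {
  p <- list(activity_window = as.integer(activity_window),
            activity_filter_fraction = as.numeric(activity_filter_fraction),
            probe_half_width = as.integer(probe_half_width),
            probe_bin = as.integer(probe_bin),
            loess_neighbours = as.integer(loess_neighbours),
            loess_order = as.integer(loess_order),
            peak_prominence_fraction = as.numeric(peak_prominence_fraction),
            peak_min_separation = as.integer(peak_min_separation),
            reference_condition = as.character(reference_condition))
  if (p$activity_window < 1L) stop("activity_window must be positive")
  if (p$activity_filter_fraction < 0 || p$activity_filter_fraction >= 1) {
    stop("activity_filter_fraction must be in [0, 1)")
  }
  if (p$probe_half_width <= p$activity_window / 2) {
    stop("probe_half_width must exceed activity_window / 2")
  }
  if (p$probe_bin < 1L || p$probe_half_width %% p$probe_bin != 0L) {
    stop("probe_bin must be positive and divide probe_half_width")
  }
  if (p$loess_neighbours < p$loess_order + 1L) {
    stop("loess_neighbours must be at least loess_order + 1")
  }
  if (p$peak_prominence_fraction <= 0 || p$peak_prominence_fraction > 1) {
    stop("peak_prominence_fraction must be in (0, 1]")
  }
  if (p$peak_min_separation < 0L) stop("peak_min_separation must be >= 0")
  class(p) <- "fork_params"
  p
}

#' Simulation parameters for a TrAEL-like fork experiment
#'
#' Describes the generative model for read ends around fired origins: each
#' origin fires independently with `firing_prob`; a fired origin places a
#' leftward and a rightward fork at distances drawn independently from a
#' Normal(`distance_mean`, `distance_sd`) truncated at zero; `reads_per_fork`
#' read ends are scattered Normal(`0`, `noise_sd`) around each fork position.
#' Rightward forks emit plus-strand reads with probability
#' `leading_fraction` (leading-strand preference) and minus-strand otherwise;
#' leftward forks are mirrored. Uniform background reads are added at
#' `background_rate` per kb and PCR-style duplicates (exact copies of
#' existing ends) at `duplicate_rate`.
#'
#' @param origins A `data.frame` with columns `chrom` and `pos` (origin
#'   midpoints, zero-based bp); an `origin_id` column is added when absent.
#' @param firing_prob Per-origin firing probability in `[0, 1]` (default 1).
#' @param distance_mean,distance_sd Mean and spread (bp) of the per-fork
#'   distance distribution (defaults 12000 and 1000).
#' @param noise_sd Positional read noise in bp (default 300).
#' @param leading_fraction Fraction of fork reads on the leading strand
#'   (default 0.8).
#' @param reads_per_fork Read ends emitted per fork (default 150).
#' @param background_rate Uniform background reads per kb (default 0.05).
#' @param duplicate_rate Probability that an emitted read is duplicated once
#'   (default 0.02).
#' @param seed Integer seed; every simulation is fully reproducible.
#'
#' @return A list of class `fork_sim_params`.
#' @export
fork_sim_params <- function(origins,
                            firing_prob = 1,
                            distance_mean = 12000,
                            distance_sd = 1000,
                            noise_sd = 300,
                            leading_fraction = 0.8,
                            reads_per_fork = 150L,
                            background_rate = 0.05,
                            duplicate_rate = 0.02,
                            seed = 1L) {
  if (!all(c("chrom", "pos") %in% names(origins))) {
    stop("origins must have columns chrom and pos")
  }
  origins <- as.data.frame(origins)
  if (is.null(origins$origin_id)) {
    origins$origin_id <- sprintf("ori%03d", seq_len(nrow(origins)))
  }
  p <- list(origins = origins[, c("origin_id", "chrom", "pos")],
            firing_prob = as.numeric(firing_prob),
            distance_mean = as.numeric(distance_mean),
            distance_sd = as.numeric(distance_sd),
            noise_sd = as.numeric(noise_sd),
            leading_fraction = as.numeric(leading_fraction),
            reads_per_fork = as.integer(reads_per_fork),
            background_rate = as.numeric(background_rate),
            duplicate_rate = as.numeric(duplicate_rate),
            seed = as.integer(seed))
  for (f in c("firing_prob", "leading_fraction", "duplicate_rate")) {
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  if (p$distance_mean <= 0) stop("distance_mean must be positive")
  if (p$distance_sd < 0 || p$noise_sd < 0 || p$background_rate < 0) {
    stop("spreads and rates must be >= 0")
  }
  if (p$reads_per_fork < 1L) stop("reads_per_fork must be a positive integer")
  class(p) <- "fork_sim_params"
  p
}

#' Simulation parameters for a three-sample LFQ proximity-labelling design
#'
#' Emulates label-free-quantification intensity tables from the standard
#' TurboID design: sample 1 lacks the biotin ligase (treatment only),
#' sample 2 carries the ligase without treatment, sample 3 carries the ligase
#' with treatment. Protein baseline intensities are log-normal. Tag-specific
#' proteins are elevated `tag_fold`-fold in samples 2 and 3;
#' treatment-enhanced proteins are elevated `treatment_fold`-fold in sample 3
#' only; background proteins (and the endogenously biotinylated control) have
#' equal expectation across samples. Intensities are set to zero (dropout)
#' with probability `dropout_prob`, never for the control. The default
#' dropout probability is 0, matching complete tables.
#'
#' @param n_proteins Number of proteins beside the control (default 300).
#' @param replicates Replicates per sample class, length-3 integer
#'   (default `c(3, 3, 3)`).
#' @param frac_tag_specific Fraction of tag-specific proteins (default 0.10).
#' @param frac_treatment_enhanced Fraction of treatment-enhanced proteins
#'   (default 0.05); the two fractions must sum to at most 1.
#' @param tag_fold,treatment_fold Fold effects (default 8).
#' @param intensity_scale Median baseline intensity (default 1e6).
#' @param intensity_dispersion Log-normal sdlog of protein baselines
#'   (default 1).
#' @param replicate_cv Log-normal sdlog of replicate noise (default 0.2).
#' @param dropout_prob Per-measurement dropout probability (default 0).
#' @param control_id Control protein id (default `"ACC1"`).
#' @param control_intensity Control protein intensity scale (default 5e6).
#' @param seed Integer seed.
#'
#' @return A list of class `lfq_sim_params`.
#' @export
lfq_sim_params <- function(n_proteins = 300L,
                           replicates = c(3L, 3L, 3L),
                           frac_tag_specific = 0.10,
                           frac_treatment_enhanced = 0.05,
                           tag_fold = 8,
                           treatment_fold = 8,
                           intensity_scale = 1e6,
                           intensity_dispersion = 1,
                           replicate_cv = 0.2,
                           dropout_prob = 0,
                           control_id = "ACC1",
                           control_intensity = 5e6,
                           seed = 1L) {
  p <- list(n_proteins = as.integer(n_proteins),
            replicates = as.integer(rep_len(replicates, 3L)),
            frac_tag_specific = as.numeric(frac_tag_specific),
            frac_treatment_enhanced = as.numeric(frac_treatment_enhanced),
            tag_fold = as.numeric(tag_fold),
            treatment_fold = as.numeric(treatment_fold),
            intensity_scale = as.numeric(intensity_scale),
            intensity_dispersion = as.numeric(intensity_dispersion),
            replicate_cv = as.numeric(replicate_cv),
            dropout_prob = as.numeric(dropout_prob),
            control_id = as.character(control_id),
            control_intensity = as.numeric(control_intensity),
            seed = as.integer(seed))
  if (p$n_proteins < 1L) stop("n_proteins must be positive")
  if (any(p$replicates < 1L)) stop("replicate counts must be positive")
  fr <- c(p$frac_tag_specific, p$frac_treatment_enhanced)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("class fractions must be in [0, 1] and sum to at most 1")
  }
  if (p$dropout_prob < 0 || p$dropout_prob > 1) {
    stop("dropout_prob must be in [0, 1]")
  }
  if (p$tag_fold <= 0 || p$treatment_fold <= 0 ||
      p$intensity_scale <= 0 || p$intensity_dispersion <= 0 ||
      p$replicate_cv < 0 || p$control_intensity <= 0) {
    stop("scales, folds and dispersions must be positive")
  }
  class(p) <- "lfq_sim_params"
  p
}
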