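#' Read a pipeline configuration file
#'
#' Configurations are flat YAML mappings (scalars plus a `samples` table for
#' the fork pipeline). Every parameter left unset falls back to the package
#' default; the fully resolved configuration is echoed into the output
#' provenance so no default is silent.
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

resolve_config <- function(config, defaults) {
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(defaults, config)
}

# Canonical YAML of the resolved config plus its md5, written alongside the
# outputs; reruns with identical config and inputs are byte-identical.
write_provenance <- function(config, outdir, stage) {
  config <- config[order(names(config))]
  txt <- yaml::as.yaml(config)
  tmp <- tempfile()
  writeLines(txt, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  path <- file.path(outdir, "provenance.yaml")
  writeLines(c(paste0("# traelkit ", stage, " run"),
               paste0("config_md5: ", hash), txt), path)
  invisible(hash)
}

load_reads_bed <- function(path) {
  bed <- read_bed6(path)
  if (nrow(bed) > 0 && all(bed$end - bed$start == 1L)) {
    read_read_ends_bed(path)   # pre-extracted ends; score = multiplicity
  } else {
    extract_read_ends(bed)
  }
}

trael_defaults <- function() {
  c(list(samples = NULL, origins = NULL, mask = NULL, chrom_sizes = NULL,
         outdir = ".", reference_condition = NULL, dedup = FALSE,
         window = 1000L, step = 100L, strand_mode = "total",
         stat_method = "tukey"),
    unclass(fork_params()))
}

#' Run the fork-progression pipeline end to end
#'
#' Stages, in fixed order: load reads, extract break ends, mask filtering
#' (and optional positional de-duplication), running-window signal, active
#' origin calling on the pooled reference condition, probe construction,
#' Loess smoothing, peak detection, fork distances, replicate summaries and
#' (when at least two conditions have two or more replicates) the group
#' comparison. All outputs plus a provenance file carrying the resolved
#' configuration and its hash are written under `outdir`; identical config
#' and inputs reproduce identical bytes.
#'
#' @param config Named list (e.g. from [read_run_config()]) with keys:
#'   `samples` — data frame or list of records with `condition`, `replicate`,
#'   `reads` (BED6 path; single-nucleotide intervals are taken as
#'   pre-extracted ends with the score as multiplicity); `origins` — origin
#'   catalogue BED; `chrom_sizes` — two-column TSV; optional `mask` (BED),
#'   `outdir`, `reference_condition` (default: first condition),
#'   `dedup`, `window`, `step`, `strand_mode`, `stat_method`, and any
#'   [fork_params()] field.
#' @return Invisibly, a list with `probes` (table), `summaries`,
#'   `comparison` (or `NULL`), `active_origins` and `files` written.
#' @export
run_trael_pipeline <- function(config) {
  cfg <- resolve_config(config, trael_defaults())
  for (key in c("samples", "origins", "chrom_sizes")) {
    if (is.null(cfg[[key]])) stop("config key '", key, "' is required")
  }
  samples <- as.data.frame(do.call(rbind, lapply(
    if (is.data.frame(cfg$samples)) split(cfg$samples, seq_len(nrow(cfg$samples)))
    else cfg$samples,
    function(s) data.frame(condition = as.character(s$condition),
                           replicate = as.character(s$replicate),
                           reads = as.character(s$reads),
                           stringsAsFactors = FALSE))))
  for (f in c(samples$reads, cfg$origins, cfg$chrom_sizes,
              if (!is.null(cfg$mask)) cfg$mask)) {
    if (!file.exists(f)) stop("input file not found: ", f)
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  params <- do.call(fork_params, unclass(cfg)[names(unclass(fork_params()))])
  layout <- read_chrom_sizes(cfg$chrom_sizes)
  catalogue <- read_origin_catalogue(cfg$origins)
  mask <- if (!is.null(cfg$mask)) read_bed3(cfg$mask) else NULL
  if (is.null(cfg$reference_condition)) {
    cfg$reference_condition <- samples$condition[1]
  }

  ends_list <- lapply(samples$reads, function(p) {
    filter_and_deduplicate(load_reads_bed(p), mask, dedup = isTRUE(cfg$dedup))
  })

  ref_rows <- which(samples$condition == cfg$reference_condition)
  if (length(ref_rows) == 0) {
    stop("reference condition '", cfg$reference_condition,
         "' has no samples")
  }
  ref_ends <- do.call(rbind, ends_list[ref_rows])
  ref_ends <- read_ends(ref_ends$chrom, ref_ends$pos, ref_ends$strand,
                        ref_ends$count)
  active <- call_active_origins(ref_ends, catalogue, params)

  files <- character(0)
  probe_rows <- list()
  summaries <- list()
  for (i in seq_len(nrow(samples))) {
    tag <- paste0(samples$condition[i], "_", samples$replicate[i])
    ws <- windowed_signal(ends_list[[i]], layout,
                          window = cfg$window, step = cfg$step)
    bg <- file.path(cfg$outdir, paste0("signal_", tag, ".bedgraph"))
    write_bedgraph(ws, bg)
    files <- c(files, bg)

    probes <- build_probes(ends_list[[i]], active, params, layout,
                           strand_mode = cfg$strand_mode)
    probes <- process_probes(probes, params)
    tab <- probe_table(probes)
    tab <- cbind(condition = samples$condition[i],
                 replicate = samples$replicate[i], tab,
                 stringsAsFactors = FALSE)
    probe_rows[[i]] <- tab
    fired <- suppressWarnings(
      count_fired_origins(ends_list[[i]], layout, params,
                          window = cfg$window, step = cfg$step))
    summaries[[i]] <- condition_summary(samples$condition[i],
                                        samples$replicate[i],
                                        tab$fork_distance,
                                        fired_origins = fired)
    if (samples$condition[i] == cfg$reference_condition &&
        i == ref_rows[1]) {
      m <- aligned_probe_matrix(probes)
      mf <- file.path(cfg$outdir, "aligned_probes_reference.tsv")
      utils::write.table(
        data.frame(probe = rownames(m), m, check.names = FALSE),
        mf, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, mf)
    }
  }
  probe_tab <- do.call(rbind, probe_rows)
  summary_tab <- do.call(rbind, summaries)

  pf <- file.path(cfg$outdir, "probes.tsv")
  sf <- file.path(cfg$outdir, "condition_summaries.tsv")
  af <- file.path(cfg$outdir, "active_origins.tsv")
  write_tsv(probe_tab, pf)
  write_tsv(summary_tab, sf)
  write_tsv(active, af)
  files <- c(files, pf, sf, af)

  comparison <- NULL
  usable <- table(summary_tab$condition[!is.na(summary_tab$median_distance)])
  if (sum(usable >= 2) >= 2) {
    comparison <- compare_conditions(summary_tab, method = cfg$stat_method)
    stf <- file.path(cfg$outdir, "statistics.tsv")
    write_tsv(cbind(comparison$pairwise,
                    F = comparison$anova$F, anova_p = comparison$anova$p,
                    method = comparison$method), stf)
    files <- c(files, stf)
  }
  write_provenance(cfg, cfg$outdir, "trael")
  invisible(list(probes = probe_tab, summaries = summary_tab,
                 comparison = comparison, active_origins = active,
                 files = files))
}

lfq_defaults <- function() {
  list(table = NULL, outdir = ".", control_id = "ACC1", log_base = 2,
       x_threshold = 1, y_threshold = 1)
}

#' Run the LFQ enrichment pipeline
#'
#' Reads a long-format intensity table, imputes zeros, normalizes to the
#' control protein, computes the dual-axis enrichment and hit flags, and
#' writes the per-protein results plus scatter-plot coordinates and
#' provenance.
#'
#' @param config Named list with keys `table` (TSV path with columns
#'   `protein`, `sample`, `replicate`, `intensity`), and optional `outdir`,
#'   `control_id`, `log_base`, `x_threshold`, `y_threshold`.
#' @return Invisibly, a list with `results` and `files`.
#' @export
run_lfq_pipeline <- function(config) {
  cfg <- resolve_config(config, lfq_defaults())
  if (is.null(cfg$table)) stop("config key 'table' is required")
  if (!file.exists(cfg$table)) stop("input file not found: ", cfg$table)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  tab <- read_tsv(cfg$table)
  res <- lfq_enrichment(tab, control_id = cfg$control_id,
                        log_base = cfg$log_base,
                        x_threshold = cfg$x_threshold,
                        y_threshold = cfg$y_threshold)
  ef <- file.path(cfg$outdir, "enrichment.tsv")
  scf <- file.path(cfg$outdir, "enrichment_scatter.tsv")
  write_tsv(res, ef)
  write_tsv(res[, c("protein", "x_enrichment", "y_enrichment", "hit")], scf)
  write_provenance(cfg, cfg$outdir, "lfq")
  invisible(list(results = res, files = c(ef, scf)))
}

fluor_defaults <- function() {
  list(table = NULL, outdir = ".", test = "welch")
}

#' Run the fluorescence quantification pipeline
#'
#' Reads per-cell measurements, computes corrected total nuclear
#' fluorescence and nuclear/cytoplasmic ratios, compares the two groups and
#' writes the annotated table, violin-plot data (group, value) and the test
#' result with provenance.
#'
#' @param config Named list with keys `table` (TSV of per-cell records with
#'   a `group` column) and optional `outdir`, `test` (`"welch"` or
#'   `"student"`).
#' @return Invisibly, a list with `metrics`, `comparison` and `files`.
#' @export
run_fluor_pipeline <- function(config) {
  cfg <- resolve_config(config, fluor_defaults())
  if (is.null(cfg$table)) stop("config key 'table' is required")
  if (!file.exists(cfg$table)) stop("input file not found: ", cfg$table)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  records <- read_tsv(cfg$table)
  metrics <- cell_fluor_metrics(records)
  cmp <- nc_ratio_and_compare(records, test = cfg$test)
  mf <- file.path(cfg$outdir, "cell_metrics.tsv")
  vf <- file.path(cfg$outdir, "nc_ratio_violin.tsv")
  tf <- file.path(cfg$outdir, "nc_ratio_test.tsv")
  write_tsv(metrics, mf)
  write_tsv(data.frame(group = cmp$records$group, value = cmp$records$nc_ratio),
            vf)
  write_tsv(data.frame(group1 = names(cmp$group_n)[1],
                       group2 = names(cmp$group_n)[2],
                       median1 = cmp$group_medians[1],
                       median2 = cmp$group_medians[2],
                       statistic = cmp$statistic, p_value = cmp$p_value,
                       test = cmp$test), tf)
  write_provenance(cfg, cfg$outdir, "fluor")
  invisible(list(metrics = metrics, comparison = cmp, files = c(mf, vf, tf)))
}
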