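test_that("fork simulation is deterministic and accounts for every read", {
  layout <- default_trael_layout()
  params <- fork_sim_params(default_trael_origins(), firing_prob = 0.8,
                            duplicate_rate = 0.05, seed = 11)
  a <- simulate_trael_experiment(layout, params)
  b <- simulate_trael_experiment(layout, params)
  expect_identical(a, b)
  cnt <- a$truth$counts
  expect_identical(sum(a$ends$count),
                   cnt$fork_reads + cnt$background_reads + cnt$duplicate_reads)
  expect_identical(cnt$total_reads,
                   cnt$fork_reads + cnt$background_reads + cnt$duplicate_reads)
  expect_identical(cnt$fork_reads,
                   2L * params$reads_per_fork * nrow(a$truth$origins))
})

test_that("nothing fires and no background gives empty output", {
  layout <- default_trael_layout()
  params <- fork_sim_params(default_trael_origins(), firing_prob = 0,
                            background_rate = 0, duplicate_rate = 0, seed = 1)
  sim <- simulate_trael_experiment(layout, params)
  expect_identical(nrow(sim$ends), 0L)
  expect_identical(nrow(sim$truth$origins), 0L)
})

test_that("noise-free forks land exactly at origin +/- the planted distance", {
  s <- spaced_origins(1)
  params <- fork_sim_params(s$origins, firing_prob = 1,
                            distance_mean = 12000, distance_sd = 0,
                            noise_sd = 0, background_rate = 0,
                            duplicate_rate = 0, seed = 5)
  sim <- simulate_trael_experiment(s$layout, params)
  ori <- s$origins$pos[1]
  expect_setequal(unique(sim$ends$pos), c(ori - 12000, ori + 12000))
  expect_identical(sim$truth$origins$fork_left, ori - 12000)
  expect_identical(sim$truth$origins$fork_right, ori + 12000)
})

test_that("strand labels follow the leading-strand convention", {
  s <- spaced_origins(1)
  params <- fork_sim_params(s$origins, firing_prob = 1, distance_mean = 12000,
                            distance_sd = 0, noise_sd = 0,
                            leading_fraction = 1, background_rate = 0,
                            duplicate_rate = 0, seed = 5)
  sim <- simulate_trael_experiment(s$layout, params)
  ori <- s$origins$pos[1]
  right <- sim$ends[sim$ends$pos > ori, ]
  left <- sim$ends[sim$ends$pos < ori, ]
  expect_true(all(right$strand == "+"))
  expect_true(all(left$strand == "-"))
})

test_that("close origin pairs are flagged in the truth metadata", {
  layout <- genome_layout("chrI", 200000L)
  origins <- data.frame(origin_id = c("a", "b"), chrom = "chrI",
                        pos = c(80000L, 110000L))
  sim <- simulate_trael_experiment(layout, fork_sim_params(origins, seed = 1),
                                   probe_half_width = 20000L)
  expect_length(sim$truth$warnings, 1L)
  sim2 <- simulate_trael_experiment(layout, fork_sim_params(origins, seed = 1),
                                    probe_half_width = 10000L)
  expect_length(sim2$truth$warnings, 0L)
})

test_that("leftward and rightward planted fork distances are exchangeable", {
  s <- spaced_origins(5, spacing = 70000L)
  left <- right <- numeric(0)
  for (seed in 1:20) {
    sim <- simulate_trael_experiment(
      s$layout, fork_sim_params(s$origins, seed = seed, reads_per_fork = 10L))
    left <- c(left, sim$truth$origins$dist_left)
    right <- c(right, sim$truth$origins$dist_right)
  }
  # both sides draw from the same truncated normal; difference of means is
  # well inside Monte-Carlo error
  se <- sqrt(var(left) / length(left) + var(right) / length(right))
  expect_lt(abs(mean(left) - mean(right)), 4 * se)
})

test_that("LFQ simulation is deterministic with labelled classes", {
  params <- lfq_sim_params(n_proteins = 60, seed = 9, dropout_prob = 0.1)
  a <- simulate_lfq_table(params)
  b <- simulate_lfq_table(params)
  expect_identical(a, b)
  expect_setequal(unique(a$truth$class),
                  c("control", "tag_specific", "treatment_enhanced",
                    "background"))
  # control never drops out
  ctrl <- a$table[a$table$protein == params$control_id, ]
  expect_true(all(ctrl$intensity > 0))
  expect_identical(nrow(ctrl), sum(params$replicates))
})

test_that("zero dropout probability yields no zero intensities", {
  sim <- simulate_lfq_table(lfq_sim_params(n_proteins = 80, seed = 2,
                                           dropout_prob = 0))
  expect_true(all(sim$table$intensity > 0))
})

test_that("treatment-enhanced proteins out-enrich background on the x axis", {
  # Monte-Carlo: the class mean of x = log2(avg3/avg2) dominates background
  # in every one of 100 seeds at an 8-fold planted effect
  worse <- 0L
  for (seed in 1:100) {
    sim <- simulate_lfq_table(lfq_sim_params(
      n_proteins = 40, frac_tag_specific = 0,
      frac_treatment_enhanced = 0.2, treatment_fold = 8, seed = seed))
    res <- lfq_enrichment(sim$table)
    m <- merge(res, sim$truth, by = "protein")
    mx <- tapply(m$x_enrichment, m$class, mean)
    if (mx[["treatment_enhanced"]] <= mx[["background"]]) worse <- worse + 1L
  }
  expect_identical(worse, 0L)
})

test_that("cell fluorescence simulation is deterministic and null-calibrated", {
  a <- simulate_cell_fluorescence(c(40, 40), effect_size = 2, seed = 4)
  b <- simulate_cell_fluorescence(c(40, 40), effect_size = 2, seed = 4)
  expect_identical(a, b)
  expect_identical(nrow(a), 80L)
  # effect 0: two-sided test rejects at ~nominal rate over 200 seeds
  rej <- 0L
  for (seed in 1:200) {
    cells <- simulate_cell_fluorescence(c(25, 25), effect_size = 0,
                                        seed = seed)
    p <- suppressWarnings(nc_ratio_and_compare(cells))$p_value
    if (p < 0.05) rej <- rej + 1L
  }
  band <- qbinom(c(0.005, 0.995), 200, 0.05)
  expect_gte(rej, band[1])
  expect_lte(rej, band[2])
})

test_that("a large ratio effect is detected essentially always", {
  hits <- 0L
  for (seed in 1:100) {
    cells <- simulate_cell_fluorescence(c(150, 150), effect_size = 5,
                                        seed = seed)
    if (nc_ratio_and_compare(cells)$p_value < 1e-4) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("simulation writers produce readable round-trip files", {
  out <- withr::local_tempdir()
  layout <- default_trael_layout()
  sim <- simulate_trael_experiment(layout,
                                   fork_sim_params(default_trael_origins(),
                                                   seed = 3))
  paths <- write_trael_simulation(sim, layout, file.path(out, "sim"))
  back <- read_read_ends_bed(paths[["ends"]])
  expect_identical(back, sim$ends)
  expect_identical(read_chrom_sizes(paths[["chrom_sizes"]]), layout)
  truth <- read.table(paths[["truth"]], sep = "\t", header = TRUE)
  expect_identical(nrow(truth), nrow(sim$truth$origins))
})
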