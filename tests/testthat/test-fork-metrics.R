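test_that("activity filter retains the top 60% by score", {
  # brute-force ranking oracle: 5 origins scoring 10..50, fraction 0.40
  s <- spaced_origins(5, spacing = 20000L, offset = 10000L)
  ends <- read_ends(rep("chrI", 5), s$origins$pos,
                    rep("+", 5), c(10L, 20L, 30L, 40L, 50L))
  active <- call_active_origins(ends, s$origins)
  expect_identical(nrow(active), 3L)
  expect_setequal(active$activity_score, c(30, 40, 50))
  # fraction 0 retains everything
  all_kept <- call_active_origins(ends, s$origins,
                                  fork_params(activity_filter_fraction = 0))
  expect_identical(nrow(all_kept), 5L)
})

test_that("filter fraction retains ceil(0.6 n) for distinct scores, any n", {
  for (n in c(3L, 7L, 10L, 41L)) {
    s <- spaced_origins(n, spacing = 20000L, offset = 10000L)
    ends <- read_ends(rep("chrI", n), s$origins$pos, rep("+", n),
                      sample(seq_len(n)))
    active <- call_active_origins(ends, s$origins)
    expect_identical(nrow(active), as.integer(ceiling(0.6 * n)))
  }
})

test_that("equal scores fall back to coordinate order with a warning", {
  s <- spaced_origins(5, spacing = 20000L, offset = 10000L)
  ends <- read_ends(rep("chrI", 5), s$origins$pos, rep("+", 5), 10L)
  expect_warning(active <- call_active_origins(ends, s$origins), "equal")
  expect_identical(active$origin_id, s$origins$origin_id[1:3])
  expect_error(call_active_origins(read_ends(), s$origins[0, ]), "empty")
})

test_that("probes orient both sides as distance from the origin", {
  layout <- genome_layout("chrI", 200000L)
  active <- data.frame(origin_id = "a", chrom = "chrI", pos = 100000L)
  ends <- read_ends("chrI", 88000L, "-", 40L)
  probes <- build_probes(ends, active, layout = layout)
  up <- probes[[1]]; down <- probes[[2]]
  expect_identical(up$side, "upstream")
  # coordinate-reflection oracle: 100000 - 88000 = 12000 -> bin centre 12050
  expect_identical(up$distance[which(up$raw > 0)], 12050)
  expect_identical(sum(up$raw), 40)
  expect_true(all(down$raw == 0))
})

test_that("symmetric reads give mirror-identical probes; empty reads give
          undefined distances", {
  layout <- genome_layout("chrI", 200000L)
  active <- data.frame(origin_id = "a", chrom = "chrI", pos = 100000L)
  ends <- read_ends(rep("chrI", 2), c(95000L, 105000L), c("-", "+"),
                    c(13L, 13L))
  probes <- build_probes(ends, active, layout = layout)
  expect_identical(probes[[1]]$raw, probes[[2]]$raw)

  none <- process_probes(build_probes(read_ends(), active, layout = layout))
  expect_true(all(vapply(none, function(p) all(p$smoothed == 0), TRUE)))
  expect_true(all(is.na(vapply(none, `[[`, 1, "fork_distance"))))
})

test_that("probes near chromosome ends are truncated and excluded", {
  layout <- genome_layout("chrI", 50000L)
  active <- data.frame(origin_id = "edge", chrom = "chrI", pos = 10000L)
  ends <- read_ends("chrI", 5000L, "-", 30L)
  probes <- process_probes(build_probes(ends, active, layout = layout))
  expect_true(probes[[1]]$truncated)                 # upstream hits pos 0
  expect_true(is.na(probes[[1]]$fork_distance))
  expect_false(probes[[2]]$truncated)
})

test_that("leading-strand mode restricts each side to its fork's strand", {
  layout <- genome_layout("chrI", 200000L)
  active <- data.frame(origin_id = "a", chrom = "chrI", pos = 100000L)
  ends <- read_ends(rep("chrI", 4), c(90000L, 90000L, 110000L, 110000L),
                    c("-", "+", "+", "-"), c(10L, 3L, 20L, 5L))
  probes <- build_probes(ends, active, layout = layout,
                         strand_mode = "leading")
  expect_identical(sum(probes[[1]]$raw), 10)   # upstream keeps minus only
  expect_identical(sum(probes[[2]]$raw), 20)   # downstream keeps plus only
})

test_that("order-2 smoothing reproduces constants and quadratics", {
  p <- fork_params()
  const <- smooth_probe(make_probe(rep(4.2, 200)), p)
  expect_equal(const$smoothed, rep(4.2, 200), tolerance = 1e-12)
  d <- (1:200 - 0.5) * 100
  quad <- 5 + 0.02 * d - 1e-6 * d^2
  sq <- smooth_probe(make_probe(quad), p)
  expect_lt(max(abs(sq$smoothed - quad)), 1e-8)
  expect_error(smooth_probe(make_probe(rep(1, 10)), p), "bins")
})

test_that("smoothing moves a symmetric peak's argmax by at most one bin", {
  p <- fork_params()
  for (k in c(40L, 100L, 157L)) {
    tri <- pmax(0, 25 - abs(seq_len(200) - k))
    sm <- smooth_probe(make_probe(tri), p)$smoothed
    expect_lte(abs(which.max(sm) - k), 1L)
  }
})

test_that("peak detection matches the brute-force oracle on short vectors", {
  set.seed(99)
  for (i in 1:40) {
    x <- pmax(0, cumsum(rnorm(sample(10:50, 1))))
    for (frac in c(0, 0.3, 0.6)) {
      thr <- frac * max(max(x), 1e-9)
      got <- find_peaks(x, min_prominence = thr, min_distance = 0)
      want <- brute_peaks(x, min_prominence = thr)
      expect_identical(got$index, want$index)
      expect_equal(got$prominence, want$prominence)
    }
  }
})

test_that("probe peak logic keeps single bumps and rejects doublets", {
  p <- fork_params()
  d <- (1:200 - 0.5) * 100
  zero <- detect_peaks(smooth_probe(make_probe(rep(0, 200)), p), p)
  expect_identical(nrow(zero$peaks), 0L)
  expect_true(zero$retained)

  one <- detect_peaks(smooth_probe(
    make_probe(100 * exp(-(d - 12000)^2 / (2 * 1500^2))), p), p)
  expect_identical(nrow(one$peaks), 1L)
  expect_true(one$retained)
  expect_lt(abs(one$peaks$distance - 12000), 300)

  # two equal bumps 10 kb apart: probe removed
  two <- detect_peaks(smooth_probe(
    make_probe(100 * exp(-(d - 5000)^2 / (2 * 1200^2)) +
               100 * exp(-(d - 15000)^2 / (2 * 1200^2))), p), p)
  expect_identical(nrow(two$peaks), 2L)
  expect_false(two$retained)
  expect_true(is.na(fork_distance(two)))
})

test_that("fork distance is the argmax of the smoothed profile", {
  p <- fork_params()
  # all mass at the origin bin
  at0 <- rep(0, 200); at0[1] <- 50
  pr <- detect_peaks(smooth_probe(make_probe(at0), p), p)
  expect_identical(fork_distance(pr), 50)   # first bin midpoint

  # argmax oracle on the unsmoothed signal: planted fork at +12,000, noise 0
  layout <- genome_layout("chrI", 300000L)
  s <- spaced_origins(1, offset = 150000L)
  sim <- simulate_trael_experiment(s$layout, fork_sim_params(
    s$origins, firing_prob = 1, distance_mean = 12000, distance_sd = 0,
    noise_sd = 0, background_rate = 0, duplicate_rate = 0, seed = 2))
  probes <- process_probes(build_probes(sim$ends, s$origins,
                                        layout = s$layout))
  for (pr in probes) {
    raw_argmax <- pr$distance[which.max(pr$raw)]
    expect_lte(abs(pr$fork_distance - raw_argmax), pr$bin)
    expect_lte(abs(pr$fork_distance - 12000), pr$bin)
  }
})

test_that("median fork distance recovers the planted truth", {
  # planted mean 12 kb, spread 1 kb, read noise 300 bp; >= 50 retained probes
  mc <- multi_chrom_origins(3L, 10L)
  for (seed in 1:10) {
    sim <- simulate_trael_experiment(mc$layout, fork_sim_params(
      mc$origins, firing_prob = 1, distance_mean = 12000, distance_sd = 1000,
      noise_sd = 300, reads_per_fork = 100L, seed = seed))
    probes <- process_probes(build_probes(sim$ends, mc$origins,
                                          layout = mc$layout))
    dist <- probe_table(probes)$fork_distance
    expect_gte(sum(!is.na(dist)), 50L)
    truth <- c(sim$truth$origins$dist_left, sim$truth$origins$dist_right)
    expect_lt(abs(median(dist, na.rm = TRUE) - median(truth)), 500)
  }
})

test_that("fired-origin counting halves the genome-wide peak count", {
  layout <- genome_layout("chrI", 400000L)
  expect_warning(none <- count_fired_origins(read_ends(), layout),
                 "no reads")
  expect_identical(as.integer(none), 0L)

  # constructed instance: 3 fired origins 60 kb apart -> 6 peaks -> 3
  s <- spaced_origins(3)
  sim <- simulate_trael_experiment(s$layout, fork_sim_params(
    s$origins, firing_prob = 1, distance_mean = 10000, distance_sd = 500,
    noise_sd = 300, background_rate = 0, duplicate_rate = 0, seed = 4))
  fo <- count_fired_origins(sim$ends, s$layout)
  expect_identical(attr(fo, "peak_count"), 6L)
  expect_identical(as.integer(fo), 3L)
})

test_that("fired-origin counts match simulator truth across seeds", {
  s <- spaced_origins(5, spacing = 70000L)
  for (seed in 1:20) {
    sim <- simulate_trael_experiment(s$layout, fork_sim_params(
      s$origins, firing_prob = 0.7, distance_mean = 10000,
      distance_sd = 500, noise_sd = 300, seed = seed))
    fired_truth <- nrow(sim$truth$origins)
    fo <- suppressWarnings(count_fired_origins(sim$ends, s$layout))
    expect_identical(as.integer(fo), fired_truth)
  }
})

test_that("aligned probe matrix is ordered by fork distance", {
  mc <- spaced_origins(4, spacing = 80000L)
  sim <- simulate_trael_experiment(mc$layout, fork_sim_params(
    mc$origins, firing_prob = 1, seed = 6))
  probes <- process_probes(build_probes(sim$ends, mc$origins,
                                        layout = mc$layout))
  m <- aligned_probe_matrix(probes)
  keep <- Filter(function(p) isTRUE(p$retained) && !p$truncated, probes)
  expect_identical(nrow(m), length(keep))
  d <- vapply(keep, `[[`, 1, "fork_distance")
  expect_identical(rownames(m),
                   vapply(keep, function(p) paste0(p$origin_id, "/", p$side),
                          "")[order(-ifelse(is.na(d), -Inf, d))])
})
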