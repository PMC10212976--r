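test_that("dwell profiles assemble baseline, pauses and 5' block correctly", {
  m <- build_dwell_profile(10, 0.025)
  expect_equal(m$dwell, rep(0.025, 10))
  expect_equal(m$velocity_mean, 40)

  m2 <- build_dwell_profile(2, 1, pause_positions = 1, pause_multipliers = 3)
  expect_equal(m2$dwell, c(1, 3))

  # arithmetic oracle: total dwell = L*b + n_pauses*(mult-1)*b
  m3 <- build_dwell_profile(7800, 0.025,
                            pause_positions = as.integer(seq(100, 7700,
                                                             length.out = 20)),
                            pause_multipliers = rep(10, 20))
  expect_equal(sum(m3$dwell), 7800 * 0.025 + 20 * 9 * 0.025)  # 199.5 s

  m4 <- build_dwell_profile(100, 0.02, pause_positions = 10,
                            pause_multipliers = 5,
                            ets5_enrichment = list(factor = 3, extent = 20))
  expect_equal(m4$dwell[11], 0.02 * 3 * 5)  # multiplier acts on local baseline
  expect_equal(m4$dwell[20], 0.06)          # last position of the 5' block
  expect_equal(m4$dwell[21], 0.02)

  expect_error(build_dwell_profile(100, 0.02, pause_positions = c(5, 5),
                                   pause_multipliers = c(2, 2)), "duplicate")
  expect_error(build_dwell_profile(100, 0.02, pause_positions = 100,
                                   pause_multipliers = 2), "out of")
  expect_error(build_dwell_profile(100, 0.02, pause_positions = 5,
                                   pause_multipliers = 0.5), ">= 1")
})

test_that("expected fractions are dwell-proportional and normalized", {
  expect_equal(expected_fractions(elongation_model(c(1, 3)))$values,
               c(0.25, 0.75))
  expect_equal(expected_fractions(elongation_model(c(2, 2, 4)))$values,
               c(0.25, 0.25, 0.5))
  L <- 57
  expect_equal(expected_fractions(build_dwell_profile(L, 0.01))$values,
               rep(1 / L, L))
  set.seed(4)
  f <- expected_fractions(elongation_model(rexp(200) + 0.01))$values
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_true(all(f >= 0))
})

test_that("raising one dwell raises its fraction and lowers all others", {
  set.seed(8)
  for (i in 1:5) {
    dwell <- rexp(30) + 0.05
    j <- sample(30, 1)
    f0 <- expected_fractions(elongation_model(dwell))$values
    dwell2 <- dwell
    dwell2[j] <- dwell2[j] * 2
    f1 <- expected_fractions(elongation_model(dwell2))$values
    expect_gt(f1[j], f0[j])
    expect_true(all(f1[-j] < f0[-j]))
  }
})

test_that("read simulation is deterministic under a fixed seed", {
  m <- build_dwell_profile(500, 0.025, pause_positions = 250,
                           pause_multipliers = 10)
  unit <- make_unit(length = 500)
  a <- simulate_reads(m, unit, 1000, seed = 99)
  b <- simulate_reads(m, unit, 1000, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_length(a, 1000L)
  c <- simulate_reads(m, unit, 1000, seed = 100)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("empirical 3'-end fractions converge to the analytic oracle", {
  # two-position model, n = 1e6: multinomial SE ~ 4.3e-4, bound ~4.6 sigma
  m <- elongation_model(c(1, 3))
  unit <- make_unit(length = 2)
  gr <- simulate_reads(m, unit, 1e6, seed = 21,
                       read_length = read_length_spec("fixed", length = 1))
  p <- to_unit_coordinates(gr, unit)
  emp <- tabulate(p + 1L, nbins = 2) / 1e6
  expect_lt(max(abs(emp - c(0.25, 0.75))), 0.002)
})

test_that("reads stay inside the unit and carry its strand", {
  m <- build_dwell_profile(300, 0.025, pause_positions = 10,
                           pause_multipliers = 20)
  for (strand in c("+", "-")) {
    unit <- transcription_unit("rDNA", 500, 800, strand)
    gr <- simulate_reads(m, unit, 2000, seed = 17)
    expect_true(all(GenomicRanges::start(gr) >= 501))
    expect_true(all(GenomicRanges::end(gr) <= 800))
    expect_true(all(as.character(GenomicRanges::strand(gr)) == strand))
    expect_false(anyNA(to_unit_coordinates(gr, unit)))
  }
})

test_that("condition pairs attenuate pause multipliers as 1 + a(m-1)", {
  m <- build_dwell_profile(200, 0.025, pause_positions = c(50, 150),
                           pause_multipliers = c(10, 4))
  dep <- attenuate_pauses(m, 0.5)
  expect_equal(dep$pause_multipliers, c(5.5, 2.5))
  expect_equal(dep$dwell[51], 0.025 * 5.5)
  ident <- attenuate_pauses(m, 1)
  expect_equal(ident$dwell, m$dwell)

  ds <- simulate_condition_pair(m, pause_attenuation = 0.5, n_replicates = 2,
                                n_reads = 500, seed = 5)
  expect_length(ds$reads_by_sample, 4L)
  expect_true(all(vapply(ds$reads_by_sample, length, integer(1)) == 500L))
  # replicates use distinct deterministic seeds
  expect_equal(anyDuplicated(ds$info$seed), 0L)
  ds2 <- simulate_condition_pair(m, pause_attenuation = 0.5,
                                 n_replicates = 2, n_reads = 500, seed = 5)
  expect_identical(
    as.data.frame(ds$reads_by_sample$wildtype_rep1),
    as.data.frame(ds2$reads_by_sample$wildtype_rep1))
  expect_error(simulate_condition_pair(m, pause_attenuation = 0), "0, 1")
})

test_that("expected log2 depletion at a pause follows from the two models", {
  m <- elongation_model(c(1, 9), pause_positions = 1, pause_multipliers = 9)
  dep <- attenuate_pauses(m, 0.5)
  expect_equal(dep$dwell, c(1, 5))
  f_wt <- expected_fractions(m)$values
  f_dep <- expected_fractions(dep)$values
  expect_equal(log2(f_dep[2] / f_wt[2]), log2((5 / 6) / (9 / 10)))
})

test_that("simulated qPCR CTs encode the programmed enrichment", {
  m0 <- simulate_qpcr(1, dilution_ip = 20, dilution_input = 20, noise_sd = 0)
  expect_equal(m0$ct_ip, m0$ct_input)
  m4 <- simulate_qpcr(4, dilution_ip = 50, dilution_input = 50, noise_sd = 0)
  expect_equal(mean(m4$ct_input) - mean(m4$ct_ip), 2)
  # noise-free round trip with dilution correction is exact
  m <- simulate_qpcr(7.3, dilution_ip = 20, dilution_input = 100,
                     noise_sd = 0)
  expect_equal(as.numeric(chip_enrichment(m, apply_dilution_correction = TRUE)),
               7.3, tolerance = 1e-12)
  # noisy recovery stays within the error-propagation bound
  mn <- simulate_qpcr(4, noise_sd = 0.1, n_technical = 3, seed = 12)
  rec <- as.numeric(chip_enrichment(mn, apply_dilution_correction = TRUE))
  expect_lt(abs(log2(rec) - 2), 3 * 0.1)
  expect_error(simulate_qpcr(0), "> 0")
})

test_that("simulated datasets round-trip through BED/bedGraph/JSON files", {
  ds <- small_world(n_reads = 300, seed = 2)
  dir <- tempfile("simout")
  write_simulated_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "wildtype_rep1.bed")))
  gr <- read_alignments(file.path(dir, "wildtype_rep1.bed"))
  expect_length(gr, 300L)
  expect_equal(GenomicRanges::start(gr),
               GenomicRanges::start(ds$reads_by_sample$wildtype_rep1))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$truth$wildtype$pause_positions, c(100, 300, 480))
  dwell <- read_track(file.path(dir, "truth_wildtype_dwell.bedgraph"),
                      ds$unit, kind = "occupancy_time_seconds")
  expect_equal(dwell$values, ds$truth$wildtype$dwell)
})
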