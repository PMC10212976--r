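test_that("occupancy time is fraction x t_total and conserves total time", {
  params <- occupancy_parameters(7800, 40)
  expect_equal(params$t_total, 195)
  uni <- position_profile(rep(1 / 7800, 7800), "fraction")
  ot <- occupancy_time(uni, params)
  expect_equal(ot$values, rep(0.025, 7800))
  expect_equal(sum(ot$values), 195, tolerance = 1e-9)
  # f = 0.001 -> 0.195 s, same order as a >150 ms pause dwell
  f <- c(0.001, rep(0.999 / 7799, 7799))
  expect_equal(occupancy_time(position_profile(f, "fraction"),
                              params)$values[1], 0.195)
  # total time conserved for arbitrary valid fractions
  set.seed(3)
  x <- rexp(7800)
  pf <- position_profile(x / sum(x), "fraction")
  expect_equal(sum(occupancy_time(pf, params)$values), 195,
               tolerance = 1e-9)
  expect_error(occupancy_time(position_profile(x, "count"), params),
               "fraction")
})

test_that("log2 ratio matches hand computation and is antisymmetric", {
  a <- position_profile(c(0.25, 0.75), "fraction")
  b <- position_profile(c(0.5, 0.5), "fraction")
  expect_equal(log2_ratio(a, b, window = 1)$values,
               c(-1, 0.584963), tolerance = 1e-6)
  expect_equal(log2_ratio(a, a, window = 1)$values, c(0, 0))
  set.seed(6)
  x <- rexp(300) + 0.01
  p <- position_profile(x / sum(x), "fraction")
  q0 <- rexp(300) + 0.01
  q <- position_profile(q0 / sum(q0), "fraction")
  expect_equal(log2_ratio(p, q, window = 51)$values,
               -log2_ratio(q, p, window = 51)$values, tolerance = 1e-12)
  zero <- position_profile(c(0, 1), "fraction")
  expect_error(log2_ratio(zero, b, window = 1), "pseudocount")
})

test_that("pause detection finds prominent maxima deterministically", {
  expect_equal(nrow(detect_pauses(rep(1, 100))), 0L)
  # single smoothed impulse -> one pause at the impulse position
  imp <- numeric(201); imp[101] <- 1
  sm <- smooth_blackman(imp, 31)
  pk <- detect_pauses(sm, min_prominence = 0.01, min_distance = 10)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$position, 100L)
  expect_gt(pk$width, 1L)
  # plateau: leftmost position wins
  plat <- c(rep(0, 10), rep(5, 4), rep(0, 10))
  pk2 <- detect_pauses(plat, min_prominence = 1, min_distance = 5)
  expect_equal(pk2$position, 10L)
  # min_distance keeps the higher of two nearby peaks
  two <- numeric(100)
  two[30] <- 5; two[35] <- 7
  pk3 <- detect_pauses(two, min_prominence = 1, min_distance = 20)
  expect_equal(pk3$position, 34L)
  pk4 <- detect_pauses(two, min_prominence = 1, min_distance = 3)
  expect_equal(pk4$position, c(29L, 34L))
  # prominence, not height: a bump on a shoulder must clear the saddle
  shoulder <- c(seq(0, 10, length.out = 50), seq(10, 0, length.out = 50))
  shoulder[70] <- shoulder[70] + 0.2
  pk5 <- detect_pauses(shoulder, min_prominence = 1, min_distance = 5)
  expect_equal(pk5$position, 49L)
})

test_that("parameter recovery: injected pauses are called near their positions", {
  ds <- small_world(n_reads = 50000, seed = 13)
  cmp <- compare_conditions(ds, ref_condition = "wildtype",
                            test_condition = "depleted",
                            min_distance = 30)
  truth <- ds$truth$wildtype$pause_positions
  called <- cmp$pauses$ref$position
  hits <- vapply(truth, function(p) any(abs(called - p) <= 15), logical(1))
  expect_true(all(hits))
})

test_that("region summaries integrate profiles over the annotation", {
  regions <- data.frame(name = c("head", "body"), start = c(0, 20),
                        end = c(20, 100))
  unit <- make_unit(length = 120, regions = regions)
  uni <- position_profile(rep(1 / 120, 120), "fraction")
  rs <- region_summary(uni, unit)
  expect_equal(rs$sum[rs$region == "head"], 20 / 120)
  expect_equal(rs$sum[rs$region == "body"], 80 / 120)
  expect_equal(sum(rs$sum), 1)  # regions + outside total the unit
  expect_equal(rs$length[rs$region == "(outside)"], 20L)
  # additivity under region concatenation
  both <- data.frame(name = "headbody", start = 0, end = 100)
  rs2 <- region_summary(uni, make_unit(length = 120, regions = both))
  expect_equal(rs2$sum[1], rs$sum[1] + rs$sum[2])
  # the packaged frame: uniform fractions put 1300/7800 = 1/6 in the 5'ETS
  unit78 <- rdna_unit()
  rs3 <- region_summary(position_profile(rep(1 / 7800, 7800), "fraction"),
                        unit78)
  expect_equal(rs3$sum[rs3$region == "5ETS"], 1 / 6)
})

test_that("identifier lists intersect after case normalization", {
  res <- intersect_id_lists(c("p1", "p2", "p3"), c("P2", "p4"))
  expect_equal(res$intersection, "p2")
  expect_equal(res$n_common, 1L)
  expect_equal(intersect_id_lists(c("a", "b"), c("c", "d"))$n_common, 0L)
  same <- intersect_id_lists(c("x", "y", "Y"), c("y", "x"))
  expect_equal(same$n_common, same$n_a)  # A = B after normalization
  expect_error(intersect_id_lists(character(0), "a"), "nonempty")
})

test_that("compare_conditions bundles a deterministic, serializable report", {
  ds <- small_world(n_reads = 5000, seed = 31)
  cmp <- compare_conditions(ds, ref_condition = "wildtype",
                            test_condition = "depleted")
  truth <- ds$truth$wildtype$pause_positions
  # depletion shows as negative dlog2 at every injected pause
  expect_true(all(cmp$dlog2$values[truth + 1L] < 0))
  # occupancy tracks integrate to ~t_total (smoothed fractions)
  expect_equal(sum(cmp$occupancy$ref$values), 600 / 40, tolerance = 0.01)
  # report round-trips losslessly through the report directory
  dir1 <- tempfile(); dir2 <- tempfile()
  write_report(cmp, dir1); write_report(cmp, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
  dl <- read_track(file.path(dir1, "dlog2.bedgraph"), ds$unit,
                   kind = "log2_ratio")
  expect_identical(dl$values, cmp$dlog2$values)  # %.17g is bit-exact
  expect_error(compare_conditions(ds, ref_condition = "missing"),
               "condition")
})
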