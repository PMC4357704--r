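test_that("initiation events sit at IdU midpoints flanked by CldU", {
  f <- fiber_of(c("CldU", "IdU", "CldU"), c(0, 30, 60), c(30, 60, 90))
  expect_equal(find_initiation_events(f, fiber_length = 90), 45)
  # a lone CldU track clipped by the fiber end is ambiguous: no event
  f2 <- fiber_of("CldU", 0, 30, length_kb = 100)
  expect_equal(length(find_initiation_events(f2, fiber_length = 100)), 0)
  # an interior CldU-only track is a second-pulse initiation
  f3 <- fiber_of("CldU", 40, 80, length_kb = 200)
  expect_equal(find_initiation_events(f3, fiber_length = 200), 60)
  # but not when implausibly long for two forks in one pulse
  f4 <- fiber_of("CldU", 40, 160, length_kb = 400)
  expect_equal(length(find_initiation_events(f4, fiber_length = 400)), 0)
})

test_that("events on simulated fibers land at the true origin positions", {
  cfg <- sim_config(seed = 23, n_fibers = 3, fiber_length_mean = 1e5)
  g <- make_genome(cfg, chrom_length = 200e3, spacing = "fixed",
                   conditions = c(x = 1), domain_size_kb = 400,
                   firing_jitter = 0.5)
  stopifnot(nrow(g$origins) == 2)
  f <- make_fibers(g, "x", cfg, pulse_offset = min(g$origins$firing_time))
  seg <- f[f$fiber_id == f$fiber_id[1], ]
  ev <- find_initiation_events(seg, fiber_length = seg$length_kb[1])
  offset <- 200 - seg$length_kb[1]   # fiber may start past the chrom start
  expect_equal(length(ev), 2)
  expect_lt(max(abs(sort(ev) + offset - g$origins$position / 1000)),
            cfg$detection_threshold_kb + 1)
})

test_that("fork velocity uses ongoing-fork CldU tracks only", {
  f <- fiber_of(c("IdU", "CldU"), c(10, 30), c(30, 60), length_kb = 100)
  v <- fork_velocity(f, pulse2_minutes = 30)
  expect_equal(v$velocity, 1.0)
  f2 <- fiber_of(c("IdU", "CldU"), c(10, 30), c(30, 75), length_kb = 100)
  expect_equal(fork_velocity(f2)$velocity, 1.5)
  # CldU-only (newborn), terminations, and edge-clipped tracks are excluded
  lone <- fiber_of("CldU", 20, 50, length_kb = 100)
  expect_equal(nrow(fork_velocity(lone)), 0)
  term <- fiber_of(c("IdU", "CldU", "IdU"), c(0, 20, 50), c(20, 50, 70),
                   length_kb = 70)
  expect_equal(nrow(fork_velocity(term)), 0)
  clipped <- fiber_of(c("IdU", "CldU"), c(10, 30), c(30, 100), length_kb = 100)
  expect_equal(nrow(fork_velocity(clipped)), 0)
})

test_that("inter-origin distances stay within single fibers", {
  f <- fiber_set(rbind(
    data.frame(fiber_id = "a", length_kb = 200,
               label = c("CldU", "IdU", "CldU", "IdU", "CldU"),
               start_kb = c(20, 45, 55, 145, 155),
               end_kb = c(45, 55, 145, 155, 180)),
    data.frame(fiber_id = "b", length_kb = 120,
               label = c("CldU", "IdU", "CldU"),
               start_kb = c(30, 55, 65), end_kb = c(55, 65, 90))
  ))
  iod <- inter_origin_distances(f)
  expect_equal(iod$distance, 100)      # 150 - 50, fiber a only
  expect_equal(attr(iod, "n_over_300"), 0)
  expect_true(all(iod$distance > 0))
})

test_that("replication figures classify by the five-class rules", {
  # lone clipped CldU: isolated fork
  c1 <- classify_figures(fiber_of("CldU", 0, 30, length_kb = 100))
  expect_equal(unname(c1["isolated_fork"]), 1L)
  # interior CldU-IdU-CldU: one-origin bidirectional
  c2 <- classify_figures(fiber_of(c("CldU", "IdU", "CldU"),
                                  c(20, 50, 60), c(50, 60, 90),
                                  length_kb = 120))
  expect_equal(unname(c2["one_origin_bidirectional"]), 1L)
  # the same figure truncated by the fiber end: single origin only
  c3 <- classify_figures(fiber_of(c("CldU", "IdU", "CldU"),
                                  c(0, 30, 40), c(30, 40, 70),
                                  length_kb = 100))
  expect_equal(unname(c3["single_origin_only"]), 1L)
  # two events on one fiber: interspersed origins, scored once
  c4 <- classify_figures(fiber_set(data.frame(
    fiber_id = "x", length_kb = 250,
    label = c("CldU", "IdU", "CldU", "IdU", "CldU"),
    start_kb = c(20, 45, 55, 145, 155),
    end_kb = c(45, 55, 145, 155, 180))))
  expect_equal(unname(c4["interspersed_origins"]), 1L)
  expect_equal(attr(c4, "n_total"), 1L)
  # converging forks fused in CldU: termination
  c5 <- classify_figures(fiber_of(c("IdU", "CldU", "IdU"),
                                  c(10, 30, 60), c(30, 60, 80),
                                  length_kb = 100))
  expect_equal(unname(c5["termination"]), 1L)
})

test_that("classification is exhaustive and mutually exclusive on simulated sets", {
  cfg <- sim_config(seed = 19, n_fibers = 150)
  g <- make_genome(cfg, chrom_length = 2e6)
  f <- make_fibers(g, "control", cfg, max_molecules = 4000)
  counts <- classify_figures(f)
  expect_equal(sum(counts), attr(counts, "n_total"))
  expect_true(all(counts >= 0))
  expect_gt(attr(counts, "n_total"), 0)
  # bounded scoring caps the structure count near the requested size
  capped <- classify_figures(f, max_structures = 50)
  expect_gte(attr(capped, "n_total"), 50)
  expect_lt(attr(capped, "n_total"), 70)
})

test_that("box summaries use 10-90 percentile whiskers with interpolation", {
  b <- box_summary(1:10)
  expect_equal(b$median, 5.5)
  expect_equal(b$p10, quantile_oracle(1:10, 0.1))
  bc <- box_summary(rep(3, 7))
  expect_equal(bc$p10, 3); expect_equal(bc$median, 3); expect_equal(bc$p90, 3)
  expect_equal(length(bc$outliers), 0)
  set.seed(8)
  for (i in 1:50) {
    x <- rnorm(sample(5:200, 1))
    b <- box_summary(x)
    expect_equal(b$p10, quantile_oracle(x, 0.1))
    expect_equal(b$median, quantile_oracle(x, 0.5))
    expect_equal(b$p90, quantile_oracle(x, 0.9))
    expect_true(all(b$outliers < b$p10 | b$outliers > b$p90))
  }
  expect_error(box_summary(numeric(0)), "no finite values")
})
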