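test_that("origin placement follows the configured renewal process", {
  cfg <- sim_config(seed = 42)
  g <- make_genome(cfg, chrom_length = 10e6)
  # Poisson-count oracle: ~100 origins expected at 100-kb spacing over 10 Mb
  expect_lt(abs(nrow(g$origins) - 100), 3 * sqrt(100))
  expect_true(all(diff(g$origins$position) > 0))
  expect_true(all(g$origins$position >= 0 & g$origins$position < 10e6))

  g1 <- make_genome(sim_config(seed = 7), early_fraction = 1)
  expect_true(all(g1$origins$timing_class == "early"))

  # determinism under a fixed seed
  expect_identical(make_genome(sim_config(seed = 5)),
                   make_genome(sim_config(seed = 5)))
  expect_error(sim_config(seed = 1, origin_spacing_mean = -3), "positive")
})

test_that("early origins fire strictly before every late origin", {
  g <- make_genome(sim_config(seed = 11), chrom_length = 20e6,
                   early_fraction = 0.5)
  ft <- split(g$origins$firing_time, g$origins$timing_class)
  expect_true(max(ft$early) < min(ft$late))
  expect_true(all(g$origins$firing_time >= 0))
})

test_that("timing profile maps the earliest interval to 100 and decays with distance", {
  cfg <- sim_config(seed = 3)
  # one isolated origin: fixed spacing puts it mid-chromosome
  g <- make_genome(cfg, chrom_length = 300e3, spacing = "fixed",
                   conditions = c(x = 1))
  g$origins <- g$origins[1, , drop = FALSE]
  prof <- make_timing_profile(g)
  expect_true(all(prof$value >= 0 & prof$value <= 100))
  ori_iv <- which(prof$start <= g$origins$position[1] &
                    prof$end > g$origins$position[1])
  expect_equal(prof$value[ori_iv], 100)
  # closed form t = t0 + d/v: values decrease monotonically away from origin
  expect_true(all(diff(prof$value[ori_iv:nrow(prof)]) < 0))
  expect_true(all(diff(prof$value[1:ori_iv]) > 0))
  # and linearly: equal decrements per interval away from the origin
  right <- prof$value[ori_iv:(ori_iv + 5)]
  expect_equal(diff(right), rep(diff(right)[1], 5), tolerance = 1e-6)

  g$origins <- g$origins[0, , drop = FALSE]
  expect_error(make_timing_profile(g), "no origins")
})

test_that("chip tracks carry counting noise, enrichment at early origins only", {
  cfg <- sim_config(seed = 21, origin_spacing_mean = 25)
  g <- make_genome(cfg, chrom_length = 4e6, early_window = c(0, 3),
                   mark_enrichment = c(H3K4me3 = 2))
  input <- make_chip_track(g, "input", cfg)
  mark <- make_chip_track(g, "H3K4me3", cfg)
  # conservation: stored library size equals reads emitted
  expect_equal(library_size(input), sum(input$count))
  expect_equal(library_size(mark), sum(mark$count))

  mids <- (input$start + input$end) / 2
  early <- g$origins$position[g$origins$timing_class == "early"]
  near <- oritime:::in_any_window(mids, early, cfg$enrichment_window_kb * 1000)
  # input is unenriched: windows look like everywhere else
  expect_lt(abs(mean(input$count[near]) - mean(input$count[!near])),
            4 * sqrt(cfg$background_rate / sum(near)) +
              4 * sqrt(cfg$background_rate / sum(!near)))
  # 2x fold: mean count in windows ~ 2 * background (Poisson mean oracle)
  expect_equal(mean(mark$count[near]), 2 * cfg$background_rate,
               tolerance = 4 * sqrt(2 * cfg$background_rate / sum(near)) /
                 (2 * cfg$background_rate))
  expect_equal(mean(mark$count[!near]), cfg$background_rate, tolerance = 0.05)

  # knockdown_scale 0 collapses the mark onto the input model
  null_mark <- make_chip_track(g, "H3K4me3", cfg, knockdown_scale = 0)
  pt <- t.test(null_mark$count[near], input$count[near])$p.value
  expect_gt(pt, 0.01)
  expect_error(make_chip_track(g, "H3K9me3", cfg), "unknown mark")
})
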