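test_that("reads are counted into the interval containing their 5' start", {
  prof <- profile_of(c(80, 20), chrom = "chr1")
  tr <- interval_coverage(data.frame(chrom = "chr1", start = 1500), prof)
  expect_equal(tr$count, c(0, 1))
  expect_equal(library_size(tr), 1)

  empty <- interval_coverage(data.frame(chrom = character(),
                                        start = numeric()), prof)
  expect_equal(empty$count, c(0, 0))
  expect_equal(library_size(empty), 0)

  # off-profile reads count toward the library only
  tr2 <- interval_coverage(data.frame(chrom = c("chr1", "chrX", "chr1"),
                                      start = c(10, 10, 5000)), prof)
  expect_equal(tr2$count, c(1, 0))
  expect_equal(library_size(tr2), 3)
})

test_that("synthetic chip counts round-trip through read counting", {
  cfg <- sim_config(seed = 9, origin_spacing_mean = 50)
  g <- make_genome(cfg, chrom_length = 5e5)
  prof <- make_timing_profile(g)
  track <- make_chip_track(g, "H3K4me3", cfg)
  reads <- data.frame(chrom = rep(track$chrom, track$count),
                      start = rep(track$start, track$count))
  back <- interval_coverage(reads, prof)
  expect_equal(back$count, track$count)
  expect_equal(library_size(back), library_size(track))
})

test_that("library normalization divides by total library size", {
  prof <- profile_of(c(10, 90))
  tr <- track_of(c(2, 3), prof, library_size = 10)
  expect_equal(normalize_library(tr), c(0.2, 0.3))
  tr2 <- track_of(c(4, 6), prof, library_size = 20)
  expect_equal(normalize_library(tr2), normalize_library(tr))
  expect_lte(sum(normalize_library(tr)), 1)
  tr0 <- track_of(c(0, 0), prof, library_size = 0)
  expect_error(normalize_library(tr0), "positive")
})

test_that("bin assignment floors into 100 bins then reverses early-to-late", {
  expect_equal(assign_bins(c(0, 100, 54.3)), c(100L, 1L, 100L + 1L - 55L))
  expect_equal(assign_bins(99.9999), 1L)
  expect_error(assign_bins(c(5, 101)), "outside")
  # reversal is an involution: reversing displayed indices restores raw bins
  v <- runif(50, 0, 100)
  raw <- pmin(floor(v * 100 / 100) + 1L, 100L)
  expect_equal(100L + 1L - assign_bins(v), raw)
})

test_that("timing distributions conserve normalized mass in their bins", {
  prof <- profile_of(c(100, 100, 40.2, 3))
  tr <- track_of(c(3, 7, 0, 0), prof)
  d <- timing_distribution(tr, prof)
  expect_equal(d$density[1], 1)           # all mass in the earliest bin
  expect_equal(sum(d$mass), sum(normalize_library(tr)), tolerance = 1e-12)
  expect_equal(d$cdf[100], 1)
  expect_true(all(diff(d$cdf) >= 0))

  tr2 <- track_of(c(0, 0, 2, 5), prof)
  d2 <- timing_distribution(tr2, prof)
  # intervals in the same bin add their mass; zero-coverage bins stay at 0
  expect_equal(d2$density[assign_bins(40.2)], 2 / 7)
  expect_equal(d2$density[assign_bins(3)], 5 / 7)

  bad <- track_of(c(1, 1), profile_of(c(10, 20)))
  expect_error(timing_distribution(bad, prof), "differ")
})

test_that("uniform coverage over uniform timing is flat across bins", {
  set.seed(1)
  vals <- runif(20000, 0, 100)
  prof <- profile_of(vals)
  tr <- track_of(rep(1, 20000), prof)
  d <- timing_distribution(tr, prof)
  # binomial SD oracle for 20000 intervals over 100 bins
  sd_bin <- sqrt(0.01 * 0.99 / 20000)
  expect_true(all(abs(d$density - 0.01) < 5 * sd_bin))
})
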