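test_that("percent input follows the dilution-adjusted delta-Ct formula", {
  expect_equal(percent_input(25, 25), 100)
  expect_equal(percent_input(26, 25), 50)
  # input aliquot 1%: adjustment is -log2(100) ~ -6.644 cycles
  expect_equal(percent_input(25, 25, input_fraction = 0.01),
               100 * 2^(-log2(100)))
  expect_equal(log2(1 / 0.01), 6.6439, tolerance = 1e-4)
  # scale-free: a common Ct offset cancels
  expect_equal(percent_input(27.3 + 2, 24.1 + 2), percent_input(27.3, 24.1))
  expect_error(percent_input(25, 25, input_fraction = 0), "input_fraction")
  expect_error(percent_input(-1, 25), "positive")
})

test_that("noise-free Ct tables recover true enrichment exactly", {
  truth <- c(TOP1_ori = 3, TOP1_m5kb = 0.8, bglobin_ori = 0.4)
  tab <- make_qpcr(truth, sim_config(seed = 1, ct_noise_sd = 0))
  res <- percent_input_table(tab)
  expect_equal(res$percent_input[match(names(truth), res$amplicon)],
               unname(truth), tolerance = 1e-12)
  # determinism of the noisy generator
  t1 <- make_qpcr(truth, sim_config(seed = 6))
  t2 <- make_qpcr(truth, sim_config(seed = 6))
  expect_identical(t1, t2)
})

test_that("noisy percent input is unbiased with the predicted CV", {
  truth <- c(amp = 2)
  vals <- vapply(1:1000, function(s) {
    percent_input_table(make_qpcr(truth, sim_config(seed = s)))$percent_input
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 2), 2 * se)
  # delta-method oracle: CV ~ ln2 * sd_ct * sqrt(2)
  cv_pred <- log(2) * 0.15 * sqrt(2)
  expect_equal(sd(vals) / mean(vals), cv_pred, tolerance = 0.15)
})

test_that("origin/flank profiles report per-locus enrichment ratios", {
  m <- data.frame(locus = rep("TOP1", 3),
                  position = c("-5kb", "ori", "+5kb"),
                  ct_ip = c(30, 30, 30), ct_input = c(25, 25, 25))
  r <- origin_flank_profile(m)
  expect_equal(r$loci$ratio, 1)
  # 3x origin enrichment: ori Ct lower by log2(3)
  m2 <- m; m2$ct_ip[2] <- 30 - log2(3)
  expect_equal(origin_flank_profile(m2)$loci$ratio, 3)
  # simulated via the Ct generator, within noise
  truth <- c(L_m5kb = 1, L_ori = 3, L_p5kb = 1)
  tab <- make_qpcr(truth, sim_config(seed = 12))
  pi <- percent_input_table(tab)
  ratio <- pi$percent_input[2] / mean(pi$percent_input[c(1, 3)])
  expect_equal(ratio, 3, tolerance = 0.15)
  # a missing flank is flagged but still summarized
  r3 <- origin_flank_profile(m[2:3, ])
  expect_true(r3$loci$flagged)
  expect_equal(r3$loci$n_flanks, 1)
})

test_that("relative BrdU normalizes net S-phase signal to the control", {
  expect_equal(relative_brdu(500, 100, reference_net = 400), 1)
  expect_equal(relative_brdu(300, 100, reference_net = 400), 0.5)
  expect_warning(z <- relative_brdu(80, 100, reference_net = 400), "negative")
  expect_equal(z, 0)
  expect_error(relative_brdu(1, 0, reference_net = 0), "positive")
})

test_that("constructed fold decreases are recovered from cytometry draws", {
  cfg <- sim_config(seed = 30)
  ref <- make_facs(20000, net_s_signal = 400, background = 100, cfg)
  ref_net <- mean(ref$s) - mean(ref$negative)
  for (fold in c(1.48, 1.64)) {
    kd <- make_facs(20000, net_s_signal = 400 / fold, background = 100,
                    sim_config(seed = 30 + fold * 100))
    rel <- relative_brdu(mean(kd$s), mean(kd$negative), ref_net)
    expect_equal(1 / rel, fold, tolerance = 0.05)
  }
  # no incorporation: S and negative populations coincide in the mean
  z <- make_facs(20000, net_s_signal = 0, background = 100, cfg)
  expect_equal(mean(z$s), mean(z$negative), tolerance = 0.05 * 100)
  expect_identical(make_facs(50, 10, 5, sim_config(seed = 2)),
                   make_facs(50, 10, 5, sim_config(seed = 2)))
})

test_that("densitometry ratios are H3-normalized and exposure-invariant", {
  expect_equal(densitometry_ratio(1200, 1200), 1)
  expect_equal(densitometry_ratio(900, 600), 1.5)
  expect_equal(densitometry_ratio(900, 1200), densitometry_ratio(900, 600) / 2)
  expect_equal(densitometry_ratio(3 * 900, 3 * 600),
               densitometry_ratio(900, 600))
  expect_error(densitometry_ratio(0, 5), "positive")
})
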