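#!/usr/bin/env Rscript
# Stage 3: molecular combing. Two sub-studies:
#  (a) fork velocity (n = 200) and inter-origin distance (n = 100) under a
#      2x firing deficit, on 1-Mb fibers (long-fiber selection, standard for
#      IOD work) - reproducing the no-elongation-defect / initiation-defect
#      pattern;
#  (b) five replication-figure classes at n = 200 structures per arm under
#      the default study conditions (control 0.7 vs knockdown 0.15).

suppressMessages(library(oritime))
seed <- as.integer(Sys.getenv("ORITIME_SEED", "1"))
dir.create("results", showWarnings = FALSE)

## (a) velocity and IOD
cfg <- sim_config(seed = seed + 1L, n_fibers = 700, origin_spacing_mean = 70,
                  fiber_length_mean = 1500, measurement_noise_kb = 0.4)
genome <- make_genome(cfg, chrom_length = 7e6,
                      conditions = c(control = 1, knockdown = 0.5))
fib <- lapply(c(control = "control", knockdown = "knockdown"),
              function(cd) make_fibers(genome, cd, cfg, max_molecules = 8000))
vel <- lapply(fib, function(f) fork_velocity(f)$velocity)
iod <- lapply(fib, inter_origin_distances)
set.seed(seed)
vel <- lapply(vel, sample, size = 200)
iod_s <- lapply(iod, function(d) sample(d$distance, min(100, nrow(d))))
stats <- list(
  velocity = list(median = sapply(vel, median),
                  box = lapply(vel, function(v)
                    box_summary(v)[c("median", "p10", "p90")]),
                  mw_p = mann_whitney(vel$control, vel$knockdown)$p_value),
  iod = list(median = sapply(iod_s, median),
             over_300 = sapply(iod, attr, "n_over_300"),
             mw_p_one_sided = mann_whitney(iod_s$control, iod_s$knockdown,
                                           alternative = "less")$p_value))
cat(sprintf("fork velocity medians (kb/min): control %.2f, knockdown %.2f (MW p = %.3f)\n",
            stats$velocity$median[1], stats$velocity$median[2],
            stats$velocity$mw_p))
cat(sprintf("IOD medians (kb): control %.0f, knockdown %.0f (one-sided MW p = %.2g)\n",
            stats$iod$median[1], stats$iod$median[2],
            stats$iod$mw_p_one_sided))

## (b) replication-figure classes
cfg_f <- sim_config(seed = seed + 2L, n_fibers = 400)
gen_f <- make_genome(cfg_f, chrom_length = 2e6)
cls <- lapply(c(control = "control", knockdown = "knockdown"), function(cd) {
  f <- make_fibers(gen_f, cd, cfg_f, max_molecules = 8000)
  set.seed(seed + 2L)
  classify_figures(f, max_structures = 200,
                   fiber_order = sample(unique(f$fiber_id)))
})
x2 <- suppressWarnings(chi_square_counts(cls$control, cls$knockdown))
tab <- data.frame(class = names(unclass(cls$control)),
                  control = as.integer(cls$control),
                  knockdown = as.integer(cls$knockdown))
write.table(tab, "results/figure_classes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("figure classes: X2 = %.1f (df %d), p = %.2g\n",
            x2$statistic, x2$df, x2$p_value))
print(tab, row.names = FALSE)
jsonlite::write_json(c(stats, list(figure_chi_square = x2[c("statistic",
                                                            "df", "p_value")])),
                     "results/combing_stats.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("wrote results/combing_stats.json and results/figure_classes.tsv\n")
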