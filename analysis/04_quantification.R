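#!/usr/bin/env Rscript
# Stage 4: exactly specified quantifications - ChIP-qPCR percent input on an
# origin/flank design, relative BrdU fluorescence, H3-normalized
# densitometry.

suppressMessages(library(oritime))
seed <- as.integer(Sys.getenv("ORITIME_SEED", "1"))
dir.create("results", showWarnings = FALSE)

truth <- c(TOP1_m5kb = 1, TOP1_ori = 3, TOP1_p5kb = 1)
ct <- make_qpcr(truth, sim_config(seed = seed + 3L))
pi_tab <- percent_input_table(ct)
write.csv(pi_tab, "results/percent_input.csv", row.names = FALSE)
ratio <- pi_tab$percent_input[2] / mean(pi_tab$percent_input[c(1, 3)])
cat("percent input per amplicon:\n"); print(pi_tab, row.names = FALSE)
cat(sprintf("origin / flank-mean enrichment ratio: %.2f (truth 3)\n", ratio))

ref <- make_facs(20000, net_s_signal = 400, background = 100,
                 sim_config(seed = seed + 4L))
ref_net <- mean(ref$s) - mean(ref$negative)
for (fold in c(1.48, 1.64)) {
  kd <- make_facs(20000, net_s_signal = 400 / fold, background = 100,
                  sim_config(seed = seed + 4L + round(100 * fold)))
  rel <- relative_brdu(mean(kd$s), mean(kd$negative), ref_net)
  cat(sprintf("constructed BrdU fold decrease %.2fx -> recovered %.2fx\n",
              fold, 1 / rel))
}

cat(sprintf("densitometry: band 860 AU / H3 430 AU -> %.2f AU (H3-normalized)\n",
            densitometry_ratio(860, 430)))
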