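#!/usr/bin/env Rscript
# Paired-spike (short-term facilitation) analysis of the detected pairs:
# first/second presynaptic spikes are selected by inter-spike interval
# (5-30 ms) after a 30 ms dead time, efficacies are recomputed triggered on
# each set, and the paired-spike ratio PSR = eff_second / eff_first is
# compared with the planted facilitation (1.7 onto excitatory, 1.3 onto
# inhibitory targets).

suppressPackageStartupMessages(library(retinoconn))

ses <- read_session("results/session")
tru <- read_ground_truth("results/session")
pairs <- read.csv("results/connectivity.csv")
conn <- pairs[pairs$connected, ]

tab <- do.call(rbind, lapply(seq_len(nrow(conn)), function(i) {
  ps <- paired_spike_analysis(ses$trains[[conn$pre_id[i]]],
                              ses$trains[[conn$post_id[i]]],
                              exclusions = ses$exclusions)
  data.frame(pre_id = conn$pre_id[i], post_id = conn$post_id[i],
             post_class = conn$post_class[i], n_pairs = ps$n_pairs,
             eff_first = ps$eff_first, eff_second = ps$eff_second,
             psr = ps$psr, low_n = ps$low_n, isi_group = "5-30")
}))
tab$planted_f <- tru$pairs$facilitation[match(paste(tab$pre_id, tab$post_id),
                                              paste(tru$pairs$pre, tru$pairs$post))]
write.csv(tab, "results/paired_spike.csv", row.names = FALSE)
print(tab, row.names = FALSE, digits = 3)

s <- population_psr(tab)
cat(sprintf("\n%.0f%% of pairs show paired-spike enhancement (PSR > 1)\n",
            100 * s$frac_enhanced))
print(s$by_class, row.names = FALSE, digits = 3)
cat(sprintf("log(eff_first) vs log(PSR): r = %.3f (p = %.3g)\n",
            s$log_correlation$r, s$log_correlation$p))
cat("Table in results/paired_spike.csv\n")
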