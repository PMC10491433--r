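#!/usr/bin/env Rscript
# Monosynaptic connectivity scan of the reference session: jitter-corrected
# cross-correlograms (0.1 ms bins, 10 ms interval jitter, 100 resamples)
# for every ordered retinal-axon -> collicular-neuron pair, with detection
# (>= 5 consecutive bins above baseline + 4 SD inside +0.5..+3.5 ms),
# transmission latency, synaptic efficacy and contribution. Optotagging
# epochs are excluded from all correlations. Detected pairs are compared
# with the planted wiring.

suppressPackageStartupMessages(library(retinoconn))

ses <- read_session("results/session")
tru <- read_ground_truth("results/session")

pairs <- scan_all_pairs(ses, ccg_params(seed = 1), detection_params())
write.csv(pairs, "results/connectivity.csv", row.names = FALSE)

conn <- pairs[pairs$connected, ]
key <- paste(pairs$pre_id, pairs$post_id)
planted <- paste(tru$pairs$pre, tru$pairs$post)
cat(sprintf("Tested %d ordered pairs: %d detected (%d planted, %d recovered, %d false)\n",
            nrow(pairs), nrow(conn), length(planted),
            sum(key[pairs$connected] %in% planted),
            sum(!key[pairs$connected] %in% planted)))
cat("\nDetected pairs:\n")
print(conn[, c("pre_id", "post_id", "post_class", "latency_ms", "efficacy",
               "contribution", "channel_distance_um")], row.names = FALSE)

for (cls in unique(conn$post_class)) {
  v <- conn$efficacy[conn$post_class == cls] * 100
  print(summarize_group(v, sprintf("efficacy %% (%s)", cls)))
  w <- conn$contribution[conn$post_class == cls] * 100
  print(summarize_group(w, sprintf("contribution %% (%s)", cls)))
}
cat("Table in results/connectivity.csv\n")
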