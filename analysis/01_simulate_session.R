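#!/usr/bin/env Rscript
# Build the reference synthetic recording session used by the downstream
# analysis scripts: the full stimulus protocol (optotagging under black
# screen and checkerboard, sparse-noise mapping, repeated movies), 6 retinal
# axons and 12 collicular neurons (8 excitatory, 4 inhibitory) with 6
# planted monosynaptic connections, shared slow rate comodulation, and
# ground truth for every planted parameter.

suppressPackageStartupMessages(library(retinoconn))

cfg <- sim_config(seed = 20230908)
st <- simulate_session(cfg)

dir.create("results", showWarnings = FALSE)
write_session(st$session, "results/session")
write_ground_truth(st$truth, "results/session")

print(st$session)
cat("\nPlanted connections:\n")
print(st$truth$pairs[, c("pre", "post", "efficacy_base", "facilitation",
                         "latency_mean_ms")], row.names = FALSE)
cat(sprintf("\nSession written to results/session (%.0f s of recording, %d units)\n",
            st$session$t_stop, length(st$session$trains)))
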