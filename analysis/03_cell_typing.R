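#!/usr/bin/env Rscript
# Cell-type assignment for the reference session, blind to ground truth:
# (1) axonal vs somatic classification from the multi-channel waveform
#     (triphasic wide-spread propagating templates = retinal axons);
# (2) optotagging of inhibitory units from their pulse-locked rate increase
#     (paired increase p < 0.001, ratio >= 1.5, onset latency <= 20 ms,
#     corroborated under the checkerboard protocol), with non-modulated
#     units inside the light-activated channel range labeled excitatory;
# (3) exclusion of any light-responsive retinal axon from connectivity.
# The resulting labels are scored against the planted classes.

suppressPackageStartupMessages(library(retinoconn))

ses <- read_session("results/session")
tru <- read_ground_truth("results/session")

wf_class <- vapply(names(ses$waveforms), function(id)
  classify_axonal_vs_somatic(waveform_features(ses$waveforms[[id]],
                                               ses$waveform_fs)), "")
sc_ids <- names(wf_class)[wf_class == "SC_SOMA"]
cl <- classify_session_units(ses, sc_ids)
cl$waveform_class <- unname(wf_class[cl$unit_id])
led <- flag_led_responsive_rgc(ses, names(wf_class)[wf_class == "RGC_AXON"])
write.csv(cl, "results/cell_typing.csv", row.names = FALSE)

truth_lab <- tru$units$true_class[match(cl$unit_id, tru$units$unit_id)]
cat("Waveform classes vs truth:\n")
print(table(wf_class, tru$units$true_class[match(names(wf_class),
                                                 tru$units$unit_id)] == "RGC"))
cat("\nOptotagging labels vs planted classes:\n")
print(table(assigned = cl$label, planted = truth_lab))
cat(sprintf("\nLED-responsive axons excluded: %s\n",
            if (any(led)) paste(names(led)[led], collapse = ", ") else "none"))
cat("Table in results/cell_typing.csv\n")
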