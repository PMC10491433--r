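#!/usr/bin/env Rscript
# Population comparisons between excitatory and inhibitory targets on the
# reference session, using the reporting layer: firing rates per class,
# efficacy / contribution / PSR by postsynaptic class (two-sided Wilcoxon
# rank-sum with Cohen's d), and first-spike efficacy vs PSR on log scales.
# With a handful of synthetic pairs these are demonstrations of the
# machinery, not powered comparisons.

suppressPackageStartupMessages(library(retinoconn))

ses <- read_session("results/session")
pairs <- read.csv("results/connectivity.csv")
psr <- read.csv("results/paired_spike.csv")
conn <- pairs[pairs$connected, ]

rates <- vapply(ses$trains, firing_rate, 0)
lab <- ses$units$label[match(names(rates), ses$units$unit_id)]
for (cls in c("RGC", "SC_EXN", "SC_IN"))
  print(summarize_group(rates[lab == cls], sprintf("firing rate Hz (%s)", cls)))

cmp <- function(metric, df) {
  a <- df[[metric]][df$post_class == "SC_EXN"]
  b <- df[[metric]][df$post_class == "SC_IN"]
  if (min(length(a), length(b)) < 2) return(invisible())
  r <- suppressWarnings(compare_groups(a, b))
  cat(sprintf("%-14s EXN vs IN: rank-sum p = %.3g, Cohen's d = %.3f (n = %d, %d)\n",
              metric, r$p_value, r$cohens_d, r$n_a, r$n_b))
}
cmp("efficacy", conn)
cmp("contribution", conn)
cmp("psr", psr)

ok <- is.finite(psr$psr) & psr$eff_first > 0
if (sum(ok) >= 3) {
  lc <- correlate(psr$eff_first[ok], psr$psr[ok], log_transform = TRUE)
  cat(sprintf("log first-spike efficacy vs log PSR: r = %.3f (p = %.3g)\n",
              lc$statistic, lc$p_value))
}

summary <- list(
  n_units = as.list(table(lab)),
  n_connected = nrow(conn),
  median_efficacy_pct = round(100 * median(conn$efficacy), 2),
  median_contribution_pct = round(100 * median(conn$contribution), 2),
  frac_enhanced = round(mean(psr$psr > 1, na.rm = TRUE), 3))
jsonlite::write_json(summary, "results/population_summary.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
cat("Summary in results/population_summary.json\n")
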