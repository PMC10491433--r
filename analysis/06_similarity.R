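#!/usr/bin/env Rscript
# Functional similarity of the detected pairs: spike-triggered-average
# receptive fields under light and dark sparse noise, trial-averaged rates
# under the movie, its scrambled surrogate and the checkerboard, combined
# into the five-correlation similarity index. Only pairs in which both
# units pass the receptive-field SNR > 8 gate enter the similarity
# population; the index is then related to connection efficacy.

suppressPackageStartupMessages(library(retinoconn))

ses <- read_session("results/session")
pairs <- read.csv("results/connectivity.csv")
conn <- pairs[pairs$connected, ]

resp <- list()
get_resp <- function(id) {
  if (is.null(resp[[id]])) resp[[id]] <<- unit_responses(ses, id)
  resp[[id]]
}
tab <- do.call(rbind, lapply(seq_len(nrow(conn)), function(i) {
  ra <- get_resp(conn$pre_id[i]); rb <- get_resp(conn$post_id[i])
  if (is.null(ra) || is.null(rb)) return(NULL)
  s <- suppressWarnings(similarity_index(ra, rb, ra$snr_pass, rb$snr_pass))
  data.frame(pre_id = conn$pre_id[i], post_id = conn$post_id[i],
             post_class = conn$post_class[i], r_sd = s$r_sd, r_sl = s$r_sl,
             r_nm = s$r_nm, r_psm = s$r_psm, r_chk = s$r_chk,
             index = s$index, snr_pre = ra$snr, snr_post = rb$snr,
             snr_pass = s$snr_pass, efficacy = conn$efficacy[i])
}))
write.csv(tab, "results/similarity.csv", row.names = FALSE)
print(tab[, c("pre_id", "post_id", "post_class", "index", "snr_pass",
              "efficacy")], row.names = FALSE, digits = 3)

gated <- tab[tab$snr_pass, ]
cat(sprintf("\n%d/%d pairs pass the receptive-field SNR gate\n",
            nrow(gated), nrow(tab)))
if (nrow(gated) >= 3) {
  print(summarize_group(gated$index, "similarity index (gated pairs)"))
  ct <- correlate(gated$index, gated$efficacy)
  cat(sprintf("similarity vs efficacy: r = %.3f (p = %.3g, n = %d)\n",
              ct$statistic, ct$p_value, ct$n))
}
cat("Table in results/similarity.csv\n")
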