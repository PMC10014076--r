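#!/usr/bin/env Rscript

# Cross-channel comparisons on per-replicate estimates: does the strong
# channel transmit more information, and does it have the higher SNR?
# Rank-sum tests are exact by enumeration at these group sizes.

library(lectincap)

cap <- read.csv("results/capacity.csv")
noise <- read.csv("results/noise.csv")

compare_metric <- function(df, col, label) {
  a <- df[[col]][grepl("^strong", df$condition)]
  b <- df[[col]][grepl("^weak", df$condition)]
  w <- wilcoxon_rank_sum(a, b)
  cat(sprintf("%-14s strong median %.3f vs weak %.3f: W = %g, p = %.3f (%s)\n",
              label, median(a), median(b), w$statistic, w$p_value, w$method))
  data.frame(metric = label, n_a = length(a), n_b = length(b),
             statistic = w$statistic, p_value = w$p_value, test = w$method)
}

out <- rbind(compare_metric(cap, "bits", "capacity_bits"),
             compare_metric(noise, "snr", "snr"))
write.csv(out, "results/comparisons.csv", row.names = FALSE)
cat("wrote results/comparisons.csv\n")
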