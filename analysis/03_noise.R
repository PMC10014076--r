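#!/usr/bin/env Rscript

# Decompose every replicate channel into signal power (variance of the
# per-dose mean log10 GFP) and noise power (mean per-dose variance), then
# test whether the strong channel's SNR exceeds the weak one's.

library(lectincap)

sheet <- read.csv("results/data/sample_sheet.csv", stringsAsFactors = FALSE)
tables <- lapply(unique(sheet$sample_id), function(sid) {
  read_events_csv(file.path("results/data", sid), "GFP")
})
names(tables) <- unique(sheet$sample_id)
datasets <- assemble_dataset(sheet, tables)

dec <- lapply(datasets, decompose)
tab <- do.call(rbind, lapply(names(dec), function(nm) {
  d <- dec[[nm]]; ds <- datasets[[nm]]
  data.frame(condition = paste(ds$condition$receptor, ds$condition$ligand,
                               sep = "/"),
             replicate = ds$condition$replicate,
             signal_power = d$signal_power, noise_power = d$noise_power,
             snr = d$snr)
}))
write.csv(tab, "results/noise.csv", row.names = FALSE)
print(tab, digits = 3)

strong <- dec[grep("^strong", names(dec))]
weak <- dec[grep("^weak", names(dec))]
cmp <- snr_compare(strong, weak)
cat(sprintf("\nSNR strong vs weak: W = %g, exact two-sided p = %.3f\n",
            cmp$statistic, cmp$p_value))
cat(sprintf("median SNR: strong %.3f, weak %.3f\n",
            median(cmp$snr_a), median(cmp$snr_b)))
cat("wrote results/noise.csv\n")
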