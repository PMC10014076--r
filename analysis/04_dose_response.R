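#!/usr/bin/env Rscript

# Fit four-parameter logistic curves to the per-dose geometric-mean GFP of
# each replicate channel, compare sensitivities (EC50 fold change), and
# test the strong-vs-weak EC50 difference with the extra-sum-of-squares
# F test on pooled per-replicate responses.

library(lectincap)

sheet <- read.csv("results/data/sample_sheet.csv", stringsAsFactors = FALSE)
tables <- lapply(unique(sheet$sample_id), function(sid) {
  read_events_csv(file.path("results/data", sid), "GFP")
})
names(tables) <- unique(sheet$sample_id)
datasets <- assemble_dataset(sheet, tables)

fits <- lapply(names(datasets), function(nm) {
  ds <- datasets[[nm]]
  sm <- dose_response_summary(ds)  # geometric mean per dose
  fit <- fit_4pl(sm$dose, sm$response)
  data.frame(condition = paste(ds$condition$receptor, ds$condition$ligand,
                               sep = "/"),
             replicate = ds$condition$replicate, bottom = fit$bottom,
             top = fit$top, ec50 = fit$ec50, hill = fit$hill,
             rss = fit$rss, converged = fit$converged)
})
tab <- do.call(rbind, fits)
write.csv(tab, "results/dose_response.csv", row.names = FALSE)
print(tab[, c("condition", "replicate", "ec50", "hill", "converged")],
      digits = 3)

pool <- function(rx) {
  keys <- grep(rx, names(datasets), value = TRUE)
  do.call(rbind, lapply(keys, function(nm) dose_response_summary(datasets[[nm]])))
}
a <- pool("^strong"); b <- pool("^weak")
ft <- compare_ec50_f_test(a$dose, a$response, b$dose, b$response)
fold <- ec50_fold_change(ft$fit_a, ft$fit_b)
cat(sprintf("\nEC50 strong %.3f vs weak %.3f (fold change %.2f)\n",
            ft$fit_a$ec50, ft$fit_b$ec50, fold))
cat(sprintf("extra-sum-of-squares F = %.2f (df %d, %d), p = %.3g\n",
            ft$F, ft$df1, ft$df2, ft$p_value))
write.csv(data.frame(pair = "strong_vs_weak", fold_change = fold, F = ft$F,
                     df1 = ft$df1, df2 = ft$df2, p = ft$p_value),
          "results/ec50_comparisons.csv", row.names = FALSE)
cat("wrote results/dose_response.csv and results/ec50_comparisons.csv\n")
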