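#!/usr/bin/env Rscript

# Between-tissue comparisons (ratios of estimated medians with Wald 95%
# CIs on the log scale) and duplicate-catheter limits of agreement per
# organ, on the per-catheter derived parameters from 03_fit_pk.R.

suppressPackageStartupMessages(library(hipecpk))

seed <- 1
out_dir <- "results"

per_cath <- read_table_csv(file.path(out_dir, "per_catheter_pk.csv"))

tissues <- sort(unique(per_cath$tissue))
pairs <- t(utils::combn(tissues, 2))
cmp <- do.call(rbind, lapply(c("auc_0_last", "c_max"), function(p) {
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    tryCatch(compare_tissues(per_cath, p, pairs[i, 2], pairs[i, 1]),
             error = function(e) NULL)
  }))
}))
write_table_csv(cmp, file.path(out_dir, "comparisons.csv"), seed = seed)

cat("largest AUC ratios between compartments:\n")
auc_cmp <- cmp[cmp$parameter == "auc_0_last", ]
print(head(auc_cmp[order(-auc_cmp$ratio), ], 5), digits = 3)
cat(sprintf("\n%d of %d AUC comparisons significant at the 5%% level (unadjusted; %d degenerate)\n",
            sum(auc_cmp$p < 0.05, na.rm = TRUE), nrow(auc_cmp),
            sum(is.na(auc_cmp$p))))

loa <- do.call(rbind, lapply(c("auc_0_last", "c_max", "t_half"), function(p) {
  do.call(rbind, lapply(unique(per_cath$organ), function(o) {
    tryCatch(limits_of_agreement(per_cath, o, p, nboot = 500, seed = seed),
             error = function(e) NULL)
  }))
}))
write_table_csv(loa, file.path(out_dir, "loa.csv"), seed = seed)

cat("\nlimits-of-agreement factors (duplicate catheters, same organ):\n")
print(loa[, c("tissue", "parameter", "loa_factor", "ci_low", "ci_high")],
      digits = 3)

fig <- plot_loa(loa)
ggplot2::ggsave(file.path(out_dir, "fig4_loa.pdf"), fig, width = 8, height = 4)
cat("\nwrote", file.path(out_dir, c("comparisons.csv", "loa.csv",
                                    "fig4_loa.pdf")), sep = "\n  ")
cat("\n")
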