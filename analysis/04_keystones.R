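#!/usr/bin/env Rscript
# Stage 4: keystone ("polarizing hub") statistics and degree distribution.
#
# For every taxon: degree, positive/negative association counts, the
# negative:positive ratio and the association balance. Polarizing hubs are
# top-quartile-degree nodes with |balance| <= 0.5 — taxa with large numbers
# of BOTH positive and negative partners. The degree tail is additionally
# fitted with the discrete power-law MLE.

suppressPackageStartupMessages(library(cecanet))

state <- readRDS("results/network/state.rds")
ks <- keystone_table(state$net)
hubs <- identify_polarizing_hubs(ks, degree_percentile = 75,
                                 balance_tolerance = 0.5)
cat(sprintf("%d nodes, max degree %d; %d polarizing hub(s)\n",
            nrow(ks), max(ks$degree), nrow(hubs)))
if (nrow(hubs)) print(utils::head(hubs, 10))

fit <- tryCatch(fit_power_law(state$net, k_min = 1),
                error = function(e) e)
if (inherits(fit, "power_law_fit")) print(fit) else
  cat("power-law fit skipped:", conditionMessage(fit), "\n")

dir.create("results/keystones", showWarnings = FALSE, recursive = TRUE)
utils::write.table(ks, "results/keystones/keystones.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(hubs, "results/keystones/polarizing_hubs.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
# degree vs negative:positive ratio, the scatter behind the hub analysis
utils::write.table(ks[ks$degree > 0, c("otu_id", "label", "degree",
                                       "neg_pos_ratio")],
                   "results/keystones/degree_ratio_scatter.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/keystones/{keystones,polarizing_hubs,degree_ratio_scatter}.tsv\n")
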