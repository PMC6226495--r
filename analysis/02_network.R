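#!/usr/bin/env Rscript
# Stage 2: compositional correlation inference and the signed network.
#
# Reads the community written by 01_simulate.R, filters OTUs with more than
# 100 total reads, infers basis correlations (20 Dirichlet resampling
# rounds, median-aggregated, iterative strong-pair exclusion) and attaches
# permutation pseudo-p-values from 100 column-shuffled null datasets. Edges
# require p < 0.05 and |rho| >= 0.3.

suppressPackageStartupMessages(library(cecanet))

x <- read_otu_table("results/sim/table.tsv", "results/sim/taxonomy.tsv",
                    "results/sim/metadata.tsv")
tab <- filter_by_total_reads(x$table, 100)
cat(sprintf("read filter (> 100 reads): %d -> %d OTUs\n",
            length(x$table$otu_ids), length(tab$otu_ids)))

corr <- sparcc(tab, rounds = 20, B = 100, seed = 17)
print(corr)
net <- build_network(corr, p_threshold = 0.05, r_threshold = 0.3,
                     labels = x$taxonomy)
print(net)

dir.create("results/network", showWarnings = FALSE, recursive = TRUE)
write_matrix_tsv(round(corr$rho, 10), "results/network/rho.tsv")
write_matrix_tsv(corr$pvalues, "results/network/pvalues.tsv")
export_network(net, "results/network/network.tsv", "edge-tsv")
export_network(net, "results/network/network.graphml", "graphml")
saveRDS(list(corr = corr, net = net, taxonomy = x$taxonomy,
             metadata = x$metadata, table = tab),
        "results/network/state.rds")
cat("wrote results/network/{rho,pvalues,network}.tsv and network.graphml\n")
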