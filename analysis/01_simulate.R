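#!/usr/bin/env Rscript
# Stage 1: generate the study community.
#
# A synthetic cecal-like community with known ground truth stands in for a
# multi-study OTU table: 50 OTUs, 300 samples at MiSeq-like depth, three
# planted blocks of 8 co-occurring OTUs (basis correlation 0.7 inside each
# block). Everything downstream (network, clusters, keystones, patterns)
# can therefore be judged against the planted truth in
# results/sim/truth.json.

suppressPackageStartupMessages(library(cecanet))

sim <- simulate_community_files(
  D = 50, n_samples = 300, n_clusters = 3, cluster_size = 8,
  within_corr = 0.7, depth_preset = "depth-miseq", seed = 17,
  out_dir = "results/sim")

cat(sprintf("wrote results/sim: %d samples x %d OTUs, depths %d-%d\n",
            nrow(sim$table$counts), ncol(sim$table$counts),
            min(sim$table$depths), max(sim$table$depths)))
cat(sprintf("planted %d clusters of %s OTUs each at basis correlation 0.7\n",
            length(sim$planted_sets),
            paste(unique(lengths(sim$planted_sets)), collapse = "/")))
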