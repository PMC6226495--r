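#' Run the full co-occurrence analysis pipeline
#'
#' Read-count filtering, correlation inference with permutation p-values,
#' signed-network construction, cohesive clustering of the positive
#' subgraph, keystone statistics, cluster recapitulation coverage and
#' frequent itemsets — one call, one seed. When `out_dir` is given, every
#' stage's table is written as TSV (rho and p-value matrices, edge list,
#' cluster memberships, cluster graph, keystone table, coverage summary,
#' itemsets) plus a JSON run manifest, so two runs with the same inputs and
#' seed produce byte-identical outputs.
#'
#' @param table an [otu_table].
#' @param taxonomy optional taxonomy ([parse_lineages]) for node labels.
#' @param min_reads total-read filter threshold (strictly-greater; default
#'   100). `NULL` skips filtering.
#' @param rounds,B,exclusion_threshold,exclusion_iterations correlation
#'   inference settings (see [sparcc]).
#' @param p_threshold,r_threshold network thresholds (defaults 0.05, 0.3).
#' @param penalty,merge_threshold,min_size,min_density clustering settings
#'   (see [detect_clusters]).
#' @param theta cluster-coverage threshold (default 0.25).
#' @param min_support,max_size itemset mining settings; `min_support = NULL`
#'   skips mining.
#' @param seed single seed driving all randomness.
#' @param out_dir optional output directory.
#' @return List with `table`, `corr`, `network`, `clusters`, `keystones`,
#'   `coverage`, `itemsets`.
#' @export
run_pipeline <- function(table, taxonomy = NULL, min_reads = 100,
                         rounds = 20, B = 100, exclusion_threshold = 0.1,
                         exclusion_iterations = 10, p_threshold = 0.05,
                         r_threshold = 0.3, penalty = 2,
                         merge_threshold = 0.8, min_size = 3,
                         min_density = 0.3, theta = 0.25,
                         min_support = 0.3, max_size = 5, seed = 17,
                         out_dir = NULL) {
  stopifnot(inherits(table, "otu_table"))
  n_before <- length(table$otu_ids)
  if (!is.null(min_reads)) {
    table <- filter_by_total_reads(table, min_reads)
    message(sprintf("read filter (> %d reads): %d -> %d OTUs", min_reads,
                    n_before, length(table$otu_ids)))
  }
  corr <- sparcc(table, rounds = rounds, B = B,
                 exclusion_threshold = exclusion_threshold,
                 exclusion_iterations = exclusion_iterations, seed = seed)
  net <- build_network(corr, p_threshold = p_threshold,
                       r_threshold = r_threshold, labels = taxonomy)
  clusters <- detect_clusters(net, penalty = penalty,
                              merge_threshold = merge_threshold,
                              min_size = min_size,
                              min_density = min_density, corr = corr)
  keystones <- keystone_table(net)
  pres <- presence_matrix(table)
  coverage <- if (length(clusters$clusters)) {
    cluster_coverage(pres, clusters, theta = theta)
  } else NULL
  itemsets <- if (!is.null(min_support)) {
    top_itemsets(frequent_itemsets(pres, min_support, max_size))
  } else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix_tsv(round(corr$rho, 10), file.path(out_dir, "rho.tsv"))
    write_matrix_tsv(corr$pvalues, file.path(out_dir, "pvalues.tsv"))
    export_network(net, file.path(out_dir, "network.tsv"), "edge-tsv")
    write_clusters_tsv(clusters, file.path(out_dir, "clusters.tsv"))
    utils::write.table(clusters$cluster_graph,
                       file.path(out_dir, "cluster_graph.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(keystones, file.path(out_dir, "keystones.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(coverage)) {
      utils::write.table(
        data.frame(cluster = names(coverage$sample_fraction),
                   sample_fraction = coverage$sample_fraction),
        file.path(out_dir, "coverage.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(itemsets)) {
      utils::write.table(itemsets[, c("items", "size", "support")],
                         file.path(out_dir, "itemsets.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest <- list(seed = seed, min_reads = min_reads, rounds = rounds,
                     B = B, exclusion_threshold = exclusion_threshold,
                     exclusion_iterations = exclusion_iterations,
                     p_threshold = p_threshold, r_threshold = r_threshold,
                     penalty = penalty, merge_threshold = merge_threshold,
                     min_size = min_size, min_density = min_density,
                     n_otus = length(table$otu_ids),
                     n_samples = length(table$sample_ids),
                     n_edges = nrow(net$edges),
                     n_clusters = length(clusters$clusters),
                     excluded_pairs = nrow(corr$excluded_pairs))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(table = table, corr = corr, network = net, clusters = clusters,
       keystones = keystones, coverage = coverage, itemsets = itemsets)
}
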