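# Small builders shared across tests.

make_table <- function(counts, sample_ids = NULL, otu_ids = NULL) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_len(nrow(counts)))
  if (is.null(otu_ids)) otu_ids <- sprintf("otu_%d", seq_len(ncol(counts)))
  otu_table(counts, sample_ids, otu_ids)
}

make_taxonomy <- function(otu_ids, genus = NULL, family = "Fam",
                          order = "Ord") {
  if (is.null(genus)) genus <- sprintf("G%d", seq_along(otu_ids))
  lineage <- paste0("p__P;c__C",
                    ifelse(is.na(order), "", paste0(";o__", order)),
                    ifelse(is.na(family), "", paste0(";f__", family)),
                    ifelse(is.na(genus), "", paste0(";g__", genus)))
  parse_lineages(otu_ids, lineage)
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# A small correlation_result-like object for network construction tests.
fake_corr <- function(rho, pvalues) {
  ids <- sprintf("otu_%d", seq_len(ncol(rho)))
  dimnames(rho) <- dimnames(pvalues) <- list(ids, ids)
  structure(list(rho = rho, pvalues = pvalues, otu_ids = ids,
                 excluded_pairs = matrix(integer(0), 0, 2)),
            class = "correlation_result")
}

# Symmetric matrix from an edge list (i, j, weight), n nodes.
adj_from_edges <- function(n, edges, ids = sprintf("n%02d", seq_len(n))) {
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  for (e in edges) {
    adj[e[1], e[2]] <- adj[e[2], e[1]] <- if (length(e) > 2) e[3] else 1
  }
  adj
}
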