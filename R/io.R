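#' Export a signed network to disk
#'
#' `"edge-tsv"` writes the edge list (`source`, `target`, `rho`, `pvalue`,
#' `sign`); `"graphml"` writes GraphML via igraph with the same edge
#' attributes plus node labels. Both round-trip losslessly through
#' [read_network].
#'
#' @param net a [build_network] result.
#' @param path output path.
#' @param format `"edge-tsv"` or `"graphml"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(net, path, format = c("edge-tsv", "graphml")) {
  stopifnot(inherits(net, "signed_network"))
  format <- match.arg(format)
  if (format == "edge-tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a signed network to an igraph object
#'
#' Undirected graph with edge attributes `rho`, `pvalue`, `sign` (and
#' `weight = |rho|`) and vertex attribute `label`; isolated nodes retained.
#'
#' @param net a [build_network] result.
#' @return An igraph graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  igraph::E(g)$weight <- abs(igraph::E(g)$rho)
  g
}

#' Read a network written by [export_network]
#'
#' @param path file path.
#' @param format `"edge-tsv"` or `"graphml"`.
#' @param p_threshold,r_threshold thresholds to record on the object (not
#'   re-applied; edges are taken as stored).
#' @return A `signed_network`.
#' @export
read_network <- function(path, format = c("edge-tsv", "graphml"),
                         p_threshold = 0.05, r_threshold = 0.3) {
  format <- match.arg(format)
  if (format == "edge-tsv") {
    edges <- utils::read.delim(path, stringsAsFactors = FALSE,
                               colClasses = c(source = "character",
                                              target = "character",
                                              rho = "numeric",
                                              pvalue = "numeric",
                                              sign = "character"))
    ids <- sort(unique(c(edges$source, edges$target)))
    nodes <- data.frame(otu_id = ids, label = ids, stringsAsFactors = FALSE)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(otu_id = igraph::V(g)$name,
                        label = igraph::V(g)$label,
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    edges <- data.frame(source = el[, 1], target = el[, 2],
                        rho = igraph::E(g)$rho,
                        pvalue = igraph::E(g)$pvalue,
                        sign = igraph::E(g)$sign,
                        stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, p_threshold = p_threshold,
                 r_threshold = r_threshold),
            class = "signed_network")
}

#' Write a square named matrix (rho or p-values) as TSV
#'
#' @param m matrix with identical row/column ids.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write cluster memberships as TSV
#'
#' One row per (cluster, member): `cluster_id`, `otu_id`, `cohesiveness`.
#'
#' @param clusters a `cluster_set` from [detect_clusters].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_clusters_tsv <- function(clusters, path) {
  stopifnot(inherits(clusters, "cluster_set"))
  rows <- do.call(rbind, lapply(seq_along(clusters$clusters), function(k) {
    cl <- clusters$clusters[[k]]
    data.frame(cluster_id = k, otu_id = cl$members,
               cohesiveness = cl$cohesiveness, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(cluster_id = integer(0), otu_id = character(0),
                       cohesiveness = numeric(0))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
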