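#' Positive-edge adjacency matrix of a signed network
#'
#' Cohesive clustering runs on co-occurrence (positive) associations only;
#' negative edges are dropped. Edge weight is the correlation rho.
#'
#' @param net a [build_network] result.
#' @return Symmetric named weight matrix over all nodes (isolates included
#'   as zero rows).
#' @export
positive_subgraph <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  ids <- net$nodes$otu_id
  adj <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  e <- net$edges[net$edges$sign == "+", , drop = FALSE]
  if (nrow(e)) {
    adj[cbind(e$source, e$target)] <- e$rho
    adj[cbind(e$target, e$source)] <- e$rho
  }
  adj
}

as_adjacency <- function(graph) {
  if (inherits(graph, "signed_network")) return(positive_subgraph(graph))
  adj <- as.matrix(graph)
  stopifnot(nrow(adj) == ncol(adj))
  if (is.null(rownames(adj))) {
    dimnames(adj) <- list(sprintf("n%02d", seq_len(nrow(adj))),
                          sprintf("n%02d", seq_len(nrow(adj))))
  }
  if (any(adj < 0)) stop("adjacency must carry non-negative (positive-edge) weights")
  diag(adj) <- 0
  adj
}

#' Cohesiveness of a node set
#'
#' `w_in / (w_in + w_bound + penalty * |V|)` where `w_in` is the total edge
#' weight inside the set and `w_bound` the total weight crossing its
#' boundary. The penalty models unobserved connections of each member and
#' keeps greedily grown groups from absorbing weak periphery. Returns 0 when
#' the denominator is 0.
#'
#' @param graph a [build_network] result or a non-negative weight matrix.
#' @param members character vector of node ids (or integer indices).
#' @param penalty per-member denominator penalty (>= 0, default 2).
#' @return Cohesiveness score in [0, 1].
#' @export
cohesiveness <- function(graph, members, penalty = 2) {
  adj <- as_adjacency(graph)
  idx <- resolve_members(adj, members)
  cohesiveness_idx(adj, idx, penalty)
}

resolve_members <- function(adj, members) {
  if (is.numeric(members)) return(as.integer(members))
  idx <- match(members, rownames(adj))
  if (anyNA(idx)) stop("unknown node id: ",
                       paste(members[is.na(idx)], collapse = ", "))
  idx
}

cohesiveness_idx <- function(adj, idx, penalty) {
  if (!length(idx)) return(0)
  w_in <- sum(adj[idx, idx, drop = FALSE]) / 2
  w_bound <- sum(adj[idx, -idx, drop = FALSE])
  denom <- w_in + w_bound + penalty * length(idx)
  if (denom == 0) 0 else w_in / denom
}

#' Greedily grow a cohesive cluster from a seed node
#'
#' Local search from the singleton seed set: at each step every single-node
#' addition from the boundary and every single-node removal is evaluated,
#' and the change with the largest strict increase in cohesiveness is
#' applied; growth stops at a local optimum. Ties are broken by preferring
#' addition over removal, then the lowest node id, so runs are bit-stable.
#'
#' @param graph a [build_network] result or non-negative weight matrix.
#' @param seed_node node id (or index) to grow from.
#' @param penalty cohesiveness penalty (default 2).
#' @return List of class `cluster`: `members` (sorted ids), `cohesiveness`,
#'   `w_in`, `w_bound`.
#' @export
grow_cluster <- function(graph, seed_node, penalty = 2) {
  adj <- as_adjacency(graph)
  seed_idx <- resolve_members(adj, seed_node)
  stopifnot(length(seed_idx) == 1)
  ids <- rownames(adj)
  current <- seed_idx
  score <- cohesiveness_idx(adj, current, penalty)
  eps <- 1e-12
  repeat {
    in_set <- logical(nrow(adj)); in_set[current] <- TRUE
    boundary <- which(!in_set & colSums(adj[current, , drop = FALSE]) > 0)
    boundary <- boundary[order(ids[boundary])]
    best_gain <- eps; best_idx <- NULL; best_add <- NA
    for (v in boundary) {
      s <- cohesiveness_idx(adj, c(current, v), penalty)
      if (s - score > best_gain) {
        best_gain <- s - score; best_idx <- v; best_add <- TRUE
      }
    }
    if (length(current) > 1) {
      removable <- current[order(ids[current])]
      for (v in removable) {
        s <- cohesiveness_idx(adj, setdiff(current, v), penalty)
        if (s - score > best_gain) {
          best_gain <- s - score; best_idx <- v; best_add <- FALSE
        }
      }
    }
    if (is.null(best_idx)) break
    current <- if (best_add) c(current, best_idx) else setdiff(current, best_idx)
    score <- score + best_gain
  }
  w_in <- sum(adj[current, current, drop = FALSE]) / 2
  w_bound <- sum(adj[current, -current, drop = FALSE])
  structure(list(members = sort(ids[current]),
                 cohesiveness = cohesiveness_idx(adj, current, penalty),
                 w_in = w_in, w_bound = w_bound),
            class = "cluster")
}

#' Overlap (match) coefficient between two node sets
#'
#' `|A intersect B|^2 / (|A| |B|)`: 1 for identical sets, 0 for disjoint
#' ones. Candidate clusters at or above the merge threshold are considered
#' redundant discoveries of the same group.
#'
#' @param A,B non-empty vectors of node ids.
#' @return Score in [0, 1].
#' @export
match_coefficient <- function(A, B) {
  A <- unique(A); B <- unique(B)
  stopifnot(length(A) > 0, length(B) > 0)
  length(intersect(A, B))^2 / (length(A) * length(B))
}

#' Mean interaction score between two clusters
#'
#' The mean of the correlation estimates over all deduplicated unordered
#' pairs (u, v) with u in A, v in B and u != v; applied reflexively (A = B)
#' it is the mean within-cluster off-diagonal correlation. Uses the full
#' correlation matrix, not only the thresholded network edges, unless a
#' thresholded matrix is supplied.
#'
#' @param corr a `correlation_result` or a named correlation matrix.
#' @param A,B vectors of node ids (cluster members).
#' @return Mean rho over the cross pairs; `NA` if there are none.
#' @export
inter_cluster_score <- function(corr, A, B) {
  rho <- if (inherits(corr, "correlation_result")) corr$rho else as.matrix(corr)
  ai <- resolve_members(rho, unique(A))
  bi <- resolve_members(rho, unique(B))
  pairs <- expand.grid(u = ai, v = bi)
  pairs <- pairs[pairs$u != pairs$v, , drop = FALSE]
  if (!nrow(pairs)) return(NA_real_)
  key <- paste(pmin(pairs$u, pairs$v), pmax(pairs$u, pairs$v))
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  mean(rho[cbind(pairs$u, pairs$v)])
}

#' Detect overlapping cohesive clusters on the positive subgraph
#'
#' Greedy seeded growth in the style of ClusterONE: seeds are processed in
#' decreasing weighted-degree order, skipping nodes already inside a grown
#' cluster; candidates whose pairwise match coefficient reaches
#' `merge_threshold` are merged transitively (union of members,
#' cohesiveness recomputed) until no pair qualifies; clusters smaller than
#' `min_size` or with internal weighted edge density below `min_density`
#' are discarded. Defaults are the published ClusterONE defaults.
#'
#' @param graph a [build_network] result or non-negative weight matrix.
#' @param penalty cohesiveness penalty (default 2).
#' @param merge_threshold match coefficient at/above which candidates merge
#'   (default 0.8).
#' @param min_size minimum members of a reported cluster (default 3).
#' @param min_density minimum `w_in / (|V| (|V|-1) / 2)` (default 0.3).
#' @param corr optional `correlation_result` (or matrix) used for
#'   cluster-level interaction scores; defaults to the positive adjacency.
#' @return Object of class `cluster_set`: `clusters` (list of `cluster`
#'   objects) and `cluster_graph` (data frame `cluster_i`, `cluster_j`,
#'   `score`, `shared_taxa`).
#' @export
detect_clusters <- function(graph, penalty = 2, merge_threshold = 0.8,
                            min_size = 3, min_density = 0.3, corr = NULL) {
  adj <- as_adjacency(graph)
  ids <- rownames(adj)
  if (!nrow(adj) || all(adj == 0)) {
    return(structure(list(clusters = list(),
                          cluster_graph = empty_cluster_graph()),
                     class = "cluster_set"))
  }
  wdeg <- rowSums(adj)
  order_idx <- order(-wdeg, ids)
  covered <- logical(nrow(adj))
  candidates <- list()
  for (v in order_idx) {
    if (covered[v] || wdeg[v] == 0) next
    cl <- grow_cluster(adj, v, penalty)
    covered[match(cl$members, ids)] <- TRUE
    candidates[[length(candidates) + 1]] <- cl$members
  }
  # transitive merge of redundant candidates until no pair overlaps enough
  repeat {
    merged <- FALSE
    for (i in seq_along(candidates)) {
      if (merged) break
      for (j in seq_along(candidates)) {
        if (j <= i) next
        if (match_coefficient(candidates[[i]], candidates[[j]]) >=
            merge_threshold) {
          candidates[[i]] <- sort(union(candidates[[i]], candidates[[j]]))
          candidates[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  keep <- list()
  for (members in candidates) {
    n <- length(members)
    if (n < min_size) next
    idx <- match(members, ids)
    w_in <- sum(adj[idx, idx]) / 2
    density <- w_in / (n * (n - 1) / 2)
    if (density < min_density) next
    keep[[length(keep) + 1]] <- structure(
      list(members = members,
           cohesiveness = cohesiveness_idx(adj, idx, penalty),
           w_in = w_in,
           w_bound = sum(adj[idx, -idx, drop = FALSE])),
      class = "cluster")
  }
  # larger, more cohesive clusters first; id order as final tie-break
  if (length(keep)) {
    ord <- order(-vapply(keep, function(c) length(c$members), numeric(1)),
                 -vapply(keep, `[[`, numeric(1), "cohesiveness"),
                 vapply(keep, function(c) c$members[1], character(1)))
    keep <- keep[ord]
  }
  score_src <- if (is.null(corr)) adj else corr
  cg <- empty_cluster_graph()
  if (length(keep) >= 2) {
    for (i in seq_along(keep)) for (j in seq_along(keep)) {
      if (j <= i) next
      cg <- rbind(cg, data.frame(
        cluster_i = i, cluster_j = j,
        score = inter_cluster_score(score_src, keep[[i]]$members,
                                    keep[[j]]$members),
        shared_taxa = length(intersect(keep[[i]]$members,
                                       keep[[j]]$members))))
    }
  }
  structure(list(clusters = keep, cluster_graph = cg), class = "cluster_set")
}

empty_cluster_graph <- function() {
  data.frame(cluster_i = integer(0), cluster_j = integer(0),
             score = numeric(0), shared_taxa = integer(0))
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d cluster(s)\n", length(x$clusters)))
  for (k in seq_along(x$clusters)) {
    cl <- x$clusters[[k]]
    cat(sprintf("  [%d] %d members, cohesiveness %.3f\n", k,
                length(cl$members), cl$cohesiveness))
  }
  invisible(x)
}
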