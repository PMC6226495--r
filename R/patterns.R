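#' Cluster recapitulation ("enterotype") coverage
#'
#' Tests whether detected co-occurrence clusters are recapitulated inside
#' individual samples: per (sample, cluster), coverage is the fraction of
#' the cluster's members present in the sample; per cluster, the summary is
#' the fraction of samples whose coverage reaches `theta` (default 0.25,
#' i.e. "at least 25% of members present"). Optionally the same statistic
#' is reported for the union of designated cluster pairs, supporting
#' statements about joint recapitulation of two clusters.
#'
#' @param presence samples x OTUs binary matrix ([presence_matrix]).
#' @param clusters a `cluster_set` from [detect_clusters], or a list of
#'   member-id vectors.
#' @param theta coverage threshold in (0, 1].
#' @param pairs optional list of length-2 integer vectors of cluster
#'   indices whose member unions are also summarised.
#' @return List with `coverage` (samples x clusters matrix),
#'   `sample_fraction` (per cluster, fraction of samples with coverage >=
#'   theta), and `pair_fraction` (named vector, one entry per requested
#'   pair).
#' @export
cluster_coverage <- function(presence, clusters, theta = 0.25,
                             pairs = NULL) {
  stopifnot(theta > 0, theta <= 1)
  presence <- as.matrix(presence)
  member_sets <- if (inherits(clusters, "cluster_set")) {
    lapply(clusters$clusters, `[[`, "members")
  } else clusters
  if (!length(member_sets)) {
    return(list(coverage = matrix(0, nrow(presence), 0),
                sample_fraction = numeric(0), pair_fraction = numeric(0)))
  }
  cov_of <- function(members) {
    missing <- setdiff(members, colnames(presence))
    if (length(missing)) {
      stop("cluster references OTU(s) absent from presence matrix: ",
           paste(missing, collapse = ", "))
    }
    rowSums(presence[, members, drop = FALSE]) / length(members)
  }
  coverage <- vapply(member_sets, cov_of, numeric(nrow(presence)))
  coverage <- matrix(coverage, nrow = nrow(presence),
                     dimnames = list(rownames(presence),
                                     sprintf("cluster_%d",
                                             seq_along(member_sets))))
  sample_fraction <- colMeans(coverage >= theta)
  pair_fraction <- numeric(0)
  if (!is.null(pairs)) {
    pair_fraction <- vapply(pairs, function(pr) {
      u <- union(member_sets[[pr[1]]], member_sets[[pr[2]]])
      mean(cov_of(u) >= theta)
    }, numeric(1))
    names(pair_fraction) <- vapply(pairs, paste, character(1),
                                   collapse = "+")
  }
  list(coverage = coverage, sample_fraction = sample_fraction,
       pair_fraction = pair_fraction)
}

#' Breed-level taxonomic profile correlation clustering
#'
#' Aggregates each sample's relative abundances to taxonomy display labels,
#' averages them per breed, drops labels whose mean abundance stays below
#' `abundance_threshold` in every breed (or, with `strict = TRUE`, in any
#' breed), computes pairwise Spearman correlations between breed profiles
#' and clusters breeds by average linkage on the correlation-centred
#' distance `1 - rho`.
#'
#' @param table an [otu_table].
#' @param tax taxonomy from [parse_lineages] covering the table's OTUs.
#' @param meta per-sample metadata with `sample_id` and `breed`.
#' @param abundance_threshold minimum mean relative abundance (default
#'   0.01, i.e. taxa present at greater than 1%).
#' @param strict if `TRUE` a label must pass the threshold in every breed.
#' @return List with `profiles` (labels x breeds mean relative abundance),
#'   `rho` (breed x breed Spearman matrix), `hclust` (average-linkage
#'   tree), `newick` (the dendrogram as a nested-parenthesis string).
#' @export
breed_profile_clustering <- function(table, tax, meta,
                                     abundance_threshold = 0.01,
                                     strict = FALSE) {
  stopifnot(inherits(table, "otu_table"))
  meta <- meta[match(table$sample_ids, meta$sample_id), , drop = FALSE]
  breeds <- unique(meta$breed)
  if (length(breeds) < 2) stop("need >= 2 breeds")
  if (any(is.na(meta$breed)) || any(!nzchar(meta$breed))) {
    stop("breed missing for some samples")
  }
  labels <- tax$display_label[match(table$otu_ids, tax$otu_id)]
  if (anyNA(labels)) stop("taxonomy missing OTUs present in table")
  rel <- table$counts / table$depths
  # sum relative abundance over OTUs sharing a display label
  agg <- t(rowsum(t(rel), group = labels))
  profiles <- vapply(breeds, function(b) {
    ix <- which(meta$breed == b)
    if (!length(ix)) stop("breed with zero samples: ", b)
    colMeans(agg[ix, , drop = FALSE])
  }, numeric(ncol(agg)))
  profiles <- matrix(profiles, ncol = length(breeds),
                     dimnames = list(colnames(agg), breeds))
  pass <- if (strict) apply(profiles > abundance_threshold, 1, all)
          else apply(profiles > abundance_threshold, 1, any)
  profiles <- profiles[pass, , drop = FALSE]
  if (nrow(profiles) < 2) stop("fewer than 2 taxa pass the abundance threshold")
  rho <- stats::cor(profiles, method = "spearman")
  hc <- stats::hclust(stats::as.dist(1 - rho), method = "average")
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(profiles = profiles, rho = rho, hclust = hc, newick = newick)
}
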