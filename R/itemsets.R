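#' Binary presence/absence matrix of an OTU table
#'
#' Presence of an OTU in a sample is a raw count of at least 1; no
#' rarefaction is applied.
#'
#' @param table an [otu_table].
#' @return samples x OTUs 0/1 matrix with the table's dimnames.
#' @export
presence_matrix <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  (table$counts >= 1) * 1
}

#' Mine frequent OTU itemsets (eclat-style)
#'
#' Exact depth-first enumeration over vertical transaction-id lists: the
#' support of an itemset is the fraction of samples in which every member
#' OTU is present, computed by intersecting the member presence lists. All
#' itemsets with `support >= min_support` and `size <= max_size` are
#' returned — no sampling — sorted by size (desc), support (desc), then
#' lexicographically. This answers "which combinations of OTUs are present
#' in the most samples".
#'
#' @param presence samples x OTUs binary matrix (see [presence_matrix]).
#' @param min_support minimum support fraction in (0, 1].
#' @param max_size maximum itemset size (>= 1).
#' @return Data frame with columns `items` (comma-joined sorted member
#'   ids), `size`, `support`, and a list column `members`.
#' @export
frequent_itemsets <- function(presence, min_support, max_size = 5) {
  stopifnot(min_support > 0, min_support <= 1, max_size >= 1)
  presence <- as.matrix(presence)
  n <- nrow(presence)
  out_items <- list(); out_support <- numeric(0)
  if (n > 0 && ncol(presence) > 0) {
    ids <- colnames(presence)
    if (is.null(ids)) ids <- sprintf("otu_%03d", seq_len(ncol(presence)))
    tidlists <- lapply(seq_len(ncol(presence)),
                       function(j) which(presence[, j] >= 1))
    min_count <- ceiling(min_support * n - 1e-9)
    frequent <- which(lengths(tidlists) >= min_count)

    dfs <- function(prefix, tids, candidates) {
      for (pos in seq_along(candidates)) {
        j <- candidates[pos]
        new_tids <- intersect(tids, tidlists[[j]])
        if (length(new_tids) < min_count) next
        items <- c(prefix, j)
        out_items[[length(out_items) + 1]] <<- items
        out_support[length(out_support) + 1] <<- length(new_tids) / n
        if (length(items) < max_size && pos < length(candidates)) {
          dfs(items, new_tids, candidates[(pos + 1):length(candidates)])
        }
      }
    }
    dfs(integer(0), seq_len(n), frequent)
  }
  members <- lapply(out_items, function(ix) sort(ids[ix]))
  df <- data.frame(
    items = vapply(members, paste, character(1), collapse = ","),
    size = lengths(members),
    support = out_support,
    stringsAsFactors = FALSE)
  df$members <- members
  df <- df[order(-df$size, -df$support, df$items), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Top itemsets per size
#'
#' Reports, for each itemset size, the `k` most supported combinations —
#' the practical summary of which OTU combinations recur across the most
#' samples.
#'
#' @param itemsets result of [frequent_itemsets].
#' @param k itemsets kept per size (default 20).
#' @return Subset of `itemsets`, same ordering.
#' @export
top_itemsets <- function(itemsets, k = 20) {
  if (!nrow(itemsets)) return(itemsets)
  keep <- unlist(lapply(split(seq_len(nrow(itemsets)), itemsets$size),
                        function(ix) utils::head(ix, k)))
  out <- itemsets[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
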