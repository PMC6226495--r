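# Graph batteries and independent oracles for the clustering contract.

adj_is_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(adj[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# All labelled connected unit-weight graphs on n nodes (feasible for n <= 5).
enumerate_connected_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^m) - 1L) {
    adj <- matrix(0, n, n,
                  dimnames = list(sprintf("n%02d", 1:n),
                                  sprintf("n%02d", 1:n)))
    bits <- bitwAnd(bitwShiftR(mask, seq_len(m) - 1L), 1L) == 1L
    if (!any(bits)) next
    sel <- pairs[bits, , drop = FALSE]
    adj[sel] <- 1
    adj[sel[, c(2, 1), drop = FALSE]] <- 1
    if (adj_is_connected(adj)) out[[length(out) + 1]] <- adj
  }
  out
}

random_connected_adj <- function(n, p) {
  repeat {
    adj <- matrix(0, n, n)
    up <- which(upper.tri(adj))
    on <- up[stats::runif(length(up)) < p]
    adj[on] <- 1
    adj <- adj + t(adj)
    dimnames(adj) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
    if (any(adj > 0) && adj_is_connected(adj)) return(adj)
  }
}

# Exhaustive best cohesiveness over every subset containing the seed:
# the independent optimum the greedy contract is checked against.
best_cohesiveness_with_seed <- function(adj, seed_idx, penalty) {
  n <- nrow(adj)
  others <- setdiff(seq_len(n), seed_idx)
  best <- 0
  for (mask in seq_len(2^length(others)) - 1L) {
    members <- c(seed_idx,
                 others[bitwAnd(bitwShiftR(mask, seq_along(others) - 1L),
                                1L) == 1L])
    w_in <- sum(adj[members, members, drop = FALSE]) / 2
    w_bound <- sum(adj[members, -members, drop = FALSE])
    denom <- w_in + w_bound + penalty * length(members)
    score <- if (denom == 0) 0 else w_in / denom
    if (score > best) best <- score
  }
  best
}

# Brute-force itemset oracle: enumerate every subset of columns directly.
brute_force_itemsets <- function(presence, min_support, max_size) {
  n <- nrow(presence)
  ids <- colnames(presence)
  D <- ncol(presence)
  rows <- list()
  for (mask in seq_len(2^D) - 1L) {
    sel <- which(bitwAnd(bitwShiftR(mask, seq_len(D) - 1L), 1L) == 1L)
    if (!length(sel) || length(sel) > max_size) next
    sup <- mean(rowSums(presence[, sel, drop = FALSE] >= 1) == length(sel))
    if (sup >= min_support - 1e-12) {
      rows[[length(rows) + 1]] <-
        data.frame(items = paste(sort(ids[sel]), collapse = ","),
                   size = length(sel), support = sup,
                   stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    return(data.frame(items = character(0), size = integer(0),
                      support = numeric(0)))
  }
  df <- df[order(-df$size, -df$support, df$items), , drop = FALSE]
  rownames(df) <- NULL
  df
}

random_presence <- function(n_samples, n_otus, p = 0.5) {
  m <- matrix(as.numeric(stats::runif(n_samples * n_otus) < p),
              n_samples, n_otus,
              dimnames = list(sprintf("s%d", seq_len(n_samples)),
                              sprintf("o%02d", seq_len(n_otus))))
  m
}
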