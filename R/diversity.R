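#' Shannon diversity of one sample
#'
#' `H = -sum(p_i log(p_i))` over OTUs with positive counts, with
#' proportions `p_i = count_i / depth`. The default logarithm base is 2
#' (bits), matching common amplicon-pipeline output; use `base = exp(1)`
#' for nats.
#'
#' @param counts non-negative count vector for one sample; at least one
#'   positive entry.
#' @param base logarithm base (default 2).
#' @return Shannon index (>= 0).
#' @export
shannon <- function(counts, base = 2) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("negative count")
  total <- sum(counts)
  if (total <= 0) stop("all-zero sample has no diversity")
  p <- counts[counts > 0] / total
  -sum(p * log(p, base = base))
}

#' Chao1 richness estimate of one sample
#'
#' `S_obs + F1^2 / (2 F2)` where F1 and F2 count OTUs seen exactly once and
#' twice; when no doubletons exist the bias-corrected form
#' `S_obs + F1 (F1 - 1) / 2` is used. Always at least the observed
#' richness.
#'
#' @param counts non-negative count vector for one sample; at least one
#'   positive entry.
#' @return Chao1 estimate (>= observed richness).
#' @export
chao1 <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("negative count")
  if (sum(counts) <= 0) stop("all-zero sample has no richness")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' Per-sample alpha diversity table
#'
#' @param table an [otu_table].
#' @param base Shannon logarithm base.
#' @return Data frame `sample_id`, `observed`, `shannon`, `chao1`.
#' @export
alpha_diversity <- function(table, base = 2) {
  stopifnot(inherits(table, "otu_table"))
  data.frame(
    sample_id = table$sample_ids,
    observed = apply(table$counts, 1, function(x) sum(x > 0)),
    shannon = apply(table$counts, 1, shannon, base = base),
    chao1 = apply(table$counts, 1, chao1),
    stringsAsFactors = FALSE)
}

welch_t <- function(a, b) {
  se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
  d <- mean(a) - mean(b)
  if (se2 == 0) {
    if (d == 0) 0 else sign(d) * Inf
  } else {
    d / sqrt(se2)
  }
}

#' Monte-Carlo permutation t-test
#'
#' The "non-parametric t-test" of amplicon pipelines: the Welch t statistic
#' is computed on the observed labels, then on `n_perm` random relabellings
#' of the pooled values; the two-sided pseudo-p-value is
#' `(#\{|t_perm| >= |t_obs|\} + 1) / (n_perm + 1)`. When both groups are
#' constant and equal, t is defined as 0 and p as 1.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return List with `t` (observed Welch statistic) and `p`.
#' @export
permutation_t_test <- function(group_a, group_b, n_perm = 999, seed = 1) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2, n_perm >= 1)
  t_obs <- welch_t(group_a, group_b)
  if (t_obs == 0 && stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    return(list(t = 0, p = 1))
  }
  pooled <- c(group_a, group_b)
  na <- length(group_a)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample(pooled)
    t_perm <- welch_t(perm[seq_len(na)], perm[-seq_len(na)])
    if (abs(t_perm) >= abs(t_obs)) exceed <- exceed + 1L
  }
  list(t = t_obs, p = (exceed + 1) / (n_perm + 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control (via [stats::p.adjust]): sorted
#' ascending, `q_(i) = min_{j >= i} p_(j) m / j`, capped at 1 and returned
#' in the input order.
#'
#' @param pvalues numeric vector with values in (0, 1].
#' @return Adjusted q-values, same order.
#' @export
bh_adjust <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Compare alpha diversity between two treatment groups
#'
#' For each stratum (e.g. hypervariable region or study) and each diversity
#' metric, runs the permutation t-test between the two levels of
#' `group_col`, then adjusts all p-values together with Benjamini-Hochberg.
#'
#' @param table an [otu_table].
#' @param metadata per-sample metadata with `sample_id` and the grouping
#'   columns.
#' @param group_col metadata column holding the two-group contrast
#'   (default `"treatment"`).
#' @param strata_col optional metadata column to stratify by (e.g.
#'   `"region"`); `NULL` for a single pooled comparison.
#' @param metrics diversity metrics to compare.
#' @param n_perm,seed permutation settings.
#' @return Data frame with `stratum`, `metric`, group means, `t`, `p`, `q`.
#' @export
compare_alpha_diversity <- function(table, metadata, group_col = "treatment",
                                    strata_col = NULL,
                                    metrics = c("shannon", "chao1"),
                                    n_perm = 999, seed = 1) {
  div <- alpha_diversity(table)
  meta <- metadata[match(div$sample_id, metadata$sample_id), , drop = FALSE]
  groups <- unique(meta[[group_col]])
  if (length(groups) != 2) stop("group column must have exactly 2 levels")
  strata <- if (is.null(strata_col)) list(all = seq_len(nrow(div)))
            else split(seq_len(nrow(div)), meta[[strata_col]])
  rows <- list()
  for (s in names(strata)) {
    ix <- strata[[s]]
    for (m in metrics) {
      a <- div[[m]][ix][meta[[group_col]][ix] == groups[1]]
      b <- div[[m]][ix][meta[[group_col]][ix] == groups[2]]
      if (length(a) < 2 || length(b) < 2) next
      res <- permutation_t_test(a, b, n_perm = n_perm,
                                seed = derive_seed(seed, length(rows) + 1))
      rows[[length(rows) + 1]] <- data.frame(
        stratum = s, metric = m,
        mean_a = mean(a), mean_b = mean(b),
        group_a = groups[1], group_b = groups[2],
        t = res$t, p = res$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no stratum had >= 2 samples per group")
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
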