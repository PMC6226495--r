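#' Build the signed co-occurrence network
#'
#' An edge joins OTUs i and j exactly when `p[i, j] < p_threshold` AND
#' `|rho[i, j]| >= r_threshold` (defaults 0.05 and 0.3: significant
#' correlations, hiding magnitudes below 0.3). Edge sign is the sign of
#' rho. Isolated nodes are retained with degree 0, so downstream keystone
#' tables cover every OTU.
#'
#' @param corr a `correlation_result` with `pvalues` filled in (see
#'   [sparcc]), or a list with `rho` and `pvalues` matrices.
#' @param p_threshold significance cutoff in (0, 1].
#' @param r_threshold minimum |rho| in [0, 1).
#' @param labels optional taxonomy (from [parse_lineages]) supplying display
#'   labels for nodes.
#' @return An object of class `signed_network`: list with `nodes` (data
#'   frame `otu_id`, `label`), `edges` (data frame `source`, `target`,
#'   `rho`, `pvalue`, `sign`), and the thresholds used.
#' @export
build_network <- function(corr, p_threshold = 0.05, r_threshold = 0.3,
                          labels = NULL) {
  rho <- corr$rho
  pv <- corr$pvalues
  if (is.null(pv)) stop("correlation result has no p-values; run sparcc() or permutation_pvalues()")
  stopifnot(p_threshold > 0, p_threshold <= 1,
            r_threshold >= 0, r_threshold < 1)
  ids <- colnames(rho)
  if (is.null(ids)) ids <- sprintf("otu_%03d", seq_len(ncol(rho)))
  D <- length(ids)
  keep <- pv < p_threshold & abs(rho) >= r_threshold
  keep[upper.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(
    source = ids[idx[, 2]], target = ids[idx[, 1]],
    rho = rho[idx], pvalue = pv[idx],
    sign = ifelse(rho[idx] >= 0, "+", "-"),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  lab <- ids
  if (!is.null(labels)) {
    m <- match(ids, labels$otu_id)
    lab <- ifelse(is.na(m), ids, labels$display_label[m])
  }
  structure(
    list(nodes = data.frame(otu_id = ids, label = lab,
                            stringsAsFactors = FALSE),
         edges = edges, p_threshold = p_threshold,
         r_threshold = r_threshold),
    class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf(
    "signed_network: %d nodes, %d edges (%d positive, %d negative), p < %g, |rho| >= %g\n",
    nrow(x$nodes), nrow(x$edges), sum(x$edges$sign == "+"),
    sum(x$edges$sign == "-"), x$p_threshold, x$r_threshold))
  invisible(x)
}

#' Per-taxon association balance ("keystone") table
#'
#' For every node: its degree, the counts of positive and negative edges,
#' the negative:positive ratio (infinite when a node has only negative
#' edges), and the balance `(n_pos - n_neg) / (n_pos + n_neg)` in [-1, 1].
#' Balanced high-degree nodes — taxa with large numbers of both positive and
#' negative associations — are the candidate polarizing keystones. Rows are
#' ordered by descending degree, then id.
#'
#' @param net a [build_network] result.
#' @return Data frame with columns `otu_id`, `label`, `degree`, `n_pos`,
#'   `n_neg`, `neg_pos_ratio`, `balance`; ratio and balance are `NA` for
#'   isolated nodes.
#' @export
keystone_table <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  ids <- net$nodes$otu_id
  n_pos <- n_neg <- stats::setNames(numeric(length(ids)), ids)
  for (s in c("+", "-")) {
    e <- net$edges[net$edges$sign == s, , drop = FALSE]
    cnt <- table(c(e$source, e$target))
    if (s == "+") n_pos[names(cnt)] <- as.numeric(cnt)
    else n_neg[names(cnt)] <- as.numeric(cnt)
  }
  k <- n_pos + n_neg
  ratio <- ifelse(k == 0, NA_real_,
                  ifelse(n_pos == 0, Inf, n_neg / n_pos))
  balance <- ifelse(k == 0, NA_real_, (n_pos - n_neg) / k)
  out <- data.frame(otu_id = ids, label = net$nodes$label,
                    degree = as.numeric(k), n_pos = as.numeric(n_pos),
                    n_neg = as.numeric(n_neg), neg_pos_ratio = ratio,
                    balance = balance, stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$otu_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Identify polarizing hub taxa
#'
#' Operationalises the qualitative criterion "relatively large numbers of
#' both negative and positive associations": a hub must have degree at or
#' above the `degree_percentile`-th percentile of all positive degrees AND
#' an association balance within `balance_tolerance` of zero. Both knobs are
#' interpretive and exposed.
#'
#' @param records a [keystone_table] data frame.
#' @param degree_percentile percentile of positive degrees, in (0, 100);
#'   default 75 (top quartile).
#' @param balance_tolerance maximum |balance|, in [0, 1]; default 0.5.
#' @return The qualifying rows, sorted by descending degree.
#' @export
identify_polarizing_hubs <- function(records, degree_percentile = 75,
                                     balance_tolerance = 0.5) {
  stopifnot(degree_percentile > 0, degree_percentile < 100,
            balance_tolerance >= 0, balance_tolerance <= 1)
  pos <- records$degree[records$degree > 0]
  if (!length(pos)) return(records[0, , drop = FALSE])
  k_cut <- stats::quantile(pos, degree_percentile / 100, names = FALSE)
  hits <- records$degree > 0 & records$degree >= k_cut &
    !is.na(records$balance) & abs(records$balance) <= balance_tolerance
  out <- records[hits, , drop = FALSE]
  out <- out[order(-out$degree, out$otu_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Discrete power-law fit of the degree distribution
#'
#' Scale-free networks have degree tails following `P(k) ~ k^-alpha`. The
#' exponent is estimated by the discrete maximum-likelihood approximation
#' `alpha = 1 + n_tail / sum(log(k_i / (k_min - 0.5)))` over nodes with
#' `k >= k_min`; as a descriptive, the R-squared of the least-squares line
#' through the log-log complementary cumulative distribution is also
#' reported. The `k_min - 0.5` continuous approximation is accurate for
#' `k_min` of a few and above; at `k_min = 1` it underestimates steep
#' exponents, so recovery checks use a higher cutoff.
#'
#' @param net a [build_network] result, or a numeric vector of degrees.
#' @param k_min lower cutoff of the fitted tail (>= 1).
#' @return List of class `power_law_fit`: `alpha`, `k_min`, `n_tail`,
#'   `loglog_r2`.
#' @export
fit_power_law <- function(net, k_min = 1) {
  degrees <- if (inherits(net, "signed_network")) {
    keystone_table(net)$degree
  } else {
    as.numeric(net)
  }
  stopifnot(k_min >= 1)
  tail_k <- degrees[degrees >= k_min]
  if (length(tail_k) < 10) {
    stop(sprintf("insufficient tail: only %d node(s) with degree >= %d (need >= 10)",
                 length(tail_k), k_min))
  }
  n_tail <- length(tail_k)
  alpha <- 1 + n_tail / sum(log(tail_k / (k_min - 0.5)))
  # complementary cumulative frequency on the distinct tail degrees
  ks <- sort(unique(tail_k))
  ccdf <- vapply(ks, function(k) mean(tail_k >= k), numeric(1))
  r2 <- if (length(ks) >= 3) {
    fit <- stats::lm(log(ccdf) ~ log(ks))
    summary(fit)$r.squared
  } else NA_real_
  structure(list(alpha = alpha, k_min = k_min, n_tail = n_tail,
                 loglog_r2 = r2),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power_law_fit: alpha = %.3f (k_min = %d, n_tail = %d, log-log R2 = %s)\n",
              x$alpha, x$k_min, x$n_tail,
              ifelse(is.na(x$loglog_r2), "NA", sprintf("%.3f", x$loglog_r2))))
  invisible(x)
}

#' Sample from a discrete power law
#'
#' Exact inverse-transform draws of integer degrees `k >= k_min` with
#' `P(k) = k^-alpha / zeta(alpha, k_min)`, used to validate
#' [fit_power_law] by round-trip. The CDF is tabulated up to 1e6; for
#' `alpha > 2` the probability mass beyond that point is negligible
#' (draws there are clamped).
#'
#' @param n number of draws.
#' @param alpha exponent (> 1).
#' @param k_min minimum degree (>= 1).
#' @param seed RNG seed.
#' @return Integer vector of length `n`.
#' @export
rpowerlaw_discrete <- function(n, alpha, k_min = 1, seed = 1) {
  stopifnot(alpha > 1, k_min >= 1)
  set.seed(seed)
  k <- seq.int(k_min, 1e6)
  pr <- k^(-alpha)
  cdf <- cumsum(pr) / sum(pr)
  k[findInterval(stats::runif(n), cdf) + 1]
}
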