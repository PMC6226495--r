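# Derive a child seed from a user seed and a stage counter, staying inside
# 32-bit integer range so set.seed() accepts it on every platform.
derive_seed <- function(seed, k) {
  x <- ((as.double(seed) %% 2147483647) * 48271 + as.double(k)) %% 2147483647
  as.integer(x)
}

#' Dirichlet resampling of component fractions
#'
#' Sequencing counts are a noisy multinomial readout of unobserved relative
#' abundances. Rather than using raw proportions (undefined log-ratios at
#' zero counts), each round draws per-sample fractions from the Dirichlet
#' posterior with parameters `counts + 1` (uniform prior), which guarantees
#' strictly positive fractions summing to one.
#'
#' @param table an [otu_table]. A zero-depth (all-zero) sample is
#'   admissible: its posterior is the uniform Dirichlet(1, ..., 1).
#' @param rounds number of resampling rounds (>= 1).
#' @param seed RNG seed; draws are deterministic given it.
#' @return A list of class `fraction_draws` with `fractions`, an array of
#'   dimension `rounds x samples x OTUs`, and `rounds`.
#' @export
estimate_fractions <- function(table, rounds, seed = 1) {
  stopifnot(inherits(table, "otu_table"), rounds >= 1)
  n <- nrow(table$counts); D <- ncol(table$counts)
  out <- array(NA_real_, c(rounds, n, D))
  set.seed(seed)
  shape <- table$counts + 1
  for (r in seq_len(rounds)) {
    g <- matrix(stats::rgamma(n * D, shape = shape), n, D)
    out[r, , ] <- g / rowSums(g)
  }
  structure(list(fractions = out, rounds = rounds), class = "fraction_draws")
}

#' Log-ratio variance matrix
#'
#' For one round of fraction draws, computes the symmetric matrix
#' `t[i, j] = Var_s(log(f_i / f_j))` (unbiased sample variance over samples),
#' the quantity from which basis correlations are decomposed. Zero exactly
#' when two components are perfectly proportional.
#'
#' @param fractions samples x OTUs matrix of positive fractions (one round).
#' @return D x D symmetric non-negative matrix with zero diagonal.
#' @export
log_ratio_variance <- function(fractions) {
  fractions <- as.matrix(fractions)
  if (nrow(fractions) < 2) stop("log-ratio variance needs >= 2 samples")
  if (any(fractions <= 0)) stop("fractions must be strictly positive")
  lf <- log(fractions)
  V <- stats::cov(lf)             # unbiased, so t inherits unbiasedness
  d <- diag(V)
  t_mat <- outer(d, d, "+") - 2 * V
  t_mat <- pmax((t_mat + t(t_mat)) / 2, 0)
  diag(t_mat) <- 0
  t_mat
}

#' Solve for basis variances under the sparsity approximation
#'
#' Assuming most pairs are uncorrelated, `t[i, j] ~ omega_i + omega_j`, so
#' the row sums `t_i` satisfy a linear system in the per-OTU basis variances
#' omega. With no exclusions the closed form is
#' `omega_i = (t_i - Omega) / (D - 2)` with
#' `Omega = sum(t_i) / (2 (D - 1))`; when strongly correlated pairs have
#' been excluded, the corresponding unit entries are dropped from the system
#' matrix and it is solved directly. Negative solutions (sparsity
#' approximation violated) are clamped to 1e-12 and flagged.
#'
#' @param t_mat log-ratio variance matrix from [log_ratio_variance].
#' @param excluded optional 2-column matrix of excluded pair indices.
#' @return A list with `omega` (per-OTU basis variance, clamped),
#'   `omega_raw` (the unclamped linear-system solution) and `flagged`
#'   (logical, clamped entries).
#' @export
solve_basis_variances <- function(t_mat, excluded = NULL) {
  D <- nrow(t_mat)
  if (is.null(excluded) || NROW(excluded) == 0) {
    t_i <- rowSums(t_mat)
    Omega <- sum(t_i) / (2 * (D - 1))
    omega <- (t_i - Omega) / (D - 2)
  } else {
    excluded <- as.matrix(excluded)
    active <- matrix(TRUE, D, D)
    diag(active) <- FALSE
    for (r in seq_len(nrow(excluded))) {
      i <- excluded[r, 1]; j <- excluded[r, 2]
      active[i, j] <- FALSE; active[j, i] <- FALSE
    }
    n_partner <- rowSums(active)
    if (any(n_partner < 1)) {
      stop("singular system: all pairs excluded for OTU ",
           which(n_partner < 1)[1])
    }
    M <- active * 1
    diag(M) <- n_partner
    t_i <- rowSums(t_mat * active)
    omega <- as.numeric(solve(M, t_i))
  }
  flagged <- omega < 0
  omega_raw <- omega
  omega[flagged] <- 1e-12
  list(omega = omega, omega_raw = omega_raw, flagged = flagged)
}

#' Basis correlations from log-ratio variances and basis variances
#'
#' `rho[i, j] = (omega_i + omega_j - t[i, j]) / (2 sqrt(omega_i omega_j))`,
#' clipped to `[-1, 1]`, with unit diagonal.
#'
#' @param t_mat log-ratio variance matrix.
#' @param omega per-OTU basis variances (all > 0).
#' @return Symmetric D x D correlation estimate.
#' @export
correlations_from_variances <- function(t_mat, omega) {
  stopifnot(all(omega > 0))
  s <- sqrt(omega)
  rho <- (outer(omega, omega, "+") - t_mat) / (2 * tcrossprod(s))
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  rho
}

# One complete pass: fractions for one round -> t -> iterative exclusion of
# the strongest pairs -> rho. Returns rho, omega, exclusions, flags.
sparcc_single_round <- function(frac, exclusion_threshold,
                                exclusion_iterations) {
  D <- ncol(frac)
  t_mat <- log_ratio_variance(frac)
  excluded <- matrix(integer(0), 0, 2)
  n_partner <- rep(D - 1, D)
  sol <- solve_basis_variances(t_mat, excluded)
  rho <- correlations_from_variances(t_mat, sol$omega)
  iter <- 0
  while (iter < exclusion_iterations) {
    cand <- abs(rho)
    cand[upper.tri(cand, diag = TRUE)] <- 0
    if (nrow(excluded)) cand[excluded] <- 0
    # never drop an OTU below 3 retained partners
    low <- n_partner <= 3
    cand[low, ] <- 0; cand[, low] <- 0
    top <- which.max(cand)
    if (cand[top] <= exclusion_threshold) break
    ij <- arrayInd(top, dim(cand))
    excluded <- rbind(excluded, c(ij[1], ij[2]))
    n_partner[ij] <- n_partner[ij] - 1
    sol <- solve_basis_variances(t_mat, excluded)
    rho <- correlations_from_variances(t_mat, sol$omega)
    iter <- iter + 1
  }
  list(rho = rho, omega = sol$omega, flagged = sol$flagged,
       excluded = excluded)
}

#' Infer basis correlations from a compositional count table
#'
#' The full point-estimation procedure: for each resampling round, draw
#' Dirichlet fractions, compute log-ratio variances, iteratively exclude
#' (up to `exclusion_iterations` times) the currently strongest-|rho| pair
#' exceeding `exclusion_threshold` — re-solving the basis variances after
#' each exclusion — and form the round's correlation estimate. The final
#' `rho` is the element-wise median across rounds; exclusions are reported
#' from the final round.
#'
#' @param table an [otu_table] with at least 4 OTUs.
#' @param rounds Dirichlet resampling rounds for the point estimate
#'   (default 20).
#' @param exclusion_threshold |rho| above which a pair violates the sparsity
#'   assumption and is excluded (default 0.1).
#' @param exclusion_iterations maximum exclusions per round (default 10).
#' @param seed RNG seed.
#' @return An object of class `correlation_result`: list with `rho`,
#'   `basis_var`, `excluded_pairs`, `flagged`, `otu_ids`, and `pvalues`
#'   (NULL until [permutation_pvalues] is run).
#' @export
infer_correlations <- function(table, rounds = 20, exclusion_threshold = 0.1,
                               exclusion_iterations = 10, seed = 1) {
  stopifnot(inherits(table, "otu_table"))
  D <- ncol(table$counts)
  if (D < 4) stop("correlation inference needs D >= 4 OTUs")
  draws <- estimate_fractions(table, rounds, seed = derive_seed(seed, 1))
  rhos <- array(NA_real_, c(rounds, D, D))
  omegas <- matrix(NA_real_, rounds, D)
  flagged <- rep(FALSE, D)
  excluded <- matrix(integer(0), 0, 2)
  for (r in seq_len(rounds)) {
    res <- sparcc_single_round(draws$fractions[r, , ],
                               exclusion_threshold, exclusion_iterations)
    rhos[r, , ] <- res$rho
    omegas[r, ] <- res$omega
    flagged <- flagged | res$flagged
    excluded <- res$excluded
  }
  rho <- apply(rhos, c(2, 3), stats::median)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  dimnames(rho) <- list(table$otu_ids, table$otu_ids)
  structure(
    list(rho = rho,
         basis_var = stats::setNames(apply(omegas, 2, stats::median),
                                     table$otu_ids),
         excluded_pairs = excluded, flagged = flagged,
         otu_ids = table$otu_ids, pvalues = NULL,
         params = list(rounds = rounds,
                       exclusion_threshold = exclusion_threshold,
                       exclusion_iterations = exclusion_iterations,
                       seed = seed)),
    class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  off <- x$rho[lower.tri(x$rho)]
  cat(sprintf(
    "correlation_result: %d OTUs, median |rho| %.3f, max |rho| %.3f, %d pair(s) excluded%s\n",
    length(x$otu_ids), stats::median(abs(off)), max(abs(off)),
    nrow(x$excluded_pairs),
    if (is.null(x$pvalues)) ", no p-values yet" else ""))
  invisible(x)
}

#' Permutation pseudo-p-values for inferred correlations
#'
#' Each of `B` null datasets permutes every OTU's counts across samples
#' independently — preserving marginal distributions while destroying
#' association — and re-infers correlations (one resampling round per null
#' for cost). Two-sided pseudo-p-values use the add-one correction
#' `p = (#\{b : |rho_b| >= |rho_obs|\} + 1) / (B + 1)`, so p is never 0.
#'
#' @param table the [otu_table] the observed correlations came from.
#' @param observed_rho observed correlation matrix (or a
#'   `correlation_result`).
#' @param B number of null datasets (default 100).
#' @param seed RNG seed.
#' @param exclusion_threshold,exclusion_iterations as in
#'   [infer_correlations]; applied to each null inference.
#' @return Symmetric matrix of p-values in (0, 1], diagonal 1. If
#'   `observed_rho` is a `correlation_result`, that object is returned with
#'   `pvalues` filled in.
#' @export
permutation_pvalues <- function(table, observed_rho, B = 100, seed = 1,
                                exclusion_threshold = 0.1,
                                exclusion_iterations = 10) {
  stopifnot(inherits(table, "otu_table"), B >= 1)
  result <- NULL
  if (inherits(observed_rho, "correlation_result")) {
    result <- observed_rho
    observed_rho <- result$rho
  }
  n <- nrow(table$counts); D <- ncol(table$counts)
  abs_obs <- abs(observed_rho)
  exceed <- matrix(0, D, D)
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, 1000 + b))
    perm <- apply(table$counts, 2, sample)
    null_tab <- otu_table(perm,
                          sample_ids = table$sample_ids,
                          otu_ids = table$otu_ids)
    null_res <- infer_correlations(
      null_tab, rounds = 1,
      exclusion_threshold = exclusion_threshold,
      exclusion_iterations = exclusion_iterations,
      seed = derive_seed(seed, 2000 + b))
    exceed <- exceed + (abs(null_res$rho) >= abs_obs)
  }
  p <- (exceed + 1) / (B + 1)
  p <- pmin(p, 1)
  p <- (p + t(p)) / 2
  diag(p) <- 1
  dimnames(p) <- dimnames(observed_rho)
  if (!is.null(result)) {
    result$pvalues <- p
    return(result)
  }
  p
}

#' Run the full correlation inference with p-values
#'
#' Convenience wrapper: [infer_correlations] followed by
#' [permutation_pvalues], each on its own seed stream derived from `seed`.
#'
#' @inheritParams infer_correlations
#' @param B permutation null datasets for the p-values.
#' @return A `correlation_result` with `pvalues` filled in.
#' @export
sparcc <- function(table, rounds = 20, B = 100, exclusion_threshold = 0.1,
                   exclusion_iterations = 10, seed = 1) {
  res <- infer_correlations(table, rounds = rounds,
                            exclusion_threshold = exclusion_threshold,
                            exclusion_iterations = exclusion_iterations,
                            seed = derive_seed(seed, 11))
  permutation_pvalues(table, res, B = B, seed = derive_seed(seed, 12),
                      exclusion_threshold = exclusion_threshold,
                      exclusion_iterations = exclusion_iterations)
}
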