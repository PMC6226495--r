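test_that("Dirichlet resampling has the posterior mean and stays positive", {
  tab <- make_table(matrix(c(0, 0), 1, 2))
  draws <- estimate_fractions(tab, rounds = 2000, seed = 4)
  # counts (0,0) -> Dirichlet(1,1): each fraction has mean 1/2
  expect_lt(abs(mean(draws$fractions[, 1, 1]) - 0.5), 0.03)

  skew <- make_table(matrix(c(999999, 0), 1, 2))
  d2 <- estimate_fractions(skew, rounds = 50, seed = 1)
  expect_true(all(d2$fractions > 0))
  expect_true(all(abs(apply(d2$fractions, c(1, 2), sum) - 1) < 1e-9))

  a <- estimate_fractions(tab, rounds = 5, seed = 11)
  b <- estimate_fractions(tab, rounds = 5, seed = 11)
  expect_identical(a$fractions, b$fractions)
})

test_that("log-ratio variances match hand computations and are order-invariant", {
  # perfectly proportional components: t = 0
  f <- cbind(c(0.2, 0.1, 0.3), c(0.4, 0.2, 0.6))
  f <- f / rowSums(f)
  t_mat <- log_ratio_variance(f)
  expect_equal(t_mat[1, 2], 0)
  expect_equal(diag(t_mat), c(0, 0))

  # two samples with log-ratio values {0, 2}: unbiased variance is 2
  g <- rbind(c(0.5, 0.5), c(exp(2) / (1 + exp(2)), 1 / (1 + exp(2))))
  t2 <- log_ratio_variance(g)
  expect_equal(t2[1, 2], 2, tolerance = 1e-12)

  h <- matrix(stats::runif(40, 0.01, 1), 8, 5)
  h <- h / rowSums(h)
  expect_equal(log_ratio_variance(h), log_ratio_variance(h[8:1, ]))
  expect_error(log_ratio_variance(h[1, , drop = FALSE]), "2 samples")
})

test_that("basis-variance solve matches closed forms and a dense oracle", {
  t3 <- matrix(2, 3, 3); diag(t3) <- 0
  expect_equal(solve_basis_variances(t3)$omega, c(1, 1, 1))
  t4 <- matrix(2, 4, 4); diag(t4) <- 0
  expect_equal(solve_basis_variances(t4)$omega, c(1, 1, 1, 1))

  set.seed(60)
  for (rep in 1:20) {
    D <- 6
    t_mat <- matrix(0, D, D)
    t_mat[upper.tri(t_mat)] <- stats::runif(D * (D - 1) / 2, 0.1, 4)
    t_mat <- t_mat + t(t_mat)
    omega <- solve_basis_variances(t_mat)$omega_raw
    # independent oracle: build the dense system matrix from its definition
    M <- matrix(1, D, D); diag(M) <- D - 1
    oracle <- solve(M, rowSums(t_mat))
    expect_lt(max(abs(omega - oracle)), 1e-10)
  }

  # exclusions drop unit entries from the system
  excl <- matrix(c(1, 2), 1, 2)
  t6 <- matrix(2, 6, 6); diag(t6) <- 0
  sol <- solve_basis_variances(t6, excl)
  active <- matrix(TRUE, 6, 6); diag(active) <- FALSE
  active[1, 2] <- active[2, 1] <- FALSE
  M <- active * 1; diag(M) <- rowSums(active)
  expect_equal(sol$omega, as.numeric(solve(M, rowSums(t6 * active))),
               tolerance = 1e-12)
  all_excl <- cbind(1, 2:6)
  expect_error(solve_basis_variances(t6, all_excl), "singular")
})

test_that("correlation back-transform applies the closed form with clipping", {
  t_mat <- matrix(0, 2, 2)
  t_mat[1, 2] <- t_mat[2, 1] <- 2
  expect_equal(correlations_from_variances(t_mat, c(1, 1))[1, 2], 0)
  t_mat[1, 2] <- t_mat[2, 1] <- 0
  expect_equal(correlations_from_variances(t_mat, c(1, 1))[1, 2], 1)
  t_mat[1, 2] <- t_mat[2, 1] <- 5
  r <- correlations_from_variances(t_mat, c(1, 1))
  expect_equal(r[1, 2], -1)   # raw -1.5 clipped
  expect_equal(diag(r), c(1, 1))
  expect_error(correlations_from_variances(t_mat, c(1, 0)))
})

test_that("inference recovers a planted pair and is reproducible", {
  spec <- plant_patterns(synthetic_spec(D = 12, seed = 21,
                                        depth_preset = "depth-miseq"),
                         list(c(3, 7)), 0.8)
  com <- generate_community(spec, 200)
  res <- infer_correlations(com$table, rounds = 5, seed = 21)
  off <- abs(res$rho); diag(off) <- 0
  expect_equal(sort(arrayInd(which.max(off), dim(off))), c(3, 7))
  expect_lt(abs(res$rho[3, 7] - 0.8), 0.2)

  r1 <- infer_correlations(com$table, rounds = 1, seed = 5)
  r2 <- infer_correlations(com$table, rounds = 1, seed = 5)
  expect_identical(r1$rho, r2$rho)
  expect_true(all(abs(r1$rho) <= 1))
  expect_equal(r1$rho, t(r1$rho))
  expect_error(infer_correlations(make_table(matrix(1:6, 2, 3)), 1),
               "D >= 4")
})

test_that("the deterministic chain is equivariant to OTU relabelling", {
  set.seed(8)
  f <- matrix(stats::runif(60, 0.01, 1), 10, 6)
  f <- f / rowSums(f)
  perm <- c(4, 1, 6, 2, 5, 3)
  t_mat <- log_ratio_variance(f)
  t_perm <- log_ratio_variance(f[, perm])
  expect_equal(t_perm, t_mat[perm, perm], tolerance = 1e-12)
  om <- solve_basis_variances(t_mat)$omega
  om_perm <- solve_basis_variances(t_perm)$omega
  expect_equal(om_perm, om[perm], tolerance = 1e-12)
  rho <- correlations_from_variances(t_mat, pmax(om, 1e-12))
  rho_perm <- correlations_from_variances(t_perm, pmax(om_perm, 1e-12))
  expect_equal(rho_perm, rho[perm, perm], tolerance = 1e-12)
})

test_that("correlations are insensitive to per-sample count scaling at high depth", {
  spec <- plant_patterns(synthetic_spec(D = 10, seed = 2,
                                        depth_low = 100000,
                                        depth_high = 100000),
                         list(c(1, 2)), 0.7)
  com <- generate_community(spec, 80)
  scaled <- otu_table(com$table$counts * 3)
  r1 <- infer_correlations(com$table, rounds = 3, seed = 9)$rho
  r2 <- infer_correlations(scaled, rounds = 3, seed = 9)$rho
  expect_lt(max(abs(r1 - r2)), 0.05)
})

test_that("permutation p-values follow the add-one pseudo-count formula", {
  # a perfectly coupled pair (log-normal abundance, wide dynamic range) is
  # never matched by a null permutation: p must equal 1/(B+1)
  set.seed(1)
  base <- round(exp(stats::rnorm(60, 5, 1.2))) + 1
  tab <- make_table(cbind(base, base,
                          round(exp(stats::rnorm(60, 5, 1.2))) + 1,
                          round(exp(stats::rnorm(60, 5, 1.2))) + 1))
  res <- infer_correlations(tab, rounds = 3, seed = 13)
  expect_gt(res$rho[1, 2], 0.9)
  p <- permutation_pvalues(tab, res, B = 19, seed = 13)$pvalues
  expect_equal(p[1, 2], 1 / 20)
  expect_true(all(p > 0 & p <= 1))
  expect_equal(p, t(p))
  # determinism of the whole wrapper
  s1 <- sparcc(tab, rounds = 2, B = 5, seed = 3)
  s2 <- sparcc(tab, rounds = 2, B = 5, seed = 3)
  expect_identical(s1$pvalues, s2$pvalues)
  expect_identical(s1$rho, s2$rho)
})
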