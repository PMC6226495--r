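unit_triangle <- function(offset = 0, ids = NULL) {
  adj_from_edges(3, list(c(1, 2), c(1, 3), c(2, 3)), ids = ids)
}

test_that("cohesiveness evaluates its defining formula", {
  tri <- unit_triangle()
  expect_equal(cohesiveness(tri, c("n01", "n02", "n03"), penalty = 0), 1)
  expect_equal(cohesiveness(tri, 1:3, penalty = 2), 3 / (3 + 6))
  # pair with one internal 0.5 edge and one 0.5 boundary edge
  adj <- adj_from_edges(3, list(c(1, 2, 0.5), c(2, 3, 0.5)))
  expect_equal(cohesiveness(adj, 1:2, penalty = 0), 0.5)
  expect_equal(cohesiveness(adj, integer(0), penalty = 0), 0)
  expect_equal(cohesiveness(adj_from_edges(2, list()), 1, penalty = 0), 0)
  expect_error(cohesiveness(tri, "nope"), "unknown node")
})

test_that("greedy growth finds isolated optima and stays local elsewhere", {
  # isolated triangle: unique optimum at penalty 0
  big <- matrix(0, 5, 5, dimnames = list(sprintf("n%02d", 1:5),
                                         sprintf("n%02d", 1:5)))
  big[1:3, 1:3] <- unit_triangle()
  cl <- grow_cluster(big, "n02", penalty = 0)
  expect_setequal(cl$members, c("n01", "n02", "n03"))
  expect_equal(cl$cohesiveness, 1)

  # two triangles joined by one light edge: growth stays in the seed's
  # triangle (a local optimum; the exhaustive global optimum containing
  # the seed is the boundary-free whole graph, and greedy stays within
  # the tested 0.8 factor of it)
  two <- adj_from_edges(6, list(c(1, 2), c(1, 3), c(2, 3), c(4, 5),
                                c(4, 6), c(5, 6), c(3, 4, 0.1)))
  cl2 <- grow_cluster(two, "n01", penalty = 0)
  expect_setequal(cl2$members, c("n01", "n02", "n03"))
  expect_equal(cl2$cohesiveness, 3 / 3.1, tolerance = 1e-12)
  best <- best_cohesiveness_with_seed(two, 1, penalty = 0)
  expect_gte(cl2$cohesiveness, 0.8 * best)

  # isolated node: singleton with zero cohesiveness
  iso <- adj_from_edges(4, list(c(1, 2)))
  cl3 <- grow_cluster(iso, "n04", penalty = 0)
  expect_equal(cl3$members, "n04")
  expect_equal(cl3$cohesiveness, 0)
})

test_that("every grown cluster is a single-move local optimum", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(4:7, 1)
    adj <- random_connected_adj(n, stats::runif(1, 0.3, 0.8))
    cl <- grow_cluster(adj, sample(rownames(adj), 1), penalty = 2)
    idx <- match(cl$members, rownames(adj))
    score <- cl$cohesiveness
    coh <- function(members) cecanet::cohesiveness(adj, members, penalty = 2)
    for (v in setdiff(seq_len(n), idx)) {
      expect_lte(coh(c(idx, v)), score + 1e-9)
    }
    if (length(idx) > 1) {
      for (v in idx) expect_lte(coh(setdiff(idx, v)), score + 1e-9)
    }
  }
})

test_that("match coefficient and inter-cluster score follow their formulas", {
  expect_equal(match_coefficient(letters[1:4], letters[1:4]), 1)
  expect_equal(match_coefficient(c("a", "b"), c("x", "y")), 0)
  expect_equal(match_coefficient(c("a", "b", "c", "d"), c("a", "b")), 0.5)
  expect_equal(match_coefficient(c("a", "b", "c", "d"),
                                 c("a", "b", "c", "e")), 9 / 16)
  expect_error(match_coefficient(character(0), "a"))

  rho <- diag(3)
  dimnames(rho) <- list(c("a", "b", "c"), c("a", "b", "c"))
  rho["a", "c"] <- rho["c", "a"] <- 0.4
  rho["b", "c"] <- rho["c", "b"] <- -0.2
  expect_equal(inter_cluster_score(rho, c("a", "b"), "c"), 0.1)
  # reflexive use: mean of within-cluster off-diagonal entries
  rho["a", "b"] <- rho["b", "a"] <- 0.6
  expect_equal(inter_cluster_score(rho, c("a", "b", "c"), c("a", "b", "c")),
               mean(c(0.6, 0.4, -0.2)))
  zero <- matrix(0, 3, 3, dimnames = dimnames(rho)); diag(zero) <- 1
  expect_equal(inter_cluster_score(zero, c("a", "b"), c("c", "b")),
               0)
})

test_that("cluster detection separates components and enforces filters", {
  two <- matrix(0, 6, 6, dimnames = list(sprintf("n%02d", 1:6),
                                         sprintf("n%02d", 1:6)))
  two[1:3, 1:3] <- unit_triangle()
  two[4:6, 4:6] <- unit_triangle()
  cs <- detect_clusters(two, penalty = 0)
  expect_length(cs$clusters, 2)
  expect_setequal(lapply(cs$clusters, `[[`, "members"),
                  list(c("n01", "n02", "n03"), c("n04", "n05", "n06")))
  expect_equal(vapply(cs$clusters, `[[`, numeric(1), "cohesiveness"),
               c(1, 1))
  expect_equal(cs$cluster_graph$shared_taxa, 0)

  # min_size filter removes pairs; empty graph yields empty set
  pair <- adj_from_edges(2, list(c(1, 2)))
  expect_length(detect_clusters(pair, penalty = 0)$clusters, 0)
  expect_length(detect_clusters(matrix(0, 0, 0))$clusters, 0)

  # min_density: a sparse ring of 6 has density 6/15 = 0.4 > 0.3 but a
  # ring of 8 has 8/28 < 0.3 and is discarded at the default threshold
  ring8 <- adj_from_edges(8, lapply(1:8, function(i) c(i, i %% 8 + 1)))
  cs8 <- detect_clusters(ring8, penalty = 0, min_density = 0.3)
  expect_length(cs8$clusters, 0)
  for (cl in detect_clusters(ring8, penalty = 0, min_density = 0)$clusters) {
    expect_gte(length(cl$members), 3)
  }
})

test_that("cluster detection is equivariant to node relabelling", {
  set.seed(77)
  adj <- random_connected_adj(7, 0.5)
  perm <- sample(7)
  relabelled <- adj[perm, perm]
  map <- stats::setNames(rownames(adj)[perm], rownames(relabelled))
  a <- detect_clusters(adj, penalty = 2, min_density = 0)
  b <- detect_clusters(relabelled, penalty = 2, min_density = 0)
  a_sets <- lapply(a$clusters, `[[`, "members")
  b_sets <- lapply(b$clusters, function(cl) sort(unname(map[cl$members])))
  expect_setequal(a_sets, b_sets)
})

test_that("retained clusters never overlap at or above the merge threshold", {
  set.seed(101)
  for (rep in 1:10) {
    adj <- random_connected_adj(8, 0.4)
    cs <- detect_clusters(adj, penalty = 2, merge_threshold = 0.8,
                          min_size = 2, min_density = 0)
    sets <- lapply(cs$clusters, `[[`, "members")
    if (length(sets) >= 2) {
      for (i in seq_along(sets)) for (j in seq_along(sets)) {
        if (j > i) expect_lt(match_coefficient(sets[[i]], sets[[j]]), 0.8)
      }
    }
  }
})
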