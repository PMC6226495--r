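#' Specify a synthetic compositional community
#'
#' Defines the generative model under which log-ratio correlation inference
#' is consistent: per sample, log basis abundances are drawn from a
#' multivariate normal with correlation `basis_corr`, exponentiated and
#' normalised to fractions, and integer counts are drawn multinomially at a
#' uniform random depth. `basis_corr` is the ground truth every downstream
#' recovery test compares against.
#'
#' Two depth presets mirror the platform contrast of real surveys (MiSeq
#' runs are roughly 20x deeper than 454): `depth_preset = "depth-454"` sets
#' bounds [1000, 3000], `"depth-miseq"` sets [20000, 60000].
#'
#' @param D number of OTUs (>= 2).
#' @param basis_corr D x D symmetric positive-semidefinite correlation
#'   matrix with unit diagonal; defaults to the identity (independent taxa).
#' @param log_mean,log_sd mean and standard deviation of the log basis
#'   abundances, recycled to length D; `log_sd` must be positive.
#' @param depth_low,depth_high inclusive uniform bounds for per-sample read
#'   depth; `depth_low` must be >= 100.
#' @param depth_preset optional `"depth-454"` or `"depth-miseq"`, overriding
#'   the explicit bounds.
#' @param seed integer RNG seed; generation is deterministic given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(D, basis_corr = diag(D), log_mean = 0,
                           log_sd = 1, depth_low = 1000, depth_high = 3000,
                           depth_preset = NULL, seed = 1) {
  if (!is.null(depth_preset)) {
    preset <- match.arg(depth_preset, c("depth-454", "depth-miseq"))
    if (preset == "depth-454") { depth_low <- 1000; depth_high <- 3000 }
    else { depth_low <- 20000; depth_high <- 60000 }
  }
  stopifnot(D >= 2, depth_low >= 100, depth_high >= depth_low)
  basis_corr <- as.matrix(basis_corr)
  check_correlation_matrix(basis_corr, D)
  log_mean <- rep_len(log_mean, D)
  log_sd <- rep_len(log_sd, D)
  if (any(log_sd <= 0)) stop("log_sd must be > 0")
  structure(
    list(D = D, basis_corr = basis_corr, log_mean = log_mean,
         log_sd = log_sd, depth_low = depth_low, depth_high = depth_high,
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

check_correlation_matrix <- function(m, D, tol = 1e-8) {
  if (nrow(m) != D || ncol(m) != D) stop("basis_corr must be D x D")
  if (max(abs(m - t(m))) > tol) stop("basis_corr must be symmetric")
  if (max(abs(diag(m) - 1)) > tol) stop("basis_corr must have unit diagonal")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stop(sprintf("basis_corr is not positive semidefinite (min eigenvalue %g)",
                 min(ev)))
  }
  invisible(TRUE)
}

#' Plant correlated OTU sets into a synthetic spec
#'
#' Sets the off-diagonal entries of `basis_corr` inside each member set to
#' `within_corr`, creating blocks of co-occurring OTUs that clustering should
#' recover. If the edit breaks positive semidefiniteness the matrix is
#' repaired by clipping negative eigenvalues at zero and re-normalising to
#' unit diagonal; the repaired matrix is the ground truth reported back.
#'
#' @param spec a [synthetic_spec].
#' @param member_sets list of integer vectors of OTU indices (each >= 2
#'   members).
#' @param within_corr target correlation inside each set, in (0, 1);
#'   recycled over sets.
#' @return A new `synthetic_spec` with the planted (and possibly repaired)
#'   `basis_corr`, plus a `planted_sets` element.
#' @export
plant_patterns <- function(spec, member_sets, within_corr) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.list(member_sets)) member_sets <- list(member_sets)
  within_corr <- rep_len(within_corr, length(member_sets))
  if (any(within_corr <= 0 | within_corr >= 1)) {
    stop("within_corr must lie in (0, 1)")
  }
  m <- spec$basis_corr
  assigned <- matrix(NA_real_, spec$D, spec$D)
  for (k in seq_along(member_sets)) {
    set <- sort(unique(as.integer(member_sets[[k]])))
    if (length(set) < 2) stop("member sets need >= 2 OTUs")
    if (any(set < 1 | set > spec$D)) stop("member set index out of range")
    for (i in set) for (j in set) {
      if (i == j) next
      if (!is.na(assigned[i, j]) && assigned[i, j] != within_corr[k]) {
        stop(sprintf(
          "overlapping member sets request contradictory values for pair (%d, %d)",
          i, j))
      }
      assigned[i, j] <- within_corr[k]
      m[i, j] <- within_corr[k]
    }
  }
  ev <- eigen(m, symmetric = TRUE)
  if (min(ev$values) < 0) {
    vals <- pmax(ev$values, 0)
    m <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(m))
    m <- m / tcrossprod(d)
  }
  m <- (m + t(m)) / 2
  diag(m) <- 1
  out <- spec
  out$basis_corr <- m
  out$planted_sets <- lapply(member_sets, function(s) sort(unique(as.integer(s))))
  out
}

#' Generate a synthetic compositional count table
#'
#' Draws, for each sample, log basis abundances from
#' `MVN(log_mean, diag(log_sd) %*% basis_corr %*% diag(log_sd))`,
#' exponentiates, normalises to fractions summing to 1, draws an integer
#' depth uniformly in `[depth_low, depth_high]`, and draws counts from a
#' multinomial at that depth. Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec].
#' @param n_samples number of samples (>= 2).
#' @return A list with `table` (an [otu_table]), `basis_corr` (the ground
#'   truth), `fractions` (the latent per-sample fraction matrix), and
#'   `planted_sets` if any were planted.
#' @export
generate_community <- function(spec, n_samples) {
  stopifnot(inherits(spec, "synthetic_spec"), n_samples >= 2)
  D <- spec$D
  sigma <- diag(spec$log_sd) %*% spec$basis_corr %*% diag(spec$log_sd)
  set.seed(spec$seed)
  logw <- MASS::mvrnorm(n_samples, mu = spec$log_mean, Sigma = sigma)
  w <- exp(logw)
  frac <- w / rowSums(w)
  depths <- if (spec$depth_low == spec$depth_high) {
    rep(spec$depth_low, n_samples)
  } else {
    sample(seq(spec$depth_low, spec$depth_high), n_samples, replace = TRUE)
  }
  counts <- t(vapply(seq_len(n_samples),
                     function(s) as.numeric(stats::rmultinom(1, depths[s], frac[s, ])),
                     numeric(D)))
  dimnames(counts) <- list(sprintf("sample_%03d", seq_len(n_samples)),
                           sprintf("otu_%03d", seq_len(D)))
  list(table = otu_table(counts), basis_corr = spec$basis_corr,
       fractions = frac, planted_sets = spec$planted_sets)
}

#' Generate a null community with independent taxa
#'
#' [generate_community] with an identity basis correlation: every true
#' off-diagonal correlation is zero, making the output a type-I-error
#' harness for the permutation p-value machinery.
#'
#' @param D number of OTUs (>= 4).
#' @param n_samples number of samples.
#' @param seed RNG seed.
#' @param ... further arguments to [synthetic_spec] (depth bounds, log
#'   moments).
#' @return As [generate_community]; `basis_corr` is the D x D identity.
#' @export
generate_null_community <- function(D, n_samples, seed, ...) {
  stopifnot(D >= 4)
  generate_community(synthetic_spec(D = D, seed = seed, ...), n_samples)
}

#' Materialise a planted synthetic community as pipeline input files
#'
#' Convenience wrapper used by the analysis workflow: builds a spec, plants
#' `n_clusters` disjoint member sets of size `cluster_size`, generates the
#' table, attaches a taxonomy stub (each planted set becomes a distinct
#' genus; background OTUs get singleton genera) and a metadata stub, and
#' optionally writes everything plus a ground-truth JSON to `out_dir`.
#'
#' @param D,n_samples community dimensions.
#' @param n_clusters number of planted co-occurring sets (0 for none).
#' @param cluster_size OTUs per planted set.
#' @param within_corr correlation inside planted sets.
#' @param depth_preset `"depth-454"` or `"depth-miseq"`.
#' @param seed RNG seed.
#' @param out_dir optional directory to write `table.tsv`, `taxonomy.tsv`,
#'   `metadata.tsv` and `truth.json` into.
#' @return A list with `table`, `taxonomy`, `metadata`, `basis_corr`,
#'   `planted_sets`.
#' @export
simulate_community_files <- function(D = 50, n_samples = 200, n_clusters = 3,
                                     cluster_size = 8, within_corr = 0.7,
                                     depth_preset = "depth-454", seed = 17,
                                     out_dir = NULL) {
  spec <- synthetic_spec(D = D, depth_preset = depth_preset, seed = seed)
  sets <- list()
  if (n_clusters > 0) {
    if (n_clusters * cluster_size > D) stop("planted sets exceed D")
    sets <- split(seq_len(n_clusters * cluster_size),
                  rep(seq_len(n_clusters), each = cluster_size))
    spec <- plant_patterns(spec, sets, within_corr)
  }
  com <- generate_community(spec, n_samples)
  ids <- com$table$otu_ids
  genus <- sprintf("Genus%03d", seq_len(D))
  for (k in seq_along(sets)) genus[sets[[k]]] <- sprintf("PlantedGenus%02d", k)
  lineage <- paste0("p__SimPhylum;c__SimClass;o__SimOrder;f__SimFamily",
                    ";g__", genus)
  taxonomy <- parse_lineages(ids, lineage)
  metadata <- data.frame(
    sample_id = com$table$sample_ids,
    study = "synthetic", platform = depth_preset,
    region = "V4",
    breed = rep(c("BreedA", "BreedB"),
                c(ceiling(n_samples / 2), floor(n_samples / 2))),
    treatment = rep_len(c("control", "AGP"), n_samples),
    stringsAsFactors = FALSE)
  out <- list(table = com$table, taxonomy = taxonomy, metadata = metadata,
              basis_corr = com$basis_corr, planted_sets = com$planted_sets)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_otu_table(out, file.path(out_dir, "table.tsv"),
                    file.path(out_dir, "taxonomy.tsv"),
                    file.path(out_dir, "metadata.tsv"))
    truth <- list(basis_corr = com$basis_corr,
                  planted_sets = lapply(com$planted_sets,
                                        function(s) ids[s]),
                  seed = seed)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  out
}
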