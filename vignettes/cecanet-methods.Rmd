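---
title: "Compositional co-occurrence networks of cecal microbiomes: models and methods"
author: "cecanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional co-occurrence networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cecanet)
```

## The problem

16S rRNA amplicon surveys of the chicken cecum (and any microbiome) report
*relative* abundances: each sample's counts are constrained by its
sequencing depth, so an increase in one abundant taxon depresses every
other fraction. Naive Pearson or Spearman correlations on such
compositional data are contaminated by spurious negative association, and
the distortion grows as communities are dominated by a few taxa. cecanet
implements a log-ratio-based pipeline for inferring *basis correlations* —
the correlations of the unobserved absolute abundances — and for the
downstream community analyses that rest on them: signed co-occurrence
networks, overlapping cohesive clusters, polarizing-hub ("keystone")
statistics, cluster recapitulation in individual samples, frequent
presence itemsets and alpha-diversity contrasts.

## Basis correlation inference

For components $i, j$ with fractions $f_i, f_j$, the log-ratio variance
$t_{ij} = \mathrm{Var}\!\left[\log(f_i/f_j)\right]$
is depth-invariant and decomposes as
$t_{ij} = \omega_i + \omega_j - 2\rho_{ij}\sqrt{\omega_i\omega_j}$,
where $\omega_i$ is the basis variance of $\log w_i$ and $\rho_{ij}$ the
basis correlation. The system is underdetermined; under the *sparsity
approximation* (most pairs uncorrelated), the row sums
$t_i = \sum_j t_{ij}$ obey a linear system whose closed-form solution is

$$\omega_i = \frac{t_i - \Omega}{D - 2}, \qquad
  \Omega = \frac{\sum_i t_i}{2(D-1)},$$

and $\rho_{ij} = (\omega_i + \omega_j - t_{ij}) / (2\sqrt{\omega_i\omega_j})$,
clipped to $[-1, 1]$. Pairs that visibly violate sparsity (current
$|\hat\rho|$ above the exclusion threshold, default 0.1) are excluded
iteratively — up to 10 times, strongest pair first — dropping the
corresponding unit entries from the system matrix, which is then solved
directly (`solve_basis_variances`). This divides by $D-2$, which is why
the pipeline requires at least four OTUs after filtering. Negative
$\omega$ solutions (sparsity badly violated) are clamped at $10^{-12}$ and
flagged rather than dropped.

Zero counts make raw log-ratios undefined, so fractions are not point
estimates: each resampling round draws per-sample fractions from the
Dirichlet posterior with parameters counts$+1$ (uniform prior), which is
strictly positive by construction. The point estimate of $\rho$ is the
element-wise **median over 20 rounds** (default); the spread across rounds
is absorbed rather than reported.

Significance uses permutation null datasets: each of $B = 100$ nulls
shuffles every OTU's counts across samples independently, preserving
marginals while destroying association, and is re-inferred with one
resampling round. Two-sided pseudo-p-values carry the add-one correction
$p_{ij} = (\#\{b: |\rho_b| \ge |\rho_{\mathrm{obs}}|\} + 1)/(B+1)$, so no
p-value is exactly zero. The resampling-round count and the null count are
deliberately separate knobs: "bootstraps" in pipeline folklore conflates
them, and both are exposed. Network-stage p-values are used raw at
$p < 0.05$; Benjamini–Hochberg adjustment (`bh_adjust`) is applied in the
diversity comparisons, where the field conventionally applies it, and is
available for edges if wanted.

## The signed network and keystones

An edge joins $i$ and $j$ iff $p_{ij} < 0.05$ **and** $|\rho_{ij}| \ge
0.3$ (both thresholds exposed; the magnitude cutoff mirrors the display
convention of co-occurrence figures in this literature). Degree is
computed on this thresholded network. Each node's record counts positive
and negative edges; the balance $(n_+ - n_-)/(n_+ + n_-)$ summarises
whether a taxon's associations are one-sided. *Polarizing hubs* — the
keystone candidates — are nodes in the top quartile of positive degrees
with $|\mathrm{balance}| \le 0.5$; both knobs are interpretive, since the
underlying criterion ("relatively large numbers of both negative and
positive associations") is qualitative. The degree tail is fitted with
the discrete maximum-likelihood exponent
$\hat\alpha = 1 + n_{\mathrm{tail}} / \sum \ln\!\big(k_i/(k_{\min} -
\tfrac12)\big)$; this continuous approximation is accurate for
$k_{\min}$ of a few and above, and noticeably underestimates steep
exponents at $k_{\min} = 1$, so recovery checks and reported fits use a
higher cutoff. The log–log R² of the complementary cumulative
distribution is reported as a descriptive only, and only when at least
three distinct tail degrees exist.

## Cohesive overlapping clusters

Clustering runs on the positive subgraph only (co-occurrence, not
avoidance), with edge weight $\rho$. A candidate cluster $V$ scores

$$f(V) = \frac{w_{\mathrm{in}}}{w_{\mathrm{in}} + w_{\mathrm{bound}} +
  p\,|V|},$$

with boundary weight $w_{\mathrm{bound}}$ and penalty $p = 2$ modelling
unobserved edges. Growth is greedy local search from a seed: every
single-node addition from the boundary and removal is evaluated and the
largest *strict* increase applied, stopping at a local optimum.
Tie-breaking (addition before removal, then lowest node id) and seeding
(every uncovered node in decreasing weighted-degree order) are fixed so
runs are bit-stable. Candidates with match coefficient
$|A \cap B|^2/(|A||B|) \ge 0.8$ merge transitively until no pair
qualifies; clusters below 3 members or weighted density 0.3 are
discarded. These are the published defaults of the cohesiveness-based
complex-detection tool this module re-implements; its internal
auto-density heuristic is not reproduced, which is why all four knobs are
explicit.

Greedy growth carries no universal approximation guarantee. Exhaustive
enumeration of all connected labelled unit-weight graphs on up to 5 nodes
shows growth from the algorithm's own (max-degree) seed attains the
global optimum containing that seed; from 6 nodes on there are graphs
(about 3% of the 26 704 connected 6-node graphs) where a tie plateau
stops growth below 0.8 of that optimum — several zero-gain additions
stand between the grown core and a better, boundary-free superset.
Accepting zero-gain moves would depart from the published strict-increase
procedure and can cycle, so the implementation stays faithful and the
limitation is documented instead. In practice the multi-seed + merge
strategy, not single-seed optimality, is what recovers planted structure.

Cluster-level interaction scores are the mean of $\rho_{uv}$ over
deduplicated cross-cluster pairs ($u \ne v$), computed on the **full**
correlation matrix, not only surviving edges, so negative inter-cluster
structure is visible even when individual edges miss the display
threshold.

## Sample-level patterns

*Recapitulation* (the enterotype check): presence is a raw count $\ge 1$
on the filtered table — no rarefaction, since none is prescribed
upstream. Per (sample, cluster), coverage is the fraction of members
present; per cluster we report the fraction of samples with coverage
$\ge \theta = 0.25$, and the same for unions of designated cluster pairs.

*Itemsets*: exact vertical (transaction-id-list) depth-first enumeration
of all OTU sets with support above a floor — the combinations of OTUs
present together in the most samples. No sampling or heuristics; the
test suite holds it equal to brute-force subset enumeration.

*Diversity*: Shannon entropy in bits (base-2 logarithm, the convention of
the amplicon pipeline this mirrors; the base is an argument) and Chao1
with the bias-corrected branch when no doubletons exist. Group contrasts
use the Welch $t$ statistic under label permutation (999 permutations,
add-one-corrected two-sided p), the "non-parametric t-test" of amplicon
pipelines; the permutation reference makes the pooled-vs-Welch choice
second-order. P-values across strata and metrics are BH-adjusted
together.

*Breed profiles*: per-breed mean relative abundances aggregated to
display labels (genus when resolved, otherwise the deepest resolved rank,
prefixed), taxa kept if they exceed 1% in **any** breed (a stricter
every-breed reading is a flag), Spearman correlation between breeds, and
average-linkage clustering on $1 - \rho$ — emitted as a Newick string.

## The synthetic-data generator

Every stage is validated against communities with known truth. Per
sample, log basis abundances are multivariate normal with a specified
correlation matrix (log-mean 0, log-SD 1 per OTU by default — a dynamic
range typical of amplicon data), exponentiated, normalised, and counted
multinomially at a depth drawn uniformly from a preset: `depth-454`
(1 000–3 000 reads) or `depth-miseq` (20 000–60 000), emulating the
~20-fold platform contrast of real surveys. Planted blocks set
within-block basis correlations to a target; if the edit breaks positive
semidefiniteness the matrix is repaired by eigenvalue clipping and
re-normalisation, and the repaired matrix is the truth recovery is
judged against. This is exactly the generative family under which
log-ratio inference is consistent, which is what makes
parameter-recovery tests meaningful — and also what they do *not* show:
real data add chimeras, sequencing error, primer and batch effects, and
phylogenetic correlation, none of which are simulated. Passing recovery
tests demonstrate correctness of the machinery, not robustness to those
artifacts.

The default study conditions of the analysis scripts (50 OTUs, 300
samples, three planted 8-OTU blocks at within-correlation 0.7, MiSeq
depths, seed 17) are fixed once; the acceptance script reruns them from
scratch at whatever seed it is given.

## Numerical and design notes

- Centred-log-ratio sanity checks on independent communities must centre
  on the $-1/(D-1)$ compositional artifact of the CLR itself; it is not
  noise.
- A zero-count sample is admissible in fraction estimation: its Dirichlet
  posterior is uniform. Downstream log-ratio variance still requires two
  or more samples.
- All randomness flows from one user seed through a multiplicative
  counter scheme (`derive_seed`), so stages are independently
  reproducible and two identical runs are byte-identical.
- Read-count filters use strict "more than" semantics; filters are
  applied to the table as given, before any metadata-based subsetting.
- Problem sizes in tests (e.g. null communities of 30 OTUs x 150 samples,
  exhaustive graph batteries to 6 nodes with sampled 7-8-node graphs) are
  chosen to make each property decisive at desk scale while the full
  suite stays fast.

## Known limitations

- Only one correlation estimator is provided; no CCLasso / SPIEC-EASI /
  proportionality alternatives, and no cross-study batch correction.
- Cluster detection reproduces the published defaults but not the
  reference binary's auto-density heuristic.
- The keystone criterion is an operationalisation of a qualitative idea;
  its two thresholds deserve sensitivity analysis on real data.
- The power-law fit reports a point estimate and a descriptive R², not a
  goodness-of-fit comparison against alternative tail models.
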