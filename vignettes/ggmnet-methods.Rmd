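---
title: "Graph-structured mixture clustering and symptom networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-structured mixture clustering and symptom networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
model and its assumptions, the estimation algorithms, every tunable
parameter with its default and rationale, what the synthetic-data generator
does and does not emulate, and the numerical conventions adopted where more
than one defensible choice existed.

## The Gaussian graphical mixture model

The data are a complete $n \times p$ matrix of continuous scores. An
ordinary finite Gaussian mixture,
$f(x_i) = \sum_k \tau_k \Phi(x_i \mid \mu_k, \Sigma_k)$, is augmented with a
per-component undirected graph $G_k$ over the $p$ variables, and each
$\Sigma_k$ is constrained so that its inverse — the precision matrix — is
exactly zero at every non-adjacent pair. A missing edge therefore means
conditional independence of the two variables given the rest, *within that
cluster*. Clusters can differ in their means, their marginal covariances,
and their dependence graphs; this is what distinguishes the model from mean-
profile clustering (latent profile analysis) on one side and from a single
pooled network analysis on the other.

Assumptions worth stating plainly: within-cluster multivariate normality of
the scores; complete data (rows with missing entries are rejected, not
imputed); continuous inputs (ordinal item-level data are out of scope — the
model is known to behave badly there, and the package refuses rather than
silently mistreating it).

## Structural EM

With $K$ fixed, estimation alternates four steps until the penalized
log-likelihood stabilizes:

1. **E-step.** Posterior responsibilities
   $z_{ik} \propto \tau_k \Phi(x_i \mid \mu_k, \Sigma_k)$, computed in log
   space (Cholesky factors, log-sum-exp), so separated clusters cannot
   underflow to 0/0.
2. **M-step (moments).** $\tau_k$, $\mu_k$ and the responsibility-weighted
   sample covariance $S_k$ (MLE denominator $n_k = \sum_i z_{ik}$).
3. **Structure step.** Per component, a greedy stepwise search over graphs:
   starting from the current graph (the empty graph on the first
   iteration), toggle the single edge whose addition or removal most
   improves the penalized profile score
   $\ell^{\max}(G; S_k, n_k) - (1+\beta)\frac{\log n_k}{2}\,|E(G)|$,
   until no toggle improves. The profile log-likelihood uses the identity
   $\operatorname{tr}(\hat\Omega S) = p$ at the constrained MLE, so scoring a
   graph costs one constrained fit. An exhaustive mode (all
   $2^{p(p-1)/2}$ graphs, $p \le 5$) exists for oracle testing.
4. **Constrained MLE.** For the chosen graph, the covariance MLE by
   edge-wise iterative proportional fitting (IPF) on the precision matrix:
   each edge's $2\times2$ block is adjusted so the fitted marginal matches
   $S_k$ exactly, sweeping until the constrained moments agree within
   `1e-8` (at most 10,000 sweeps). For a Gaussian, matching all pairwise
   (edge) marginals plus variances is equivalent to matching all clique
   marginals, which is why edge-wise sweeps suffice. Off-graph precision
   entries are exactly zero by construction: updates never touch them.

**Penalty form.** The per-edge penalty $(1+\beta)\log(n_{\mathrm{eff}})/2$
with $\beta = 0$ makes the structure score a BIC-type penalized likelihood —
each edge is one free parameter charged half a $\log n$. $\beta$ is exposed
as a tuning knob (larger $\beta$, sparser graphs; $\beta = -1$ removes the
penalty entirely) but defaults to 0. The effective sample size is the
*component's own* responsibility mass $n_k$, not the total $n$: each
component's structure is supported only by its own weight of data, and using
total $n$ would over-penalize small components' edges.

**Initialization and restarts.** Ten seeded k-means hard partitions
(independent starts), each refined by a short (5-iteration) unconstrained
EM burn-in; the start with the best burn-in likelihood continues to the
full structural EM. Running the expensive structure search only from the
best start is the classical short-run/long-run ("emEM") compromise: with
ten starts the selection is as robust as ten full runs on separated data at
a tenth of the cost. All randomness flows from one integer seed recorded in
the fitted object; identical seeds give identical fits.

**Convergence and monotonicity.** Iteration stops when the relative change
in the penalized log-likelihood falls below `1e-6` (at most 500
iterations). At fixed graphs the E/M steps are exact EM, so the objective
is non-decreasing; the structure step can change the penalty term, so
monotonicity is asserted (in tests, with `1e-6` relative slack) only
between iterations whose graphs did not change. The fitted object stores
the full objective trace and a per-iteration graphs-changed flag so this is
checkable after the fact.

**Failure semantics.** Two degeneracies abort a fit with a typed condition
rather than silent regularization: a component covariance whose minimum
eigenvalue falls to `1e-8` or below (`not_positive_definite`), and a
component responsibility mass below $p+1$ (`empty_component`), the point
at which its weighted covariance loses full rank. `select_ggmm()` catches
these, records a failure record (K, reason, detail), and excludes that $K$
from the BIC comparison — so an overfit candidate (say $K$ one above the
truth collapsing a component) degrades gracefully instead of contaminating
model selection. If every candidate fails, `no_valid_model` is raised.

**Tie-breaking.** Equal structure scores (within `1e-9`) prefer fewer
edges, then the lexicographically smallest edge set; equal responsibilities
classify to the lowest component index. These make fits and labels
deterministic.

**Model selection.** $\mathrm{BIC} = -2\ell + \nu \log n$, minimized, with
$\nu = (K-1) + Kp + \sum_k (p + |E_k|)$ free parameters (proportions,
means, variances, one covariance per edge).

## Per-cluster partial-correlation networks

Networks are estimated on the *hard* (MAP) cluster subsets, matching the
two-stage workflow the package automates (clustering first, network
estimation per cluster second); responsibility-weighted covariances would
blur exactly the cluster boundaries the first stage established. For each
cluster: the MLE covariance (denominator $n$, consistent with the Gaussian
likelihood used in scoring), then the graphical lasso — maximizing
$\log\det\Omega - \operatorname{tr}(S\Omega) - \lambda \sum_{i \ne j}
|\omega_{ij}|$ by blockwise coordinate descent, diagonal unpenalized —
along a grid of 100 logarithmically spaced $\lambda$ values from
$\lambda_{\max} = \max |S_{\text{off}}|$ down to $0.01\,\lambda_{\max}$.
Each fit is scored by the extended BIC,
$-2\ell + |E|\log n + 4\gamma |E| \log p$, with $\gamma = 0.5$ — the
conventional conservative setting. Ties prefer the larger $\lambda$
(sparser network). The winning precision is converted to partial
correlations, $-\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}$.

Two practical notes, both visible in the test suite: EBIC-tuned graphical
lasso does *not* achieve exact support recovery — weak spurious edges
(|partial correlation| of a few hundredths) occasionally survive selection
even at $n = 1000$, a documented behavior of the unthresholded estimator —
and with small clusters plus the conservative $\gamma$, genuinely weak
dependence structures can yield an empty selected network. Both are
properties of the method, not defects of the implementation; the KKT
conditions of every fitted instance are verified to `1e-5`.

## Centrality

Strength ($\sum_j |w_{ij}|$) and expected influence ($\sum_j w_{ij}$) are
direct edge-weight sums. Geodesic indexes use edge lengths $1/|w_{ij}|$ —
the standard transform for association networks, making strong associations
short — with Dijkstra distances and Brandes betweenness (tied shortest
paths counted fractionally, endpoints excluded) from igraph. Closeness is
the inverse of a node's summed distances, defined as 0 when any node is
unreachable: a convention, but a testable one, chosen over dropping
unreachable pairs because it penalizes disconnection instead of rewarding
it. Bridge strength and bridge expected influence are the same sums
restricted to edges crossing disorder communities, in their 1-step (direct
edge) form. z-standardization is per network across that network's nodes,
with the population (denominator-$n$) standard deviation; a constant index
column yields NA z-scores with a warning in tables, and an error from the
bare `z_standardize()` operation.

## The synthetic-data generator

`psychopathology_fixture()` emulates the *structure* of a transdiagnostic
symptom-score dataset: 12 variables (MDD1–2, PD1–3, SAD, OCD1–6) in four
disorder communities; four components whose mean profiles are "strong
OCD/PD, moderate MDD/SAD", "moderate MDD/PD/SAD, weak OCD", "all weak",
and "all strong"; mixing proportions 235/357/138/791 over 1521; and sparse
per-component dependence graphs in which the six OCD variables are mutually
connected in every component. All numeric constants — mean levels (strong
3.5, moderate 1.5, weak 0), precision diagonals (2.5) and edge precisions
(±0.25–0.4) — are invented package constants. They were set once so that
between-component mean separation exceeds three within-component standard
deviations, the premise under which cluster-number recovery is a fair test
of the fitting machinery; at visibly smaller contrast even the
Bayes-optimal classifier (using the true generating parameters)
misclassifies enough points that partition-recovery criteria would measure
cluster overlap rather than estimation quality.

What the generator does **not** emulate: the marginal distributions,
covariances or effect sizes of any empirical dataset; ordinal measurement;
floor effects; or any violation of within-cluster normality. Passing the
recovery tests therefore demonstrates that the estimator works where its
assumptions hold — it says nothing about robustness to the ways real
symptom data violate them.

The general-purpose pieces (`random_graph`, `graph_constrained_precision`,
`sample_ggmm`) build arbitrary graph-structured mixtures; positive
definiteness of generated precisions is enforced by strict diagonal
dominance (diagonal = row absolute sum + 0.1), which is crude but always
valid and keeps off-graph zeros exact.

## Problem sizes in the test suite

The suite runs everything at deliberately modest sizes chosen as the
package's own trade-off between statistical resolution and a fast
check-every-commit suite: cluster-number recovery at $n = 1500$, $p = 12$,
ten seeds; structure-search oracle comparisons on 100 random $p \in \{3,4\}$
instances; brute-force path-enumeration oracles at $p = 7$; moment-
consistency checks up to $n = 50{,}000$. The full suite and the acceptance
script each complete in about a minute on one CPU.

## Known limitations

- Greedy structure search finds a local optimum; the oracle tests show it
  attains the exhaustive optimum in ≈99/100 small random instances, but no
  guarantee exists at $p = 12$.
- BIC's consistency for the number of components assumes the model family
  contains the truth; under misspecification (heavy tails, skew) it tends
  to add components to absorb the misfit.
- The two-stage network workflow conditions on the estimated partition;
  uncertainty in cluster assignment is not propagated into the
  partial-correlation networks or centrality indexes, and no bootstrap
  stability analysis is provided.
- Exhaustive structure search is limited to $p \le 5$ by design
  ($2^{p(p-1)/2}$ fits).
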