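---
title: "Estimating and probing symptom networks with symptomnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and probing symptom networks with symptomnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

## The model

`symptomnet` analyses item-level questionnaire data — here the Three-Item
Loneliness Scale (items scored 1–3), the PHQ-9 depression items and the
GAD-7 anxiety items (both scored 0–3) — as a *Gaussian graphical model*
(GGM): a multivariate normal model in which zeros of the precision matrix
$K = \Sigma^{-1}$ encode conditional independence. The network's edge
weights are partial correlations,

$$\rho_{ij} = -\,K_{ij} / \sqrt{K_{ii}\,K_{jj}},$$

the association between two symptoms after controlling for all other
symptoms in the set.

### Estimation: glasso path, constrained refits, stepwise BIC

The final model is *unregularized*; the graphical lasso is used only to
propose candidate structures:

1. **Path.** Solve the graphical lasso at 100 logarithmically spaced
   penalties between $\lambda_{\max} = \max_{i\ne j}|S_{ij}|$ (the smallest
   penalty giving the empty graph) and $\lambda_{\max}/100$, and collect the
   distinct supports along the path.
2. **Refit.** Re-estimate each candidate edge set without regularization by
   the constrained concentration-graph MLE (cyclic regression updates on the
   working covariance; at convergence the implied covariance equals $S$ on
   every edge and the diagonal, and $K_{ij}=0$ exactly off the edge set).
3. **Select.** Score each refit by $\mathrm{BIC} = -2\,\ell + |E|\log n$,
   where $\ell = \tfrac n2(\log\det K - \mathrm{tr}(S K))$ and $|E|$ is the
   edge count — the only parameter count that varies across models of fixed
   $p$, so BIC differences are unaffected by the dropped constants.
4. **Search.** From the BIC-best refit, greedily evaluate every single-edge
   addition and removal (each via a warm-started constrained MLE), apply the
   best strictly improving change, and stop at a local BIC optimum. Ties
   within $10^{-10}$ prefer removal, then the lexicographically smallest
   pair, so the search is deterministic.

Numerical choices: the glasso coordinate descent converges at
$10^{-7}$ (scaled by the mean absolute off-diagonal of $S$), the
constrained MLE at $10^{-8}$ on the maximum change of the implied
covariance. While *screening* candidate moves the MLE tolerance is relaxed
to $10^{-3}$ — BIC gaps between competing moves are orders of magnitude
larger, every applied move is refitted at full tolerance, and the selected
edge set was verified to be invariant to this relaxation on simulated
data — which makes bootstrap re-estimation loops roughly four times
faster. The stepwise search is capped at $10 \cdot p(p-1)/2$ moves; BIC
strictly improves each move, so the cap only guards against floating-point
pathology.

The correlation input is Pearson by default. For ordinal items a
`polychoric` option estimates each pair's latent correlation by two-step
maximum likelihood on the contingency table; it targets the latent scale
and is the consistent choice under the package's own generating model
(below), at the cost of extra computation. Spearman is also available. A
non-positive-semi-definite polychoric matrix is repaired by eigenvalue
clipping, with a warning.

## Centrality, bridges, communities

* **Expected influence** (one-step) is the signed sum of a node's edge
  weights — preferred over strength where negative edges exist, as in this
  network. Standardization uses z-scores with the sample (n−1) SD; that
  convention reproduces the published standardized values from the
  packaged weights within two-decimal rounding.
* **Closeness and betweenness** operate on edge lengths $1/|w_{ij}|$
  (stronger association = shorter path), so they ignore edge sign.
  Betweenness uses Brandes-style accumulation with fractional credit for
  geodesic ties, detected at a $10^{-9}$ float tolerance. On a
  disconnected network closeness is computed within components and the
  result is flagged; the packaged study network is connected.
* **Bridge expected influence** restricts the signed sum to edges crossing
  construct clusters; it decomposes ordinary expected influence into
  within-cluster and cross-cluster parts (an identity the tests assert at
  $10^{-12}$). The raw sums are the primary output: the published
  standardized bridge values (0.03/0.02) cannot be reconciled with any
  rescaling of the printed weights matrix, so only rank order is treated
  as reproducible.
* **Clique percolation** (weighted): a k-clique percolates if the
  geometric mean of its absolute edge weights reaches the intensity
  threshold I; retained cliques sharing $k-1$ nodes chain into
  communities, nodes may belong to several communities or to none.
  Absolute weights are used because the published community containing
  the negative PHQ9–GAD3 edge can only percolate on magnitudes. The
  $(k, I)$ search compares the observed community count against nulls
  that shuffle the nonzero weights over the fixed skeleton (testing
  weight organization, not topology) and ranks candidates by the
  z-score of that departure — the choice of ranking statistic is an
  implementation decision (the cited permutation procedure is not fully
  specified in the literature), so the full diagnostic grid is always
  returned for manual selection.

### Rounding limits of the packaged weights

The packaged matrix stores the published values exactly as printed, to two
decimals. That precision limit has one visible consequence: at
$k=3, I=0.225$ the two borderline cliques {PHQ8, PHQ9, GAD5} (intensity
$\approx 0.2165$) and {PHQ3, PHQ4, PHQ5} ($\approx 0.2146$) fall just
below threshold, so the published five-community solution is not
bit-reproducible from the printed weights. Within $I \in [0.21, 0.225]$
the five published node groups and the exact published unassigned set
{PHQ1, PHQ7, GAD4, GAD6} all appear, with one merge (a bridging clique
{GAD2, GAD3, PHQ9}, intensity $\approx 0.216$, joins the mixed
depression–worry community to the pure anxiety community). The acceptance
tests assert exactly that: the two robust communities at $I = 0.225$, and
the five-group structure with the merge caveat inside the band.

## Stability analysis

`bootstrap_edges()` resamples respondents with replacement and re-runs the
*entire* estimation (path, refits, stepwise search) per replicate, giving
per-edge quantile CIs and pairwise difference tests (two edges differ when
the bootstrap 95% CI of their difference excludes zero).
`case_dropping()` re-estimates on progressively smaller subsamples drawn
without replacement and correlates each subsample's centrality with the
full-sample centrality; the CS coefficient of an index is the largest drop
proportion at which ≥95% of subsamples correlate ≥0.7 with the original.
The rule constants (0.7, 0.95, grid maximum 0.75) follow the established
bootstrap-stability convention and are configurable; correlations are
Pearson on raw centrality values, and failed or degenerate replicates
(e.g. a constant betweenness vector) count against stability. A `fast`
mode stops at the BIC-best path refit, skipping the stepwise search; it is
an approximation intended for CI sanity checks and is labelled as such.

All randomness flows from one root seed through deterministic child
streams (one per operation/replicate), so reports are bit-reproducible and
adding an operation never perturbs existing draws.

## The synthetic-data generator

No respondent-level data are distributed, so the generator is the
package's test bed. It is a latent-Gaussian (Gaussian copula) model:
latent vectors are drawn from a multivariate normal whose correlation
matrix is implied by a target partial-correlation structure
($K = I - P$ up to diagonal scaling, which leaves partial correlations
invariant), then discretized item-wise by strictly increasing thresholds
into each item's score range. This is precisely the model under which
polychoric correlation is consistent, and discretization is monotone in
the latent draw.

Calibration (`calibrate_thresholds()`) works against the published
construct-level summary (loneliness/depression/anxiety total-score means
4.97/5.79/5.03, SDs 1.867/6.096/5.521, inter-scale correlations
.560/.530/.805):

* **Thresholds** are shared across items within a construct (only
  construct-level moments are published) and parametrized as an equally
  spaced ladder $\tau_c = a + b\,c$; $(a, b)$ are found by Nelder–Mead on
  *analytic* ordinal moments (bivariate-normal cell probabilities), so the
  search is smooth and deterministic. The heavy right skew of the
  depression and anxiety totals (mean 5.79, SD 6.096 on a 0–27 scale) is
  produced purely by asymmetric cut-point placement, keeping the Gaussian
  copula. Achieved moments match the targets to well under the documented
  tolerances (mean 2%, SD 10%).
* **Cross-construct structure.** The latent correlations implied by the
  printed two-decimal partial-correlation matrix overstate the published
  total-score correlations (e.g. they imply a depression–anxiety total
  correlation near 0.87 after discretization, against the published
  0.805) — an expected artifact of sparsification plus rounding of the
  printed matrix. Calibration therefore solves three cross-construct
  scale factors (monotone one-dimensional root finds, again on analytic
  moments) so the model-implied total-score correlations match the
  published values exactly; within-construct structure is left untouched.
  For parameter-recovery studies the unscaled printed structure is used
  instead (`match_correlations = FALSE`), since there the generating
  partial correlations are the truth being recovered.

What the generator deliberately does not emulate: per-item marginal
heterogeneity within a construct (unpublished), non-Gaussian latent
dependence (tail co-movement), and any respondent heterogeneity or
response styles. Passing tests therefore demonstrate correctness of the
estimation machinery under the stated copula model, not robustness of the
published substantive findings to violations of it.

## Problem sizes used in the checks

The test suite and the acceptance script run the conditions the study
reports where that is feasible at interactive scale: the study sample size
(n = 1041) for calibration and stability, 200 subsamples per drop level
for the case-dropping bootstrap, n = 20 000 for parameter recovery, and
exhaustive oracles (path enumeration, subset enumeration, all $2^6$ edge
sets at $p=4$) at small p where enumeration is exact. Edge-bootstrap unit
tests run at reduced sizes (small p, fast mode) with the full-size
behaviour covered by the stability acceptance check.

## Worked example

```{r example, eval = FALSE}
net <- lad_network()                        # packaged published network
edge_count(net)                             # 52 of 171 possible edges
standardize(expected_influence(net))["GAD4"]  # ~2.19
percolate(net, k = 3, I = 0.225)            # communities at the published solution
bridge_expected_influence(net)              # GAD6 and PHQ1 top-ranked

spec <- lad_generator_spec(n = 1041, seed = 1)  # calibrated generator
d <- generate_responses(spec)
compute_scale_scores(d)$correlations
fitted <- estimate_network(d)               # path + refits + stepwise BIC
edge_count(fitted) / 171                    # density near 30%
```

## Known limitations

* The stepwise search is greedy; it guarantees a single-edge local BIC
  optimum, not the global one (the exhaustive-enumeration tests show it
  lands in the top tail of all models at small p).
* Polychoric estimation is two-step (thresholds from margins, then the
  pairwise correlation), the standard trade-off of speed against full-ML
  efficiency.
* The packaged weights are two-decimal; every quantity derived from them
  inherits rounding error of that order, which is why the fixture-based
  tolerances are what they are.
* Missing data are rejected, not imputed; the intended inputs are complete
  survey panels.
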