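---
title: "Parsimonious higher-order HMMs for Array-CGH profiles: model, priors and training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimonious higher-order HMMs for Array-CGH profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

An Array-CGH profile is an ordered sequence of tiles along one chromosome,
each carrying a log-ratio $o_t$ of sample versus reference intensity. The
package models a profile with a hidden state sequence $q_1,\dots,q_T$ over
$K = 3$ states — `del` (deletions or sequence deviations, log-ratios well
below zero), `neutral` (unchanged, near zero) and `amp` (amplifications,
above zero) — with Gaussian emissions $o_t \sim N(\mu_{q_t},
\sigma_{q_t}^2)$. States deliberately do not encode specific copy numbers;
each covers a broad band of log-ratios through its flexible mean and
standard deviation.

The state process is an order-$r$ Markov chain whose transition law is
*tree-structured*. For each history length $k = 1..r$ a *state-context
tree* $T^{(k)}$ of height $k$ is kept: every internal node partitions the
state set, and a path from the root to a leaf selects one subset per
position of the context $(q_{t-1}, \dots, q_{t-k})$ — position 1, directly
under the root, is the most recent predecessor. Every concrete context
therefore resolves to exactly one leaf, and all contexts in a leaf share
one transition vector over next states. The two extremes are the fused
tree (one leaf: the history is ignored and the transition process
collapses to a mixture) and the complete tree ($K^k$ leaves: a full
order-$k$ HMM). Everything in between trades complexity for data sharing;
with $K = 3$ and $r = 4$ the complete tree has $81$ leaves and $243$
transition parameters, while e.g. a 14-leaf tree needs only $42$.

The transition into position $t \le r$ uses the height-$(t-1)$ matrix with
the context available so far; from $t > r$ on the height-$r$ matrix
applies. Order $0$ is the Gaussian mixture: positions are independent and
the initial distribution acts as mixture weights everywhere.

Inference (likelihood, posteriors $\gamma_t(i)$, expected context counts
$N^{(k)}(c, j)$) runs on the equivalent first-order chain over $K^r$
tuples of recent states, with per-position scaling; the construction is
validated in the test suite against exhaustive enumeration over all $K^T$
state sequences on small instances. Decoding assigns each tile its
posterior-maximal state (ties to the lower state index, for determinism).
There is deliberately no Viterbi decoder: ranking and decoding both use
marginal posteriors.

## Priors

The prior factorizes over parameter classes:

* **Initial distribution and transition leaves** carry transformed
  (log-space-parameterized) Dirichlet priors: the density exponent of
  $p_j$ is the pseudocount $a_j$ itself, *not* $a_j - 1$. Consequently the
  MAP update is the pseudocount-smoothed frequency $(n_j + a_j) / \sum_l
  (n_l + a_l)$ with no subtraction. Leaf pseudocounts are additive
  aggregates of per-context pseudocounts $\alpha^{(k)}(c, j)$, so total
  pseudocount mass is conserved for any tree, and a complete tree reduces
  to independent per-context Dirichlets.
* **Emissions** carry per-state Normal-scaled-Inverse-Gamma priors on
  $(\mu, \sigma^2)$ with location $m$, strength $\tau$, shape $a$ and
  scale $b$; the M-step uses the joint posterior mode, whose variance
  denominator $2a + 3 + \sum_t \gamma_t$ keeps $\sigma^2$ strictly
  positive even for empty states.
* **Tree structure**: an unnormalized log-prior $\kappa L$ in the leaf
  count $L$. Only the qualitative behaviour is fixed by the modeling goal
  (penalize leaves for $\kappa < 0$, reward them for $\kappa > 0$); any
  exponent base would only rescale $\kappa$, so natural-log units are used
  and $\kappa$ is documented in them. The prior is left unnormalized over
  trees — sufficient for MAP selection, where only score differences
  matter; a tree-independent offset is absorbed by $\kappa$.

Defaults are weak and order-balanced: one pseudocount per initial state;
$\alpha^{(k)}(c, j) = K^{-k}$ so each order contributes total mass $K$;
emission locations at the initialization anchors with $\tau = 1$, $a = 2$,
$b = \widehat{\mathrm{Var}}(o)$; $\kappa = 0$. All are overridable (YAML
config in the CLI). Hyper-parameters are inputs throughout; there is no
empirical-Bayes learning of them.

## Bayesian Baum-Welch training

Each iteration runs the exact E-step over all chromosome profiles
(independent sequences, counts summed) and then maximizes the penalized
auxiliary function exactly, class by class: closed forms for the initial
distribution and emissions, and for every height $k$ a search over *all*
state-context trees for

$$\sum_{\text{leaves}} \Big[ \sum_j (N_j + a_j) \log p_j - \log Z(a)
\Big] + \kappa L,$$

where $N$ and $a$ are the leaf-aggregated expected counts and
pseudocounts and $Z(a) = \prod_j \Gamma(a_j) / \Gamma(\sum_j a_j)$. The
number of trees grows super-exponentially in $k$, but the objective
decomposes over subtrees: the value of a node depends on its subset path
only, so a depth-first recursion over the $(2^K - 1)$-ary path space with
memoization and, at each internal node, a maximization over the $B_K$
(Bell number) partitions of the state set finds the global optimum
exactly. Ties are broken by a fixed canonical partition order (restricted
growth strings; blocks by smallest element), making selection
deterministic. The normalizer $-\log Z(a)$ is part of the per-leaf score:
it differs across trees because pseudocounts aggregate, so leaving it out
would silently re-weight structures.

Because every maximization is exact, the log-posterior is non-decreasing
across iterations — the property the test suite checks across orders
1–4 and random starts. Training stops when the improvement stays below
`tol` for two successive iterations (default `tol = 1e-3` log-posterior
units, a deliberate package default) or at `max_iterations`.

Initialization mirrors how a practitioner reads the log-ratio histogram:
the `del` mean starts at the pooled 5th percentile, `neutral` at zero
(unchanged regions have log-ratios about zero), `amp` at the 95th
percentile, all standard deviations at the pooled standard deviation.
$\pi$ and the rows of *complete* trees of each height are drawn from
Dirichlet distributions with the prior pseudocounts, so the initial model
is a full higher-order HMM and training *reduces* complexity from there.
(Sampling uses the ordinary Dirichlet with the pseudocounts as shape; for
the transformed Dirichlet density this is a slightly flatter proposal
than the prior mode, which is harmless for an initializer and keeps draws
strictly interior.) The `del` < `neutral` < `amp` mean ordering is
enforced at initialization only; if EM swaps components, states are
relabeled by mean order at output time, permuting trees and rows
consistently.

Restarts are deterministic: restart $i$ of base seed $s$ uses a seed
derived only from $(s, i)$, so results are identical regardless of
execution order and the same initializations are compared across a
$\kappa$ grid. The scan driver enumerates (order, $\kappa$, restart)
combinations — 40 $\kappa$ values $\times$ 20 restarts schedule 800 fits
per order, the replication protocol supported by `kappa_scan()`. For
$\kappa$ spanning $-10^6$ to $+10^6$ on fixed data the selected
complexity moves from 1 leaf to $K^r$ leaves, non-decreasing in between —
the mixture-to-higher-order interpolation that motivates the model class.
Negative $\kappa$ of moderate size (order $-100$ to $0$ for datasets of a
few thousand tiles) is where parsimonious structures appear.

Two accepted consequences of the construction: trees of height $k < r$
see only one transition per profile, so their posteriors are prior-
dominated; and heights are selected independently per matrix (no
projection constraint ties $T^{(k)}$ to $T^{(r)}$), since each matrix is
defined by its own tree.

## Evaluation machinery

* **PACF**: partial autocorrelations (Durbin–Levinson, via `stats::pacf`)
  of observed profiles, of within-profile permutations (a dependence-free
  baseline whose mean and sd sit near zero), and of profiles sampled from
  a fitted model — a diagnostic for how much spatial dependence a model
  order actually reproduces. Per-profile PACFs are averaged weighted by
  profile length; the lag axis is tile steps, converted to bp only for
  display via the mean spacing.
* **Labeling**: a tile is a positive if at least 75% of its bases (45 of
  60 bp by default geometry) are covered by candidate regions, after
  merging overlaps. The threshold is configurable.
* **Ranking**: tiles are ranked by the posterior of `del`; TPR is
  reported at a target FPR with tied scores entering or leaving the
  threshold set atomically, taking the largest set whose FPR does not
  exceed the target — a deterministic policy. ROC curves and AUC follow
  the same tie handling (half credit in the pairwise view).

## The synthetic generators

Two generators provide ground-truth datasets. `generate_from_model()`
samples ancestrally from any model and lays tiles out at the defaults of
60 bp width and 350 bp start spacing — the geometry of typical tiling
arrays. `generate_painted()` plants non-overlapping deletion and
amplification segments with geometric tile lengths (memoryless, matching
HMM run lengths; a fixed-length mode exists for worst cases) until target
tile fractions are met within ±10%, then draws log-ratios from class
Gaussians. Its defaults emulate the asymmetry of inter-accession
Array-CGH data: a dominant bulk at $N(0, 0.2^2)$, a minor deletion
component at $N(-1.5, 0.5^2)$ (5% of tiles), a very small amplification
component at $N(1, 0.5^2)$ (0.2%). `degrade_labels()` turns exact truth
intervals into imperfect validation labels by boundary jitter and random
dropout.

What the generators do *not* emulate: probe-sequence effects,
hybridization physics, wavy baselines, outlier tiles, or non-equidistant
tile spacing. Passing tests on synthetic data therefore demonstrate
correctness of the algorithms and detectability under the stated
conditions, not performance on any particular array platform.

Study conditions used by the tests and the acceptance script are fixed
once: the reference generator is a sticky order-2 chain (self-transition
0.85–0.94, most-recent-state dependence only, i.e. a 3-leaf height-2
tree) with means $(-1.5, 0, 1.5)$ and sds $(0.4, 0.2, 0.4)$ — adjacent
class means about five pooled standard deviations apart, a
designed-detectable regime. Recovery runs fit 5 chromosomes × 5,000
tiles per seed; EM property checks use 2 × 300 tiles and 50 iterations;
the interpolation scan 2 × 1,500 tiles; PACF checks 4,000-tile samples.
In the end-to-end ranking check the label degradation is kept compatible
with a 1% FPR budget (2% dropout, 15 bp jitter): mislabeled true
deletions rank at the top as nominal negatives, so heavier degradation
would bound TPR@1%FPR away from 1 for *any* method — a property of the
metric, not of the model.

## Numerical choices and degenerate inputs

* Forward–backward uses per-position scaling plus a per-row rescaling of
  emission densities by their maximum, keeping profiles of $10^5$ tiles
  finite end to end; posteriors are clamped against $\pm\epsilon$
  round-off.
* A transition probability of exactly zero against a positive pseudocount
  scores $-\infty$ in the prior; this is allowed and flagged rather than
  masked.
* Zero-variance series are rejected by the PACF (no finite
  autocorrelation exists); profiles with missing values are rejected at
  parse time — the chain assumes contiguity, and silent gaps would
  distort transition counts.
* Coordinates are 0-based half-open internally and in BED output; GFF
  input (1-based closed) is converted on ingest; strand is ignored
  (Array-CGH tiles are unstranded). Tie-breaks everywhere (decoding,
  partitions) favour the lower index / canonical order.

## Limitations

Context trees have fixed height per matrix — no variable-length (pruned
depth) contexts. Hyper-parameters are not learned. No comparisons to
other segmentation methods are bundled. The DP is exponential in the
context length ($\le (2^K - 1)^k$ memo entries); at the intended desk
scale ($K = 3$, $r \le 5$) a single selection runs in well under a
second, but large $K$ would require the factored bottom-up organization
instead.
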