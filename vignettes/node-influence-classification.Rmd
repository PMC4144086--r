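---
title: "Node-influence classification: model, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Node-influence classification: model, assumptions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nimclass)
```

## The model

The classifier treats a cohort of expression profiles as a single dense
weighted network. Three ingredients:

1. **Joint min-max scaling.** Every feature of the combined train+test
   data is mapped linearly onto [0, 1]. Scaling is joint because the
   method is transductive: one graph is built over all samples, so all
   samples must share a coordinate system. Constant features map to 0 and
   are kept, so feature indices stay stable.

2. **Gaussian similarity graph.** Edge weights are
   $S(x,y) = \exp(-\lVert x-y\rVert^2 / 2\delta^2)$ on pairwise Euclidean
   distances (the kernel on *squared* distance; an alternative `raw`
   exponent convention is available for reproduction studies, since the
   two conventions appear in the literature describing this construction).
   Between distinct samples every weight is strictly positive, so the
   graph is complete — hence connected and non-bipartite, which is
   exactly what the centrality's convergence requires.

3. **Node-influence centrality.** For walk length $k$, the influence of
   node $i$ on node $j$ is $A^k(i,j) / \sum_m A^k(m,j)$ — the fraction of
   weighted $k$-walks ending at $j$ that start at $i$, using the
   walk-counting property of adjacency powers. Diagonalizing the
   symmetric $A$ shows the ratio converges, as $k \to \infty$, to
   $P_i / \sum_m P_m$ where $P$ is the entrywise-positive leading
   (Perron) eigenvector — a limit independent of $j$. The implementation
   therefore computes the limit by symmetric eigendecomposition
   (`method = "eigen"`), keeping the finite-$k$ path (`method = "power"`,
   `walk_influence()`, `influence_trace()`) as the validation route and
   for convergence traces.

A test sample $x$ is assigned to the class $C$ maximizing
$\sum_{t \in C} S(x,t)\,w(t) / \sum_{t \in C} w(t)$, the
influence-weighted average similarity over $C$'s training samples, with
weights $w$ = influence centralities of the full train+test graph
restricted to training nodes. NIM1 uses one bandwidth throughout; NIM2
uses $\delta_1$ for the influence graph and $\delta_2$ for the scoring
similarities. NIM1 $\equiv$ NIM2 at $\delta_1 = \delta_2$, exactly — the
test suite asserts bit-level equality.

## When the limit exists — and when it does not

Convergence of the walk ratio needs the leading eigenvalue to dominate in
absolute value. Two structural failures exist:

* **Disconnected graphs** have no graph-wide limit; `node_influence()`
  refuses them.
* **Bipartite graphs** have spectra symmetric about zero: the extreme
  eigenvalues tie in absolute value and the ratio oscillates with the
  parity of $k$ forever (a single edge and the 4-cycle are the canonical
  cases). `check_convergence()` flags this; `node_influence()` errors.

```{r bipartite}
edge <- weighted_graph(matrix(c(0, 1, 1, 0), 2, 2))
check_convergence(edge)[c("bipartite", "gap")]
```

The spectral gap $|\lambda_1| - \max_{l>1}|\lambda_l|$ reported by
`check_convergence()` governs the convergence *rate*: the finite-$k$
residual is $\Theta((|\lambda_2|/\lambda_1)^k)$. This matters for
validation design: at $k = 200$, a graph needs
$|\lambda_2|/\lambda_1 \lesssim 0.91$ for the ratio to sit within
$10^{-8}$ of the limit. The property tests that pin the finite-$k$ path
against the eigen path at $k = 200$ therefore draw random connected
non-bipartite graphs whose spectral ratio is at most 0.85 (residual
$\le 0.85^{200} \approx 8\times10^{-15}$); slower-mixing graphs are not
counterexamples to the limit statement — they simply need a larger $k$.
Complete similarity graphs, the only graphs the classifier itself builds,
mix far faster than this bound.

Numerical choices on this path: the Perron vector's sign is fixed by
requiring a positive sum; tolerances for detecting a repeated leading
eigenvalue and for the positivity check are *relative* to $|\lambda_1|$,
because kernel matrices can be uniformly tiny (all entries
$e^{-\text{large}}$ at small bandwidths) without being degenerate. A
repeated leading root — impossible for complete similarity graphs, but
possible for abstract inputs — is handled by summing the eigenspace basis
and is reported via `leading_multiplicity`. The finite-$k$ path uses
iterated multiplication (so intermediate powers feed convergence traces)
with a rescaling guard above $10^{250}$; rescaling leaves the ratio
unchanged.

## Tunable parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `delta` / `delta1` | kernel bandwidth of the influence graph (units of normalized feature distance) | none — data-dependent | grid search provided |
| `delta2` | bandwidth of the class-scoring similarities (NIM2) | = `delta1` | decoupling these is NIM2's entire difference |
| `metric` | pairwise distance | `euclidean` | the recommended default absent prior knowledge |
| `diagonal` | self-loop policy | `zero` | a uniform diagonal shift $A \to A + cI$ leaves eigenvectors unchanged, so influence is provably unaffected (tested); `zero` also keeps class scores free of self-matches |
| `exponent` | kernel on squared vs raw distance | `squared` | `raw` provided for reproduction studies |
| `tie_break` | equal class scores | first declared class | ties are exact only in degenerate limits |

Bandwidth intuition: $\delta$ sets the distance scale at which affinity
decays. Too small, and scores are dominated by single nearest neighbours
(high variance); too large, and all similarities flatten toward 1
(no discrimination). The `grid_search()` operation sweeps $\delta$ (or
the $(\delta_1,\delta_2)$ product grid) under LOOCV or a holdout split;
default grid resolutions are deliberately coarse — dense sweeps of $10^6$
evaluations are supported but not default.

## Evaluation protocol

`loocv()` runs $N$ folds, each holding out one sample. Because
normalization is joint and $\delta$ fixed, the similarity graph over all
$N$ samples is identical in every fold, so the default path computes the
graph and influence vector once and re-restricts training weights per
fold; `per_fold = TRUE` reruns everything inside each fold, and the test
suite asserts both paths agree exactly. Accuracy is exactly
`n_correct / n_total`. A fold whose held-out sample leaves its class
empty is recorded as errored and excluded from the denominator with a
warning. Declared classes with no training members are an error, never a
silent zero score.

## The synthetic generator

`simulate_dataset()` emulates the data regime this method targets:
thousands of features, tens-to-hundreds of samples, 2–7 classes,
imbalanced sizes (defaults: two classes of 10 and 50 samples, 2000
features of which 20 informative, class separation 2, unit noise).
Each class's mean sits on its own disjoint block of informative
features, scaled so any two class means are $\sqrt{2}\,\times$
`class_separation` apart; every feature carries i.i.d. Gaussian noise.
Non-informative features are pure noise — microarray dimensionality
without signal.

What it does *not* emulate: probe/batch effects, heavy-tailed or
count-distributed expression, correlated gene modules, label noise.
Passing recovery tests on this generator therefore shows the pipeline is
correct and that separable Gaussian classes are recovered — not that any
particular real cohort would reach a given accuracy.

One geometric fact shapes the recovery tests. Min-max scaling stretches
*every* feature to unit range, so pure-noise features contribute
$O(1)$-spread coordinates no matter how small `noise_sd` is: separability
in the normalized metric is governed by the informative fraction of
features (signal adds $\approx n_{\text{inf}}\,g^2$ to between-class
squared distance, while noise dimensions fluctuate intra-class distances
by $O(\sqrt{n_{\text{noise}}})$), not by the raw
`class_separation`/`noise_sd` ratio alone. The perfect-recovery checks
accordingly use 100 features with a 20-feature informative block,
separation $10\times$ the noise sd, and bandwidths in $[1, 2]$ —
verified stable across dozens of seeds; smaller bandwidths leave the
regime by making scores nearest-neighbour dominated, and much wider
noise-only blocks dilute the signal below the fluctuation floor. Problem
sizes throughout the test suite (cohorts of 10–20 samples, grids of a
few points) were chosen as the smallest that exercise every code path.

## Design choices where the design was open

* **Min-max form.** The normalization step is implemented as the
  standard $(x - \min)/(\max - \min)$; the variant form floating around
  with max and the value swapped in the numerator does not map into
  [0, 1] and divides by zero at the minimum, contradicting the step's
  stated purpose.
* **Kernel exponent.** Squared distance in the exponent (the standard
  Gaussian kernel) is the default, as the fully expanded form of the
  construction; the `raw` convention is available.
* **Class-score normalizer.** Weights are summed over the scored class
  only (so each score is a weighted *average* in (0, 1]), matching the
  index ranges of the scoring formula.
* **Transductive weights.** Influence is computed over the full
  train+test graph, and only training nodes receive weights. There is no
  inductive mode: freezing weights would change the method.
* **Duplicated training samples** are scored literally: a duplicated
  member does not automatically share weight mass, because the two
  copies' influence values enter the weighted average independently. No
  invariance under duplication is claimed or tested.
* **On-disk format.** Delimited text (CSV/TSV) with samples in rows, one
  header, sample ids in the first column, values written at 17
  significant digits so round-trips are lossless.

## Known limitations

* Dense $N \times N$ graphs and a full eigendecomposition per fit:
  $O(N^3)$, fine for cohort sizes in the hundreds, not for
  $N \gg 10^4$.
* No feature selection; all features enter the distance equally, so the
  method inherits the usual curse-of-dimensionality dilution when
  informative genes are a vanishing fraction (see the geometry note
  above).
* Bandwidths must be chosen by search; no automatic selection rule is
  provided.
* Class scores from very small or very imbalanced training classes rest
  on few similarities and can be unstable — the LOOCV harness surfaces
  this rather than hiding it.
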