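---
title: "Methods: the reversal-distance framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the reversal-distance framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tred)
```

## The model

Signature-reversion drug repositioning asks whether a drug's transcriptomic
response points *against* a disease's transcriptomic signature. `tred`
scores this with a projection statistic rather than the older
Kolmogorov–Smirnov pattern matching.

A **disease signature** is a vector of per-gene association scores: TWAS
Z-scores (genetically anchored — enriched for upstream, potentially causal
genes) or DGE log fold changes (observed consequences of disease, well
powered at small sample sizes). A **drug response profile** is a vector of
per-gene differential-expression scores for one perturbation experiment
(compound × cell line × dose × time), LINCS Level-5 style.

Both vectors are converted to **centered rank ratios**: within a vector, a
gene's rank divided by the number of genes ranked, minus 0.5. The largest
score receives rank 1, so upregulated genes occupy uncentered ratios below
0.5; this orientation is applied identically to signatures and profiles,
and makes a *positive* reversal distance mean reversal. Ranks are
tie-averaged, which keeps the mean centered ratio of a full vector at
`1/(2n)` (effectively 0). The rank transform makes the statistic invariant
to any monotone rescaling of either input — Z-scores and log fold changes
never meet on a common scale, their ranks do.

The two vectors are embedded in a shared space:

* the signature is rank-transformed **over its own genes**;
* the profile is rank-transformed **over every gene it measures** (the
  global ranks are what a perturbation experiment reports), then restricted
  to the signature's genes;
* signature genes the profile does not measure are dropped and counted;
  fewer than `min_overlap = 10` shared genes is a hard error. We do not
  impute: zero-filling unmeasured genes would silently shrink the cosine.

With `g` and `d` the embedded vectors and θ their angle:

$$\omega = \cos\theta = \frac{g \cdot d}{\lVert g\rVert\,\lVert d\rVert},
\qquad rd = \lVert g\rVert \cos(\pi - \theta) = -\lVert g\rVert\,\omega,
\qquad d_{norm} = \frac{2}{\pi}\arccos\!\left(\frac{rd}{\lVert g\rVert}\right).$$

`rd` is invariant to positive rescaling of the drug vector, scales linearly
with $\lVert g\rVert$, and spans $[-\lVert g\rVert, +\lVert g\rVert]$;
$d_{norm}$ rescales it to $[0, 2]$ (0 = perfect reverser, 1 = orthogonal,
2 = perfect mimic). Norms are computed on the shared support after
restriction, which keeps rd magnitudes comparable across profiles of
different sizes and puts them on the ~0.5–2 scale typical for 100–200-gene
signatures.

Closed-form sensitivities $\partial\omega/\partial d_i$ and
$\partial\omega/\partial g_i$ quantify single-gene influence. For the
sampling distribution of ω we provide a first-order delta-method
approximation treating $\omega = h(s, t, u)$ with $s = g\cdot d$,
$t = g\cdot g$, $u = d\cdot d$ and $h(s,t,u) = s/\sqrt{t\,u}$ — the only
algebraic form consistent with ω (a plain $s/(tu)$ is dimensionally wrong).
At signature dimension 10 with 200,000 Monte-Carlo replicates the
approximation tracks the empirical variance of ω within 15% (asserted in
the test suite). Softmax conversion of the K reversal distances into drug
probabilities, and the deterministic argmax (lexicographic tie-break), are
provided for the search-problem view of repurposing.

## Significance testing

**Label-shuffle null.** The signature's centered values are reassigned to
uniformly random gene subsets of the profile's measured universe; a null rd
is computed per permutation (default `n_perm = 1000`). The p-value uses
add-one smoothing, $p = (1 + \#\{rd_{null} \ge rd_{obs}\})/(n_{perm}+1)$,
so it is never 0 — the standard exact-test convention. The test is
one-sided toward large positive rd by default, because prioritization only
acts on large rd; a two-sided variant is available. Under a null simulation
(signature independent of profile) the empirical type-I error at α = .05
is 0.05 within Monte-Carlo error (asserted over 1000 simulated datasets).

**Degree-preserving network null.** Genes are correlated; a coexpression
network can carry that structure into the null. We randomize the network by
double edge swaps — edges a–b and c–d with four distinct nodes become a–c
and b–d, rejected if either new edge exists — which preserves every node's
degree exactly. The stopping rule is 80% of the original edges rewired
(with a `100·|E|` attempt cap; hitting the cap warns and reports the
achieved fraction). The rewiring alone does not define a null statistic, so
each accepted swap also transposes the signature values held at nodes b and
d; the accumulated transpositions are a structure-respecting permutation of
the signature, from which null rd values follow. This is a design choice of
this package. On weakly structured synthetic data the two nulls' p-values
correlate strongly (r > 0.5 asserted in the test suite).

**Multiplicity.** With >1000 drugs, per-profile resolution
$1/(n_{perm}+1)$ cannot survive Bonferroni. We therefore recompute each
profile's experiment-wise p against the null rd draws *pooled across all
profiles of the signature* (resolution $1/(K\,n_{perm}+1)$), then apply
Bonferroni with m = number of distinct drugs per signature — drugs, not
profiles, are the tested hypotheses.

## Prioritization rules

A profile *supports* a signature when it is nominally significant
(p < .05), its rd exceeds the per-signature mean by more than 2 sample SDs,
its replicate group (compound × cell line × dose × time) is
direction-consistent (groups with mixed rd signs are removed entirely), and
— if unreplicated — the same compound shows a nominally significant,
same-direction rd in a *different* cell line for the same signature (our
formalization of the confirmatory-cell-line requirement). A drug passes
when at least one profile survives adjustment (p_adj < .05) and it supports
at least `min_signatures` signatures; disease modes that combine genetic
and observational evidence additionally require the supported set to
include both a TWAS and a DGE signature.

## The KS baseline

The comparison method splits the signature at uncentered rank ratio 0.5
into disease-up and disease-down gene sets and computes the classic
connectivity-map enrichment $a/b$ statistics of each set in the drug-ranked
gene list, combining them as `ks_up − ks_down` (0 when the two share a
sign), `ks_up` or `−ks_down` when only one set exists. Tag positions are
taken in the drug list ordered **most drug-downregulated gene first**; with
that orientation the literal combination rules above yield positive scores
for reversers and negative for mimics, matching the sign convention of rd.
(With the more common up-first ordering the same formulas score mimicry
positively; the orientation is the entire difference.)

## The synthetic-data generator

`simulate_dataset()` emulates the study inputs: Gaussian per-gene signature
scores; profiles with i.i.d. standard-normal background scores; planted
reversers whose scores on a signature's support are
$-\rho\,\mathrm{sig} + \sqrt{1-\rho^2}\,\varepsilon$ (mimickers use
$+\rho$), so `effect` = ρ is the target anti-correlation; replicates share
a latent profile plus Gaussian noise (`replicate_sd = 0.3`); planted
constructions repeat in every cell line so confirmatory checks can succeed.
Defaults — 2000 genes, 200 drugs, 150 signature genes, effect 0.8 — are the
generator's study conditions: the gene count of a reduced L1000-like panel,
a screening-sized compound set, a realistic signature size, and a strong
but noisy planted effect. Signature supports are disjoint whenever they fit
in the gene universe. The generator does **not** emulate LINCS noise
structure, gene–gene correlation within profiles, dose–response ordering,
or batch effects — so passing recovery tests demonstrate correctness of the
machinery under a clean Gaussian model, not performance on real LINCS data.
At these conditions the planted reverser attains the top rd in ≥95% of
runs and the full pipeline (7 signatures, `min_signatures = 4`, TWAS+DGE
mix) returns exactly the planted drug; both are asserted in the test suite,
alongside a harness comparing rd and the KS score on sensitivity,
specificity and AUC.

`simulate_network()` draws Poisson degrees (mean 4 by default — a typical
coexpression-graph density after thresholding) and wires a simple graph via
igraph's degree-sequence sampler.

## Numerical choices

* Cosines are clamped into [−1, 1] with tolerance 1e−12; larger excursions
  of `rd/‖g‖` raise a domain error rather than silently clamping.
* Softmax subtracts the maximum before exponentiating (shift-invariant,
  overflow-safe).
* Ties: average ranks everywhere, except the drug-ranked list for KS tag
  positions, where first-occurrence ranking guarantees distinct positions.
* Degenerate inputs error early with typed conditions: < 2 genes,
  non-finite scores, zero-norm embedded vectors, overlap below
  `min_overlap`, covariance not PSD, empty tag sets.
* All stochastic operations take an explicit seed and leave the caller's
  RNG stream untouched; pipeline functions derive per-(signature, profile)
  child seeds from the run seed, so results are bit-identical across runs
  and invariant to profile chunking.
* Test-suite problem sizes (500–2000 genes, 8–200 drugs, 100–1000
  permutations, 100–1000 simulated datasets) are chosen so the full suite
  exercises every statistical claim at meaningful power while completing in
  a few minutes on one CPU.

## Known limitations

* **The normalized distance is not a metric.** $d_{norm} = 2 - 2\theta/\pi$
  is a *reversed* angular distance: it is 0 for any exact reverser pair
  (not only identical vectors — the coincidence axiom fails), and the
  triangle inequality fails for near-antipodal configurations (consider
  x = −y and z = x: then $d_{norm}(x,y) = d_{norm}(y,z) = 0$ yet
  $d_{norm}(x,z) = 2$). Such configurations become increasingly improbable
  for random vectors as dimension grows; at the dimensions the framework
  operates on (≥ 10-gene overlap enforced, typically 50–150 genes) the
  test suite asserts symmetry and the triangle inequality on 1000 random
  triples. Treat $d_{norm}$ as a bounded
  reversal score, not a metric embedding.
* Rank-direction flips at the raw-score level shift centered values by
  $1/n$ (the centered ratios of a finite list are not symmetric around 0),
  so "flip both vectors" invariance holds exactly for negated centered
  vectors, and only up to $O(1/n)$ through the rank transform. The same
  $1/n$ edge effect limits the antisymmetry of the KS score under list
  reversal.
* The permutation null reassigns signature values genome-wide and so
  assumes exchangeability across the profile's measured genes; the network
  null relaxes this only as far as the supplied coexpression graph is
  faithful.
* Bonferroni across drugs is deliberately conservative; no FDR variant is
  provided.
* Gene identifiers are opaque strings: no symbol/Entrez conversion, no
  cross-platform liftover.
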