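---
title: "Network diffusion seed scanning: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network diffusion seed scanning: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndmscan)
```

## The model

`ndmscan` treats the spread of neurodegenerative pathology as linear
diffusion on the structural connectome. With `C` the weighted adjacency
matrix (streamline counts), `D = diag(rowSums(C))` the weighted degrees,
and

$$H = I - D^{-1/2} C D^{-1/2}$$

the symmetric normalized graph Laplacian, a seed pattern $f_0$ evolves as
the heat kernel

$$f(t) = e^{-\alpha H t} f_0
       = \sum_{i=1}^{N} e^{-\alpha \lambda_i t}\,(u_i^\top f_0)\, u_i,$$

where $(\lambda_i, u_i)$ are the eigenvalues and orthonormal eigenmodes of
$H$. Useful analytic facts, all enforced or tested in the package:

* $0 \le \lambda_i \le 2$, and $\lambda_1 = 0$ for a connected graph with
  zero-mode $u_1 \propto \sqrt{\mathrm{deg}}$;
* the zero-mode coefficient $u_1^\top f(t)$ is conserved, every other mode
  decays monotonically, so $f(t) \to (u_1^\top f_0)u_1$ — diffusion ends
  at a degree-weighted equilibrium regardless of the seed;
* the model is linear in $f_0$, and $\alpha$ only rescales the time axis.

The last two points shape the whole analysis. Because every seed converges
to the *same* equilibrium, seed identity is encoded only in the transient;
and because Pearson correlation is scale invariant, neither the seed
magnitude (1 per hemisphere) nor $\alpha$ (fixed at 1, configurable)
materially affects the correlation-time surface on a dense time grid.

## Seed scanning

Candidate epicentres are bilateral homologous pairs: the seed vector has 1
at both members, 0 elsewhere. For the default 82-region bilateral
parcellation this gives 41 initial conditions. Each trajectory is sampled
on the unit grid $t = 0, 1, \dots, 50$ (51 points, matching the regime in
which diffusion peaks and then settles), and correlated at each time with
the measured atrophy t-map over the regions *excluding the seed pair* (80
regions), so a seed cannot be rewarded for its own atrophy. Each seed's
score is its maximum correlation over valid times.

Numerical and inferential choices:

* **t = 0 is always dropped from the maximum**: the non-seed prediction is
  identically zero there, so the correlation is undefined. Undefined
  correlations at any other zero-variance time are likewise recorded as
  missing, never imputed as 0.
* **Ties** in the argmax (time) or the ranking are broken toward the
  smaller time / earlier region-table entry, with a message.
* **p-values** come from the two-sided t transform of the maximal r with
  df = 80 − 2. They are *not* corrected for the maximization over time —
  the max over 51 dependent time points makes them optimistic, which is
  one reason the package also ships the null-network test (below). Family
  wise correction across the 41 seed hypotheses is Bonferroni by default;
  Holm is available. Bonferroni was chosen as the most conservative
  reading of "family-wise corrected" when the original method is not more
  specific.
* Whether the correlation test should be one- or two-sided is genuinely
  open; two-sided is the conservative choice and the default.

## Atrophy maps

Regional volumes are divided by the subject's total intracranial volume
(head-size correction) before group statistics. The two-sample map uses
the pooled-variance t (df $= n_1 + n_2 - 2$); "two-sample t-test" is
ambiguous between pooled and Welch, so pooled is the default and Welch sits
behind `var_equal = FALSE`. The paired map uses within-subject differences
(df $= n - 1$). The sign convention — nowhere stated in common usage — is
fixed here as **loss-positive**: t is computed as control-minus-patient
(or earlier-minus-later), so larger t means more atrophy. Uncorrected
p-values accompany the maps; the t-values are what the NDM stage consumes,
as effect sizes.

## Null networks

The observed maximum correlation is compared against the same scan run on
randomized connectomes. The randomization (a) rewires the binary graph by
Maslov–Sneppen double-edge swaps (10 swap attempts per edge, via igraph),
preserving the degree sequence exactly; (b) reassigns the original weight
multiset to the rewired edges greedily, heaviest weight to the free edge
with the largest residual-strength product, preserving the weight
distribution exactly and the nodal strength distribution approximately
(Spearman ≈ 0.99 between original and null strengths on the default
synthetic connectome). Connectivity is checked on the final graph, with
bounded retries, rather than per swap. The empirical p uses the add-one
estimator $(1 + \#\{r_{null} \ge r_{obs}\})/(K+1)$, so it is never 0. The
original analysis names the preserved properties but not the algorithm;
equivalence is at the level of those properties, not bit-level.

## The synthetic world

The generator exists so that every stage — file IO, Laplacian, scanning,
nulls, group statistics — can be exercised against a known ground truth.
Defaults mirror the reference study design: 82 regions in 41 mirrored
pairs, 14 patients vs 12 controls, $\alpha = 1$, grid 0..50, observation
noise $\sigma = 0.05 \times \max f$, planted time mid-grid.

**Topology.** Each hemisphere is a weighted ring lattice: first- and
second-neighbour edges with weight $\propto 1/d^2$, log-normal
multiplicative noise (sdlog 0.5) around a streamline-like scale of 50,
sparse weak long-range shortcuts (density 0.03, weight ×0.05), and strong
homotopic callosal edges (×2) anchoring the bilateral pairing. This is a
deliberately spatial parametrization, mimicking the exponential distance
rule of cortical connectivity. It was chosen over Erdős–Rényi-style
"dense within hemisphere" blocks for an identifiability reason worth
recording: under the normalized-Laplacian heat kernel, unstructured dense
hemispheres mix so fast that by model time ~15 every seed's pattern has
collapsed onto the common equilibrium, and no scanner can recover a
planted seed reliably at the stated noise level — planted-seed recovery
saturates near 90% however densities are tuned, and block-community
variants fail the same way within a community. A spatially embedded
lattice keeps the transient (a localized, idiosyncratically shaped bump)
alive across the whole 5–30 window, and recovery exceeds 99% (measured at
~700 replicates across disjoint seed batches before the defaults were
frozen). Real connectomes are distance-ruled for the same reason the
method works on them at all.

**Volume tables.** Controls draw log-normal volumes around region-level
means; patients' means are shrunk by $\mathrm{effect} \times f_k(t^*)$
with $f$ normalized to max 1, so `effect` reads as the maximal fractional
loss. Each subject's volumes scale with their own ICV (7% between-subject
SD) — the confound ICV normalization is meant to remove. Subject-level
multiplicative noise has CV 2% by default.

**What a green test does not establish.** The generator emulates the
*statistical structure* the analysis assumes (atrophy ∝ diffused pattern
plus noise), not real data: no spatial autocorrelation in the noise, no
subject-level connectome variability, no registration/segmentation error,
and a topology far more regular than tractography output. Passing tests
certify the machinery, not the biological claim.

**A noise-floor limit worth knowing.** With 14 vs 12 subjects and 2%
subject CV, a per-region t-statistic has intrinsic noise SD ≈ 1.04, while
a 5% maximal volume loss yields a maximal signal of about
$0.05/(0.02\sqrt{1/14+1/12}) \approx 6.3$ — an effective pattern noise of
~0.17 × max f, more than three times the σ = 0.05 of the direct
atrophy-map simulations. At that level, end-to-end recovery (volumes →
t-map → scan) saturates near 70% for *any* topology; it exceeds 95% once
the maximal loss reaches ~15%. The end-to-end property test therefore
runs in the detectable-atrophy regime (effect = 15%, within the "at least
5%" constraint), and the 5%-effect regime should be read as the method
degrading gracefully, not failing.

## Degenerate inputs and numerics

* Connectome matrices must be symmetric within $10^{-8} \times \max|W|$
  (float noise is averaged out with a warning; worse is an error), finite,
  nonnegative, hollow-diagonal, and connected — an isolated region is
  reported by name rather than silently propagated as a zero-degree error
  downstream.
* Degenerate Laplacian eigenspaces (e.g. complete graphs) need no special
  handling: any orthonormal basis gives the same heat kernel; this is
  property-tested against the independent matrix-exponential oracle.
* `propagate()` returns $f_0$ *exactly* at $t = 0$ (the eigenmode
  reconstruction would be exact only to machine precision).
* A constant atrophy map makes every correlation undefined and is
  rejected as "degenerate atrophy" rather than returning an empty result.

## Known limitations

The model is first-order linear on a static healthy connectome: no
nonlinear aggregation–fragmentation kinetics, no disease-dependent network
degradation, no subject-specific connectomes or seeds. The null model
preserves weight/degree/strength but not spatial embedding; on a
distance-ruled network, geometry-preserving nulls would be stricter. The
per-seed p-values inherit an optimism from maximizing over time; the
empirical null-network p does not, and should be preferred when the two
disagree.
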