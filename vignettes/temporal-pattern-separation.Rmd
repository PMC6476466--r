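---
title: "Quantifying temporal pattern separation in single neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying temporal pattern separation in single neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Pattern separation is the transformation of similar input activity
patterns into less similar output patterns; pattern convergence is the
opposite computation. In the hippocampal dentate gyrus this computation is
classically attributed to granule cells, and it can be probed at the level
of a single neuron: deliver an ensemble of designed afferent spike trains
(an *input set*) repeatedly, record the evoked spike trains (*output
sweeps*), and ask whether the outputs are less similar to each other than
the inputs were. Because "similar" depends on what the downstream reader
of the code cares about — binwise spike counts, vector angles, firing
rates, exact spike times — the analysis must be run under several metrics
and across time scales.

`patsep` implements this assay end to end as testable code: input-set
generators with controlled similarity structure, a stochastic
input-to-output neuron standing in for the recorded cell, the four
similarity metrics, firing-rate/burstiness features, the parentage-aware
pattern-separation graphs, and the associated statistics. The numbered
scripts under `analysis/` run the stages in order and write their tables
under `results/`.

## The assay

A standard protocol delivers 5 trains repeated 10 times (or 10 trains
repeated 5 times), yielding 50 output sweeps with known parentage. All
pairwise similarities between the 55 trains form a 55×55 matrix. For each
of the `choose(n, 2)` parent pairs, the *output similarity* is the
unweighted mean over all cross-parent child pairs — comparisons between
sweeps that share a parent are never used, because they measure
reliability, not separation. Plotting mean pairwise output similarity
against input similarity gives the pattern-separation graph: for
similarity metrics, points below the identity line indicate separation.

```{r}
library(patsep)
inp <- gen_correlated_set(target_r = 0.76)
rec <- simulate_recording_set(inp, celltype_preset("GC"))
pts <- separation_points(pairwise_matrix(rec, metric = "R", tau_w_ms = 10))
pts[, c("parent_i", "parent_j", "s_input", "s_output", "n_child_pairs")]
```

## Similarity metrics and the codes they assume

Two spike trains of duration $T$ are binned into $N = T/\tau_w$ spike
counts $X_i, Y_i$ for the binned metrics:

* **R** — Pearson's correlation coefficient,
  $R = \mathrm{cov}(X,Y) / (\sigma_X \sigma_Y)$, in $[-1, 1]$. Assumes a
  binwise synchrony code in which common silent bins count as agreement.
  R is undefined when a count vector is constant; such pairs are flagged
  (`defined = FALSE`) and excluded from averages rather than silently
  propagating `NaN`.
* **NDP** — the normalized dot product
  $\cos\theta = \sum_i X_i Y_i / (\lVert X\rVert\,\lVert Y\rVert)$, in
  $[0, 1]$: 0 means orthogonal, 1 collinear. Orthogonality is the
  classical notion of fully separated patterns.
* **SF** — the scaling factor
  $\min(\lVert X\rVert, \lVert Y\rVert) / \max(\lVert X\rVert, \lVert
  Y\rVert)$, in $(0, 1]$: sensitive to firing-rate and burstiness
  differences and blind to which bins the counts occupy. NDP and SF are
  complementary: angle and norm fully describe a pair of vectors.
* **SPIKE** — a binless similarity, $1 - \frac{1}{T}\int_0^T D(t)\,dt$,
  where $D(t)$ is the instantaneous SPIKE-dissimilarity profile built
  from each train's preceding/following spikes and their distances to the
  nearest spikes of the other train, with auxiliary spikes at $t = 0$ and
  $t = T$ bounding edge effects. The implemented variant is the standard
  non-rate-adaptive profile. $D(t)$ is piecewise linear between event
  times, so the integral is computed exactly by trapezoid over the
  corners; the test suite checks this against dense numerical integration
  of an independently coded pointwise evaluator (agreement well below
  $10^{-6}$). SPIKE has a compressed dynamic range: even independent
  10 Hz Poisson pairs rarely fall below 0.45.

The canonical time scales are $\tau_w \in \{5, 10, 20, 50, 100, 250, 500,
1000\}$ ms, all dividing the 2-s sweep exactly. Bins are half-open
$[k\tau_w, (k+1)\tau_w)$ and a spike at exactly $t = T$ is excluded by the
type, so no ambiguous final edge exists; widths that do not divide the
sweep keep a partial final bin.

## Input-set generators

Three designs cover the stimulus space:

* **Correlated Poisson sets** (`gen_correlated_set()`): 5 (or 10) trains
  at one rate whose mean pairwise R at 10 ms is tuned to a target.
  Construction: every train keeps each spike of a common reference
  Poisson train with probability $p$ and is topped up with private
  uniform spikes; pairwise correlation is then approximately $p^2$, and
  $p$ is tuned by bisection against the correlation *measured on the
  generated trains*, with a final single-spike refinement pass. A target
  of 1 short-circuits to identical copies, so the achieved correlation is
  exactly 1. Because the sets model designed stimuli that hold their
  nominal rate, realized spike counts (reference and per-train) are
  conditioned to ±12% of `rate * duration` by rejection; the trains are
  therefore Poisson-like with a lightly truncated count distribution, not
  exact Poisson samples.
* **Rate-varying set** (`gen_varying_rate_set()`, "input set A"): ten
  trains with rates spaced linearly 7→31.5 Hz and mean pairwise R held
  near 0.75. With Poisson marginals, the correlation between a 7 Hz and a
  31.5 Hz train is bounded near $\sqrt{7/31.5} \approx 0.47$, so no
  shared-reference copy scheme can reach 0.75 for all pairs. The
  generator instead couples thinnings of one maximum-rate reference:
  each reference spike carries a shared uniform mark and train $k$ keeps
  spikes with mark below $\mathrm{rate}_k/\mathrm{rate}_{\max}$. Fully
  shared marks give the comonotone (maximally correlated) coupling, whose
  mean pairwise R for this schedule is ≈ 0.76; redrawing marks
  independently with probability $1 - w$ interpolates toward independent
  thinning, and $w$ is tuned by bisection against the measured mean R.
* **Bursty set** (`gen_bursty_set()`, "input set B"): ten trains of
  exactly 21 spikes (10.5 Hz) whose spikes occupy a specified number of
  construction bins (default 10 ms), chosen uniformly without
  replacement, one guaranteed spike per chosen bin and the surplus spread
  uniformly. The per-train occupied-bin counts are not fixed by the
  design beyond "spanning a wide range"; the default `seq(3, 21, by = 2)`
  runs from tightly clustered (Occupancy 7 at 10 ms) to one spike per bin
  (Occupancy 1).

All generators are deterministic under `set.seed()` and attach a
generation report (achieved correlation, spread, iterations).

## The synthetic neuron

Real recordings are the transform under study; the package substitutes a
stochastic input→output model so that every downstream stage is testable
without tissue. The mechanisms are the minimal set that reproduces the
qualitative behaviors of the recorded cells: Bernoulli per-pulse
transmission (`p_spike`, default 0.5 — the mid-range transmission
probability targeted in the assay, plausible range ~0.2–0.8), Gaussian
latency jitter (default 5 ± 2 ms, chosen so that 5 ms binning still
mostly co-bins parent and child events), geometric bursts riding on a
transmitted pulse (`p_burst`, extra spikes at the intra-burst interval),
an absolute refractory period, and optional exponential-recovery
synaptic depression. An output spike is attributed to the inter-pulse
interval $(t_{\mathrm{pulse}}, t_{\mathrm{next}}]$; p(Burst) is the
probability of more than one output spike in such an interval.

Cell-type presets (`GC`, `FS`, `HMC`, `CA3`, `GC+gzn`) are *qualitative*
parameterizations reproducing orderings only — fast-spiking interneurons
transmit most reliably and burst most, granule cells are sparse
(mean output rate below the input rate) and near-Poisson, and partial
disinhibition (`GC+gzn`) raises both transmission and burst probability
relative to `GC`. No claim is made that the presets reproduce any
recorded cell's quantitative results.

Because transmission is probabilistic, even repetitions of the same input
train produce decorrelated outputs; a deterministic pass-through
parameterization (`p_spike = 1`, zero latency/jitter, no bursts)
reproduces each input exactly and is the suite's no-false-separation
control.

## Firing-rate and burstiness codes

Per-train features connect the similarity metrics to interpretable spike
train properties:

* firing rate = count / duration;
* Compactness = $1 - \mathrm{occupied\ bins}/N$ (maximum $1 - 1/N$ for a
  non-empty train, all spikes in one bin);
* Occupancy = count / occupied bins ($\geq 1$). At $\tau_w = T$ the
  single bin makes Occupancy equal the spike count, so separation through
  firing rate and through Occupancy coincide at the full-sweep scale.

Set-level burstiness is the Kullback–Leibler divergence of the output
set's pooled ISI distribution from a pooled Poisson-like input reference
of the matching rate class, both normalized to their own median ISI and
discretized into 250 bins over [0, 50] (normalized ISIs beyond 50 are
counted as overflow and dropped). Numerical choices the definition leaves
open: natural logarithm, and additive smoothing with
$\varepsilon = 1/(4\,n_{\mathrm{ISI}}\cdot 250)$ added to every bin of
both distributions before renormalizing — this keeps the divergence
finite in empty bins, vanishes asymptotically, and preserves
$D_{KL}(M\Vert M) = 0$ exactly. Note that between two finite samples of
the *same* process the estimate sits above zero by a sparsity floor on
the order of $K/2n$ for $K$ bins and $n$ ISIs; tests assert "near
Poisson" against that floor, not against literal zero.

Dispersion of a feature across a set is the Gini mean difference (mean
absolute pairwise difference), with self-comparisons and same-parent
sweep pairs excluded; `dispersion_output - dispersion_input` is positive
under pattern separation through that feature.

## Statistics

Graphs are summarized by unconstrained least-squares fits (linear or
parabolic — the parabola is not forced through (1, 1) even though
perfectly similar inputs could argue for it, matching the unconstrained
convention). Per input set, a two-tailed one-sample t-test of
$S_{\mathrm{input}} - S_{\mathrm{output}}$ against zero classifies
separation/convergence at $\alpha = 0.05$; a Kolmogorov–Smirnov normality
check is reported alongside but does not gate the test (a signed-rank
alternative is a flag), since the choice is a judgment call per dataset.
Group comparisons use a separate-lines ANCOVA (`s_output ~ s_input *
group`) with Tukey-adjusted pairwise slope and intercept contrasts via
`emmeans`. Points are parent pairs, so sets contribute several
non-independent points each; the pseudo-replication caveat applies as it
does to any pairwise-point convention.

Distances to the identity line are signed perpendicular distances
$(S_{\mathrm{input}} - S_{\mathrm{output}})/\sqrt{2}$ (positive =
separation; the sign is flipped for difference-based graphs so positive
always reads as separation). Vertical distances would differ only by the
$\sqrt{2}$ factor; the perpendicular convention was chosen and documented
since either reading is defensible.

## What the synthetic data can and cannot show

The generators emulate the designed stimulus statistics (rates,
correlation targets, burstiness spans) and the neuron model reproduces
the qualitative transformations: decorrelation growing with input
correlation, stronger decorrelation/orthogonalization at short time
scales with the scaling code showing the opposite trend, firing-rate
sparsification, and the celltype burstiness ordering. They do not model
membrane potentials, synaptic conductances, network inhibition, or any
recorded cell's quantitative parameters — so passing tests validate the
*measurement pipeline* and the qualitative computation, not quantitative
claims about tissue.

## Problem sizes and degenerate inputs

The shipped analyses use desk-scale batteries — eleven 5-train input sets,
50-sweep recording sets, 200-pair SPIKE batches, a few hundred
statistical replicates — chosen to estimate every reported quantity to
well within its assertion tolerance. Degenerate inputs are handled
explicitly: empty sweeps are flagged and excluded pairwise (a parent pair
keeps its graph point while any valid child pair remains, and exclusion
counts are reported); zero-variance count vectors make R undefined rather
than `NaN`-poisoning averages; duplicate spike times are rejected at
construction, and generators re-draw the rare floating-point tie.
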