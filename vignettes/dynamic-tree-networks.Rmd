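---
title: "Dynamic PLI networks and spanning-tree backbones: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic PLI networks and spanning-tree backbones: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mstnet)
```

This vignette is the package's account of its science: the model behind
each stage, the parameters that matter, what the synthetic generator
does and does not emulate, and the numerical choices made where the
design was genuinely open.

## 1. The pipeline

Trial-structured multichannel epochs (by convention −200 to 800 ms
around a stimulus at 1000 Hz) pass through:

1. common average reference → zero-phase band-pass per frequency band →
   baseline correction (−200–0 ms);
2. analytic-signal phases on the **full epoch**, sliced afterwards into
   five 100-ms post-stimulus windows (T1–T5) — filtering or Hilbert
   transforms are never applied per window, so their edge artifacts stay
   outside the analysis span;
3. a phase-lag-index (PLI) adjacency per trial × band × window;
4. the maximum spanning tree (MST) of each adjacency and its topology
   measures;
5. an information-based tree-dissimilarity gate against a reference
   tree, then Wilcoxon/FDR feature selection in the gated cells;
6. repeated stratified cross-validation of an RBF SVM on the selected
   features of a held-out trial subset.

## 2. Phase lag index

With analytic signal $z(t) = x(t) + i\tilde x(t) = A(t)e^{i\phi(t)}$,

$$\mathrm{PLI} = \Bigl|\tfrac1N \sum_{k=1}^{N}
  \mathrm{sgn}\,\sin\bigl(\Delta\phi(t_k)\bigr)\Bigr|,$$

where $\Delta\phi$ is the instantaneous phase difference of a channel
pair and $N$ the window's sample count (100 at 1000 Hz). The signum is
three-valued with $\mathrm{sgn}(0)=0$: a consistently zero-lag pair
contributes nothing, which is what makes the index robust to volume
conduction. Sine values within $10^{-12}$ of zero are truncated to zero
so analytically zero-lag inputs behave deterministically rather than at
the mercy of floating-point noise.

Two facts drive every design decision downstream:

* For iid phases, $E[\mathrm{PLI}] \approx \sqrt{2/(\pi N)} \approx
  0.08$ at $N = 100$.
* Band-limited phases are **not** iid: the phase difference of two
  independent signals confined to a band of width $B$ decorrelates on a
  $1/B$ timescale. A 100-ms window of a 4-Hz-wide band holds less than
  one independent sign sample, so the narrowband null PLI is large
  (≈0.85 in the alpha band) and broadly distributed. This is a property
  of windowed narrowband PLI itself, not of any estimator choice; it is
  why mean MST edge PLI values in such analyses sit around 0.7–0.8,
  why single-trial effects in narrow bands are intrinsically weak, and
  why the package's recovery studies plant their coupling in the
  widest band (gamma, 15 Hz) where ~3 independent phase samples per
  window give the backbone extraction real power.

## 3. Zero-phase filtering

The band-pass is specified as a 4th-order Butterworth applied
forward-and-backward (zero phase), because the connectivity stage
consumes instantaneous phase and any group delay would corrupt it. Two
numerical facts shape the realization:

* the expanded transfer-function coefficients of very narrow, very low
  bands (delta 0.5–4 Hz, theta 4–8 Hz at 1000 Hz) are unstable —
  coefficient rounding pushes poles outside the unit circle;
* a forward-backward pass without padding lets edge transients of
  narrow filters reach hundreds of samples into a 1-s epoch.

The package therefore applies the *exact* forward-backward response in
closed form: for a bilinear-transformed Butterworth band-pass of order
$n$ with prewarped edges $W_{l,h} = \tan(\pi f_{l,h}/f_s)$,

$$|H(\omega)|^2 = \Bigl[1 + \Bigl(\tfrac{W^2 - W_l W_h}
  {(W_h - W_l)\,W}\Bigr)^{2n}\Bigr]^{-1},\qquad W = \tan(\omega/2),$$

multiplied onto the FFT of the odd-reflection-padded epoch. This is the
same squared-magnitude (hence zero-phase) response `filtfilt` converges
to in steady state, is unconditionally stable for arbitrarily narrow
bands, and vectorizes across channels. Parity with `signal::filtfilt`
was verified on the stable bands (pointwise agreement away from the
unpadded implementation's edge transients). Passband centre gain is 1
within measurement tolerance and attenuation one octave outside the
band exceeds 40 dB.

## 4. Spanning-tree backbone and measures

Kruskal's algorithm on descending weights, ties broken by lexicographic
$(i,j)$ order so repeated runs and weight-tied test fixtures are
deterministic; zero-weight edges are admissible so any symmetric
nonnegative matrix yields a tree. With $N$ nodes and $m = N-1$ links,
the normalizations are: degree, leaf fraction, diameter and
eccentricity divided by $m$; betweenness divided by the undirected pair
count $(N-1)(N-2)/2$; tree hierarchy $Th = L/(2\,m\,\mathrm{MaxBC})$
with $L$ the raw leaf count. These conventions place the line and star
extremes at $D = 1$ vs $2/m$ and $L_f = 2/m$ vs $1$, and give the
published scale of such measures on 63-channel montages (e.g. $D
\approx 0.1$). "MST PLI" is the **mean** of the $m$ edge weights — a
sum over 62 edges could not live on the unit scale on which these
values are reported — and binarization keeps the topology while
preserving the pre-binarization weights for that one measure.

## 5. Tree dissimilarity and the gate

For trees $n, m$ on the same nodes,
$S_{n/m} = \tfrac1N\sum_i \log_{10} |S_n(i)/S_m(i)|$, where $S_k(i)$
sums the edge distances from node $i$ to its *direct neighbours* in
tree $k$. The edge distance is $d = 1/\mathrm{PLI}$ (the standard
similarity-to-distance map for PLI), which makes the score scale
invariant — rescaling all weights cancels in the ratio; $d = 1 -
\mathrm{PLI}$ is available behind the `distance` switch but is not
scale invariant and is non-default. The score is exactly 0 on
identity and antisymmetric under argument swap. Reference trees are
built per (band, window) from the element-wise mean adjacency of the
reference-condition trials of the analysis subset.

The gate runs a two-sided Wilcoxon rank-sum on the two contrast
conditions' scores per cell and adjusts by Benjamini–Hochberg across
the full band × window grid; only cells with adjusted $p \le \alpha$
(default 0.05) enter measure testing. BH (rather than
Bonferroni-family control) is the field default for this correction
and matches how per-cell critical p-values well above $\alpha/m$ arise.
Correction families are **per measure**: the full grid for global
measures, the grid × node count for nodal degree and betweenness —
the gate restricts which cells are tested, but the family size stays
the full grid, so gating never makes the correction more lenient.
Direction is reported as the sign of the median difference, as befits
an ordinal test. The rank-sum is computed exactly (enumeration) for
combined $n \le 20$ without ties, otherwise by normal approximation
with tie and continuity correction.

## 6. Classification

Significant features (global measures per gated cell; nodal degree/BC
per gated cell × node) are concatenated per trial in deterministic
(band, window, measure, node) order. The SVM uses an RBF kernel with
$C = 1$ and $\gamma = 1/d$ on z-scored features — the scale convention;
the kernel and hyperparameters are declared rather than tuned, and
means/SDs are fitted on training folds only so no information leaks
from test folds. Five stratified folds, five repetitions; decision
values are pooled within a repetition for the ROC and metrics are
averaged over repetitions. Cross-validation is stratified at trial
level (conditions pooled across subjects); with few subjects this can
be optimistic about subject-level generalization, which is a known
limitation, not a target of the synthetic studies. The time-segment
baseline concatenates raw amplitudes of an occipito-temporal channel
subset — it sees evoked amplitude, not phase coupling, and serves as
the comparison floor.

## 7. The synthetic generator

Each channel is a sum over bands of unit-RMS narrowband Gaussian noise
(synthesized spectrally, so the analytic signal is exact by
construction) plus broadband white noise. A planted
`coupling_graph` in a (condition, band, window) cell replaces a
fraction $w \cdot \texttt{coupling\_strength}$ of a coupled channel's
narrowband component by a shared carrier offset by the edge's target
lag, crossfaded with a 10-ms cosine ramp centred on each window border.
Centring the ramps matters: ramps placed fully inside the window would
de-couple 20 of the 100 PLI samples and cap planted-edge PLI near 0.8,
while the centred ramps leave ≤5 low-mixing samples per border inside
the window and a bleed into neighbouring windows that is undetectable
at the study sizes.

Carrier scoping follows the planted topology:

* **component carrier** (default; used by `star_coupling`): one carrier
  per connected component with per-node offsets accumulated along the
  edges. Every pair in the component is phase locked — for a star with
  equal edge lags that is exactly right, since all leaf–leaf pairs lock
  at lag 0 and are invisible to the PLI, leaving precisely the star.
* **edge carrier** (`chain_coupling`): one carrier per edge, mixed at
  its two endpoints with power split across a node's edges. Locking is
  strictly pairwise; a component carrier would lock all odd-hop pairs
  of a path at visible lags ($k\pi/2$) and turn the planted path into
  an effective clique for the PLI.

Defaults: 63 channels (10-10 montage labels), 1000 Hz, epochs −200 to
800 ms, the five classical bands, `coupling_strength = 0.9`,
`noise_sd = 0.3`. The noise default is a deliberate calibration: no
per-trial SNR is available to emulate, and 0.3 puts the broadband
contribution at ~5% in-band amplitude so that unit-weight planted
couplings at strength 0.9 reach near-ceiling PLI — the generator's
purpose is planted-truth recovery, and realistic EEG spectra, volume
conduction and artifacts are explicit non-goals. Everything is a
deterministic function of the single config seed.

What passing recovery tests therefore show: that the pipeline's
estimator chain (filter → phase → PLI → MST → dissimilarity → gated
selection → CV-SVM) recovers known coupling topology, direction and
location from signals with the right phase structure. What they do not
show: performance on volume-conducted, artifact-laden recordings with
subject heterogeneity — on real data the effects are far smaller and
require thousands of trials, consistent with the narrowband null
physics described in section 2 above.

## 8. Study sizes used by the automated checks

The recovery studies use 12 channels, bands {theta 4–8, gamma 31–46}
(two spectrally distant bands, so filter skirts do not leak one band's
coupling into the other's null), planted star vs chain graphs in gamma,
strength 0.9, 300 trials/condition for gate/selection studies (10
repetitions) and an independent 500-trial/class set — with coupling in
the two adjacent windows T2 and T3, mirroring multi-window condition
effects — for classification. The common average reference is applied
to recorded data but **not** in the recovery studies: the synthetic
montage is reference-free, and when every channel of a small montage is
coupled, the montage mean approximates the shared carrier itself, so
re-referencing would subtract the planted signal (with a 12-channel
all-node star the mean nearly equals a leaf signal). On a 63-channel
recording with a localized coupled subgraph this cancellation is
negligible and CAR behaves as intended.

## 9. Degenerate inputs and tie-breaking

All-zero signals have undefined phase and raise an error rather than
emitting arbitrary phases. Two identical samples give a degenerate
rank-sum flagged with $p = 1$. Zero-PLI tree edges make the reciprocal
distance undefined and raise. Weight ties in Kruskal are broken
lexicographically; exact ties are measure-zero on estimated PLI but
common in fixtures. A gate cell missing one contrast condition is
skipped with a warning. Constant feature columns get unit SD in
z-scoring to avoid division by zero.
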