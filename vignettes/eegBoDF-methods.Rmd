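---
title: "Scalograms, subset entropy and Bag-of-Deep-Features: the methods behind eegBoDF"
author: "eegBoDF authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scalograms, subset entropy and Bag-of-Deep-Features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegBoDF)
```

`eegBoDF` classifies emotional state (negative / neutral / positive) from
multi-channel EEG windows through five stages: wavelet scalograms, image
feature extraction, rough-set channel selection, Bag-of-Deep-Features
(BoDF) histogram encoding, and classical classifiers under cross-validation.
This vignette explains each model component, the parameters that matter,
the numerical choices we made where the design was genuinely open, and what
the synthetic-data experiments do and do not demonstrate.

## 1. The continuous wavelet transform

For a single channel $x(t)$ sampled at $f_s$ Hz, the transform at scale $m$
(in samples) and shift $n$ is

$$W_x(m, n) = \frac{1}{m^{p}} \int x(t)\, \psi^*\!\left(\frac{t-n}{m}\right) dt,$$

with $p = 1$ (L1 normalization, the default) or $p = \tfrac12$ (L2), both
selectable in `waveletSpec()`. The daughter wavelets
$\psi_{m,n}(t) = m^{-p}\,\psi((t-n)/m)$ reduce to the mother wavelet at
$m = 1, n = 0$. Two analytic mothers are provided, both defined in the
frequency domain and zero for $\omega \le 0$:

* **generalized Morse** (default): $\hat\psi(\omega) = a_{\beta,\gamma}\,
  \omega^{\beta} e^{-\omega^{\gamma}}$ with $\gamma = 3$, $\beta = 20$,
  normalised so the peak value is 2. This family is fully parameterised by
  its time-bandwidth product and avoids the Morlet's (tiny) non-zero mean.
* **analytic Morlet**: $\hat\psi(\omega) = 2 e^{-(\omega-\omega_0)^2/2}$,
  $\omega_0 = 6$. Its closed-form time expression makes it the reference
  for quadrature cross-checks.

**Scale grid.** 64 logarithmically spaced scales whose centre frequencies
$f = \omega_{\mathrm{peak}} f_s / (2\pi m)$ cover 1–45 Hz. This spans the
four classical EEG bands — $\delta$ 1–4, $\theta$ 4–8, $\alpha$ 8–13,
$\beta$ 13–30 Hz — with headroom, and the $\Delta\ln m \approx 0.06$
spacing is much finer than the Morse relative bandwidth
($\approx 1/\sqrt\beta \approx 0.22$), so reconstruction sums converge.

**Fast path and edge handling.** `cwt()` evaluates the transform as a
Fourier-domain product $X(\omega)\, m^{1-p}\hat\psi(m\omega)$ per scale.
The signal is symmetrically (reflect-) padded by up to one signal length
and then zero-extended so that the padded length exceeds the wavelet's
one-sided support at the largest scale — 7 scale units for the Morlet
(Gaussian envelope) but 26 for the Morse, whose envelope tails are heavier
than Gaussian. Without the zero gap, circular wrap-around contaminated
coefficients at the $10^{-2}$ level; with it, the FFT path agrees with
direct time-domain quadrature of the definition to better than $10^{-6}$
of the peak magnitude (this is asserted in the test suite against
independently evaluated mother wavelets: the closed form for Morlet,
high-order Gauss–Legendre inversion of $\hat\psi$ for Morse).

**Admissibility and inversion.** `admissibilityConstant()` evaluates
$C_\psi = \int \hat\psi^2(\omega)/|\omega|\, d\omega$ by adaptive
quadrature over the wavelet's effective support; it is quadratic in the
wavelet amplitude and diverges (an error) for nonzero-mean "wavelets" such
as a plain Gaussian bump. `icwt()` reconstructs through the single-integral
(delta-function) formula valid for analytic wavelets,

$$x(t) = \frac{2}{C_\delta}\,\mathrm{Re} \sum_j W(m_j, t)\, m_j^{p-1}\,
\Delta \ln m, \qquad C_\delta = \int_0^\infty
\frac{\hat\psi(\omega)}{\omega}\, d\omega,$$

with trapezoidal weights over $\ln m$. The two constants serve different
purposes: $C_\psi$ certifies invertibility, $C_\delta$ normalises the
synthesis sum. On band-limited signals (5–25 Hz content, 1000 samples at
200 Hz) the round trip `icwt(cwt(x))` achieves a relative $L_2$ error of
about 3–4 % with the default grid; the residual is dominated by scale
discretisation and signal edges, and the 5 % bound is asserted in the
tests.

## 2. Scalogram images and feature extraction

`renderScalogramImage()` maps $|W|$ through `log1p` compression (linear
optional), normalises, applies a colormap (jet or gray) and bilinearly
resizes to $224 \times 224$ (the conventional CNN input size; simulations
here use 64 px, see §6).

One rendering decision deserves emphasis: amplitudes are normalised by the
**98th-percentile** coefficient magnitude (clipped at 1), not by the
maximum. The per-image maximum is an extreme order statistic with high
sampling variance; dividing by it injects a common "brightness" factor
into every feature of every image, which for pure-noise channels creates
spurious coherent variation that the channel-selection statistic (§3)
mistakes for structure. With the quantile reference the effect disappears
(informative-channel recovery rose from 8/10 to 10/10 seeds in our
simulations). `refQuantile = 1` restores plain max-normalisation.

Feature extraction is a contract (`featureExtractor()`): any deterministic
function image $\to$ fixed-length vector, so a pretrained CNN backbone can
be adapted without touching the rest of the pipeline. The bundled
`fallbackExtractor()` computes interpretable multi-scale grid statistics —
per-cell means and standard deviations on $2\times2$, $4\times4$ and
$8\times8$ grids, magnitude-weighted 8-bin gradient-orientation histograms
on the $4\times4$ and $8\times8$ grids, and global intensity statistics —
zero-padded to $q = 1000$ (matching the output width of common 1000-class
backbones). Feature names are prefixed (`mean_`, `sd_`, `grad_`, `glob_`,
`pad_`) so intensity and texture statistics are distinguishable: a constant
brightness shift provably moves only intensity features, which the tests
assert. Cell standard deviations use a two-pass computation; the one-pass
moment difference loses all significant digits on near-constant cells.

## 3. Rough-set subset entropy and channel selection

Given discretized features, a decision table $(U, C \cup D)$ has objects
$U$ (here: recordings), discrete condition attributes $C$ and a decision
attribute $D$ (the emotion label; it is carried for stratification but does
not enter the statistic). Every attribute subset $P \subseteq C$ induces an
indiscernibility partition $U/P$; $[x]_P$ is the block containing $x$. The
subset entropy is

$$E(P \mid U \oplus C) = -\frac{1}{|U|} \sum_{x \in U} \log_2
\frac{|[x]_C \cap [x]_P|}{|[x]_P|}
 = -\frac{1}{|U|} \sum_{x \in U} \log_2 \frac{|[x]_C|}{|[x]_P|},$$

the simplification holding because $[x]_C \subseteq [x]_P$ for every
$P \subseteq C$. Key properties, all tested (and cross-checked against a
literal double-loop evaluation with explicit set intersections):
$E = 0$ iff $U/P = U/C$; $0 \le E \le \log_2 |U|$; and $E$ is monotone
under coarsening ($P' \subseteq P \Rightarrow E(P') \ge E(P)$).

**Discretization.** The statistic needs discrete attributes; features are
binned by equal-frequency (default) or equal-width cuts
(`discretizeFeatures()`, default 10 bins for general tables, 3 bins inside
channel ranking — one per class is the natural resolution there). Constant
columns collapse to one bin with a warning.

**Why channels are summarised before scoring.** The joint partition over
hundreds of discretized feature columns is all singletons at any realistic
number of recordings, sending every channel's score to the same degenerate
value. `rankChannels()` therefore summarises each channel's feature block
by the leading principal component of each of `nComponents` (default 3)
disjoint, interleaved feature chunks. The chunks are the crux: if a channel
carries coherent class structure, every chunk's leading component reflects
*the same* latent factor, the discretized attributes agree, and the
channel's partition stays coarse — large $E$. A noise channel's chunk
components are mutually independent, their joint partition collapses
towards singletons, and $E \to 0$. (A plain top-3-PC summary fails here:
components beyond the first are orthogonal to the class factor by
construction and refine the partition exactly like noise.)

**Score orientation.** With continuous features, $U/C$ is essentially
always the singleton partition, so *low* $E$ means "this channel alone
already distinguishes every recording" — which a pure-noise channel does
perfectly well. Channels that carry a *large information boundary* —
coherent, class-structured feature blocks — are the informative ones, so
the default ranking is **descending** $E$ (`direction = "high"`), and the
recovery simulations confirm it: with 4 informative + 4 noise channels the
top-4 set equals the informative set in 20/20 seeds at the study
conditions of §6. `direction = "low"` (most $C$-faithful first) is
available for tables whose $U/C$ is genuinely coarse. Ties break by
ascending channel index for determinism.

`selectFeatures()` keeps the top-budget channels (default budget 26,
matching the conventional 26-of-62 working subset; the montage's fixed
default subset in `seedMontage()` is an a-priori alternative to the
data-driven selection).

## 4. Bag of Deep Features

Per class, the selected per-channel feature vectors are clustered with
k-means into $k$ centroids (`stats::kmeans`, 10 random restarts, best
inertia kept, all under a supplied seed; with at most $k$ distinct vectors
the centroids are the vectors themselves). The per-class codebooks are
concatenated — three classes give $3k$ centroids — and each recording is
encoded as the histogram of Euclidean-nearest-centroid counts of its
channel vectors, ties to the lowest centroid index. Counts always sum to
the number of encoded vectors (asserted over randomised inputs), and the
$3k \le 42$-dimensional code replaces the raw
$q \times \text{channels}$-dimensional representation.

$k$ is searched over $\{8, 10, 12, 14\}$ by `selectK()`, which maximises a
user-suppliable evaluator (default: cross-validated downstream accuracy;
ties resolve to the smallest $k$). With feature vectors built from 10
latent clusters per class, an inertia evaluator prefers $k = 10$ over
$k = 8$ in at least 80 % of seeds — the grid search behaves as a model
selector, not a formality.

## 5. Classifiers and evaluation protocol

GUI-style classifier names are mapped onto standard learners: *cubic SVM*
= polynomial kernel of degree 3 (`e1071::svm`), *fine KNN* = 1 nearest
neighbour (`class::knn`), *medium tree* = depth-20-capped `rpart`,
*subspace KNN ensemble* = 30 bagged 1-NN learners on random halves of the
feature dimensions with majority vote. `class::knn` breaks ties at random,
so predictions run inside a locally seeded RNG scope — end-to-end reports
are byte-identical across runs with the same master seed.

`runPipeline()` evaluates by stratified $k$-fold cross-validation (default
5 folds) at the recording level; `groupBySubject = TRUE` instead assigns
whole subjects to folds for subject-independent evaluation. **Everything
data-dependent — channel ranking, discretization, the k-means vocabulary —
is fitted inside each training fold only.** The report records, per fold,
which recordings contributed vectors to the vocabulary, and the test suite
asserts this set never intersects the test fold. A permuted-label control
(same pipeline, labels shuffled) lands in the three-class chance band.

## 6. The synthetic generator: what it emulates, and what it does not

`generateDataset()` emulates the *layout and spectral structure* of a
SEED-style emotion study: `nSubjects` subjects × 3 classes ×
`nTrialsPerClass` trials, a 62-channel extended 10–20 montage with a
26-channel working subset, 1000-sample windows. Signal model per
informative channel: per band, 3 sinusoids at uniform-random in-band
frequencies and phases, amplitude = 5 µV × the class's band gain, plus
white Gaussian noise (sd 1 µV) on all channels; non-informative channels
are noise only. Defaults chosen once and fixed:

* **sampling rate 200 Hz** — 1000-sample windows then span 5 s and resolve
  every band up to β = 30 Hz with a comfortable margin below Nyquist;
* **class gains differing only in β** (negative 0.6×, neutral 1×, positive
  2×; the separability studies use 3× for the positive class) — reflecting
  the common finding that higher-frequency power discriminates affective
  valence, and giving a controlled, periodogram-verifiable ground truth;
* **per-subject lognormal amplitude multiplier** (sd 0.1) so that
  cross-validation splits are not trivially exchangeable;
* **hashed per-recording RNG streams** — each recording's stream derives
  from (master seed, subject, trial, label), so any single recording is
  bit-reproducible regardless of generation order.

Deliberately *not* modelled: ocular/muscle artifacts, volume conduction
and inter-channel correlation, 1/f background spectra, non-stationarity
within a window, and any stimulus semantics. Passing tests on this
generator therefore demonstrate that the pipeline's machinery is correct
and that it recovers planted band-power structure; they do not establish
accuracy figures on real EEG, where artifact handling and cross-subject
variability dominate.

**Problem sizes.** The simulation studies use 32 scales, 64 × 64 images,
and datasets of 30 recordings (channel recovery, 20 seeds) and 90
recordings (end-to-end classification); these sizes were chosen as the
smallest at which the statistics of interest are stable, and all defaults
scale up unchanged.

## 7. Numerical choices and degenerate inputs

* Eq-style conv layer arithmetic (`convOutputSize()`) errors on non-exact
  division rather than silently flooring.
* Cross-entropy (`crossEntropyLoss()`) uses the natural logarithm (the
  softmax convention) and signals a zero probability at the true class as
  an infinite-loss condition with a warning.
* Equal-frequency binning uses interpolated (type-7) quantiles, so a
  column with exactly `nBins` distinct values is coded bijectively.
* Degenerate requests fail loudly: empty scale grids, non-admissible
  wavelets, band edges at/above Nyquist, `k` exceeding the vector count,
  empty classes, budgets exceeding the channel count, single-channel
  rankings (returned but flagged degenerate).
* Dataset containers are HDF5 (groups `subject_*/trial_*` with `samples`,
  `label`, `fs`, `channels`); MATLAB ≥ v7.3 files are HDF5 underneath and
  read through the same path, while writing pre-HDF5 MAT containers is not
  supported.

## 8. Known limitations

The subset-entropy statistic scores channels through a low-dimensional
summary; channels whose class information lives only in high-order feature
interactions could be missed. The BoDF code discards within-recording
channel identity (histograms are bags). The bundled extractor is a
hand-crafted stand-in whose separability on real scalograms will be below
a trained CNN backbone's. And the generator's clean spectral ground truth
makes the end-to-end accuracy an upper bound on what identical settings
would achieve on real recordings.
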