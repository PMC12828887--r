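---
title: "Decoding repetition suppression and measuring memory sharpening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding repetition suppression and measuring memory sharpening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

In a mnemonic similarity task a subject views a stream of images and
reports, for each one, whether it is novel or an exact repeat of an image
seen earlier in the session. Some "novel" images are *lures*: new images
that are visually similar to a previously shown image, at a graded visual
dissimilarity `d`. Plotting the percent-chose-repeat (PCR) against `d`
gives a memory-fidelity curve running from the hit rate at `d = 0` (exact
repeats) to the false-alarm rate at `d = 1` (unrelated novel images). If
memory behavior tracked visual similarity exactly, that curve would fall on
the straight line joining those endpoints. Systematic deviation below the
line — lures treated more "novel" than their visual similarity warrants —
is *sharpening*; deviation above it is *broadening*. Sharpening is the
behavioral signature of pattern-separation-like computations somewhere
between high-level visual representations and the memory read-out.

Neurally, recognition memory in high-level visual cortex and hippocampus is
carried largely as *repetition suppression* (RS): a reduced spiking
response to a repeated image. A linear decoder trained to separate novel
from repeated responses therefore predicts a PCR for any test condition,
including lures, and the same sharpening analysis can be applied to the
decoder's predictions. This package implements that full chain — visual
dissimilarity, session screening, pseudopopulation assembly,
cross-validated decoding, the sharpening metric and its dynamics — plus a
spiking-data simulator with a known ground-truth transfer function, so
every stage can be validated end to end without access to recordings.

## The generative model

`simulate_session()` draws, for unit $i$ and time bin $t$ (10 ms bins on a
−300 to +600 ms peristimulus grid), Poisson counts with rate (spikes/s)

$$\lambda_i(t) = b_i + g_i\, v(t)\,\bigl(1 - s_i\, r(t)\, m(d)\bigr)$$

* $b_i$, $g_i$: baseline and visually evoked gain, log-normal across units
  (defaults: median 5 and 10 spikes/s, `sdlog` 0.5 — typical cortical
  rates).
* $v(t)$: visual response envelope, ~0 before 80 ms, ~1 during the 500 ms
  viewing window, decaying after offset.
* $r(t)$: logistic suppression onset ramp (half-maximum 200 ms, reaching
  ~1 by 400 ms), reproducing the within-trial growth of RS.
* $s_i$: fraction of the evoked response removed on an exact repeat,
  normal with mean 0.15 and SD 0.10, truncated to $[0, 0.95]$; a
  configurable minority (default 10%) of units have the sign flipped
  (repetition *enhancement*). The suppression term is present only on
  second presentations.
* $m(d)$: the *memory transfer function*, the simulator's ground truth.
  `transfer_profile()` provides linear ($1-d$), power ($(1-d)^\gamma$;
  $\gamma>1$ sharpened, $\gamma<1$ broadened) and logistic families, all
  with $m(0)=1$, $m(1)=0$, non-increasing.

The default suppression level was chosen so that a few-hundred-unit
pseudopopulation decodes novel vs repeat at roughly 85% accuracy with unit
d′ near 0.17 — the regime in which these experiments operate. Behavioral
choices are a logistic read-out of the z-scored population spike count in
the 300–500 ms decision window, mixed with a 5% lapse rate, so behavior and
neural predictions derive from the same signal.

A session has 1,500 trials by default: 450 exact novel/repeat pairs, 160
novel/lure pairs at N-backs drawn from {23,…,26}, and fillers standing in
for vigilance trials and lure repeats (excluded from analysis, as in the
task's design, where they serve to balance the reward structure:
`session_composition()` shows ~57% of trials rewarded "novel" and ~13%
lures). Lure dissimilarities are uniform on (0.05, 0.95); the empirical
per-session distribution of lure dissimilarities in real experiments is not
published, so the uniform default is an explicit, configurable placeholder.

**What the simulator does not emulate.** True temporal ordering (N-back is
recorded as metadata; no lag-dependent forgetting), aborted trials, eye
movements, firing-rate drift, correlated noise between simultaneously
recorded units, and image-identity effects (every first presentation is
statistically identical). Passing tests therefore validate the analysis
chain's correctness and calibration, not these aspects of real recordings.
All randomness flows from one master seed: `simulate_study()` draws one
sub-seed per session, so studies are reproducible and sessions
independent.

## Dissimilarity and confound checks

`representational_dissimilarity()` is 1 minus the Pearson correlation of
two images' feature vectors (model-derived ITC representations): 0 for an
image with itself, ~1 for unrelated images, 2 for anti-correlated ones.
`select_lure_pairs()` greedily pairs the two closest images in a
within-category dissimilarity matrix (ties break lexicographically by image
id — the source procedure is silent, so determinism wins), and
`assign_pairs_to_sessions()` spreads pairs over sessions by round-robin
over dissimilarity strata under a per-session category cap of 4; the exact
"spread evenly" procedure is likewise unspecified, so the stratified
round-robin is this package's documented choice.

The low-level-statistics confound check (`lowlevel_stats_vector()` +
`loo_correlation_classifier()`) asks whether dissimilarity bins can be
predicted from trivial image properties: 18 values per image (mean, sample
variance, standardized skew, standardized kurtosis — not excess — max, min
per RGB channel; constant channels record skew/kurtosis as 0 with a flag),
classified by highest Pearson correlation with leave-one-out bin
prototypes. For label-independent features the accuracy converges to the
1/3 chance benchmark.

## Screening, d′, pseudopopulations

Sessions are included when they have ≥1,200 completed trials, at least one
visually responsive unit (two-sample t test of per-trial rates in
[−300, 0) vs [50, 350) ms, p < 0.1), and ≥2% repetition modulation on
exact repeats in 300–500 ms. The by-eye stability criterion of the source
procedure is not algorithmic, so it is replaced by an optional split-half
rate-ratio drift screen, off by default. Unit d′ is
$(\mu_N - \mu_R)/\left(\tfrac{1}{2}(\sigma_N + \sigma_R)\right)$; positive
= RS.

`build_pseudopopulation()` pools units across sessions into four aligned
blocks (novel/exact, repeat/exact, novel/lure, lure). Lure pairs are sorted
ascending by dissimilarity within session and aligned across sessions *by
rank* (per-session dissimilarity distributions differ, so value-based
alignment would leave gaps); exact pairs are aligned in seeded random
order, consistent with dissimilarity 0. Sessions are trimmed to the
shortest session's pair count by seeded random ablation. Alignment permutes
trials only — a tested invariant is that each unit's count multiset per
condition is untouched. The reported dissimilarity at each rank is the
across-session mean at that rank.

## Decoders and cross-validation

Both decoders are linear discriminants $f(x) = w \cdot x - b$ with
$b = \tfrac12 w\cdot(\mu_N + \mu_R)$: the spike-count classifier uses
$w = \mathbf 1$ (pure population-RS read-out) and the weighted (prototype)
classifier uses $w = \mu_N - \mu_R$. Responses with $f(x) \ge 0$ are
classified "novel" — the tie goes to novel, so "repeated" means strictly
below criterion, matching a PCR defined as the fraction of trials *below*
the criterion.

Each of the (default) 100 cross-validation iterations shuffles every
unit's responses across pairs within condition — jointly for the two exact
blocks (preserving the novel/repeat pairing per image) and jointly within
each of 3 ranked lure bins with the matched novel-lure responses — to
destroy artificial within-session correlations while leaving every unit's
marginal distribution per condition exactly unchanged. When the lure count
is not divisible by 3, remainder pairs go to the lowest-dissimilarity bins
(133 → 45/44/44). The holdout of exact pairs defaults to the largest bin
size; published holdout counts do not equal pairs/3 exactly and the
underlying arithmetic is unspecified, so `holdout_size` is exposed as an
override rather than guessed. Per iteration the held-out novel/repeat PCRs
anchor the rescaling $C_{\text{resc}} = (C - C_R)/(C_N - C_R)$, which maps
repeat performance to 0 and novel performance to 1 (i.e. rescales both
anchor accuracies to 100%).

`ranked_unit_curve()` grows the population in deciles ranked by the signed
training weights (high → RS first, low → enhancement first, random),
recomputing the ranking from each iteration's training split only; all
rankings share each iteration's shuffle and holdout, so the three curves
coincide exactly at 100%.

## The sharpening metric

`sharpening_metric()` takes a PCR curve with endpoints at `d = 0` and
`d = 1`: (1) anchor-rescale all PCRs so the curve $y(d)$ runs 0 → 1;
(2) signed area $A = \int_0^1 (y(d) - d)\,dd$ by the trapezoidal rule over
the curve's points (no smoothing or parametric fit); (3) double it so the
saturating step curves score ±1; (4) weight by
$\min\{((\text{acc}-0.5)/(\text{peak}-0.5))^2, 1\}$ where acc is the mean
of the curve's novel and repeat accuracies — 1 at the highest observed
performance, 0 at chance. Positive values mean sharpening. Three numerical
choices deserve note:

* **Orientation.** After rescaling, $y$ measures "novelness", so lures
  classified more novel than the benchmark lie *above* the diagonal; the
  sign convention is fixed so that this — sharpening — is positive.
* **Clipping.** When classifier performance is near chance the anchors
  nearly coincide and the rescaled curve can leave $[0, 1]$; the doubled
  area is clipped to the metric's defined range $[-1, 1]$. At chance the
  anchors coincide exactly and the result is 0 with weight 0 (degenerate
  flag).
* **Weight anchor.** For a single-window analysis the peak is that
  analysis's own mean accuracy; for sliding-window dynamics it is the
  maximum mean accuracy across windows, so pre-onset windows (chance
  accuracy) are down-weighted toward 0.

The same metric applies to behavioral curves with behavioral accuracies as
anchors; whether the performance weight is applied to behavior is exposed
by simply passing the desired `peak_accuracy` (the package applies it
uniformly).

`sliding_window_sharpening()` uses 21 windows of 200 ms. The source
procedure fixes the count and width but not the placement; centers at
−100 to +500 ms in 30 ms steps were chosen to span the pre-onset baseline
through stimulus offset while keeping every window on the recorded grid.
`sharpening_latency()` is the first window center at or above 0.1 with no
interpolation; crossings before 0 ms are impossible latencies triggered by
noise and are excluded (counted in an attribute), never-crossing iterations
are missing. `compare_latencies()` is a Welch two-sample t test (fractional
degrees of freedom).

## Calibration and recovery behaviour

The test suite pins down, among others: metric calibration (diagonal → 0,
dense step curves → ±1 within trapezoid discretization, chance → 0),
anchor rescaling (anchors map to exactly 0/1), oracle equivalence of the
vectorised routines against brute-force loops, and parameter recovery — 20
replicate studies of 200 units, 150 exact / 100 lure pairs per session,
100 CV iterations per condition recover the correct sharpening sign for
$\gamma = 3$ and $\gamma = 1/3$ and stay within ±0.03 of zero on average
for linear transfer. These problem sizes were chosen to put the
population-level signal-to-noise ratio in the ~85%-accuracy regime
described above while keeping a full recovery run in minutes on one CPU.

Two properties of the estimator are worth keeping in mind when
interpreting results on real data. First, *noise linearizes*: decreasing
the suppression signal-to-noise ratio pulls the measured curve toward the
linear benchmark, so measured sharpening is attenuated toward 0, never
inflated — halving the generative suppression strictly shrinks the
recovered value for a sharpened generator (a tested property). Second,
because count noise enters a threshold read-out, a high-SNR population
adds a small sigmoidal distortion of its own around mid-dissimilarity;
this distortion is antisymmetric about the curve's midpoint and therefore
cancels in the signed area for a symmetric lure-dissimilarity
distribution, which is why the linear regime recovers ≈0 rather than a
spurious positive value.

## Known limitations

* The uniform lure-dissimilarity placeholder and the absence of
  session-to-session heterogeneity make the simulated studies cleaner than
  real ones; between-study variance of the recovered metric is therefore a
  lower bound on what real data would show.
* With only 3 interior lure points, the trapezoidal area is a coarse
  estimate of the underlying curve's area; this matches the binned
  analysis it implements but limits sensitivity to non-monotonic
  transfer shapes.
* The metric is undefined-by-design at chance performance (weight 0); runs
  whose peak accuracy does not exceed 0.5 report 0 everywhere.
* Session/pseudopopulation persistence is plain CSV/JSON
  (`write_session_csv()`), chosen for portability and text-only
  reproducibility; large studies are meant to be re-simulated from their
  seed rather than stored.
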