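---
title: "Methods: calcium transient analysis and population co-activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium transient analysis and population co-activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calico)
```

`calico` implements an analysis pipeline for chronic two-photon calcium
imaging of hippocampal CA3-like pyramidal neuron populations, together
with a synthetic-data generator that emulates the recording design closely
enough that every stage can be validated by parameter recovery. This
vignette explains the underlying models, the parameters that matter, the
numerical choices, and what the validation does and does not show.

## The measurement model

A neuron's somatic calcium, reported by a red genetically encoded
indicator, is observed as a raw fluorescence trace sampled at 10 Hz
(population imaging, 325 × 325 μm field of view) or 20 Hz (zoomed-in
recordings paired with juxtacellular electrodes). Acquisition is organized
in 30-s trials separated by 10-s gaps without frames; all per-trace
computations therefore run strictly per trial and never bridge gaps.

Preprocessing follows the standard percentile-baseline scheme:

1. **Background**: the 1st percentile (linear-interpolation convention,
   used for every percentile in the package) of a background signal over
   the whole session, subtracted from the ROI trace. The background should
   come from an off-cell measurement; taking it from the ROI trace itself
   partially nulls the baseline, so `estimate_background()` warns unless
   this is acknowledged. Synthetic sessions emit an explicit background
   signal for this purpose.
2. **Baseline F0**: the 51st percentile of the background-subtracted
   signal in a centered 8-s sliding window, truncated (not padded) at
   trial edges. A percentile just above the median tracks slow drift while
   ignoring transients. `ΔF/F = (F − F0)/F0`; a baseline that reaches zero
   indicates background over-subtraction and is an error, not a value.
3. **Smoothing**: a five-point first-order Savitzky–Golay filter. For
   polynomial order 1 this equals the 5-point moving average (an exact
   identity, which the tests verify against a direct least-squares line
   fit and against a reference filter implementation). At trial edges the
   window shrinks symmetrically — 3 points at the penultimate samples,
   passthrough at the endpoints — rather than reflecting data, which would
   fabricate curvature.

ΔF/F is a fraction internally everywhere; interfaces that quote percent
say so explicitly.

## Event detection and classification

Transients are detected on the smoothed ΔF/F trace. The noise scale is
the median absolute deviation × 1.4826 — chosen because it ignores sparse
transients — computed per neuron and session. Frames above k·SD define
threshold-crossing segments (k = 3 under anesthesia, 4 awake, where noise
and residual motion are larger); within each segment the *first* local
maximum with topographic prominence ≥ 20% ΔF/F and ≥ 1.5 s separation
from previously accepted peaks becomes the event peak. The prominence
floor has an important scientific consequence: single APs (≈11% ΔF/F)
are below it, so detection deliberately misses a floor of single APs and
very brief bursts — detected events ride on bursts, which the
burst-statistics validation quantifies (mean largest burst under detected
synthetic events ≈ 6 APs).

Each event gets three descriptors: the peak ΔF/F; the full width at half
maximum, with the local baseline taken as the median over the second
before the event and half-max crossings linearly interpolated between
frames (events whose half level is not reached inside the trial get `NA`);
and the mean ΔF/F over the 3-s window from 1 s before to 2 s after the
peak, which is proportional to the integral calcium influx and hence to
the number of APs in the window. Windows clipped by trial bounds are kept
but flagged.

Awake events whose 3-s-window mean exceeds the 95th percentile of the
pooled anesthetized distribution are classified **large**; anesthetized
events are never split by size. Large events are the locomotion-associated
prolonged firing episodes the population analyses track across days.

## Ground-truth calibration

Paired juxtacellular + imaging recordings anchor the interpretation of
ΔF/F in spikes. Spike times come from simple thresholding (median +
5 robust SD, 1-ms refractory period — both configurable). *Isolated
transients* are AP groups spanning at most 200 ms and preceded by at
least 2 s of silence; their segments are aligned to the first AP and
expressed relative to the **local pre-event baseline** (median
background-subtracted fluorescence over the preceding silent second)
rather than the sliding-percentile F0. On activity-dense calibration
traces the 51st-percentile baseline sits measurably above the true
baseline and would shrink all amplitudes by 5–10%; the isolation rule
guarantees the local baseline is sampled from silence, making it
unbiased.

Per AP count, the decay time constant is fitted by profiled least squares
(a 1-D search over τ with the amplitude solved linearly — it cannot fail
to converge) to the pooled decay frames of all the count's events, where
each event contributes only frames between its transient peak and its
next AP. Per-event peak amplitudes are then single linear coefficients
with τ held fixed, evaluated at the last AP of the group. Evaluating the
fit at the last AP back-extrapolates the frame-sampled maximum (biased
low by up to `exp(−Δt/τ)` ≈ 8% at 20 Hz) to the true transient peak.
Free-offset per-event exponential fits were rejected: at the realistic
signal-to-noise ratio of single-AP events (≈2) their τ estimates pile up
on bounds and their mean amplitude is biased upward by nearly a factor of
two. The 90% confidence interval on τ comes from a bootstrap over events.

Pooled interspike intervals are split by k-means (k = 2, 10 restarts,
seeded) into intraburst and interburst components, reported ascending.
Clustering is done on linear ISIs; with a heavy-tailed interburst
distribution the squared-error objective would prefer splitting off the
pause tail instead, which is why the generator bounds its pauses (below).

## The look-up table

The 3-s-window mean ΔF/F of every detected ground-truth transient
(fluorescence resampled to 10 Hz, anesthetized detection criteria) is
paired with the true AP count in the same window. Two descriptions are
fitted: a linear reference line on points below 40% mean ΔF/F, and a
model-free Gaussian-process regression (squared-exponential kernel,
hyperparameters chosen by 5-fold cross-validated predictive log density,
at most 400 training points) whose 95% *predictive* corridor quantifies
the uncertainty. The estimate is projected to be monotone nondecreasing
with isotonic regression — AP count cannot decrease with integral ΔF/F
under the forward model — and anchored at (0, 0). Queries beyond the
table support extrapolate along the linear reference line with the last
corridor width doubled, and are flagged. Because the window also catches
neighboring bursts (APs whose ΔF/F contribution lies partly outside the
window), the empirical slope is slightly steeper than the naive
`0.011 ΔF/F per AP`; the table is consistent because queries at
application time have the same property.

## Spike inference stand-in

The supervised deconvolution network used in the original analysis chain
is external; `deconvolve()` is a transparent stand-in with the same
interface: per trial, nonnegative least squares against the calibrated
single-AP kernel yields AP counts per frame, converted to AP/s and
smoothed with a 470-ms-FWHM Gaussian. Downstream consumers only see a
spike-rate trace, so a trained network can be slotted in unchanged. The
stand-in is exact for frame-aligned spikes in the linear regime; spikes
at sub-frame phase are attenuated by up to `exp(−Δt/τ)` (a documented
discretization property the tests pin down). Its correlation with ground
truth is reported by `evaluate_inference()` but not asserted against any
fixed target, since the stand-in is not the cited network.

## Behavioral state and population statistics

Wheel speed (40 Hz) is averaged within each imaging frame interval and a
frame is `run` iff its speed strictly exceeds 0.5 cm/s. Events are
assigned to the state at their peak frame; state rates are counts over
dwell time (undefined, not zero, when a state has no dwell), compared by
one-way ANOVA; speed histograms are occupancy-normalized and compared by
Kolmogorov–Smirnov — all standard tests called from `stats`.

Co-activity of a neuron pair is the symmetric mean of the fraction of
each neuron's events with a partner peak within the window (default 1 s:
0.5 s before to 0.5 s after the peak, closed interval). The window-sweep
family anchors exactly as follows: 0.1 s means the single peak frame;
windows up to 2 s start 0.5 s before the peak; from 3 s on they start 1 s
before. The shuffle null redraws each neuron's peak times uniformly
within its own trials — respecting the acquisition structure — while
preserving per-trial event counts and the detector's 1.5-s separation
(an exact order-statistics construction, no rejection sampling), and
averages 100 randomizations. Stability across days is the Pearson
correlation of pair co-activity on day N+1 against day N over pairs
defined on both days; pairs with no events on a day are dropped, not
imputed as zero, which would manufacture stability. Distance dependence
uses Euclidean centroid distances with pairs ≤ 10 μm flagged as
neighbors and excluded in the contamination control.

For multi-day large-event incidence the null preserves each day's count
of large-event neurons and reassigns which tracked neurons carry them,
independently across days; the chance level is the null mean and the
p-value the fraction of simulations at or above the observed fraction.
On two days this null has a closed hypergeometric form that the Monte
Carlo implementation is tested against. The null strategy is exposed as
its own function precisely because reasonable alternatives (conditioning
on per-neuron propensities, for instance) give different chance levels.
Condition contrasts subtract the shuffle-null means before forming
ratios, with SEMs combined by Gaussian error propagation.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions and were fixed from the recorded constants, not adjusted to
test outcomes:

- **Spike trains**: bursts at interburst intervals with mean 0.81 s,
  modeled as a 0.5-s offset plus a lognormal (shape 1.2) winsorized at
  3 s total, the location solved so the mean is exact. The offset keeps
  the slow ISI component separated from the fast one and the cap bounds
  the pause tail; both are needed for two-cluster k-means on linear ISIs
  to have its optimum at the component split (an unbounded tail with the
  nominal spread would make k-means split off the pauses instead, and the
  component means would be unrecoverable by the stated analysis). The
  realized interburst SD (≈0.4 s) is consequently smaller than the
  recorded cluster SD; the cluster *means* are the validated quantities.
- **Intraburst ISIs**: normal with mean 5.3 ms and nominal SD 7.3 ms,
  rejection-sampled into [2.0, 8.6] ms — a 2-ms refractory floor with the
  upper bound symmetric about the mean so the truncated mean stays
  exactly 5.3 ms (a one-sided floor alone would shift it to ≈9 ms).
- **Burst sizes**: truncated geometric on 1–17 with mean ≈ 2.13. This
  value follows from rate consistency: ≈5000 APs in 33 min of paired
  recording at 0.81-s interburst intervals force a mean burst size near
  2.1 and an overall rate of ≈2.5 AP/s (within the 0.3–5 Hz range typical
  of these neurons). The often-quoted ≈6-AP mean describes bursts
  underlying *detected* transients — a detection-biased subset the
  pipeline reproduces (≈6 APs) without putting it into the generator.
- **Forward model**: each AP adds an instant-rise kernel of 11% ΔF/F
  (linear to 10 APs per burst, half gain beyond; optional supralinear
  factor, off by default) decaying with a time constant interpolated
  linearly in burst size from 0.3 s (1 AP) to 0.8 s (≥10 APs). Noise is
  additive Gaussian with per-frame SD 0.05 ΔF/F-equivalent at any frame
  rate (the value that leaves single APs below the detection floor), with
  an optional mean-preserving Poisson-like component.
- **States and large events**: burst-rate multipliers 1.0 (anesthetized),
  0.70 (awake rest) and 1.53 (run), taken from the reported small-event
  rate ratios; large events are 3-s dense Poisson AP trains (40 APs
  expected) inserted only during run bouts, at 2/min, in a persistent
  random subset of neurons (default one quarter). The anesthetized
  condition is rest-only with no large events.
- **Sessions**: behavior alternates exponential rest/run bouts (means
  40 s / 20 s, lognormal run speeds around 8 cm/s); neuron identities,
  centroids (uniform in the field of view with a 5-μm minimum spacing),
  per-neuron lognormal amplitude scaling (SD 0.2) and co-activity group
  membership persist across days. Group members receive shared burst
  times with probability `p_shared` on top of independent background
  activity. Everything derives from one master seed through fixed
  per-neuron, per-day substreams, so sessions are bit-identical given the
  seed.

What the generator does **not** emulate: imaging movies and motion
artifacts (traces are generated directly), optical crosstalk between
neighboring ROIs, bleaching trends, non-stationary noise, and any
systematic difference between anesthetized and awake burst *shapes*.
Passing the validation suite therefore shows that the analysis correctly
inverts this generative family at realistic noise — it does not show
robustness to the imaging artifacts the out-of-scope motion-correction
and ROI-selection steps address in real data.

## Numerical choices and edge cases

- One percentile convention (linear interpolation between order
  statistics) everywhere.
- Exponential fits are profiled 1-D optimizations — no start values, no
  convergence failures; decay windows end at the next AP, so fits never
  see contamination.
- Kernels are rendered to 30 decay constants, making superposition exact
  to numerical precision (the additivity tests rely on it).
- The NNLS solver tolerance is the `pracma::lsqnonneg` default; traces
  are deconvolved per trial because trial gaps are non-physical.
- Degenerate inputs error loudly and early: empty or non-finite signals,
  baselines reaching zero, flat traces in noise estimation, unsatisfiable
  shuffle separation constraints, unreachable truncated-geometric means,
  co-activity with fewer than two neurons.
- Shuffle redraws use the order-statistics construction for uniform
  sampling under a minimum-separation constraint, which is exact and
  rejection-free.

## Problem sizes in the validation

The test suite and the acceptance script size their simulations to what
the analysis needs statistically: calibration recovery uses five
independent seeds of 33 min of paired recording (four neurons of
8.25 min each — matching the recorded calibration corpus and yielding
≈40 isolated single-AP events per seed); ISI clustering pools ≈25 000
intervals; look-up validation uses ≈200 detected ground-truth events with
a held-out pair for corridor coverage; population round-trips use 8–10
neurons over 2 days of 8 trials. These sizes give standard errors
comfortably inside the recovery tolerances while keeping the whole
validation in the minutes range.

## Known limitations

- The look-up table is calibrated for the event-density regime it was
  built from; transferring it to recordings with very different rates
  changes the neighboring-burst contribution to the 3-s window.
- The GP corridor assumes roughly Gaussian residuals; AP counts are
  integers, so coverage is nominal only to binomial accuracy.
- The deconvolution stand-in shares the interface but not the accuracy
  profile of a trained network; its correlations with truth are
  informative, not comparable to published network scores.
- k-means on linear ISIs is the stated analysis and is validated for the
  generator's (bounded-pause) regime; strongly heavy-tailed pause
  distributions require log-scale clustering, which the clustering
  function does not currently implement.
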