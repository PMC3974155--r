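---
title: "Methods: BF bursting / frontal ERP coupling analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BF bursting / frontal ERP coupling analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfcoupling)
```

This vignette is the package's account of the science it implements: the
generative model behind the synthetic sessions, the statistics the analysis
stages compute, the numerical conventions, and the choices made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The scientific setting

In a rodent auditory oddball task, a frequent standard tone is presented
every 2 s and a rare reward-predicting oddball tone appears after a
uniformly drawn 2–6 intervening standards (oddball-to-oddball gaps of
6–14 s). A subpopulation of basal forebrain (BF) neurons responds to
motivationally salient tones with a phasic burst in the 50–200 ms window;
simultaneously, a negative-going event-related potential (ERP) appears over
frontal cortex, with a positive local-field-potential (LFP) counterpart
concentrated in deep cortical layers. The analyses here quantify, at the
single-trial and millisecond scale, how tightly the two phenomena are
coupled: bursting-neuron classification, ROC "choice probability" of
behavioral outcome from EEG amplitude, spike-count-to-amplitude coupling,
fine-timescale spike–EEG cross-correlation, laminar profile similarity, and
the latency with which electrical BF stimulation reinstates the same
laminar profile.

## The generative forward model

`forward_model_params()` defines an ensemble of `n_neurons = 10` BF
bursting neurons. Neuron $i$ has peri-stimulus intensity

$$\lambda_i(t) = b + s \cdot A_i \exp\!\left(-\frac{(t - \mu_i)^2}{2\sigma^2}\right),$$

with baseline $b$ = 4 Hz, peak rates $A_i$ descending linearly from 100 to
20 spikes/s, burst-peak latencies $\mu_i = 50 + 5(i-1)$ ms (the strongest
bursters fire earliest), kernel width $\sigma$ = 25 ms, and a per-trial
amplitude scale $s$ (1.0 on hits, 0.5 on miss/standard trials). Spikes are
drawn as an inhomogeneous Poisson process: a homogeneous baseline over the
session plus, per trial, a Poisson number of burst spikes with Gaussian
times. The frontal EEG is

$$\mathrm{EEG}(t) = p \cdot g \sum_i d_i(t - \delta) + \varepsilon(t),$$

where the drive $d_i$ is the exact evoked intensity (noise-free mode) or
the Gaussian-smoothed spike rate (spike-driven mode), $\delta$ = 5 ms is
the fixed spike-to-ERP delay, polarity $p = -1$ makes the frontal ERP
negative-going, and $\varepsilon$ is white Gaussian noise. The 32-channel
laminar LFP uses the same summed delayed drive weighted by a fixed
unit-norm depth profile with a positive deep-layer lobe and a weaker
negative superficial lobe. Both renderers are exactly linear in $s$, which
is the property the quintile "linear scaling" analysis visualizes.

Parameter defaults and their reasoning:

| parameter | default | why |
|---|---|---|
| peak rates | 100..20 Hz, linear | the model's graded-ensemble premise |
| onset stagger | 5 ms/neuron | strong-bursts-lead premise |
| burst kernel | Gaussian, sigma 25 ms | symmetric and unimodal; symmetry makes the cross-correlation peak recover the ERP delay in expectation (shift theorem); the width puts most burst mass inside the 50–200 ms window |
| baseline rate | 4 Hz | round value typical of the homogeneous BF bursting-neuron baseline (~3.8 Hz) |
| miss/standard scale | 0.5 | the model's 50% attenuated example trial |
| ERP delay | 5 ms | the model's fixed spike-to-ERP delay |
| ERP gain | 0.2 uV/Hz | puts hit-trial ERP peaks near 100 uV at the summed drive's scale |
| noise SD | 15 uV | evoked window amplitudes resolvable in single trials but far from noise-free |
| hit rate / FA rate | 0.85 / 0.05 | well-trained performance: high hit rate, low false-alarm rate |
| stimulation latency | 8 ms | evoked laminar response beginning shortly after a BF pulse |

The generator emulates: the oddball trial grammar, graded bursting with
Poisson variability, linear amplitude scaling across trial types, the
delayed linear spike-to-ERP transform, a depth-structured LFP, a control
EEG channel with no task-locked component, and stimulation blocks with
pulse artifacts and an early non-specific transient. It does **not**
emulate: hardware filtering, slow drifts or oscillatory background (noise
is white), cross-trial adaptation or learning, correlated noise across
channels, spike-sorting artifacts, or biophysical current sources. Passing
tests therefore demonstrate correctness of the *analyses* under the model's
assumptions, not that real recordings satisfy those assumptions.

## Numerical conventions

* **Windows are half-open** $[a, b)$ everywhere; a sample or spike at $t$
  belongs to the bin whose left edge is $\le t$. Bursting windows are
  [50, 200) ms, cross-correlation windows [0, 170) ms, layer-profile
  windows are the 60 ms centered on the population burst peak.
* **Milliseconds at the interface, seconds internally**, converted once.
* **1-ms binning** uses `floor((t - onset) * 1000 + 1e-6)`: the microsecond
  guard keeps a spike lying exactly on a bin edge in its half-open bin
  despite floating-point subtraction noise.
* **Bin centers**: the noise-free intensity renderer evaluates the
  intensity at sample-bin centers so that spike-count bins (effective
  center $t + 0.5$ ms) and EEG samples share a time base; without this the
  recovered spike-to-ERP lead is systematically inflated by half a
  millisecond.
* **Permutation p-values** use the add-one form
  $p = (1 + \#\{|T_{null}| \ge |T_{obs}|\})/(n_{perm} + 1)$, avoiding
  $p = 0$ at finite sample.
* **Ties**: ROC choice probability uses midranks (Mann–Whitney
  equivalence); quintile assignment breaks amplitude ties by stable sort on
  trial order; the burst-peak argmax returns the earliest bin on ties.
* **Degenerate inputs error loudly**: silent units (undefined bursting
  index), zero-variance correlations, zero vectors in cosine similarity,
  all-negative profiles in peak-positive normalization, empty trial
  selections.

## Design choices where the method was open

* **Concatenation layout.** Each [0, 170) ms trial window is flanked by
  100 ms constant segments, with a single flank *shared* between adjacent
  trials (flank, trial, flank, trial, ..., flank; length
  $270 n_{trials} + 100$). The flanks are constants (spike flank = the
  unit's session mean rate per 1-ms bin; EEG flank = the channel mean), so
  they contribute no covariance and their sharing does not affect the
  correlation materially; the layout is fixed so tests can be bit-exact.
* **Sign conventions.** Positive best lag means the unit's spiking *leads*
  the EEG. Because the frontal ERP is negative-going, the EEG is
  polarity-rectified before both the amplitude-coupling and
  cross-correlation analyses: the channel is multiplied by the sign of its
  session-average evoked deflection in the burst window, so "strong
  bursting with a deep negative ERP" registers as a *positive* correlation
  and the coupling lag is the lag of the *maximum* coefficient. Both
  rectifications can be disabled.
* **Permutation envelope.** The cross-correlation null permutes the trial
  order of the EEG segments before concatenation. The significance band is
  per-lag two-sided quantiles by default, with a max-statistic (global)
  variant available via `method = "max_stat"`; the per-lag band matches the
  per-bin reading of the test, the max-stat band controls the family-wise
  rate across lags.
* **Choice-probability lags are left-aligned**: the 100 ms window starts at
  `onset + lag`.
* **Layer-profile window is centered** (+-30 ms) on the burst peak.
* **Stimulation onset** is the first post-pulse millisecond at which the
  normalized scalar projection exceeds the upper permutation band for at
  least 5 consecutive ms, excluding the +-5 ms artifact window; the
  stimulation band is 95% (two-sided 5%), profile-similarity significance
  1%, both configurable. The permutation band is computed per time point.
* **Population amplitude is a mean** (not sum) across bursting units; the
  30% trial-selection rule is scale-invariant either way.
* **"Baseline rate" in the lead/lag summaries is the session mean rate.**
  In the generator every neuron shares the same tonic baseline, but the
  session mean also inherits each unit's burst mass, so on synthetic data
  this covariate tracks bursting strength; on real data a pre-stimulus
  baseline would be the cleaner covariate.
* **Stimulation-evoked kernel.** An onset-truncated Gaussian (zero before
  the latency parameter, rising to its peak 10 ms later): the discontinuity
  at onset makes the configured latency exactly recoverable on noise-free
  data, which anchors the onset-detector tests.

## Delay recovery in the single-neuron reduction

The acceptance analysis reduces the forward model to one bursting neuron
(100 spikes/s peak), renders the ERP noise-free from the smoothed
intensity, and asks the concatenated cross-correlation to recover the 5 ms
generative delay. Two scale choices matter and are deliberate:

* **All trials enter the analysis.** The 30% selection rule exists to
  exclude weak-bursting trials in real multi-unit sessions, where the
  population amplitude averages many units. With a single unit the
  "population" amplitude *is* that unit's own window count, and selecting
  on it conditions the spike train being correlated on itself; measured on
  this generator, that biases the recovered lead low by 2–3 ms. In the
  noise-free model every trial's expected amplitude is at least 50% of the
  hit mean, so the 30% criterion excludes nothing at the intensity level;
  the reduction therefore analyzes all trials.
* **About 1500 trials.** The correlation function of a sigma = 25 ms kernel
  is flat near its peak, so the argmax over integer lags wobbles by +-2 ms
  at ~500 trials; at ~1500 trials it is within +-1 ms of 5 ms across seeds.

## Problem sizes

The default test suite simulates sessions of 8–40 oddballs (roughly 45–220
trials), uses 50–1000 permutations depending on the statistic, 200–300
replicates for the calibration (uniformity) checks, 2000 trials for the
Poisson PSTH calibration, and ~1500 trials for delay recovery; the whole
suite and the acceptance script each run in well under a minute of CPU
apart from the pipeline integration test. Calibration tests use a
chi-square bound on the per-bin z-scores rather than a per-bin 3 SE rule,
because with 30 bins the latter rejects a correct simulator about 8% of the
time.

## Known limitations

* The generator's white noise makes permutation nulls better behaved than
  on real EEG with autocorrelated background; significance calibrations
  here do not guarantee calibration on real 1/f-type noise.
* The spike-driven ERP renderer smooths with the same kernel that shapes
  the intensity; on real data the effective spike-to-field kernel is
  unknown and asymmetric kernels would bias the recovered lead.
* Cross-correlation assumes 1 kHz signals; 2 kHz inputs are decimated by
  2-sample means, a mild low-pass that is not a hardware anti-alias filter.
* Real-data summary fractions (how many units are bursting, coupled, or
  significant) depend on the generator's settings and are reported, not
  asserted, by the pipeline.
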