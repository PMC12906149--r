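---
title: "A softmax decision stage for simulated 3AFC auditory detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A softmax decision stage for simulated 3AFC auditory detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softafc)
```

## The model

`softafc` simulates three-alternative forced-choice (3AFC) auditory
detection experiments. On each trial a listener hears three intervals —
two containing only a reference stimulus $R$ and one containing the
reference plus a test signal $RT$ — and must pick the odd one out. The
simulated listener works on *internal representations* (IRs): band
$\times$ time matrices of spike counts obtained by passing each interval
through an auditory-nerve frontend and histogramming all fibers' spikes
per critical band.

The decision pipeline, per trial:

1. **Memory template.** The listener's auditory memory is
   $S_{max} = IR(RT_{max}) - IR(R)$, the difference between the internal
   representation of the *highest-intensity* test stimulus in the sweep
   and the clean reference representation. The rationale: the strongest
   stimulus is the one used in practice trials, so it is the memory the
   listener carries into the experiment. A legacy mode instead rebuilds
   the template from the stimulus presented at the current trial's
   intensity (`memory_mode = "RT"`).
2. **Internal noise.** Independent zero-mean Gaussian noise of standard
   deviation $\sigma_w = \sigma \cdot x$ is added to each interval's IR,
   where $x$ is the standard deviation of the clean reference IR (pooled
   over all bands and bins, population convention) for the current
   frontend profile and paradigm. Expressing the noise *relative* to the
   representation's own scale makes the normal-hearing (NH) and
   electric-hearing (EH) profiles comparable even though their IR
   amplitudes differ by the fiber-count ratio (50 fibers per band vs 1).
3. **Per-band correlation.** For each interval $i$ and band $b$, the
   score $z_{b,i}$ is the zero-lag correlation between
   $NIR_i[b] - IR(R)[b]$ and $S_{max}[b]$. The default statistic is the
   Pearson correlation (scale-invariant and bounded, which keeps $z$ on a
   temperature-comparable scale across profiles); a raw dot product is
   available via `normalization = "dot"`.
4. **Softmax decision.** Per band, scores are mapped to interval
   probabilities by a temperature-parameterised softmax
   $$p_i = \frac{e^{z_i/T}}{\sum_j e^{z_j/T}},$$
   computed with max-subtraction so no finite score can overflow. The
   probability assigned to the odd interval is averaged (unweighted) over
   bands, and then over trials (100 by default), giving the per-intensity
   probability correct. The legacy winner-take-all rule
   (`decision_rule = "argmax_legacy"`) instead picks the interval holding
   the single largest score across all bands, with exact ties broken
   uniformly at random.

The temperature $T$ is the model's slope dial: as $T \to 0$ the softmax
approaches the argmax indicator (steep psychometric function, high
asymptote), as $T \to \infty$ it approaches uniform guessing at the 3AFC
chance level $1/3$. The relative noise $\sigma$ positions the curve.
Because the unweighted band average includes bands whose template carries
no information, the mean-softmax rule does not reach 100% correct even at
high intensity — those bands contribute $1/3$ each. This is a property of
the decision rule, not a bug; an optional template-energy threshold
(`band_inclusion = "template_energy_threshold"`) is provided, off by
default, for exploring that ceiling.

## Paradigms and stimulus conventions

Two validation paradigms are built in:

* **Masker-probe**: a 100-ms 1-kHz masker, 100 ms of silence, then a
  10-ms 1-kHz probe whose level is swept in dB relative to the masker
  amplitude (default $-40\ldots0$ dB in 9 steps). The reference omits the
  probe.
* **Amplitude-modulation detection**: a 1500-Hz carrier with 40-Hz
  sinusoidal modulation of depth $m \in [0,1]$, peak-normalised so the
  modulated and unmodulated stimuli share the same maximum amplitude; the
  reference is the pure carrier. Default duration 300 ms (12 modulation
  cycles); default depth grid $0.01\ldots1$, log-spaced.

Neither paradigm's source specifies ramps, so every tone segment gets
2-ms raised-cosine on/off ramps (configurable) to avoid spectral
splatter. The reference is calibrated to 65 dB under the package's fixed
convention $\mathrm{dB} = 20\log_{10}(\mathrm{RMS}/\mathrm{ref})$, with
the reference pressure chosen so 65 dB corresponds to RMS 0.05 in model
pressure units; test stimuli reuse the gain computed from their
paradigm's reference so $R$ and $RT$ share one physical scale. For the
masker-probe paradigm the calibration RMS is computed over the masker
segment only, since the reference defines loudness and the probe is the
manipulated part. Only relative levels matter downstream because the
internal noise is itself relative.

## The surrogate auditory-nerve frontend

The detection stage accepts spike trains from *any* frontend
implementing the one-function contract `simulate_frontend(frontend,
stimulus, seed) -> spike_train_set` (validated at the boundary:
half-open time support, sorted times, refractoriness). The built-in
surrogate is deliberately phenomenological — it is **not** a
reimplementation of any published auditory-nerve or cochlear-implant
model, and its parameters must not be read as reproducing one. It
emulates the features the detection model needs:

* **Tonotopy**: one-ERB-wide first-order Butterworth bands (zero-phase,
  applied forward and backward) on an ERB-spaced grid, 20 bands
  125–8000 Hz for NH and 16 bands (mirroring an electrode array) for EH;
  rectified, 150-Hz-lowpassed envelopes averaged into 1-ms bins.
* **Rate-intensity dependence**: a sigmoid from spontaneous to saturated
  rate. The sigmoid midpoint (40 dB) was placed while inspecting
  envelope levels alone: a 65-dB tone yields roughly 56 dB in its best
  band under the envelope convention above, so the default −40…0 dB
  probe sweep spans the sigmoid's dynamic range. NH defaults: 50 sp/s
  spontaneous, 250 sp/s maximum, 10-dB slope. EH defaults reflect
  electric stimulation of a deafened cochlea: 0.1 sp/s spontaneous,
  400 sp/s maximum, 3-dB slope (narrow electric dynamic range).
* **Stochastic timing with refractoriness**: per fiber, at most one
  spike per 1-ms bin, emitted with probability
  $1-\exp(-r \cdot a \cdot \Delta t)$ and jittered uniformly within
  $[0, \Delta t - t_{refr})$ of the bin onset, which guarantees the
  0.7-ms absolute refractory period between consecutive spikes.
* **Slow adaptation producing forward masking**: each spike multiplies
  the fiber's adaptation state by $1 - 0.02$; the state relaxes toward 1
  with $\tau = 100$ ms, so a 100-ms masker measurably suppresses the
  response to a probe 100 ms later.
* **Reproducible, isolated randomness**: each (band, fiber) pair draws
  from its own counter-based substream derived from the simulation seed,
  so changing the fiber count never perturbs other fibers' spike trains,
  and output is bit-reproducible given a seed.

What the surrogate does *not* emulate: phase locking and fine timing,
spread of excitation and channel interaction in electric hearing, any
speech-processing strategy, loudness growth, and rates above
1000 sp/s (the one-spike-per-bin discretisation compresses very high
rates). Passing tests therefore demonstrate properties of the detection
model under a plausible spike-train generator, not fidelity to any
specific cochlear model.

## Forward-masking stage (FMS)

Between histogramming and noise, each band's time series passes through
a leaky-subtraction operator:
$$\mathrm{out}[t] = \max(0,\ \mathrm{in}[t] - k\,a[t]), \qquad
  a[t] = d\,a[t-1] + (1-d)\,\mathrm{in}[t-1],\quad d = e^{-\Delta t/\tau},$$
with $\tau = 50$ ms, $k = 0.5$, and $a[1] = 0$. The state $a$ is a
*leaky average* of recent activity: the $1-d$ normalisation keeps it on
the scale of the input, so $k$ is a dimensionless attenuation fraction
independent of the bin width. (An unnormalised accumulator at these time
constants would carry roughly $\tau/\Delta t = 50\times$ the mean input
and, at any useful $k$, would zero the entire representation — including
the probe — so the normalised form is the one implemented.) Sustained
input decays toward $(1-k)$ of its level, onsets pass through, and
activity shortly after a masker is suppressed relative to the same
activity in quiet. The operator is a documented stand-in for a masking
stage whose exact published form is not restated here; it can be
disabled (`fms_config("none")`), and conclusions should be checked with
it off as well.

## Memory quality and the two memory modes

Stored representations (the clean $IR(R)$ and the template source) are
averages over `memory_reps = 10` independent frontend simulations: a
listener's memory is built over repeated presentations, so its spike
noise is suppressed relative to the single-presentation trial intervals.
This matters most for the EH profile, whose single fiber per band would
otherwise hand the detection stage a template dominated by sampling
noise.

Under `memory_mode = "RT"` the template is an independently simulated
clean IR of the stimulus *at the trial's intensity*. At the sweep
maximum this makes the two modes distributionally identical (the
"right side" of the psychometric curve is unaffected by the memory
choice). At low intensities the intensity-matched template is weak. Two
caveats discovered while validating this stage are worth recording:

* With a *near-deterministic* frontend (electric stimulation), an
  intensity-matched template still carries the systematic $RT - R$
  difference at low intensity, which is what elevates the legacy model's
  left asymptote above chance. This surrogate is not in that regime: its
  intrinsic spike variability dominates the relative Gaussian noise at
  $\sigma$ values of order $10^{-2}$, so the left-asymptote elevation is
  weak here.
* In fact, for the NH profile the ordering at the sweep floor *inverts*
  slightly but systematically (about $+0.02$ in favour of RT\_max at
  $-40$ dB, stable across seeds at $n = 300$ trials): a $-40$ dB probe
  still drives a small rate increase above background, and the
  high-intensity memory — being the cleaner matched filter — exploits it
  better than the weak intensity-matched one. The corresponding
  acceptance check asserts the expected ordering and is allowed to fail
  for NH rather than papering over the discrepancy; the right-side
  agreement and the EH comparison hold.

An alternative reading of the legacy memory — reusing the *presented
realisation itself* as the template — was implemented and rejected: in
this surrogate's noise regime the template then self-correlates in every
band and pins the probability correct at 1.0 at all intensities, which
contradicts the unaffected right side that motivates the comparison.

## Numerical choices

* IR bin width 1 ms; mass-conserving boxcar smoothing of 5 bins (each
  source bin's kernel renormalised over its in-range support, so totals
  are conserved exactly at the edges). Both configurable.
* Population (divide-by-$N$) convention for $x$; $x$ is a scale factor,
  so only a fixed, documented convention is needed.
* Pearson scores for a zero-variance template or difference band are
  defined as 0 (the band then contributes chance, $1/3$).
* Softmax uses max-subtraction; overflow is impossible for finite
  scores. Strictly interior probabilities are only guaranteed while the
  scaled score range stays below $\log 2^{52}$ (double-precision
  rounding, not underflow, is the binding constraint).
* Argmax ties (measure-zero in practice, common in degenerate fixtures)
  are broken uniformly at random from a seeded stream.
* All randomness derives from one master seed through substreams keyed
  by (intensity value, trial, interval, stage), so a point's result does
  not depend on its position in a sweep and any component can be re-run
  in isolation.
* The logistic summary fits $p(I) = 1/3 + (a - 1/3)\,
  \mathrm{logistic}((I-\theta)/s)$ with the 3AFC guess rate fixed;
  `max_slope` $= (a - 1/3)/(4s)$ is the steepest ascent, the natural
  slope summary when the asymptote and scale both react to $T$. Flat
  curves return `fit_ok = FALSE` instead of failing.

## Problem sizes used by the test suite

The stochastic checks run at sizes chosen to keep Monte Carlo error
well below the effects being asserted while remaining quick on a
laptop: slope-versus-temperature uses 10-band NH curves, 7 intensities,
50 trials per point and 5 seed replicates; the chance-floor check uses
1000 trials; the memory-mode comparison uses 300 trials per point; the
forward-masking sign test uses 200 repeats. `scripts/acceptance.R`
recomputes the same quantities from scratch at comparable sizes.

## Known limitations

* The surrogate's noise regime differs from detailed cochlear models:
  here the frontend's own spike variability, not the relative Gaussian
  noise, limits performance at small $\sigma$. Consequently $\sigma$
  begins to shift the psychometric curve at values of order 1 rather
  than $10^{-2}$, and Fig.-style comparisons at very small $\sigma$
  mainly probe the frontend, not the noise stage.
* The EH profile's psychometric range is compressed (a single stochastic
  fiber per band carries little probe information even with an averaged
  memory); treat EH curves as qualitative.
* The mean-softmax ceiling depends on the fraction of informative bands
  and therefore on the band grid; absolute asymptote values are not
  comparable across band sets.
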