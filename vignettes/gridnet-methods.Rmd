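---
title: "Grid-cell analysis and attractor-network methods in gridnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-cell analysis and attractor-network methods in gridnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gridnet` implements the spatial-coding analysis chain used for medial
entorhinal cortex (MEC) recordings in open-field arenas — rate maps,
gridness, firing fields, spike-train statistics, speed and head-direction
tuning, pairwise cross-correlation stability, and theta-band LFP analysis —
together with a synthetic-recording generator that supplies ground-truth
data for every stage, and a spiking continuous-attractor model of the grid
network with manipulations that emulate perineuronal-net (PNN) removal
around inhibitory interneurons. This vignette is the package's own account
of the methods: the models, the tunable parameters, the numerical choices,
and what the synthetic tests do and do not establish about real data.

## Rate maps and spatial correlations

A session is a tracked trajectory (default 50 Hz) and per-unit spike
times. The arena (1 x 1 m by default) is divided into 2 cm bins; a spike
map and an occupancy map are accumulated and *separately* smoothed with a
truncated Gaussian (4 sigma support, zero-padded boundaries), then divided
bin-wise. Two smoothing presets are in common use, sigma = 3 cm and 5 cm;
3 cm is the default everywhere. Bins whose smoothed occupancy is zero get
rate 0 and are flagged. Bin (1,1) sits at the lower-left corner and bins
are half-open, `[k*b, (k+1)*b)`.

Spatial correlations (between sessions, or first vs last 10 minutes within
a session) are Pearson correlations over bins, excluding bins with zero
*raw* occupancy in either map — unvisited locations carry no evidence.
Sessions shorter than 20 minutes are split at the midpoint for the
within-trial statistic and flagged.

The spatial autocorrelogram is the full, un-normalized sliding dot product
of the smoothed map with itself (size `(2n-1)^2`), computed by FFT and
tested against direct summation. It is left un-normalized because the
gridness statistic below correlates masked rotations and is therefore
scale-invariant. One consequence worth knowing: the linear (non-periodic)
autocorrelogram carries a triangular overlap envelope that pulls
peripheral peaks inward by 1–2 bins. The gridness rotations are computed
on the raw autocorrelogram, exactly as the procedure prescribes, but the
*spacing* estimator divides by the per-offset overlap count
`(n-|du|)(n-|dv|)` before locating the six peaks; without this correction
a 40 cm grid is recovered at ~36 cm, with it recovery is within one 2 cm
bin. Torus (wrap) autocorrelograms, used for the model's sheet activity,
have no envelope.

## Gridness, fields, and the field statistics

Gridness: local maxima of the autocorrelogram are found in 3 x 3
neighborhoods; the peak closest to the array center is the central peak
and the six nearest others (ties broken by angle) define the annulus —
inner radius half the distance to the closest peak, outer radius 3/2 the
distance to the outermost of the six. The annulus is rotated by 30, 60,
90, 120 and 150 degrees (bilinear interpolation about the array center;
bins leaving the valid region are excluded pairwise) and correlated with
the unrotated annulus:

  score = min(r60, r120) − max(r30, r90, r150).

Fewer than six peripheral peaks yields `NaN`. Peripheral peaks below 10%
of the strongest one are discarded (the underlying procedure says only
"finding the maxima"; some threshold is required on noisy maps). Spacing
is the median of the six peak radii (envelope-corrected, see above).

Firing fields: the global field radius is 0.7 times half the
center-to-closest-peak distance of the autocorrelogram. Rate-map peaks
closer together than that radius are pruned (the lower one loses); bins
with positive Laplacian (5-point stencil, reflected edges — the valleys)
are excluded; the remaining bins are labeled into 8-connected components;
components under 9 bins are dropped; components containing a surviving
peak become fields, sorted by descending mean rate. A component holding
two surviving peaks counts as one field. From the fields:

* spatial specificity = log10(FR_in / FR_out), with ±Inf sentinels (and a
  warning) when a rate is zero — such units are excluded from group
  statistics;
* spatial information = Σ p_i (λ_i/λ) log2(λ_i/λ), with p_i the occupancy
  probability, λ_i the bin rate and λ the occupancy-weighted mean rate.
  The formula as printed is the bits-per-spike form even though the
  surrounding text calls it bits per second; the default follows the
  formula, and `per_second = TRUE` gives Σ p_i λ_i log2(λ_i/λ) instead.

One selection effect is worth stating: for an *untuned* cell, fields
segmented from its own (noisy) map necessarily sit on its noise peaks, so
its in/out-field ratio is biased above 1. This is a property of the method
itself, which is why classification relies on shuffle nulls rather than
raw specificity, and why the package's "homogeneous cell" test evaluates
in/out rates against fields of an independent cell.

## Spike-train statistics and waveforms

The ISI coefficient of variation (sigma/mu, population sigma by default;
`sample_sd = TRUE` for the n−1 form) comes in three variants: per pass
through a field (≥ 3 spikes per pass, pass = contiguous in-field samples,
unit value = unweighted mean over passes), whole session, and slow-running
segments (speed < 8 cm/s, duration > 0.2 s, ≥ 2 spikes). Bursting uses a
10 ms rule: a spike with pre-ISI > 10 ms and post-ISI < 10 ms starts a
burst; both ISIs above 10 ms marks a single-spike event; everything else
(spikes inside bursts) is uncounted; the ratio is n_burst / n_single.

Waveform features are measured on the channel with the deepest trough:
trough-to-peak time on a 200-fold cubic-spline-upsampled trace, half-width
from linearly interpolated half-amplitude crossings. Units are split into
narrow- and broad-spiking classes by 2-means clustering of
(trough-to-peak, half-width), run per experimental group. Initialization
is deterministic — centers start at the units with extreme trough-to-peak —
so labels are reproducible and independent of input order.

## Tuning scores, shuffles, and classification

Instantaneous rate is a Gaussian kernel density of the spike times on a
regular clock. The speed score is the Pearson correlation between that
rate (kernel sigma 0.4 s, on the tracking clock) and running speed,
restricted to 0.02–1.0 m/s. Speed itself is estimated by smoothing the
positions with a 0.1 s Gaussian and taking central differences. Head
direction tuning uses 60 angular bins (6 degrees), occupancy-normalized
rates, and the resultant vector length of the rate-weighted unit vectors.

Null distributions come from whole-train time shifts: each of n = 1000
surrogates shifts every spike by one uniform draw from ±30 s, wrapping
circularly at the session edges (a drop-at-edges mode is provided; the
wrap preserves the spike count and is the default). The 95th percentile
of the surrogate statistics is the classification threshold. A unit is a
grid cell when both gridness and spatial information exceed their
thresholds, a speed cell when the speed score does, a head-direction cell
when the resultant length does; a "pure" speed cell is speed-tuned but
neither grid nor head-direction tuned (that last rule is a documented
choice — the source procedure names pure speed cells without defining
them). By exchangeability the per-criterion false-positive rate on
untuned cells is 5% by construction; the acceptance suite verifies this
on 200 untuned cells within the binomial interval.

## Pairwise cross-correlations and stability

Temporal cross-correlograms: kernel rates (10 ms Gaussian, 1 kHz) are
z-scored with the population standard deviation and cross-correlated over
lags ±1 s, divided by the sample count so a train against itself gives
exactly 1 at lag zero. Positive lags mean the second unit fires after the
first. Spatial cross-correlograms are periodic (wrap) cross-correlations
of z-scored rate maps divided by the bin count. A pair's stability across
two sessions is the Pearson correlation of its correlograms (2-D maps
flattened, NaN bins excluded pairwise); it is symmetric in session order.

Two controls mirror the original analysis: a zero-phase order-4
Butterworth band-stop (4–10 Hz) on the rate series, and deletion of
out-of-field spikes before correlating. On theta-free synthetic data the
controls leave the *structure* of the result intact (per-pair stabilities
correlate above 0.9 with the uncontrolled values); the band-stop does
shift raw stabilities slightly upward, because it also removes broadband
Poisson rate noise while the sub-hertz co-traversal signal that carries
the pairwise relationship is untouched. Conclusions drawn from either
version agree, which is the sense in which the controls "do not change
the results".

## LFP theta analysis

Raw traces (stored at 4.8 kHz) are low-passed with a zero-phase order-8
Butterworth at 90 Hz, linearly interpolated onto the 250 Hz analysis
clock (4800/250 is not an integer, so classical decimation does not
apply; 90 Hz puts the stop-band attenuation at the new Nyquist above
40 dB), and z-scored per session. The spectrogram is a Morlet continuous
wavelet transform with nondimensional frequency omega0 = 80 on a 2–20 Hz
grid at 0.1 Hz steps; omega0 = 80 is an extremely narrowband analysis
whose time support spans several seconds at theta frequencies — good for
tracking instantaneous theta frequency, poor for fast transients. Samples
inside the cone of influence (e-folding time sqrt(2)·scale from each
edge) are excluded from band averages.

Theta measures (band 4–12 Hz): the speed profile bins band power and
within-band peak frequency by running speed (0.02 m/s bins over
0.02–1 m/s); the power and frequency *scores* average the same measures
in 1 s time bins, keep bins with mean speed in 0.02–1 m/s, and correlate
each against binned speed. The Welch PSD (Hann, 50% overlap, 1024-sample
segments) supplies the theta peak in 6–12 Hz, with recording-level
bootstrap confidence intervals. Because of the wavelet's multi-second
support, slope-recovery tests use slowly varying speed (velocity
correlation time 10 s); with ordinary 1 s velocity correlations the
regression of frequency on instantaneous speed is attenuated — an
errors-in-variables effect of the estimator, not a bug.

## The synthetic-data generator

The generator defines the study conditions for every test:

* Trajectory: 2-D Ornstein–Uhlenbeck velocity (correlation time 1 s,
  mean speed 0.15 m/s, Rayleigh speeds), reflective walls, 50 Hz. In 20
  minutes it visits over 97% of the 2 cm bins; the unvisited remainder
  hugs walls and corners, as real foraging does. Head direction is the
  heading of motion plus von Mises noise; two-LED geometry is not
  simulated.
* Grid cells: intensity = baseline + (peak − baseline) · g(x), where g is
  the classic three-cosine hexagonal interference pattern (wave number
  4π/(√3·spacing)) rescaled to [0, 1] — an analytically known field
  geometry so spacing, orientation and phase are recoverable. Spikes are
  drawn by exact thinning of an inhomogeneous Poisson process at the
  interpolated position; options add multiplicative theta modulation and
  burst injection (a spike becomes 2–4 spikes at 5 ms ISI). Defaults:
  spacing 0.4 m, peak 15 Hz, baseline 0.5 Hz — a clean MEC grid cell.
  Head-direction (von Mises tuning), speed (linear rate-speed, rectified)
  and untuned Poisson cells use the same thinning machinery. A place cell
  is emulated by a grid cell whose spacing exceeds the arena.
* Protocol: Familiar I → Novel I–III → Familiar II. In novel sessions all
  grid cells share one rotation and shift, applied to the lattice *and*
  the phases (phase' = R·phase + shift), so pairwise offsets are preserved
  in the lattice frame — that is what makes remapping "coherent", and it
  is what leaves pairwise temporal cross-correlograms intact. Familiar II
  reuses the Familiar I map. `drift_sigma > 0` adds a random-walk phase
  drift in novel sessions; `drift_mode` selects one walk shared by the
  population (which degrades single-cell stability but spares pairwise
  relations) or one walk per cell (which destroys both). The shared mode
  is the default; the per-cell mode exists because destabilization of
  *pairwise* structure is a separate experimental signature.
* LFP: a theta oscillator with instantaneous frequency f0 + beta_f·v and
  amplitude a0 + beta_a·v plus 1/f background noise, synthesized directly
  at the 250 Hz analysis rate.
* Waveforms: two templates with trough-to-peak 0.2 ms (narrow) and 0.6 ms
  (broad) plus Gaussian noise, 50 samples at 48 kHz.

What passing tests show — and what they do not: the generators share the
tuning *families* the analyses assume (cosine grids, von Mises head
direction, linear speed coupling), so parameter recovery demonstrates the
estimators are correct and calibrated, not that real MEC data satisfies
those families. Real recordings add theta-phase precession, conjunctive
tuning, electrode drift and spike-sorting errors that the generator
deliberately omits.

## The continuous attractor model

Two populations of exponential integrate-and-fire neurons (E and I,
equal-sized square grids on the periodic sheet [0, 2π)²) interact only
through E→I and I→E synapses: each E unit excites the I units inside an
annulus (doughnut) around it, each I unit inhibits the E units inside a
disc. E units receive independent Poisson drive. Synapses are
difference-of-exponentials (beta) conductances normalized so the peak
equals the weight; membrane dynamics follow the EIF equation with the
exponential term clamped at the spike cutoff to avoid overflow; spikes
reset to V_reset (= E_L by default, satisfying both readings of the
reset rule) with a 2 ms refractory clamp and 1 ms axonal delay; the
integrator is forward Euler at 0.1 ms, validated against a fine-step RK4
reference on a single neuron to better than 2%.

Membrane and synapse constants are standard EIF values (E: 200 pF, I:
100 pF, g_L 10 nS, E_L −70 mV, V_T −50 mV, Δ_T 2 mV, V_peak 0 mV; τ_rise
1 ms; τ_decay 5 ms excitatory, 10 ms inhibitory; E_rev 0 / −80 mV). The
connectivity radii and coupling strengths were calibrated once, by
scanning until the excitatory sheet settles into a stable hexagonal
pattern: annulus 0.5–0.9, disc 0.25 sheet units, g_EI 4.5 nS and g_IE
30 nS at the 50 x 50 reference density, drive 3000 Hz x 0.4 nS. Weights
are scaled by `reference_n_side/n_side` when the sheet is refined — the
empirically determined rule that preserves the pattern-forming regime,
balancing the growing connection count against the shrinking quantal
fluctuations. The lower bound of the disc rule is read as the polar
coordinate domain, so the disc includes the co-located unit, matching
center-inclusive topology masks; the torus wrap is assumed because the
attractor pattern requires it. Initial potentials are drawn uniformly
between E_L and V_T to avoid a synchronized start.

Read-outs: per-neuron mean rates over the analysis window (the first
second is excluded as settling), with medians over all units and over
*active* units (≥ 1 spike) reported separately — the directionality
checks use active-unit medians, since the reference simulation's unit
counts indicate silent units were excluded there too. The sheet pattern
is the matrix of E spike counts, its torus autocorrelogram, and the
gridness score from the same module the recordings use.

PNN removal is emulated two ways: scaling g_EI by 0.7 (reduced
excitatory drive onto interneurons) or scaling the inhibitory C_m by 1.25
(the capacitance change reported for PNN digestion in vitro). Both lower
the median inhibitory *and* excitatory rates relative to paired-seed
controls — the model's central, somewhat counterintuitive prediction: the
excitatory drop is a composition effect, since weakened competitive
inhibition lets many more units fire at very low (out-of-field) rates,
dragging the median down even as total activity spreads.

Known limitations. Settling from random initial conditions occasionally
freezes a lattice defect (a grain boundary between bump domains), giving
an otherwise-patterned sheet a low gridness score; at 50 x 50 this
happens in roughly one settle in five, at 100 x 100 less often, and
defects do not anneal on simulated-seconds timescales. Sheet-gridness
evaluations therefore use the median over five independent settles, and
pattern-quality checks run at the full 100 x 100 scale (about 15 s per
simulated 4 s here) while the paired-seed rate comparisons use the
cheaper 50 x 50 sheet. Second, in this calibration the selected grid
spacing always exceeds the annulus outer radius, so interneurons at bump
centers receive no input from neighboring bumps and field-peak excitatory
units are drive-limited rather than inhibition-limited; both
manipulations can then only *lower* within-field peak activity, and the
in vivo-style ordering in which reduced coupling *raises* field peaks
while increased capacitance lowers them is not reproduced. The
corresponding acceptance check is left failing by design rather than
re-tuned away. Third, the excitatory-median drop under both manipulations
is a composition effect of the sparse patterned control state; when a
control settle lands in a disordered, large-halo state (many units firing
at very low rates) the median comparison can invert, even though the
inhibitory-rate drop is unconditional — total excitatory activity in fact
rises slightly with weakened inhibition, as expected physiologically.
Directionality statements therefore refer to controls that settle into
the patterned state, the regime the reference simulation's control
figures display. Finally, there is no velocity input, so the model
produces a static sheet pattern, not single-cell arena rate maps.

## Problem sizes and reproducibility

Synthetic sessions default to 10–20 minutes at 50 Hz tracking; shuffle
nulls use n = 1000 surrogates; classifier calibration uses 200 untuned
cells; attractor comparisons use 5 paired seeds of 4 simulated seconds.
Every stochastic function takes a `seed` and is bit-reproducible under
it; the pipeline driver records seeds and parameters in JSON logs next to
its outputs. The analysis scripts under `analysis/` run these stages in
order and write plain-text tables under `results/`.
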