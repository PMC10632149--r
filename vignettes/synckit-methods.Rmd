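---
title: "Methods: analysing optogenetically induced syncope recordings with synckit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing optogenetically induced syncope recordings with synckit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific setting

Optogenetic activation of cardiac vagal sensory afferents in the brainstem
triggers the Bezold–Jarisch triad — bradycardia, hypotension, suppressed
respiration — and, at sufficient stimulation frequency (20 Hz), syncope:
transient loss of consciousness with a broadband collapse of cortical
activity, cerebral hypoperfusion, pupil dilation, and silencing of spiking
across most recorded brain regions. synckit packages the analyses such an
experiment needs: spectral quantification of the EEG/LFP collapse, Poisson
statistics on spike trains, a behaviour-to-neural encoding model that
separates movement-driven activity from stimulation effects, and
cardiovascular/cerebral-blood-flow metrics, all on one session clock.

Because the corresponding animal recordings are too large to ship, every
stage is validated against a synthetic-session generator
(`generate_session()`) whose ground truth is programmed, so each analysis
can be tested as a recovery problem.

## Spectral analysis and syncope detection

EEG/LFP traces are notch-filtered (59–61 Hz, zero-phase Butterworth) and
decomposed with 80 logarithmically spaced analytic Morse wavelets from 0.5
to 120 Hz. The Morse family is parameterized by `gamma = 3` (the symmetric
member) and `beta = 27`; `sqrt(beta * gamma) = 9` corresponds to roughly six
oscillations under the envelope, a Morlet-like trade-off between time and
frequency resolution. Wavelets are amplitude-normalized to a common peak
response so a pure sinusoid attains its maximum at the centre frequency
nearest (in log spacing) its own — the property the bin-localization tests
exercise. Power is normalized per frequency by the mean power in a
pre-stimulus baseline window, making the baseline mean exactly 1 in every
row.

Syncope is operationalized on the 8–100 Hz band average of the normalized
spectrogram: onset is the first post-laser time the smoothed band power
falls below 50% of baseline, offset the first subsequent time it recovers
above 80%. The smoothing window is a 1-s centred moving mean; the width is a
config parameter because the source analyses specify smoothing without a
width. A centred window adds no systematic onset lag; the residual bias is a
fraction of the window for a sharp power step.

Light-on vs light-off inference uses a Monte Carlo cluster permutation test.
Trial labels are shuffled (1000 permutations by default); the per-pixel
permutation distribution of condition differences defines a two-sided
cluster-forming threshold (pixelwise p < 0.05), suprathreshold pixels are
grouped by 4-connectivity, and each observed cluster's area (pixel count) is
compared with the permutation distribution of maximum cluster areas of the
matching sign. A cluster is significant at p ≤ 0.025 per tail. Cluster-forming
threshold and connectivity are design choices — the source describes the
max-area logic but not these details. With small discrete areas the
(1 + k)/(n + 1) p-value is mildly conservative; the calibration experiment in
the acceptance suite measures the realized type-I rate under the null
(typically 2–4% against the nominal 5% combined across tails).

FFT band power uses non-overlapping 2-s segments (trailing partial segment
dropped), no taper by default (a Hann taper is available), and the six fixed
bands delta 1–4, theta 4–8, alpha 8–13, beta 13–30, low gamma 30–59 and high
gamma 61–120 Hz, with half-open band edges so shared boundaries are counted
once.

## Spike-train statistics

Curation precedes everything: a unit is *drifting* if its 100-ms binned rate,
smoothed with a Gaussian of sigma = 30 s, varies by more than a factor of 5
over the recording ("width" is read as the standard deviation; a config
switch can halve it for an FWHM reading). The minimum rate in the ratio is
floored at 1e-3 Hz so units that fall silent for an epoch are flagged.
Units averaging strictly less than 0.25 Hz are excluded; exactly 0.25 Hz is
retained. The curation order — drift, then rate, then all downstream
statistics — is fixed and idempotent.

*Inactivity at syncope.* Under Poisson spiking at the unit's baseline rate
lambda (computed excluding the encoding-model test segments), the
probability of a silent run of `k` 1-ms bins is `exp(-lambda k dt)`. Setting
this to 1% gives `k = -ln(0.01) / (lambda dt)`, capped at 4,000 bins (4 s)
for low-rate units. A unit is inactive at syncope onset if a silent stretch
of at least `k` bins *starts within 250 ms of the onset* — implemented as:
some inter-spike gap of length ≥ `k · dt` has an admissible start point
inside the ±250 ms tolerance window. Reading "starting within 250 ms" as the
start of the *maximal* silent run would make detection of a fully silenced
unit depend on when its last pre-onset spike happened to fall
(probability `1 - exp(-0.25 lambda)`, only 0.39 at 2 Hz), which contradicts
the 1% chance-probability construction; the admissible-start reading keeps
the false-flag probability near the designed 1% and detection of genuinely
silenced units near certainty. The tolerance is two-sided by default
(config-switchable to one-sided). `time_off` is the fraction of the bout's
1-ms bins lying inside qualifying gaps, reported only for flagged units; the
bout extends from onset to offset, or to the laser end when the offset is
undefined. A matched control applies the same criterion at a random
baseline onset and compares per-region percentages with a paired t-test
across regions.

*Laser-response latency.* Pooling spikes across the N laser onsets, windows
`[onset, onset + t)` grow in 1-ms steps and the tail probability of the
pooled count under the baseline Poisson rate,
`P = 1 - sum_{m<n} (N lambda t)^m e^{-N lambda t} / m!`, is accumulated in
log space; the latency is the first `t` with `P < 1e-6`. The search stops at
1 s (config; no upper bound is stated in the source analyses). A unit is
*laser-activated* when (1) its behaviour-prediction residual averaged over
the 800-ms post-onset windows across stimulations is strictly positive,
(2) the onset-window residual strictly exceeds the 800-ms pre-onset window
for every stimulation, and (3) its latency is below 250 ms. Region summaries
report the median latency of activated units, the percentage inactive at
syncope, and mean time off.

## Behaviour features

Face movies are reduced by motion-energy SVD: the absolute difference of
consecutive frames (first frame's energy set to 0) and the raw movie are
each decomposed in time segments (1000 frames by default), the per-segment
spatial bases are merged by a second SVD over their concatenation, and both
streams are projected onto the top 250 merged components. Whisking is the
L2 norm of the top 10 whisker-pad motion components per frame. Pupil area
comes from four tracked keypoints (top/bottom/left/right): coordinates are
median-filtered over 5 frames, the two axis lengths form an ellipse area
`pi a b / 4`, and frames with keypoint likelihood below 0.75, a blink (eye
dark-pixel count below a per-rig threshold), or a degenerate axis are
undefined and never interpolated. Traces are normalized per event to stated
baselines (30 s pre-laser; −6 to −4 s pre-syncope) with stated summary
windows (5 s post-laser; 2 s post-syncope).

## The behaviour-to-neural encoding model

Neural activity is binned at 100 ms (10 Hz); behaviour (the movie and
motion SVDs, concatenated to 500 inputs) stays at 30 Hz. The session is
split into one 63-s laser-free control test segment, one 63-s test segment
per laser (−3 to +60 s around onset), and 50-s non-test segments assigned
80/20 to training/validation — segment lengths chosen against leakage
through the slow autocorrelation of behaviour. Laser periods never touch
training.

The network is: linear layer → one-dimensional temporal convolution, whose
output is subsampled at the neural bin centres → ReLU → a narrower linear
layer whose output is the *latent* time series → linear output layer. Fitting
minimizes mean squared error with AdamW, early-stopped on the validation
segments. Architecture constants are not specified by the source analyses
and are package defaults chosen for stable single-CPU fitting at these data
sizes: 64 hidden units, 32 convolution channels over 9 frames (0.3 s),
16 latents, learning rate 2e-3, decoupled weight decay 1e-4, patience 8
epochs (all config). Inputs are z-scored with training-segment statistics;
the output bias initializes at the training-mean rate.

The *nearest-neighbour prediction* finds, for each test-bin latent, the 50
nearest training-bin latents (Euclidean; ties broken by earlier time index)
and averages the *recorded* activity at those training bins. Averaging
recorded data — not model outputs — is what lets this route outperform the
direct network prediction when the latent-to-rate map is harder than the
readout can express. The residual is recorded minus nearest-neighbour
prediction, exactly, bin-wise; positive residual means the behaviour model
underpredicts. Variance explained is computed per unit on the control
segment, and predicted-vs-recorded correlations in 1-s bins separately for
control and stimulation segments.

## Physiology

ECG is band-passed 10–50 Hz (zero phase); R peaks are detected with an
adaptive height threshold of 4 MADs of the filtered trace and a refractory
minimum R-R of 40 ms; instantaneous 60/RR is interpolated to the sample
grid, smoothed with a 1-s sliding window, and normalized per stimulation to
the 30-s pre-laser mean (the source protocol allows 30 s–1 min; 30 s is the
default). Heart-rate changes are summarized over 6–24 s (stim) and 30–60 s
(post) relative to onset; respiration — breath peaks in a 1–10 Hz band, same
smoothing — over 6–15 s and 36–45 s. The respiration band and peak threshold
(1.2 MAD, below a sinusoidal breath's peak-to-MAD ratio of ~1.4) are package
choices; the source used unpublished scripts. Adaptation protocols are
isolated by shifted self-subtraction `x(t) - x(t - shift)` (10 s for PBG,
40 s for PE), cancelling components periodic at the stimulation period.

LDF traces are normalized to the 30-s pre-stimulus baseline and
median-filtered over 500 ms; six metrics follow: latency to 50% drop,
minimum during the 30-s stimulation, time below the half-minimum level
`(1 + min)/2` (the stated "full width at half-minima" does not fix a
reference level; halfway between baseline and minimum is the geometric
reading that makes the symmetric triangle fixture give exactly 5 s), mean
over the final 100 s, post-stimulus recovery time to baseline, and the rate
coefficient — the ratio of ascent to descent slope magnitudes, fitted by
least squares over the limbs flanking the minimum (robustness to noise;
two-point slopes are not). Trials are aligned to syncope onset (the 50%
power-drop time) for averaging, and a per-trial event-sequence table orders
heart-rate minimum, flow minimum, power drop, and the optional eye-roll
annotation.

## The synthetic-session generator

`generate_session()` produces a complete 600-s session: four 30-s laser
trains (5, 10, 2 × 20 Hz) at onsets 66/129/192/255 s, which tile the session
into exactly one 63-s control window, four 63-s laser test windows and five
50-s non-test segments under the default split. Programmed phenomena:

- **Behaviour latents**: five smooth factors (low-pass filtered white noise,
  1-Hz cutoff, warm-up padded so filter transients never enter the session),
  mapped linearly to the 250-component movie SVD, linear-rectified to the
  motion SVD, and to unit rates.
- **Rate coupling**: each unit's gain is `1 + 0.6 · (w'z)` plus a
  bell-shaped (Gaussian, width 0.4, amplitude 1.5) tuning of its latent
  projection to a per-unit preferred value, mean-centred analytically.
  Bell tuning gives the latent-to-rate map a non-monotone component the
  shallow readout underfits — which is precisely the regime in which the
  nearest-neighbour route outperforms the direct one — while keeping the
  50-neighbour average unbiased in the mean, because shrinkage of sparse
  neighbourhoods toward the latent centroid biases individual units in
  center-dependent directions that cancel across the population. (An earlier
  radial choice, a centred quadratic, produced a systematic positive
  residual offset for exactly this reason and was rejected.)
- **Spiking**: inhomogeneous Poisson by thinning of the coupled rates
  (2–8 Hz baselines); with coupling noise at its default of zero the
  underlying rates are an exact deterministic function of the latents.
- **Laser responses**: half the units per region respond at a programmed
  latency (uniform 10–100 ms) with a 500-Hz, 30-ms onset burst — the
  time-locked multi-spike volley characteristic of direct opsin drive —
  followed by a +20 Hz sustained excess for 2 s. A pure rate step cannot be
  localized to 10 ms by a 1e-6 Poisson criterion over four repetitions
  (crossing the threshold requires ~6 excess spikes), so the burst is what
  makes the stated 10-ms recovery accuracy attainable, matching the
  8–60 ms latencies such stimulation produces in practice.
- **Syncope**: 4–8 s after each 20-Hz onset, lasting 10–20 s; the 8–100 Hz
  component of the 1/f EEG (split exactly in the Fourier domain) is scaled
  to 20% power with 0.5-s cosine ramps, and units outside PVZ are fully
  silenced. PVZ stays active, mirroring the push–pull role of the
  periventricular zone.
- **Physiology**: heart rate ramps from 600 bpm to 30%, with an asystole
  placed so the programmed event order is heart-rate minimum, then flow
  minimum, then the 50% power drop; LDF dips scale with pulse frequency
  (0.85/0.7/0.4 of baseline); respiration drops to 50% during 20-Hz trains;
  the pupil dilates 1.5× at laser onset with occasional 200-ms blinks
  (confidence dropouts and dark-pixel dips).

What the generator does **not** emulate: realistic ECG morphology (R peaks
are Gaussian impulses), raw video pixels (SVD streams are synthesized
directly; a small moving-blob movie exercises the motion-energy SVD in
tests), behavioural collapse during syncope (latents continue through the
bout, so the suppression is by construction *not* explainable from
behaviour — the property the residual triad tests), electrode drift, and
non-Poisson spike-train structure (bursting, refractoriness). Passing
recovery tests therefore demonstrates correctness of the analysis chain
under its own statistical assumptions, not robustness to every failure mode
of real recordings.

## Validation scales and numerical choices

The acceptance suite runs: syncope recovery on 20 seeded 160-s sessions
(onset within ±0.5 s, offset within ±1 s, ≥90% of events); cluster-test
calibration with 200 null repetitions of 8+8 trials on 30×50 maps at 500
permutations (observed type-I within the binomial 99% CI of 5%); latency
recovery at 10/50/200 ms over 100 seeds each (median error ≤ 10 ms) with
null specificity ≥ 99% over 300 units; the silence-bin formula against the
Poisson CDF oracle to 1e-10 plus sensitivity ≥ 0.9 / false-flag ≤ 0.05 on 50
units; the encoding triad (pre-laser |mean residual| < 0.1 of the mean rate,
positive at laser onset, negative at syncope outside PVZ) and the
nn-over-direct ordering across 10 full sessions; the deterministic fixture
identities; and the curation screens on 100 units. These sizes were chosen
so the full suite fits comfortably in a routine run on one CPU while keeping
Monte Carlo error well inside the stated tolerances; `scripts/acceptance.R`
re-runs the same experiments at moderately reduced replication and reports
the measured quantities as JSON.

Numerical details worth knowing: all bins are half-open `[t, t + dt)` on a
single session clock starting at 0; wavelet transforms use circular FFT
convolution (tests evaluate interior time points); spectrogram power may be
decimated in time (the wavelet envelope is far slower than the raw sampling
rate); moving means renormalize at the edges so constant traces stay
constant; the Poisson tail accumulates in log space and is clamped to
[0, 1]; `ppois`, used nowhere in the implementation, serves as the
independent oracle in the tests; nearest-neighbour ties break toward the
earlier training index; and the train/validation assignment, weight
initialization and all generator draws are controlled by explicit seeds.

## Known limitations

Eye-roll events are consumed as optional manual annotations, never computed.
Cross-probe clock alignment is assumed done upstream. The cluster test's
discrete areas make it conservative at small trial counts. The encoding
network is deliberately small; scaling to hundreds of units and hours of
data would warrant minibatching and a GPU backend. Respiration-rate
extraction parameters are package defaults, not published values.
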