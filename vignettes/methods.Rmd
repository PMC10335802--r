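---
title: "Methods: stream processing, Riemannian classification and latency calibration for closed-loop EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stream processing, Riemannian classification and latency calibration for closed-loop EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcistream)
```

## Scope

`bcistream` is the computational core of a human-in-the-loop EEG setup:
everything between "samples and markers arrive" and "a decision leaves",
with a seeded synthetic-EEG generator standing in for hardware so the whole
loop runs and is testable offline. It deliberately excludes GUIs, network
transport, real device drivers and artifact-removal algorithms beyond
baselining and notch filtering.

## The execution model

Processing is organised as rate-scheduled directed acyclic graphs
(`graph_spec()`, `build_graph()`, `run_graph()`). One *tick* calls every
node's update exactly once, in a topological order of the edge relation;
outputs produced in a tick are visible downstream within the same tick,
matching strictly sequential execution. Ticks are counted on a simulated
clock — a graph at rate $r$ run for $T$ seconds executes exactly
$\lfloor T\,r\rfloor$ ticks — so tests are free of wall-clock dependence.
Graphs communicate only through a publish/subscribe `broker()` whose
per-topic FIFO queues conserve items (published = drained + pending) and
never block the publisher.

Timestamps are 64-bit floats in seconds on a single session clock.
Hardware streams disagree about units and offsets, so every ingest path
normalises to seconds and records the applied offset on the
`sample_block`. Streaming blocks are samples-by-channels (appending rows
is natural); epochs are channels-by-samples (covariance arithmetic wants
channels as rows); the orientation flips exactly once, at epoching.

When a node is slower than its rate the engine logs and continues — ticks
are never dropped and simulated time is unaffected; the scheduling
contract stays exact. Pub/sub delivery is exposed as per-tick drained
batches; we make no claim about sub-tick delivery timing.

## Causal filtering

Online filters must be causal. The only implemented design is the
windowed-sinc construction: the ideal non-causal impulse response is
time-shifted by half the filter length and multiplied by a Hamming window
(`design_filter()`). This yields a linear-phase FIR with group delay
$(N-1)/(2 f_s)$ seconds, which is *reported, never silently compensated* —
compensation would be non-causal; callers that know they are offline may
shift epoch windows by the reported delay. The default motor-imagery
band-pass is 8–30 Hz with 129 taps at 256 Hz, giving a ~6.6 Hz transition
band and a 0.25 s delay. Streaming application (`apply_causal()`) carries
the last $N-1$ input samples across calls, so chunked filtering is
bit-equal to one-shot filtering regardless of the chunking.

Highpass and notch responses are built by spectral inversion, which
requires an odd tap count; `filter_spec()` enforces that. A single-tap
spec is the identity passthrough.

## Epoching and baselining

Epoch windows are half-open $[t_\min, t_\max)$ in sample terms: the
boundary sample belongs to the next window. That convention makes the
rolling-window count exact, $\lfloor (T-\ell)/s\rfloor + 1$, and is
asserted against brute-force window enumeration. Time-locked epochs match
by *timestamp*, not sample index — the first sample at or after
`onset + t_min` — which tolerates marker jitter; the alignment error is
below one sample period. Markers whose window is not covered are skipped
and reported with a reason, so markers always equal epochs plus skips.
Overlapping marker windows each produce an independent epoch.

Baselining subtracts the per-channel mean over a pre-onset window. It is
exact (the window mean is zero to float rounding afterwards), idempotent,
and adds no processing delay because it only uses samples already inside
the epoch — unlike a causal high-pass, which is why it is the preferred
drift correction around event onsets.

`narrowband_power()` implements the electrode-contact proxy: mains
interference rises with electrode impedance, so the mean squared output
of a causal narrow band-pass around 50/60 Hz, per channel, ranks
electrodes by contact quality. The statistic is quadratic in the injected
line amplitude and monotone across channels.

## Covariances on the SPD manifold

Each epoch is summarised by its shrunk empirical covariance
$C = (1-\lambda)\,\hat C + \lambda\,\frac{\mathrm{tr}\,\hat C}{p} I$,
$\lambda = 0.05$ by default. Shrinkage guarantees positive definiteness
for short epochs at a bias that is negligible for well-conditioned
estimates; $\lambda = 0$ is allowed and may return a boundary
(rank-deficient) matrix, which the manifold operations then reject. A
zero-variance epoch with $\lambda > 0$ shrinks toward the unit prior
(giving $\lambda I$) rather than failing.

Distances use the affine-invariant Riemannian metric
$\delta(A,B) = \lVert \log(A^{-1/2} B A^{-1/2})\rVert_F$ — the standard
choice for EEG covariances because it is invariant under any affine
re-referencing of the sensor space ($A \mapsto WAW^\top$). The
log-Euclidean metric is available as a cheaper option. Class means are
Fréchet means computed by the standard fixed-point iteration, initialised
at the arithmetic mean, stopping when the tangent-space gradient norm
falls below $10^{-8}$ (at most 50 iterations; non-convergence is an error
that reports the final gradient norm). Minimum-distance-to-mean
classification assigns an epoch to the nearest class mean; ties break
toward the first class id, and scores are $\mathrm{softmax}(-\delta)$
with unit temperature — a reporting convenience, not a calibrated
probability.

Models persist as a single JSON file: human-readable metadata (format
tag, version, parameter digest, class ids, estimator settings) plus the
mean matrices as base64-encoded little-endian doubles. Loading verifies
the digest and reproduces predictions bit-identically; writes are atomic
(temp file + rename).

## The unsupervised oddball statistic

In an oddball session the target class elicits a time-locked P300-like
deflection, but no labels say which class is the target. Epochs are
grouped by stimulus class; each group is reduced to a representative SPD
matrix; the score of class $k$ is the sum of its pairwise distances to
the other representatives, and probabilities are the proportionally
normalised scores (scale-free and parameter-free; a softmax would
introduce an arbitrary temperature). The predicted target is the argmax.
With two classes the single pairwise distance makes the statistic
uninformative by construction — it needs $K \ge 3$.

Two representative modes are implemented. The default, `avg-then-cov`,
averages the epochs pointwise and takes the covariance of the average:
averaging suppresses everything not time-locked by $1/\sqrt{m}$ while the
ERP survives, which is precisely the deviance being sought.
`cov-then-mean` (Riemannian mean of per-epoch covariances) is kept as an
alternative; it is sensitive to ongoing-activity differences rather than
time-locked ones.

The incremental form (`running_update()`) accumulates per-class epoch
sums, so re-scoring after $n$ epochs equals the batch computation on the
same $n$ epochs exactly. Classes not yet seen are held at the uniform
prior weight $1/K$, and results are flagged low-confidence until every
class has at least 3 epochs. Per-class epoch counts are reported but not
reweighted; random sequencing leaves counts slightly unbalanced and the
statistic inherits that.

**Sequencing matters.** With stimuli a few per second and 0.8 s analysis
epochs, each epoch overlaps its neighbours. Under a deterministic
round-robin cycle the target's ERP therefore leaks into the epochs of the
always-adjacent classes at a *fixed* relative latency, survives
averaging, and the statistic flags the one class that is never adjacent
to the target instead of the target itself. Random sequences break the
adjacency so the leak attenuates by $1/K$ and averages toward a common
offset for all classes. For this reason the generator and the session
controller default to random sequencing; round-robin remains available
and is the right choice only when epochs do not overlap.

## Latency calibration

Stimulus chains add an unknown fixed delay between a logged marker and
the EEG record. The calibration session shows flashes while the subject
taps the headset in sync; taps create large artifacts whose offsets from
the flash markers estimate the delay. Human tap timing contributes noise
with a standard deviation around 30 ms (we read the literature's "~30 ms
variance" as a standard deviation), which averages out over taps: the
standard error falls as $1/\sqrt{n}$.

Detection (`detect_tap_artifacts()`) drift-corrects with a causal
trailing 1 s running-mean subtraction — an effective 1 Hz high-pass with
*zero lag at a sharp edge*, where a windowed-sinc high-pass would delay
the edge by its group delay and bias every onset — then thresholds the
rectified channel average at median + 5 robust standard deviations
(scaled MAD), with a 0.25 s refractory period. The reported onset is the
midpoint between the last sub-threshold and first supra-threshold sample,
an unbiased half-sample convention. Pairing walks markers in time and
takes the nearest unused artifact within `(marker, marker + 0.5 s]`
(taps follow flashes; reaction offsets are well below half a second);
unpaired markers are dropped and counted, offsets beyond 3 robust
standard deviations from the median are rejected as outliers and counted.
The estimate is never applied to subsequent epoching automatically —
applying it is an explicit opt-in shift of the epoch windows.

Two closed forms round out the module: acoustic propagation
(`acoustic_latency()`, $1000\,d/343$ ms for $d$ metres of air at 20 °C)
and the worst-case display refresh jitter
(`refresh_jitter_bound()`, $1000/r$ ms for an unsynchronised draw on an
$r$ Hz display).

## The synthetic generator: what it does and does not emulate

The generator (`synth_config()`, `make_background()`,
`make_oddball_session()`, `make_mi_session()`, `make_tap_session()`)
states a world:

| parameter | default | why |
|---|---|---|
| `fs` | 256 Hz | common consumer-headset rate |
| `n_channels` | 8 | small dry-electrode montage |
| `noise_exponent` | 1 | pink background; log-periodogram slope −1 over 1–40 Hz |
| `line_amp` | 0.2 | mild mains contamination relative to unit background |
| `blink_rate`, `blink_amp` | 12/min, 5 | frontal-weighted low-frequency bumps, for robustness tests only |
| `erp_amp` | 1 | ERP peak equal to one background standard deviation |
| `erp_latency`, `erp_width` | 0.3 s, 0.05 s | P300-like Gaussian deflection on the posterior channel half |
| `hw_latency` | 30 ms | mid-range of reported wireless-headset delays (20–40 ms) |
| `marker_jitter_sd` | 5 ms | reported marker timing jitter |
| `erd_band` | 8–30 Hz | sensorimotor band used by the MI pipeline |
| `tap_amp` | 20 | tap artifact ~20 background standard deviations |

Background channels are built by spectral shaping of white noise (one FFT
per channel, gain $f^{-\alpha/2}$, clamped below 0.5 Hz, normalised to
unit standard deviation) — simple and exactly seedable; identical seed
and configuration give bit-identical output. Motor-imagery epochs mix
independent band-limited unit-variance sources through the Cholesky
factor of the requested class covariance, so the band-passed epoch
covariance converges to the requested matrix: the generating covariances
are the *exact* recovery target of the classifier. To keep that exact,
the MI session uses a faint (amplitude 0.05) background instead of a
full-strength one. Tap artifacts rise instantly and decay exponentially
(30 ms constant), so their onset is well-defined at sample resolution.

What the generator does **not** emulate: biophysical source geometry and
volume conduction (channels are statistically, not anatomically,
related), non-stationary rhythms, electrode drift and pops, packet loss,
or saturation. A green test on this generator therefore establishes the
*algorithmic* contract — alignment, convergence, invariance, recovery
under the stated noise model — not performance on a particular headset or
subject.

## Session applications and archiving

The motor-imagery controller is a five-phase machine
(idle → calibration → training → feedback → done) driven by admin
commands (`start`, `pause`, `cancel`, `train`, `stop`); entering
training publishes exactly one train request and feedback is blocked
until a model-ready message returns. The oddball controller runs a fixed
timeline — instructions, then rest/stimulus-block pairs — whose default
durations (10 s + 5 s + 35 s + 5 s + 35 s) sum to 90 s of scheduled
session with stimuli at 3/s; block structure, durations and rate are all
configuration fields. Every transition emits a phase marker and every
displayed stimulus a class-labelled marker, so scheduled stimuli, emitted
markers and attempted epochs agree exactly.

`archive_session()` writes the raw (pre-filter) EEG, all markers and the
event log (XDF, or CSV fallback) plus a manifest holding the
configuration and its digest; `replay_oddball_archive()` re-processes an
archive offline and reproduces the online probabilities bit-identically,
which is the package's replay-equivalence guarantee. Application/graph
configuration files are JSON (no yaml parser is available in the target
environment); the document layout — one file per app, graphs with
`rate`, `nodes`, `edges` — is unchanged.

## Numerical choices and degenerate inputs, collected

* Fréchet mean: tolerance $10^{-8}$ on the gradient norm, max 50
  iterations, arithmetic-mean initialisation; error on non-convergence.
* MDM ties: argmin ties break toward the first class id; identical means
  give exactly 0.5/0.5 scores.
* All-zero odd-one-out scores (identical representatives): uniform
  probabilities.
* Zero-length background: a valid empty block. Zero-tap or zero-marker
  calibration inputs: explicit errors.
* Epoch windows shorter than two samples, band edges at or above
  Nyquist, even FIR orders, non-SPD covariances, unknown class ids,
  channel-count changes mid-stream: all rejected with specific errors.
* Truncated XDF files report the byte offset; truncated model files fail
  without producing a partial model.

## Known limitations

The odd-one-out statistic needs at least three classes and benefits from
randomised sequencing (see above). The probability mapping is a
normalisation, not a calibrated posterior. The engine is single-process
and simulated-clock; it makes no claims about wall-clock latency or
cross-machine clock synchronisation. CSV marker files carry only the
`label`/`class`/`phase` payload keys (XDF keeps arbitrary payloads).
Live-stream ingestion is out of scope; anything satisfying the
`sample_block`/`marker_event` contract can be adapted in.
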