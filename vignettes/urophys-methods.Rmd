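---
title: "Methods: cystometry with simultaneous pontine-cortical electrophysiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cystometry with simultaneous pontine-cortical electrophysiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

During continuous-infusion cystometry, the bladder fills and voids in
repeated cycles: pressure rises slowly to a peak, micturition occurs, and
pressure falls back to (near) zero. In the pons, neurons of the micturition
centre (PMC, Barrington's nucleus) discharge around the void and emit
stereotyped high-frequency bursts; locus coeruleus (LC) neurons become
tonically active tens of seconds *before* the void; and in the same
pre-micturition window the LC field potential develops a theta oscillation
while the medial prefrontal cortex (mPFC) desynchronises, with LC--mPFC
coherence rising in the theta band. `urophys` implements the complete
analysis chain for such recordings, together with a synthetic-session
generator so that every stage can be validated end to end without
laboratory data.

All analyses share one timestamp convention: times are seconds from session
start, micturition is timestamped by **peak pressure**, and every window is
half-open `[start, end)`.

# Cycle segmentation

`detect_micturition_events()` finds maximal runs of pressure above a
threshold (default: half the trace's global maximum — the event is defined
qualitatively in this preparation, so the threshold is an explicit,
configurable convention), takes the argmax of each run as the peak, and
requires pressure to return to a baseline (default 2 mm Hg) within 30 s for
the excursion to count as a void. `segment_cycles()` then derives, per
event:

* a **pre-micturition** window `[peak - 20 s, peak)`;
* a **post-micturition** window `[peak, peak + 20 s)`;
* an **intermicturition** window from 120 s after the previous peak to
  120 s before the current one (absent for the first event, and for cycles
  shorter than 240 s).

The first cycle is excluded from every summary by default
(`drop_first = TRUE`): cycles regularise only after the first void.

# Firing-rate statistics

Rates are counts over half-open bins divided by the bin width (5 s bins for
across-cycle averages, 1 s bins for latency estimation). Z-scores are
`(rate - m)/s` with `m`, `s` the mean and sample SD over bins lying wholly
inside the background windows — by default the pooled intermicturition
windows, the natural "background" of this preparation. A zero-variance
background is degenerate: a fully constant series is defined to have `z = 0`
(with a warning); otherwise an error of class `uro_degenerate_background` is
signalled.

The pre/post contrast uses the mean rate in `[peak - 50, peak - 40)` versus
`[peak, peak + 10)`, averaged over cycles, compared by a paired t-test
across units. The peri-event matrix stacks 10 s-binned rates over
`[-50, +50]` s around each peak.

**Activation latency.** LC activation onset is estimated from z-scored 1 s
bins: scanning `[peak - 70 s, peak]`, the onset is the start of the
earliest run of at least 3 consecutive bins with `z >= 2` whose end reaches
to within 5 s of the peak; the latency is `peak - onset`. "Significant
activation" has no standard operational definition, so all four constants
are declared, configurable parameters; the 70 s search window covers the
observed 0--65 s latency range. Two small biases follow from the
construction and are visible in the synthetic recovery: bin flooring loses
up to one bin, and for units with high baseline rates an occasional
sub-threshold bin can split the run and shift the detected onset later.
Together they depress the recovered mean latency by roughly 1--2 s at the
packaged preset (18.5 s recovered versus 19.9 s planted); we report this
rather than compensate for it.

# Burst detection

A burst opens at an interspike interval (ISI) of at most 80 ms, continues
while ISIs stay strictly below 160 ms, closes at the first ISI of 160 ms or
more, and is retained only when it contains more than 4 spikes (>= 5). The
80 ms rule applies to the *onset* ISI only — the Grace/Bunney-style
convention. ISIs within 1 microsecond of a boundary are treated as exactly
on it, so the conventions survive floating-point noise. The greedy
left-to-right scan resumes after each closing spike, so bursts never share
spikes; the test suite proves the scan equivalent to an independent
run-based formulation on 1,000 random trains. Burst phase is assigned by
onset time; per-phase summaries report bursts per cell per cycle (counts
divided by units x cycles possessing that window) and per-burst means with
SEMs. The per-burst ISI column is the mean within-burst ISI, averaged
across bursts.

# Spectral analysis

Spectra are multitaper estimates. DPSS tapers are computed from the
symmetric tridiagonal matrix that commutes with the concentration operator
(numerically robust even at `n = 1560`), with concentrations evaluated via
the sinc-kernel quadratic form; tapers are cached per `(n, NW, K)`. The
defaults mirror the recording configuration: 2 s windows at 780 Hz,
time-bandwidth `NW = 2` (a +/-1 Hz analysis bandwidth), `K = 3 = 2NW - 1`
tapers, windows overlapping by 0.5 s (step 1.5 s — the overlap is read
literally; both step and overlap are configurable because toolboxes differ
in which of the two the number denotes). PSDs are one-sided and scaled so
that the integrated PSD approximates the signal variance; power is reported
in linear units, log scaling being a display choice. FFTs are zero-padded
to the next power of two for a smooth grid; passing `nfft = n` gives the
raw-grid (bit-exact) estimate. Coherence averages cross- and auto-spectra
over tapers and windows before forming `|Sxy|^2/(Sxx Syy)`, which keeps the
estimate in `[0, 1]` and equal to 1 for affinely related signals.

**Epoch comparison.** Per cycle, the *pre* epoch is `[peak - 30, peak]` and
*baseline* the preceding `[peak - 60, peak - 30]`; the epoch PSD is the
mean over all complete 2 s windows inside the epoch. Epochs truncated by a
session edge skip that cycle with a warning. The epoch contrast is a
two-way repeated-measures ANOVA with cycles as subjects and epoch x
frequency as within-subject factors, each effect tested against its
interaction with cycles; the headline epoch effect therefore has
`(1, cycles - 1)` degrees of freedom. No sphericity correction is applied:
the two-level epoch factor satisfies sphericity trivially, and the
frequency factor is not the inferential target. With real multi-animal data
the error structure (and hence the denominator degrees of freedom) would
differ; the convention here is documented rather than inherited.

# The synthetic-session generator

`gen_session()` composes four generators under one master seed, split into
fixed per-component sub-streams so adding units never perturbs existing
components, and a fixed seed reproduces a session bit for bit.

* **Pressure**: piecewise-linear rise (60 s) to a 30 mm Hg peak at each
  planted event, fall to baseline over 10 s, plus optional 1 mm Hg
  transients at post-void burst times. The figures in this literature show
  peaks of a few tens of mm Hg; exact values are presentation scale only,
  since detection is threshold-relative.
* **PMC units**: tonic Poisson discharge at 1 Hz, elevated to 2 Hz from
  each peak until the bladder is empty, plus planted bursts per phase.
  Burst counts per cycle are Poisson with the preset means
  (pre/inter/post = 0.3/12.3/2.7); per burst, intra-burst frequency and
  duration are drawn from truncated normals (post: 28 +/- 2 Hz,
  606 +/- 66 ms; inter: 28 +/- 2 Hz, 432 +/- 35 ms; pre: ~15 Hz,
  263 +/- 14 ms — the printed spreads are used as per-burst SDs, a modest,
  recoverable dispersion). Spikes within a burst are near-regular with
  uniform +/-10% ISI jitter, rescaled to span the drawn duration, so the
  onset ISI can never breach the 80 ms criterion. Onsets are uniform in the
  phase window with a 300 ms separation margin — without it overlapping
  planted bursts would merge and the planted truth would not be
  individually recoverable. The tonic rates are deliberately low: at 1--2
  Hz the probability that background ISIs imitate a burst is small enough
  that the planted Table-1-style statistics dominate the detected ones.
  The residual contamination (background spikes adjacent to a planted
  burst extend it; rare chance bursts during the void) inflates recovered
  durations by ~4% — quantified by the recovery tests.
* **LC units**: per-unit baseline drawn from 0.5--5 Hz; in each cycle the
  rate steps to 15 Hz at a latency drawn uniformly from 10--30 s before
  the peak (mean 20 s) and returns to baseline at the peak. 15 Hz is
  chosen so that a `z >= 2` threshold is cleared decisively even at the
  worst-case 5 Hz baseline.
* **LFPs**: the LC signal is band-limited (1--150 Hz) pink noise plus a
  slow 1--4 Hz component at baseline; inside each 30 s theta epoch the
  slow component is replaced by a 6 Hz sinusoid with a random per-epoch
  phase and amplitude 2 (in background-SD units — strictly more power than
  the slow component it replaces, so the pre-epoch effect is a genuine
  power increase, not a pure redistribution). The mPFC signal is
  independent pink noise attenuated by 0.5 during epochs, plus 0.12 times
  the identical theta sinusoid: the shared component produces theta-band
  coherence (~0.5 at the preset) while leaving the mPFC pre-epoch PSD
  below baseline at every frequency up to 20 Hz, reproducing the "dim
  theta band inside a broadband decrease" picture.

What the generator does **not** emulate: pump and detrusor dynamics,
non-micturition contractions, anesthesia, spike-sorting noise, unit
correlations beyond the planted structure, non-stationary baselines, 1/f
knee behaviour, or volume conduction. Passing the recovery tests therefore
demonstrates that the estimators are correct and well calibrated for data
with this statistical structure, not that they are robust to every artifact
of real recordings.

# Numerical and degenerate-input conventions

* Ties/boundaries: window membership is half-open everywhere; a spike at a
  bin edge belongs to the right bin; a burst onset ISI of exactly 80 ms
  opens a burst, an ISI of exactly 160 ms closes it.
* Empty inputs: an empty train bins to all-zero rates; a flat pressure
  trace yields zero events (not an error); a session without events skips
  the event-locked stages with warnings but still returns a result.
* The coherence of a signal with itself is 1 to machine precision by
  construction (identical averaging on both axes).
* DPSS sign convention: each taper's largest-magnitude element is positive
  (any fixed rule serves determinism; spectra are sign-invariant).

# Problem sizes used in validation

The packaged validation runs use the preset's full 36 PMC + 51 LC units and
10 cycles per session: five seeded sessions for parameter recovery (about
20,000 detected intermicturition bursts and 2,300 latency estimates), and
fifty seeded LFP sessions for the epoch-contrast power check. Unit tests
use a three-cycle, two-unit session at reduced sampling rates; these sizes
give stable statistics while keeping a full run of the suite within a few
minutes.

# Known limitations

* The latency estimator's small negative bias (above) is inherent to the
  run-persistence rule at finite SNR.
* Bursts-per-cell-per-cycle treats all units as equally observable; with
  real recordings, undetected units would require a different denominator.
* The RM-ANOVA degrees of freedom follow the per-cycle design and will not
  match analyses that pool frequency bins as independent observations.
* Reading large LFP tables from text is robust but not fast; the text
  bundle format favours transparency and determinism over speed.
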