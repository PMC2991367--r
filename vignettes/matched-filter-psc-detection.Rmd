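---
title: "Matched-filter detection of photostimulation-evoked postsynaptic currents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched-filter detection of photostimulation-evoked postsynaptic currents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pscdetect)
```

## The problem

Laser-scanning photostimulation maps the synaptic inputs of a neuron by
uncaging glutamate at a grid of sites (typically 16 x 16) while the cell is
held in whole-cell voltage clamp. Each site yields a current trace
containing, besides background noise and spontaneous synaptic activity, up
to three kinds of deflection: the *direct* uncaging response (glutamate
acting on the recorded cell itself, starting within ~10 ms of the laser),
*evoked* postsynaptic currents (EPSCs at -70 mV, inward/negative; IPSCs at
0 mV, outward), and events *over-riding* the decaying direct response.
Quantitative circuit mapping needs every evoked event found, timed and
measured — hundreds of traces per cell — which makes reliable automated
detection essential. Simple amplitude thresholds and single-template
matching struggle because evoked events vary widely in amplitude and shape
and frequently overlap.

`pscdetect` implements a two-stage matched-filtering approach. A matched
filter is the detector that maximizes output signal-to-noise ratio when the
target waveform is known; since no single waveform describes all evoked
events, a *bank* of approximate matched filters is trained from operator-
marked examples, and detection statistics derived from the bank replace
hand-tuned thresholds.

## Training stage

For each marked event (onset, negative peak, offset — onset and offset at a
similar baseline level, no superimposed events):

1. the segment is extracted and anchored so the onset value is 0 pA
   (`extract_segment()`);
2. an 8th-order polynomial is least-squares fitted on a time axis rescaled
   to [-1, 1] (conditioning) and the fitted waveform is divided by its L1
   norm (`fit_template()`). The L1 normalization makes a candidate event's
   convolution amplitude proportional to the event's own amplitude, not the
   training event's. Single-synapse events are classically fitted with
   exponentials, but photostimulation-evoked events are usually compound;
   at a 10 kHz sampling rate and ~14 ms mean duration the 8th-order
   polynomial fits them well, while higher orders risk overfitting;
3. per-event statistics are recorded (`template_statistics()`): the leading
   part (peak minus onset, ms), trailing part (offset minus peak), the
   amplitude (onset value minus peak value, pA), the maximum `c_max` of the
   convolution of the raw anchored segment with its own template, and the
   `shift` between the convolution maximum and the event peak, which the
   detection stage uses to align convolution traces.

`build_bank()` pools means and sample SDs (n - 1; banks are small, 10-18
filters) of `c_max`, lead, trail and amplitude. At least 10 filters are
recommended so these statistics are estimated usefully. The bank is
serialized losslessly to JSON (`write_bank()`/`read_bank()`), including the
anchored training segments, so a bank trained on one experiment can be
reused on similar ones.

## Detection stage

`detect_events()` runs, in order:

1. **Zero-phase high-pass** (`highpass_zero_phase()`): 5th-order Butterworth,
   10 Hz corner, applied forward and reverse so occurrence times are not
   shifted. This suppresses the slow direct response and drift. The trace
   is demeaned and odd-reflection padded before filtering; an IIR filter
   started from a zero state would otherwise inject an edge transient with
   a ~1/cutoff time constant whenever the trace sits on a DC level.
2. **Bank convolution** (`convolve_bank()`): one convolution trace per
   filter, each advanced by its training-stage shift so convolution maxima
   align with candidate peaks.
3. **Thresholding**: the detection threshold is `mu + k sigma` of the
   pooled `c_max` (default `k = -1.2`; the practical band is -1.5 to -1,
   because training events are deliberately strong examples and the
   threshold must sit below them). Maximal runs of convolution samples
   above threshold are the *suprathreshold segments*; the amplitude-
   weighted mean time of each run is its occurrence-time candidate `t_cm`
   (`suprathreshold_candidates()`).
4. **Window gating** (`gate_windows()`), only when a laser onset is known:
   candidates inside the direct-response window `W_d` (10 ms) are
   dismissed — synaptic latencies that short are impossible. Inside the
   wider outlier window `W_o` (30 ms) a candidate is dismissed when any
   convolution trace exceeds `mu + 4 sigma` within its run (large direct
   responses convolve to values several times larger than synaptic ones),
   or when the run's leading edge traces back into `W_d` (small direct
   responses that stay below the outlier threshold).
5. **Candidate merging**: `t_cm` values from different filters within one
   mean leading part of each other refer to the same event and are merged
   (weighted by run maximum). The cluster diameter is bounded rather than
   single-linkage chained, so candidates straddling two nearby events stay
   separate.
6. **Peak localization** (`locate_peak()`): local negative peaks are sought
   in `[t_cm - L, t_cm + T]` (bank mean lead/trail), the window clipped so
   it never reaches into the next pending candidate's vicinity. Competing
   peaks are scored on three equally weighted 0-100 criteria
   (`peak_scores()`): convolution support (how many filters exceed
   threshold at the peak), relative amplitude, and relative second-
   derivative magnitude, which prefers sharp peaks over flat inflections.
   Ties go to the earlier peak.
7. **Onset/offset and overlap splitting** (`locate_onset_offset()`): the
   onset is the largest local maximum within `L_on = mean lead + 1 SD`
   before the peak (supremum fallback); the offset search within
   `L_off = mean trail + 1 SD` applies the boundary cascade: a local
   maximum followed by a local minimum whose drop exceeds the amplitude
   cutoff marks the offset *and* the next event's onset, and the minimum
   is queued as the next event's peak. Between competing boundary maxima
   the higher one wins; with no qualifying split the offset is the higher
   of the last boundary maximum and the window end.
8. **Amplitude gate** (`amplitude_gate()`): an event is kept only if
   `value(onset) - value(peak)` on the raw trace exceeds the cutoff
   (default: the bank's mean spontaneous amplitude). This rejects
   baseline notches on direct-response tails at the cost of missing
   events at the spontaneous level — the basic sensitivity/specificity
   trade of any detector.
9. **Measurement** (`measure_event()`): peak amplitude (raw trace), rise
   time (peak minus onset), summed input = 2 x |trapezoidal integral of
   the baseline-referenced current from onset to peak| (pA ms; the
   trailing limb is excluded because direct responses skew it), and
   latency from laser onset.

Candidates are processed from earlier to later; each localized event claims
its `[onset, offset]` interval and candidates resolving inside a claimed
interval are consumed, so each event is localized exactly once and
overlapping events are recovered through the splitting cascade.

### Recovering events that lose their candidate

When two events share one suprathreshold segment, the center of mass is
pulled toward the larger one and the smaller may end up with no usable
candidate. Two pieces of evidence recover it, both consequences of how an
aligned convolution trace behaves: it *peaks* where an event peaks, and it
*rises* at an event's onset. After the main pass the detector therefore
re-queues (a) any suprathreshold local maximum of the filter-wise maximum
convolution that lies farther than one mean lead from every localized peak
and outside every claimed interval, and (b) the unexplained leading stretch
of any run that starts more than one mean lead before the earliest onset
claimed inside it (heavy overlaps leave no separate convolution maximum).
In simulated pairs 6-10 ms apart at SNR 9 this recovers both events in
essentially every trial, compared with about 1 in 20 without it.

### Numerical choices

*Extrema landscape.* Local extrema are defined on the discrete grid as
strict sign changes of the first difference (plateaus resolve to their
first sample). That definition only makes sense at the event timescale, so
peaks, onsets, offsets and the split tests are located on a copy of the
filtered trace smoothed with a zero-phase 1.5 ms moving average
(`landscape_smooth_ms`, configurable; roughly an order of magnitude below
the event duration and above the sampling interval). The symmetric kernel
does not shift event times. All amplitudes are still measured on the raw
trace; the split-test drop is evaluated on the landscape so a single noisy
sample cannot trigger or veto a split. The second-derivative criterion uses
a central difference on a ~1 ms stencil (about one rise time) for the same
reason.

*Peak timing.* The minimum sample of a noisy asymmetric trough is a biased
time estimator: noise drags it toward the flatter (decay) flank. The peak
found structurally on the landscape is therefore re-timed as the vertex of
a least-squares parabola over +-0.8 smoothing widths, whose noise error is
zero-mean to first order because both flanks are weighed. The residual
deterministic displacement that waveform asymmetry induces in this
estimator is measured by pushing each clean training segment through the
same computation, and the bank mean is subtracted — the same calibration
idea as the training-stage convolution shift. Overlapping events retain a
small early bias (the neighbor's decay slope genuinely shifts the combined
waveform's minimum); the 1.5 ms matching tolerance absorbs it.

*Degenerate inputs.* Empty traces yield empty event tables; all-zero
segments and segments shorter than order + 2 samples are rejected at
training; traces shorter than three filter orders are rejected at
filtering; a flat peak-search window discards its candidate.

## The simulator

`simulation_spec()` defaults *are* the study conditions: 20 events/s, 27 ms
refractory period, 20% of violations forgiven, 215 ms trials, 10 kHz.

*Arrival times* (`generate_arrivals()`): the event count is Poisson
(mean 4.3 per trial); positions are uniform; a position violating the
refractory spacing against any accepted event is re-drawn unless forgiven
(20% of violations), which is what produces overlapping events. A rare
surplus of events that cannot be packed is dropped, leaving the long-run
mean at ~4.30. An alternative reading — thinning violating arrivals with a
20% skip — was rejected because at these rates it discards a third of all
events (measured mean ~3.1, irreconcilable with the intended ~4.3).

*Template library* (`synth_template_library()`): ten double-exponential
EPSC shapes, rise constants 0.4-1.2 ms, decay 2.5-5.5 ms, giving 5%-of-peak
support durations of roughly 11-20 ms; each is L-infinity normalized (unit
peak) so one number, SNR = peak amplitude / noise SD, describes a trial.
Waveforms are stored peak-centered (leading zero padding), mirroring how
recorded event segments are extracted centered on the peak time, so
placing a waveform's midpoint at an arrival time puts its peak there and
the planted peak is the ground-truth arrival. The marked onset used for
training includes 2 ms of baseline before the kinetic rise — a human
operator marks the onset where the signal starts falling sharply, at
baseline level — which is why the bank's mean lead (~4 ms) exceeds the
rise time proper and gives the onset search its baseline margin.

*Training amplitudes* (`train_bank_from_library()`): drawn uniformly from
0.15-0.45 of the unit test-template peak. Recorded training events are
strong relative to noise but small relative to the largest event of a
recording; this ratio reproduces the characteristic dispersion of pooled
`c_max` statistics (coefficient of variation near 0.5) and places the
whole practical threshold band — and even `mu + 3 sigma` — below the
convolution response of a unit-peak event, which is what makes the
threshold choice uncritical at high SNR. The amplitude-gate basis defaults
to 0.25, about a quarter of the test-template peak.

*Noise library* (`synth_noise_library()`): sixteen 400 ms traces of white
Gaussian noise low-pass filtered at 2 kHz (zero phase), emulating the
band-limited current noise of a whole-cell recording chain, plus sparse
spontaneous EPSC-like transients (2/s, 2-5 background SDs) that create
realistic false-alarm challenges; each trace is standardized to mean 0,
SD 1. AR(1) and plain white spectra are available alternatives. Trials add
a random contiguous segment of a random library trace, scaled by 1/SNR
(`compose_trial()`).

*What the generator does not emulate*: electrode-series-resistance
artifacts, slow baseline drift beyond what the high-pass removes, the
direct uncaging response itself (gating is exercised with synthetic
constructions in the tests instead), bursting or rate-modulated event
trains, and amplitude variability of the *planted* events (test templates
are unit-peak by construction, so amplitude-recovery checks measure the
measurement chain, not biological variability). Passing simulation tests
therefore validates the detection and measurement machinery under
controlled conditions; they do not certify performance on any particular
recording preparation.

## Evaluation

`match_events()` matches detections to ground truth greedily, nearest
first, one-to-one, within 1.5 ms (well under the ~11 ms mean template
duration; ties to the earlier truth event). Unmatched truths are omissions,
unmatched detections false alarms. Per-trial correct-detection and
false-alarm rates are averaged across trials (`roc_curve()`); the false-
alarm denominator defaults to the number of detected events (the fraction
of detections that are wrong) and can be switched to the number of true
events. `arrival_error_stats()` pools signed errors of correct detections.

Problem sizes in the shipped tests and the acceptance script were chosen to
keep the full suite in the minutes range on one CPU: 20-50 trials per
operating point for detector characteristics, 25 seeded pair trials for
overlap splitting, and 100,000 trials for the event-count statistic (which
needs no detection and runs in seconds). A 200-trial run at one SNR and
one threshold takes on the order of ten seconds.

## Mapping

`build_maps()` aggregates detected events per photostimulation site into
the three standard map layers: mean input amplitude — the summed-input
total in the analysis window divided by the window length, minus the same
statistic on the pre-stimulus portion of the same trace, so purely
spontaneous sites map to 0 pA; event count; and first-event latency. The
analysis window defaults to 10-150 ms after laser onset (opening at the
direct-response window's end; the closing edge is configurable since map
figures conventionally show ~200 ms). `summarize_by_cell()` reports
group-level event statistics as per-cell medians averaged across cells
(mean +/- SE); pooled-event medians are available as an alternative
convention since both appear in the literature.

## IPSC analysis

IPSCs recorded at 0 mV are outward. `invert_polarity()` (or
`detect_events(..., ipsc = TRUE)`) negates the trace so the entire
EPSC pipeline applies unchanged — training, detection and mapping; the
detection output is identical event-for-event to running the mirrored
trace, which the test suite asserts exactly.

## Known limitations

- Events at or below the amplitude cutoff are missed by design; with the
  default cutoff at the spontaneous level this is the intended rejection
  of noise-related artifacts.
- Events closer than about the refractory of the boundary cascade's
  resolution (~3-4 ms) merge into one detection.
- The arrival-time estimate of an event over-riding another's decay is
  shifted early by a fraction of a sample to a few tenths of a millisecond,
  because the superposition genuinely moves the combined minimum.
- Thresholds assume the trained bank's amplitude scale matches the
  recording being analyzed; a bank trained on a different cell type or
  holding potential should be retrained or its `c_max` statistics
  inspected first.
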