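---
title: "Mapping unitary synaptic connections from voltage-imaging movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping unitary synaptic connections from voltage-imaging movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voltcon)
```

## The measurement problem

Chemigenetic voltage sensors make the membrane potential of individual
neurons optically readable: an action potential (AP) appears as a brief,
cell-shaped *drop* in fluorescence, and with enough trial averaging even
subthreshold postsynaptic potentials become visible. In a sparsely
labelled acute slice this allows a connectivity experiment without
electrodes: every spontaneously spiking cell serves simultaneously as a
potential presynaptic trigger source and as a potential postsynaptic
reporter, so a single field of view yields an entire directed
connectivity matrix rather than the two or three directions a paired
patch-clamp session can test.

`voltcon` implements the full analysis chain for such experiments —
from raw 1 kHz movies (or per-cell fluorescence traces) to detected
spikes, verified unitary EPSPs, and network-level statistics — together
with a synthetic-experiment generator that plants known spikes and
connections so that every stage can be validated against ground truth.

## Signal model and conventions

* Sampling is fixed at 1 kHz; one frame is one millisecond everywhere.
  Recordings are trial-structured (2,200-frame trials by default,
  repeated tens to hundreds of times); global time in ms equals
  `trial_index * frames_per_trial + frame`.
* The basic signal is the fractional fluorescence change
  ΔF/F₀, with F₀ the per-pixel (or per-trace) trial mean. Depolarisation
  makes the sensor dimmer, so raw ΔF/F₀ transients are negative;
  analysis traces are sign-inverted ("AP-up") so that depolarisation is
  positive. A 20th-percentile F₀ is available as an option for
  recordings with dense activity.
* Subthreshold amplitudes are expressed in **AP%**: percent of the same
  cell's optical AP peak. Because the AP is a large, stereotyped
  electrical event, this normalisation cancels cell-to-cell differences
  in fluorescence gain and makes amplitudes comparable across cells.

## The synthetic generator

`gen_config()` / `generate_network()` / `generate_spikes()` /
`render_movie()` / `render_traces()` define the study conditions:

* **Network** — a directed Erdős–Rényi graph over the pyramidal cells
  at 5.3 % connection probability (optionally block-structured by
  afterdepolarisation class), per-edge amplitudes drawn lognormally
  (median 2.3 AP%, log-SD 0.8) truncated to 0.2–15 AP%, decay time
  constants uniform in 8–22 ms.
* **Spiking** — homogeneous Poisson baselines (pyramidal cells 1.31 Hz,
  interneurons 4 Hz) restricted to trial windows, plus Poisson-thinned
  excess postsynaptic firing in the 4–19 ms window after each
  presynaptic spike; the excess rate is 2.19 Hz for an edge of mean
  amplitude (2.69 AP%) and scales linearly with the edge amplitude. A
  5 ms absolute refractory period is enforced; cells of the aAP class
  can fire doublets at 8–20 ms intervals instead of bursting through the
  refractory mechanism. The synaptic delay from presynaptic AP peak to
  EPSP onset is 2.5 ms, the midpoint of the 2–3 frame post-AP range
  where the constrained fit is empirically optimal.
* **Optics** — per-pixel fluorescence is
  `baseline × bleach(t) × (1 − Σ kernels) + noise`. The AP kernel is a
  negative biexponential scaled to the cell's ΔF/F₀ amplitude (default
  0.04, lognormal cell-to-cell spread), with an additive
  afterdepolarisation component for aAP cells whose mean over 15–40 ms
  post-peak equals the configured ADP fraction; interneurons get a
  narrower spike. EPSP kernels rise with τ = 3 ms and decay with the
  per-edge constant, scaled in AP% of the *postsynaptic* cell's AP.
  Photobleaching is an order-3 polynomial per trial; optional cross-talk
  bleeds a fraction of a cell's kernel onto neighbours within 50 µm.
  The trace noise SD equals `ap_peak_dff / ap_snr`; the default SNR of
  15 was calibrated once so that single APs are detected essentially
  always, consistent with how easily they are identified by eye in real
  ΔF/F₀ movies. ROIs are non-overlapping filled ellipses (10–20 µm
  somata) with a minimum centroid separation.

Two rendering backends share this kernel/bleach/noise model.
`render_movie()` rasterises pixels and feeds the image-analysis stages
(activity scan, ROI refinement, triggered videos); it is exercised on
small fields. `render_traces()` produces the ROI-mean fluorescence trace
of every cell directly and enters the pipeline at the trace stage; the
multi-slice studies below use it, because rendering and re-segmenting
tens of full-length pixel movies adds nothing to what the small-field
movie tests already establish while multiplying the compute by orders of
magnitude.

What the generator does **not** emulate: dendritic voltage propagation
(the sensor is soma-targeted and kernels are somatic only), biophysical
membrane dynamics, chloride-reversal effects on IPSPs (inhibition is not
rendered), slice-to-slice optical heterogeneity beyond a lognormal gain,
and slow network states. Passing tests therefore demonstrate that the
*analysis* is correct and calibrated under the stated statistical model
of the data — not that the model captures every property of real slices.

## Pipeline stages and their parameters

1. **ΔF/F₀ and trace extraction** (`compute_dff()`, `extract_trace()`,
   `traces_from_raw()`): per-trial F₀; ROI-mean; sign inversion;
   per-trial polynomial bleach correction (order 3) in two passes — the
   second fit excludes a ±10 ms guard around frames more than 4 robust
   SDs above the first fit, so large transients do not bend the
   baseline.
2. **Filtering** (`lowpass_100hz()`): 4-pole Butterworth applied
   forward–backward per trial. Zero phase keeps event onsets and peaks
   unshifted; the single-pass cutoff is set to 113.12 Hz so that the
   *effective* response is −3 dB at exactly 100 Hz.
3. **Spike detection** (`activity_scan()`, `detect_spikes()`): movies
   are scanned frame-by-frame with a grayscale morphological opening
   (disc of ~1.5 µm radius) so single-pixel noise cannot form cell-sized
   dark areas; a per-pixel activity heat-map thresholded at 3 robust SDs
   defines provisional ROIs (the threshold was calibrated on synthetic
   movies: all planted cells recovered, no false components on silent
   movies). Trace-level detection uses threshold crossings at 5× the RMS
   of the AP-free trace, with the RMS estimated iteratively
   (detect → mask ±10 ms → re-estimate, at most 5 rounds) and a 5 ms
   minimum inter-spike interval. A local maximum within 30 ms of a ≥2×
   larger peak is treated as that AP's afterwave: without this guard the
   ADP plateau of aAP cells (up to 20 % of the AP peak) produces
   spurious doublet detections, while true doublets (near-equal
   amplitudes) are unaffected.
4. **Quality control** (`qc_cell()`): cells with fewer than 10 APs are
   excluded; waveform inconsistency is operationalised as a per-spike
   peak-amplitude CV above 0.5 (an automated stand-in for visual
   verification, and flagged as such); an "abnormal transient" pattern —
   five or more spikes within 200 ms with monotonically decreasing
   amplitudes falling below half of the first — is excluded.
5. **Alignment** (`crosscorr()`, `flag_cross_detection()`,
   `ap_triggered_video()`, `refine_roi()`, `ap_amplitude()`,
   `ap_template()`): cross-correlograms over ±100 ms in 5 ms bins;
   cross-detection (one AP picked up on two ROIs) flags when the
   zero-lag bin exceeds the out-of-±20 ms baseline by 5 SDs *and* holds
   at least 5 % of the reference spikes — the second condition separates
   co-detection (which duplicates a large share of the train) from a
   strong synapse (whose 4–19 ms transmission window adds only a count
   or two to the [0, 5) ms bin). AP-triggered average videos (−45..+50
   ms) give minimal-intensity projections over the peak ±2 frames; the
   refined ROI is the thresholded component of the projection, contested
   pixels going to the cell with the larger projection magnitude; the
   cell's AP amplitude is the refined-ROI mean at the peak frame.
   Averaged templates are slightly broader and smaller than single
   events because 1 kHz peak assignment carries ±1–2 ms jitter; the
   tests assert this inequality rather than fighting it.
6. **Pair testing** (`pair_segments()`, `silent_cell_baseline()`,
   `normalize_ap_percent()`, `decontaminate()`, `candidate_screen()`,
   `shift_window_fit()`): for every ordered pair with a pyramidal
   presynaptic cell, the postsynaptic trace is averaged over −45..+50 ms
   around every presynaptic AP peak (segments crossing trial boundaries
   dropped). Shared photometric artifacts are removed by subtracting the
   mean average of eligible "silent" cells — cells with neither AP
   contamination nor an event-like deflection, judged on the residual
   after removing the pool median so a common artifact cannot disqualify
   everyone; with fewer than 3 eligible cells the pool median is
   subtracted and the pair flagged. Averages are normalised to AP% and
   decontaminated by dropping triggers with a postsynaptic spike within
   −15..+50 ms (pairs losing more than half their triggers are excluded
   as AP-contaminated). In this generator the decontaminated amplitude
   is the unbiased one, because excess postsynaptic firing is driven by
   the rate model rather than by per-trial amplitude fluctuations.
7. **The candidate screen**: exclusions first — somata closer than 50 µm
   (potential optical cross-talk), deflections already rising at the
   trigger with AP-like (≤5 ms half-decay) kinetics, baselines with SD
   above 1.5 AP%. Surviving averages are candidates when the onset falls
   in a loose band just after the trigger, the amplitude is 0.2–15 AP%,
   and the waveform is EPSP-asymmetric (half-rise shorter than
   half-decay, or half-decay ≥ 5 ms, which no AP-like waveform reaches).
   Screen features are measured on a 5-point smoothed copy — single
   noisy frames must not flip a kinetic check — while all quantitative
   fitting consumes the unsmoothed average. The screen is deliberately a
   coarse pre-filter: precise timing is enforced by the fit.
8. **The shifting-window fit**: a unit-peak biexponential EPSP template
   (rise τ fixed at 3 ms) is fitted by bounded least squares over a
   40 ms window starting at every shift from 17 frames before to 17
   frames after the presynaptic peak, with the amplitude constrained to
   1–20 AP%, the decay constant to 8–22 ms, and the baseline offset to
   ±1 AP% (decay handled by a 0.5 ms grid with the gain and offset
   solved in closed form and clamped). Acceptance requires three things:
   the overall best shift falls 1–5 frames *after* the presynaptic AP;
   its RMSE drops below the mean of the 16 pre-AP fits by at least 2 of
   their SDs; and the fitted amplitude sits strictly above its mandatory
   lower bound. The noise reference is taken from the pre-AP fits only:
   for a real connection the post-AP windows contain the EPSP itself, so
   their RMSE mean and spread grow with amplitude and any threshold
   built from them makes sensitivity *fall* as EPSPs get larger —
   calibration on planted traces showed recall collapsing at 5 AP%
   under such a rule, while the pre-AP baseline gives recall that rises
   monotonically with amplitude (≈0.7/0.95/1.0 at 2/3/5 AP%). The
   interior-amplitude guard removes almost all remaining false
   positives: on pure noise the optimiser pins the amplitude at the
   mandatory 1 AP% bound in ~96 % of best fits, so requiring an interior
   solution cuts fit-alone null acceptance from ~6–8 % to ~0.5 % without
   touching genuine EPSPs. Smoothing is never applied before fitting.
9. **Kinetics** (`epsp_kinetics()`): amplitude above the pre-trigger
   baseline, single-exponential decay fitted from the peak over the
   following 40 ms (profiled gain/offset, golden-section search over τ),
   and the half-width by linear interpolation at half amplitude. Note
   that this *procedure* applied to a biexponential input reads a
   somewhat larger constant than the kernel's decay parameter (≈12 ms
   for an 8.6 ms kernel) — the tests freeze that closed-form value; the
   constrained fit is the estimator that recovers the kernel parameter
   itself.

## Network statistics

`connectivity_experiment()` carries the partially observed directed
graph: a tested mask (directions that survived all exclusions — the
denominator of every rate) and a connected mask. Rates are `100·k/n`
with optional pre/post label filters; 2×2 comparisons use the exact
hypergeometric two-sided test.

The motif census counts reciprocal, divergent, convergent, three-chain
and four-chain patterns **non-induced** over distinct-node tuples:
extra edges never disqualify a tuple, and a reciprocal pair is not
additionally counted as the chain A→B→A. One convention is applied
identically to the observed graphs and to the bootstrap null, which is
what makes the comparison meaningful. The null re-places each slice's
observed number of connections uniformly (without replacement) over that
slice's tested directions — excluded directions can never receive a
connection — for 10,000 iterations; the overall profile comparison is a
plain chi-square over the five categories with df = 4 (the total is
fixed). Census correctness is established against an exhaustive
brute-force enumeration on hundreds of random graphs, and bootstrap
means against complete enumeration of all placements on small skeletons.

Per-cell input/output connection probabilities come from slices with at
least 9 pyramidal cells; occurrence counts at distinct probability
values are fitted by least squares on log-log axes (the small-sample
regime; the fit is flagged undefined with fewer than three occupied
values). A hub is a cell whose input *and* output probabilities both
exceed twice the overall rate; the expected hub count under independence
is `N · P(p_in > thr) · P(p_out > thr)`.

Cell classes: the afterdepolarisation ratio is the mean AP-up template
value 15–40 ms after the peak divided by the peak (negative for an AHP);
7–20 % defines the aAP class and 0–4 % the rAP class, with the 4–7 % gap
left unassigned. A cell bursts when at least 10 % of its APs are
preceded by another within 25 ms. The pyramidal layer is trisected by
normalised depth with half-open bins ([0, ⅓) deep, [⅓, ⅔) middle,
[⅔, 1] superficial). The pyramidal/interneuron heuristic combines
template width, spike count and layer position, and is calibrated on the
synthetic waveforms — a supplied anatomy label always overrides it.

## Problem sizes and reproducibility

The multi-slice recovery study (`run_recovery_study()`) uses 26
pseudo-slices of 9–12 pyramidal cells at 40 trials × 2,200 frames with
trace-level rendering, ~2,200 tested directions in total; it completes
in well under a minute and is the basis of both the acceptance test and
`scripts/acceptance.R`. Pixel-movie stages are validated on small fields
(48–96 px, a few trials), where every planted cell and ROI is recovered
and the noiseless movie is reproduced exactly. All randomness flows from
explicit integer seeds: the same seed and configuration give
bit-identical movies, spike trains and pair tables.

## Known limitations

* IPSPs are neither rendered nor fitted (a negative-deflection screen is
  the only trace of them), mirroring the physical fact that
  chloride-mediated events are near-invisible at slice resting
  potentials.
* The pair stage tests only spiking cells, so the connectivity rate is a
  lower bound by construction, exactly as in the real experiment.
* The waveform-CV quality gate and the automated cross-detection flag
  replace steps that are done by eye in practice; both are exposed as
  parameters and their outputs carry enough detail for manual review.
* Amplitude recovery is unbiased under the generator's assumption that
  excess postsynaptic firing follows the rate model; if real EPSP
  amplitudes fluctuate trial-to-trial and spikes preferentially ride
  large trials, decontamination will under-estimate amplitudes — the
  direction of bias the real experiment reports.
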