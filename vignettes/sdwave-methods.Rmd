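---
title: "Detecting and characterizing spreading depolarizations with sdwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing spreading depolarizations with sdwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spreading depolarizations (SDs) are near-complete depolarizations of
cortical neurons and glia that propagate across the cortex at a few
mm/min.  In DC-coupled electrocorticography (ECoG) an SD appears as a
negative slow potential change (SPC) of a few millivolts lasting on the
order of a minute, accompanied by a depression of the spontaneous
0.5–45 Hz activity.  In intrinsic optical signal (IOS) imaging at an
isosbestic wavelength (~564 nm), reflected intensity tracks total
hemoglobin, so it serves as a cerebral blood volume (CBV) surrogate with
an inverted sign: an intensity *decrease* means hyperemia.  Laser speckle
contrast imaging (LSCI) yields cerebral blood flow (CBF) together with
oxy- and deoxyhemoglobin traces in arbitrary perfusion units (APU).

`sdwave` implements the full analysis chain for such recordings after
cerebral venous (superior sagittal sinus) occlusion: per-sensor event
detection, propagation-aware grouping into SD events, decomposition of
the SD hemodynamic response into the canonical vasomotor components
I–V, classification of the four response morphologies, and cohort-level
statistics (incidence, expansion, first-versus-last response
comparisons) with exact rank tests.  Because no public dataset of this
kind exists, the package ships a synthetic cohort generator with full
ground truth, so that every stage of the pipeline is testable end to
end.

## The detection model

**ECoG.**  Each channel is viewed through three zero-phase FFT filters
built from one forward transform: a slow band (default 0.002–0.5 Hz), a
plain 0.5 Hz low-pass, and the spontaneous-activity band (0.5–45 Hz,
capped at 45% of the sampling rate).  Candidate SPCs are negative
deflections of the slow trace with trough depth ≥ 2 mV and a
width-at-half-depth between 30 s and 5 min.  The slow band is a
detection view only: its high-pass edge slightly attenuates and delays
minute-scale deflections, so depth, onset and duration are re-measured
on the low-passed trace against a local linear baseline fitted over
[trough − 5 min, trough − 2 min].  Onsets are interpolated leading
half-maximum crossings — the same convention the generator uses to place
pulses, which makes onset-recovery errors well defined.  A note on the
slow band: the figure legends of DC-coupled studies often quote bands
like "0.5–0.05 Hz" for visualizing slow events, but a 0.05 Hz *floor*
would remove essentially all energy of a 90 s deflection (its spectrum
is concentrated below 0.01 Hz).  The default high-pass edge is therefore
0.002 Hz, low enough to pass SPCs intact and high enough to reject
instrumental drift; it is a configuration parameter
(`ecog_config(slow_band_hz=)`).

Depression of spontaneous activity is scored on the RMS envelope of the
high band (10 s window, decimated to 1 Hz) relative to a 10 min rolling
median: a drop to ≤ 50% for ≥ 2 min within 10 min of the SPC onset
upgrades a candidate from "possible" to "confirmed".  Candidates without
depression are kept (configurable via `require_depression`), and
candidates without a pre-event baseline are flagged low-confidence
rather than dropped.

**Grouping.**  Candidates are merged greedily in onset order: a
candidate joins the earliest open event of its hemisphere when every
pairwise onset lag is consistent with a wavefront speed in 1–10 mm/min
given the sensor distances; one candidate per sensor per event; events
never span the midline; two sensors minimum (the IOS "at least two
ROIs" rule, applied to channels as well).  Orphan candidates are
reported separately.  Greedy grouping (rather than global optimization)
is a deliberate choice: event density is a few per hour at most, so
collisions are rare and the behavior stays auditable.

**IOS.**  Per ROI, an individual baseline is established as the median
and robust SD (1.4826 × MAD) of the pre-occlusion window, after removing
a linear drift fitted robustly over the *whole* trace (outlier-trimmed
least squares, three passes) — a trend extrapolated from a 10 min window
alone would be worthless hours later.  Intensity is converted to CBV
percent (`cbv = −(I − I₀)/I₀ · 100`, hyperemia positive).  Deviations
are maximal segments with |CBV| ≥ 3σ for ≥ 20 s on a 5 s-smoothed trace;
segments with two peaks separated by a valley below half the smaller
peak are split; segments on one ROI closer than 75 s are consolidated
into one response (an SD response is a *sequence* of deflections).  The
75 s merge gap sits between the largest intra-response gap the component
geometry produces (≈ 40 s) and the smallest inter-event gap in dense
hours (≈ 98 s).  Grouping across ROIs then reuses the ECoG path.

**Decomposition.**  Within a response window the smoothed CBV trace is
reduced to turning points with a minimum reversal ("prominence") of 3σ;
maxima must exceed +3σ and minima fall below −3σ, so noise ripples on a
component's flank and shallow positive valleys between hyperemic peaks
never count as components.  The ordered extrema are labeled by rule: the
largest positive peak is peak hyperemia (III); a positive peak before
III and before any trough is the brief initial hyperemia (I); a trough
before III is the initial hypoperfusion (II); positive peaks after III
are late hyperemia (IV); a sustained terminal negative plateau is
post-SD oligemia (V).  Amplitudes and half-maximum durations are then
refined by least-squares fitting of a sum of log-normal pulses
(`minpack.lm::nls.lm`), initialized from the rule-based estimates; the
refinement is rejected per component if it changes sign or scale
implausibly, falling back to the rules.  "Duration" is full width at
half maximum throughout — the generator uses the same definition, which
keeps amplitude/duration targets self-consistent.

**Morphologies.**  Classification is a pure function of the ordered
component kinds: `III` monophasic, `III,IV` biphasic, `II,III,IV`
triphasic, `I,II,III,IV` tetraphasic, anything else "other".

**LSCI.**  CBF traces (5 s sampling) run through the same
deviation-and-grouping path; percent elevation is
`100·(peak − baseline)/baseline` (invariant under APU rescaling), with a
returns-to-baseline flag at ±2σ.  Oxy-/deoxyhemoglobin coupling reports
the signs of the peak deltas and the deOxyHb onset lag relative to CBF.
LSCI output is descriptive (per-event reports, no cohort tests), since
such recordings typically survive in single animals.  Cross-modal
matching is greedy nearest-onset within ±5 min — wide enough to bracket
the ~3 min ECoG–LSCI onset offset seen for the same wave.

## The synthetic cohort

The generator is kinematic, not biophysical: an SD wave is a point
origin at the midline occlusion site, an onset time, and a constant
speed (1–10 mm/min plausibility band); the wavefront reaches the
nearest fraction of the hemisphere's sensors, and per-sensor arrival
times are exactly `onset + distance/speed`.  On arrival it injects:

* ECoG: a negative log-normal SPC (depth 4.5–7 mV, FWHM 80–100 s)
  whose leading half-maximum crossing is placed at the arrival time,
  plus suppression of the broadband signal to 30% for 5 min (with
  cosine ramps).  Instrumental drift (a 1.5 mV, 2 h-period sinusoid
  plus a 0.02 mV/min ramp) is added after injection, because depression
  scales cortical activity, not the amplifier baseline.
* IOS: the component sum of the event's morphology, converted to
  intensity with the inverted sign convention.  Component III carries
  per-ROI amplitude/width; accessory components are fixed conventions
  (I +4.5%/0.8 min, II −5%/1.2 min, IV +6%/2.5 min).  The II→III lag
  grows with III's width (`max(2.2, 0.4·fwhm + 0.7)` min) so that a wide
  peak's leading tail does not swallow the hypoperfusion.
* LSCI: a monophasic CBF pulse with OxyHb co-varying at gain +0.6 and
  deOxyHb at −0.4 with a 15 s lag.

Noise models: pink (1/f) broadband at 0.05 mV RMS for ECoG; white noise
at 0.5% of baseline plus a 0.1%/h linear drift for optical traces.
These levels exercise baseline estimation and the depression scorer
without overwhelming detection at the default thresholds.

Geometry defaults (conventions, since sensor counts but not coordinates
are typically reported): two parasagittal 5-contact strips at 10 mm
spacing (x = ±6 mm), 12 IOS ROIs (6 per hemisphere, x = ±4 mm), 4 LSCI
ROIs on the right hemisphere with ROI 4 parietal (nearest the occlusion)
and ROI 1 frontal, and the occlusion site at the origin.  All
within-hemisphere sensors lie at distinct distances from the origin, so
a wavefront produces strictly ordered arrivals — degenerate simultaneous
arrivals would otherwise defeat the pairwise speed-consistency rule.

**The replication preset.**  `build_roster("paper_replication")` is a
fixed, seed-independent event table encoding a published swine
SSS-occlusion cohort's Results statistics *by construction*: 12 ECoG
animals over 95.3 h with 26 SDs (17 in hour 1; none in hours 4–6; 10 of
12 animals affected; mean time to first SD 49.3 min; per-animal mean
expansion 69.4% of the 5 ipsilateral contacts; per-animal incidence
mean ≈ 0.3 SDs/h), six IOS animals over 38.3 h with 16 SDs (9 in hour 1;
first-SD mean 101 min; per-animal mean expansion ≈ 85.8% of the 6
ipsilateral ROIs), a 5/5/3/3 mono/bi/tri/tetraphasic morphology mix
that equals 31.25% monophasic at the ROI-response level, per-ROI first
responses at 18.5%/3.1 min and last responses at 16.3%/8.3 min, and one
LSCI animal with a single SD at 9 min post-occlusion (ROI order
4→3→2→1, mean CBF elevation 61.5%) whose ECoG counterpart sits at
12 min.  The seed drives only the noise streams.  Within the roster, the
reached-sensor counts were chosen so that the per-animal means land on
the printed values exactly (expansion means are constrained to
integer reached-counts, so the achievable values are 69.40% and 85.83%);
where a published number under-determines the design (e.g. a first-SD
standard deviation larger than its mean), the roster fixes a plain
per-animal onset list rather than sampling from a guessed distribution.

Hemisphere assignment alternates (balanced), reflecting the absence of
hemisphere differences in this model.  Event times avoid hour-bin edges
by at least a minute relative to each morphology's detected-onset lag.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: breathing/pulsation motion and the elastic
registration it requires (a motion-QC exclusion stage stands in),
electrode artifacts, seizure activity and epileptiform discharges,
inter-animal variability of response shapes beyond the first/middle/last
role parameters, APU scale differences between animals, and any
biophysical coupling between the ECoG and optical signatures of one
wave (the modalities are injected independently).

## Numerical choices

* Replication ECoG is synthesized at 10 Hz.  SD-band content lives below
  1 Hz and the depression band is capped at 0.45·fs, so nothing the
  detector measures is lost, while a 95 h cohort stays tractable; the
  same code path handles user data at any rate ≥ 10 Hz (including
  1000 Hz acquisitions).  IOS is 1 frame/s and LSCI one sample per 5 s.
* FFT filtering detrends linearly, reflection-pads by one high-pass
  period, extends to a 2-3-5-smooth length, and uses raised-cosine band
  edges — together these remove the circular-convolution artifacts that
  would otherwise appear at the recording edges and around sharp
  deflections.
* The baseline robust SD has a floor (0.05% of baseline) so noiseless
  traces keep a finite detection threshold.
* Exact rank tests enumerate the tie-aware null (2ⁿ sign assignments up
  to n = 15; all group assignments up to n = 12) and fall back to
  tie-corrected normal approximations with continuity correction above;
  the two agree to within 0.02 in p at the crossover sizes.  Zero
  differences are dropped (all-zero input returns p = 1 with a warning).
  Two-sided p-values throughout, no multiple-testing correction —
  matching the exploratory analysis style of the study design this
  mirrors.
* Per-animal expansion is the mean over that animal's events, and the
  cohort mean is over animals with at least one event; cohort incidence
  is reported both as the mean of per-animal rates and pooled, because
  printed values of ~0.3 ± 0.7 SDs/h imply the former.
* Tie-breaking in grouping is earliest-onset-first; each candidate joins
  the earliest compatible open event.

## Problem sizes used in the tests

The default test suite analyzes the full replication cohort once
(95.3 h of 10 Hz ECoG, 38.3 h of IOS, 2.5 h of LSCI), simulates 100
SD-free hours for the false-positive check, and runs all property suites
at small n; `scripts/acceptance.R` repeats the continuous statistics
over 20 noise seeds.  These sizes were chosen so a complete run stays in
the minutes range on one CPU while every cohort statistic is recovered
from signal, not from the roster.

## Known limitations

* Propagation is kinematic and radial; curved or branching wavefronts,
  re-entrant waves and wave collisions are out of scope.
* The component-V (post-SD oligemia) path is implemented in the
  classifier and detector but not exercised by the replication preset,
  which contains only the four canonical morphologies.
* The morphology prevalence denominator is defined at the ROI-response
  level (each ROI a reached event classifies is one response).  Published
  prevalence figures do not always state their denominator; with the
  replication roster the two conventions coincide by construction.
* `motion_qc` detects global frame shifts; it does not correct them.
  Data requiring elastic registration should be registered upstream.
* EDF output quantizes to 16 bits over each channel's observed range
  (the declared LSB); CSV output is lossless.
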