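# sdwave

Detection and hemodynamic characterization of **spreading depolarizations
(SDs)** in multimodal cortical recordings after cerebral venous occlusion:
DC-coupled electrocorticography (ECoG), intrinsic optical signal (IOS)
imaging, and laser speckle contrast imaging with oxygenation (LSCI).

SDs are near-complete neuronal/glial depolarizations that propagate across
the cortex at mm/min.  The package is aimed at experimental
neurophysiologists analyzing such recordings (gyrencephalic large-animal
models in particular), and at anyone who needs a fully ground-truthed
synthetic cohort to validate an SD pipeline end to end.

## What it computes

* **ECoG**: zero-phase slow-band filtering; detection of negative slow
  potential changes (depth ≥ 2 mV, 30 s–5 min at half depth) with
  concurrent depression of the 0.5–45 Hz activity (envelope ≤ 50% of a
  10 min rolling median for ≥ 2 min); grouping of per-channel candidates
  into propagating events when pairwise onset lags imply a wavefront speed
  of 1–10 mm/min; per-event **expansion** (% of channels reached) and
  cohort **incidence** (SDs/h).
* **IOS**: individual ROI baselines (median / 1.4826·MAD, robust linear
  detrending); CBV conversion with the inverted isosbestic sign convention
  `cbv% = −(I − I₀)/I₀·100` (hyperemia positive); 3σ deviation detection;
  the ≥ 2-ROI SD rule; decomposition of each response into the vasomotor
  components I–V (brief hyperemia, initial hypoperfusion, peak hyperemia,
  late hyperemia, post-SD oligemia) with log-normal pulse-fit refinement;
  morphology classification — `III` monophasic, `III,IV` biphasic,
  `II,III,IV` triphasic, `I,II,III,IV` tetraphasic; amplitude (% of
  baseline) and FWHM duration (min) of the hyperemic response.
* **LSCI**: monophasic CBF elevations in arbitrary perfusion units
  (`100·(peak−baseline)/baseline`), OxyHb/deOxyHb coupling signs and lag,
  propagation order across ROIs, and chronologic matching to ECoG events.
* **Cohort statistics**: per-animal incidence and expansion, hourly event
  profiles, first-versus-last SD comparisons per ROI, and exact tie-aware
  Wilcoxon signed-rank / Mann-Whitney U tests.
* **Synthetic cohorts**: `simulate_cohort()` builds multichannel
  post-occlusion recordings with pink-noise ECoG, drifting optical traces
  and kinematically propagating SD waves, with every injected event listed
  in a ground-truth roster (`build_roster()`, `roster_stats()`).

## Worked example

Simulate a small two-SD animal and run both detectors:

```r
library(sdwave)
sim <- simulate_cohort("unit_test", seed = 1, what = c("ecog", "ios"))

rec <- sim$animals$u01$ecog           # 10 channels, 2 h post-occlusion
det <- detect_sd_ecog(rec)
tab <- events_table(det$events)
tab$onset_min <- round((tab$onset_s - rec$occlusion_time_s) / 60, 2)
tab[, c("event_id", "hemisphere", "onset_min", "n_sensors", "expansion_pct", "amplitude")]
#>   event_id hemisphere onset_min n_sensors expansion_pct amplitude
#> 1     E001       left     14.99         4            80  5.078741
#> 2     E002      right     60.00         5           100  6.069773
```

The roster injected SDs at 15 and 60 min post-occlusion reaching 4/5 and
5/5 contacts with 5 and 6 mV deflections — the detector recovers the
onsets to within a second, the reached-channel counts exactly, and the
deflection depths to within ~0.1 mV.  The same animal's IOS traces:

```r
ios <- sim$animals$u01$ios
deti <- detect_sd_ios(ios)
resp <- classify_responses(deti, ios)
head(resp[, c("event_id", "roi_id", "morphology", "amplitude_pct", "duration_min")], 4)
#>   event_id roi_id morphology amplitude_pct duration_min
#> 1     I001    iL1  triphasic          17.3         3.01
#> 2     I001    iL2  triphasic          17.4         3.02
#> 3     I001    iL3  triphasic          17.4         3.00
#> 4     I001    iL4  triphasic          17.4         3.00
```

Both events are recovered with their injected morphologies (triphasic and
monophasic), peak-hyperemia amplitudes within 0.1% of the injected 17.4%
of baseline, and half-maximum durations within 0.02 min of the injected
3.0 min.

One call runs the whole multi-animal pipeline:

```r
res <- replicate_study("paper_replication", seed = 1)
nrow(res$ecog_events)                       # 26 ECoG SDs over 95.3 h
res$summary$ecog$expansion$mean             # 69.4 (% per-animal mean)
res$summary$first_last$last_dur_mean        # ~8.3 (min)
```

A thin command-line wrapper ships in `inst/cli/sdwave.R`
(`simulate`, `detect-ecog`, `detect-ios`, `detect-lsci`, `classify`,
`summarize`).

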