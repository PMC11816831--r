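#' Pink (1/f) noise
#'
#' Spectral synthesis: Fourier coefficients with amplitude proportional to
#' f^(-1/2) (power 1/f) and random phases, scaled to a target RMS.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param rms target root-mean-square amplitude.
#' @return numeric vector of length n.
#' @keywords internal
pink_noise <- function(n, fs, rms = 1) {
  if (n < 2) return(numeric(n))
  m <- n %/% 2
  f <- seq_len(m) * fs / n
  amp <- f^(-0.5)
  re <- stats::rnorm(m) * amp
  im <- stats::rnorm(m) * amp
  spec <- complex(real = re, imaginary = im)
  full <- complex(length.out = n)
  full[2:(m + 1)] <- spec
  # hermitian symmetry for a real signal
  full[n:(n - m + 2)] <- Conj(spec[seq_len(m - 1)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  x * rms / stats::sd(x)
}

# Smooth 0..1 plateau window with raised-cosine ramps, used for the
# depression of spontaneous activity.
plateau_window <- function(t, start, end, ramp = 30) {
  w <- numeric(length(t))
  up <- t >= start & t < start + ramp
  w[up] <- 0.5 * (1 - cos(pi * (t[up] - start) / ramp))
  w[t >= start + ramp & t <= end] <- 1
  dn <- t > end & t <= end + ramp
  w[dn] <- 0.5 * (1 + cos(pi * (t[dn] - end) / ramp))
  w
}

#' Inject a spreading depolarization into an ECoG recording
#'
#' At each contact the wavefront reaches, adds a negative slow potential
#' change of depth `dc_amplitude_mV` (FWHM `dc_duration_s`, leading half-max
#' at the kinematic arrival time) and suppresses the broadband activity to
#' `depression_fraction` of its amplitude for `depression_duration_min`.
#' Contacts the wavefront does not reach are unmodified.  Arrivals beyond the
#' recording end truncate the event with a warning.
#'
#' @param recording a [ts_recording()].
#' @param template an [sd_template()]; arrival times are interpreted as
#'   minutes post-occlusion.
#' @return the modified recording; attribute "truncated" is TRUE when any
#'   arrival fell beyond the end.
#' @export
inject_sd_ecog <- function(recording, template) {
  arr <- template_arrivals(template, recording$channels)
  t <- rec_time(recording)
  span_s <- max(t)
  truncated <- FALSE
  for (k in seq_len(nrow(arr))) {
    ch <- arr$id[k]
    t_arr <- recording$occlusion_time_s + arr$arrival_min[k] * 60
    if (t_arr > span_s) {
      warning(sprintf("arrival at %s (%.1f s) beyond recording end; event truncated",
                      ch, t_arr))
      truncated <- TRUE
      next
    }
    j <- match(ch, recording$channels$id)
    spc <- lognormal_pulse(t, onset = t_arr, peak = -template$dc_amplitude_mV,
                           fwhm_s = template$dc_duration_s)
    supp <- plateau_window(t, t_arr, t_arr + template$depression_duration_min * 60)
    base <- recording$samples[, j]
    recording$samples[, j] <- base * (1 - (1 - template$depression_fraction) * supp) + spc
  }
  attr(recording, "truncated") <- truncated
  recording
}

#' Inject an SD hemodynamic response into an IOS trace set
#'
#' Each reached ROI receives the sum of the template's component pulses
#' (log-normal pulses in the CBV-positive convention), converted to intensity
#' with the inverted sign convention: a hyperemic (positive CBV) response is
#' an intensity *decrease*.  Component III parameters can be overridden per
#' ROI through `iii_override` (used by the replication roster to carry the
#' first/last response amplitudes and durations).
#'
#' @param traceset an IOS [roi_traceset()].
#' @param template an [sd_template()] with a non-empty component list.
#' @param roi_components optional named list (by ROI id) of component lists
#'   replacing `template$components` at specific ROIs (used by the
#'   replication roster to carry per-ROI first/last response parameters).
#' @return the modified trace set.
#' @export
inject_sd_optical <- function(traceset, template, roi_components = NULL) {
  stopifnot(traceset$modality == "IOS")
  if (!length(template$components))
    stop("template has no hemodynamic components")
  check_component_order <- function(comps) {
    kinds <- vapply(comps, `[[`, "", "kind")
    if (all(c("I", "II") %in% kinds) &&
        comps[[match("II", kinds)]]$lag_min < comps[[match("I", kinds)]]$lag_min)
      stop("component II cannot precede component I")
  }
  check_component_order(template$components)
  arr <- template_arrivals(template, traceset$rois)
  t <- traceset_time(traceset)
  for (k in seq_len(nrow(arr))) {
    roi <- arr$id[k]
    j <- match(roi, traceset$rois$id)
    t_arr <- traceset$occlusion_time_s + arr$arrival_min[k] * 60
    comps <- template$components
    if (!is.null(roi_components) && !is.null(roi_components[[roi]])) {
      comps <- roi_components[[roi]]
      check_component_order(comps)
    }
    cbv <- numeric(length(t))
    for (cmp in comps)
      cbv <- cbv + lognormal_pulse(t, onset = t_arr + cmp$lag_min * 60,
                                   peak = cmp$peak_amplitude_pct,
                                   fwhm_s = cmp$fwhm_min * 60)
    base <- baseline_level(traceset, j)
    traceset$traces[, j] <- traceset$traces[, j] - base * cbv / 100
  }
  traceset
}

# Nominal baseline used by the injectors: median of the pre-occlusion window
# (or of the whole trace when there is none).
baseline_level <- function(traceset, j, field = NULL) {
  x <- if (is.null(field)) traceset$traces[, j] else traceset$traces[[field]][, j]
  t <- traceset_time(traceset)
  pre <- t < traceset$occlusion_time_s
  if (sum(pre) >= 3) stats::median(x[pre]) else stats::median(x)
}

#' Inject a monophasic CBF transient into an LSCI trace set
#'
#' CBF rises by `cbf_amplitude_pct` (per-ROI amplitudes via `roi_amps`) and
#' returns to baseline; OxyHb co-varies positively (gain `oxy_gain`) and
#' deOxyHb negatively (gain `deoxy_gain`) with a short lag.
#'
#' @param traceset an LSCI [roi_traceset()].
#' @param template an [sd_template()]; `cbf_amplitude_pct` scales all ROIs
#'   unless `roi_amps` is given.
#' @param roi_amps optional data.frame (roi_id, cbf_amp_pct, cbf_fwhm_min).
#' @param oxy_gain,deoxy_gain coupling gains relative to the CBF % elevation.
#' @param deoxy_lag_s lag of the deOxyHb response after the CBF onset (s).
#' @return the modified trace set.
#' @export
inject_sd_lsci <- function(traceset, template, roi_amps = NULL,
                           oxy_gain = 0.6, deoxy_gain = 0.4, deoxy_lag_s = 15) {
  stopifnot(traceset$modality == "LSCI")
  arr <- template_arrivals(template, traceset$rois)
  t <- traceset_time(traceset)
  for (k in seq_len(nrow(arr))) {
    roi <- arr$id[k]
    j <- match(roi, traceset$rois$id)
    amp <- template$cbf_amplitude_pct
    fwhm <- 2.5
    if (!is.null(roi_amps)) {
      o <- roi_amps[roi_amps$roi_id == roi, , drop = FALSE]
      if (nrow(o)) { amp <- o$cbf_amp_pct[1]; fwhm <- o$cbf_fwhm_min[1] }
    }
    if (amp == 0) next
    t_arr <- traceset$occlusion_time_s + arr$arrival_min[k] * 60
    pulse <- lognormal_pulse(t, onset = t_arr, peak = amp / 100, fwhm_s = fwhm * 60)
    lagged <- lognormal_pulse(t, onset = t_arr + deoxy_lag_s, peak = amp / 100,
                              fwhm_s = fwhm * 60)
    cbf0 <- baseline_level(traceset, j, "cbf")
    oxy0 <- baseline_level(traceset, j, "oxyhb")
    dxy0 <- baseline_level(traceset, j, "deoxyhb")
    traceset$traces$cbf[, j] <- traceset$traces$cbf[, j] + cbf0 * pulse
    traceset$traces$oxyhb[, j] <- traceset$traces$oxyhb[, j] + oxy0 * oxy_gain * pulse
    traceset$traces$deoxyhb[, j] <- traceset$traces$deoxyhb[, j] - dxy0 * deoxy_gain * lagged
  }
  traceset
}

# Deterministic per-stream seed derived from the roster's master seed.
stream_seed <- function(seed, idx, offset) {
  (as.integer(seed) %% 100000L) * 10000L + idx * 97L + offset
}

#' Simulate one animal of a roster
#'
#' Synthesizes the baseline signals (noise + drift) for the requested
#' modalities and injects every roster event of the animal.  Identical
#' (roster, animal, noise_scale) inputs give identical outputs.
#'
#' @param roster an [build_roster()] roster.
#' @param animal_id animal to simulate.
#' @param what subset of c("ecog", "ios", "lsci").
#' @param noise_scale multiplier on all noise amplitudes (0 = noiseless).
#' @return list with elements `ecog` ([ts_recording()]), `ios`, `lsci`
#'   ([roi_traceset()]); absent modalities are NULL.
#' @export
simulate_animal <- function(roster, animal_id, what = c("ecog", "ios", "lsci"),
                            noise_scale = 1) {
  an <- roster$animals[roster$animals$animal_id == animal_id, ]
  if (!nrow(an)) stop("unknown animal: ", animal_id)
  idx <- match(animal_id, roster$animals$animal_id)
  nz <- roster$noise
  base_s <- roster$fs$baseline_min * 60
  out <- list(ecog = NULL, ios = NULL, lsci = NULL)

  if ("ecog" %in% what && an$ecog_hours > 0) {
    fs <- roster$fs$ecog_fs
    n <- round((base_s + an$ecog_hours * 3600) * fs)
    t <- (seq_len(n) - 1) / fs
    set.seed(stream_seed(roster$seed, idx, 1L))
    chans <- roster$layout$contacts
    samp <- matrix(0, n, nrow(chans))
    phases <- stats::runif(nrow(chans), 0, 2 * pi)
    for (j in seq_len(nrow(chans)))
      samp[, j] <- noise_scale * pink_noise(n, fs, nz$ecog_rms_mV)
    rec <- ts_recording(samp, chans, sampling_rate = fs,
                        occlusion_time_s = base_s, animal_id = animal_id)
    evs <- roster$ecog_events[roster$ecog_events$animal_id == animal_id, ]
    for (i in seq_len(nrow(evs))) {
      ri <- which(roster$ecog_events$event_id == evs$event_id[i])
      rec <- inject_sd_ecog(rec, ecog_template(roster, ri))
    }
    # instrumental drift is added after injection: the depression of
    # spontaneous activity scales the cortical broadband signal, not the
    # amplifier baseline
    for (j in seq_len(nrow(chans))) {
      drift <- nz$ecog_drift_amp_mV * sin(2 * pi * t / nz$ecog_drift_period_s +
                                          phases[j]) +
               nz$ecog_drift_slope_mV_min * t / 60
      rec$samples[, j] <- rec$samples[, j] + noise_scale * drift
    }
    out$ecog <- rec
  }

  if ("ios" %in% what && an$ios_hours > 0) {
    dt <- roster$fs$ios_dt
    n <- round((base_s + an$ios_hours * 3600) / dt)
    t <- (seq_len(n) - 1) * dt
    set.seed(stream_seed(roster$seed, idx, 2L))
    rois <- roster$layout$rois_ios
    I0 <- 1000
    traces <- matrix(0, n, nrow(rois))
    for (j in seq_len(nrow(rois))) {
      drift <- nz$optical_drift_pct_h / 100 * t / 3600
      traces[, j] <- I0 * (1 + noise_scale * drift) +
        noise_scale * stats::rnorm(n, 0, nz$optical_sigma_pct / 100 * I0)
    }
    ts <- roi_traceset(traces, rois, "IOS", sampling_interval_s = dt,
                       occlusion_time_s = base_s, animal_id = animal_id)
    evs <- roster$ios_events[roster$ios_events$animal_id == animal_id, ]
    for (i in seq_len(nrow(evs))) {
      ri <- which(roster$ios_events$event_id == evs$event_id[i])
      ov <- roster$ios_responses[roster$ios_responses$event_id == evs$event_id[i],
                                 c("roi_id", "morphology", "amp_iii_pct",
                                   "fwhm_iii_min")]
      rc <- lapply(seq_len(nrow(ov)), function(k)
        morphology_components(ov$morphology[k], ov$amp_iii_pct[k],
                              ov$fwhm_iii_min[k]))
      names(rc) <- ov$roi_id
      ts <- inject_sd_optical(ts, ios_template(roster, ri), roi_components = rc)
    }
    out$ios <- ts
  }

  if ("lsci" %in% what && an$lsci_hours > 0) {
    dt <- roster$fs$lsci_dt
    n <- round((base_s + an$lsci_hours * 3600) / dt)
    set.seed(stream_seed(roster$seed, idx, 3L))
    rois <- roster$layout$rois_lsci
    mk <- function(level) {
      m <- matrix(0, n, nrow(rois))
      for (j in seq_len(nrow(rois)))
        m[, j] <- level + noise_scale * stats::rnorm(n, 0, nz$lsci_sigma_pct / 100 * level)
      m
    }
    ts <- roi_traceset(list(cbf = mk(100), oxyhb = mk(60), deoxyhb = mk(40)),
                       rois, "LSCI", sampling_interval_s = dt,
                       occlusion_time_s = base_s, animal_id = animal_id)
    evs <- roster$lsci_events[roster$lsci_events$animal_id == animal_id, ]
    for (i in seq_len(nrow(evs))) {
      ri <- which(roster$lsci_events$event_id == evs$event_id[i])
      ts <- inject_sd_lsci(ts, lsci_template(roster, ri), roi_amps = roster$lsci_rois)
    }
    out$lsci <- ts
  }
  out
}

#' Simulate a full cohort
#'
#' Generates every animal of a preset roster.  With `out_dir`, recordings and
#' the roster are also written to disk (CSV/JSON, and EDF for ECoG).
#' Identical (preset, seed) calls produce identical outputs.
#'
#' @param preset "paper_replication" or "unit_test", or an `sd_roster` built
#'   with [build_roster()] (the "custom" route).
#' @param seed integer master seed for the noise streams.
#' @param what modalities to synthesize.
#' @param noise_scale multiplier on all noise amplitudes.
#' @param out_dir optional output directory.
#' @return list with `roster` and `animals` (named list of
#'   [simulate_animal()] results).
#' @export
simulate_cohort <- function(preset = "paper_replication", seed = 1,
                            what = c("ecog", "ios", "lsci"), noise_scale = 1,
                            out_dir = NULL) {
  roster <- if (inherits(preset, "sd_roster")) preset else build_roster(preset, seed)
  animals <- lapply(roster$animals$animal_id, function(a)
    simulate_animal(roster, a, what = what, noise_scale = noise_scale))
  names(animals) <- roster$animals$animal_id
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_roster(roster, file.path(out_dir, "roster.json"))
    for (a in names(animals)) {
      bundle <- animals[[a]]
      if (!is.null(bundle$ecog))
        write_ecog(bundle$ecog, file.path(out_dir, paste0(a, "_ecog.edf")))
      if (!is.null(bundle$ios))
        write_traces(bundle$ios, file.path(out_dir, paste0(a, "_ios.csv")))
      if (!is.null(bundle$lsci))
        write_traces(bundle$lsci, file.path(out_dir, paste0(a, "_lsci.csv")))
    }
  }
  list(roster = roster, animals = animals)
}
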