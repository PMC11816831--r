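# ECoG spreading-depolarization detection: slow potential changes (SPCs)
# with concurrent depression of spontaneous activity, grouped across
# contacts into propagating events.

#' Zero-phase FFT band-pass
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param low,high band edges (Hz); `low = 0` keeps DC.
#' @return filtered vector, same length.
#' @keywords internal
fft_bandpass <- function(x, fs, low, high) {
  prep <- fft_prep(x, fs, low)
  fft_apply(prep, low, high)
}

# One forward FFT per channel, reusable for several bands.  Linear detrend +
# reflection padding suppress the circular-convolution edge artifacts a slow
# instrumental ramp would otherwise produce; the padded length is 2-3-5
# smooth so the mixed-radix FFT stays fast.
fft_prep <- function(x, fs, lowest) {
  n <- length(x)
  tt <- seq_len(n)
  cf <- stats::lm.fit(cbind(1, tt), x)$coefficients
  xd <- x - (cf[1] + cf[2] * tt)
  pad <- if (lowest > 0) min(n, ceiling(fs / lowest)) else min(n, 10L * round(fs))
  ne <- stats::nextn(n + 2L * pad, c(2, 3, 5))
  pad2 <- min(n, ne - n - pad)
  xe <- c(rev(xd[seq_len(pad)]), xd, rev(xd[(n - pad2 + 1):n]))
  if (length(xe) < ne) xe <- c(xe, rep(0, ne - length(xe)))
  f <- (seq_len(ne) - 1) * fs / ne
  list(X = stats::fft(xe), ne = ne, pad = pad, n = n, cf = cf, tt = tt,
       f_eff = pmin(f, fs - f))
}

# Apply a raised-cosine-edged band gain to a prepared spectrum.
fft_apply <- function(prep, low, high) {
  ne <- prep$ne
  gain <- rep(1, ne)
  f_eff <- prep$f_eff
  if (low > 0) {
    w <- 0.5 * low
    gain <- ifelse(f_eff >= low, 1,
                   ifelse(f_eff <= low - w, 0,
                          0.5 * (1 - cos(pi * (f_eff - (low - w)) / w))))
  }
  w2 <- 0.1 * high
  gain <- gain * ifelse(f_eff <= high, 1,
                        ifelse(f_eff >= high + w2, 0,
                               0.5 * (1 + cos(pi * (f_eff - high) / w2))))
  out <- Re(stats::fft(prep$X * gain, inverse = TRUE)) / ne
  out <- out[(prep$pad + 1):(prep$pad + prep$n)]
  if (low <= 0) out <- out + prep$cf[1] + prep$cf[2] * prep$tt
  out
}

#' Slow-band (DC-shift) view of an ECoG recording
#'
#' Zero-phase band-pass isolating the minute-scale slow potential changes of
#' spreading depolarization while removing instrumental drift and spontaneous
#' fast activity.  The default band is 0.002-0.5 Hz: the high-pass edge sits
#' well below the ~0.005 Hz spectral core of a 90 s deflection (so SPC depth
#' and timing are preserved) but still eliminates DC offset and drifts slower
#' than ~8 min.
#'
#' @param recording a [ts_recording()] (sampling rate >= 10 Hz).
#' @param band band edges in Hz, `c(low, high)`.
#' @return matrix of slow traces (one column per channel).
#' @export
slow_band <- function(recording, band = c(0.002, 0.5)) {
  if (recording$sampling_rate < 10)
    stop("slow_band requires a sampling rate of at least 10 Hz")
  span <- nrow(recording$samples) / recording$sampling_rate
  if (span < 10 / band[1])
    stop(sprintf("recording (%.0f s) shorter than 10x the low-cutoff period (%.0f s)",
                 span, 10 / band[1]))
  apply(recording$samples, 2, fft_bandpass, fs = recording$sampling_rate,
        low = band[1], high = band[2])
}

#' High-frequency envelope power of a recording
#'
#' Band-passes each channel to the spontaneous-activity band (0.5-45 Hz,
#' capped at 90% of Nyquist), takes the RMS envelope over a short window and
#' decimates it to 1 Hz.  This is the signal in which the depression of
#' spontaneous activity accompanying an SD is scored.
#'
#' @param recording a [ts_recording()].
#' @param band nominal envelope band (Hz).
#' @param window_s RMS window (s).
#' @return list with `t` (1 Hz time axis, s) and `power` (matrix of RMS
#'   envelopes).
#' @export
band_envelope <- function(recording, band = c(0.5, 45), window_s = 10) {
  fs <- recording$sampling_rate
  hi <- min(band[2], 0.45 * fs)
  env <- apply(recording$samples, 2, function(x)
    rms_envelope(fft_bandpass(x, fs, band[1], hi), fs, window_s))
  n1 <- nrow(env)
  list(t = (seq_len(n1) - 1) * 1.0, power = env)
}

# RMS envelope decimated to 1 Hz.
rms_envelope <- function(b, fs, window_s = 10) {
  p <- b^2
  w <- max(1L, round(window_s * fs))
  cs <- c(0, cumsum(p))
  idx <- seq(1, length(p) - w + 1, by = round(fs))
  sqrt((cs[idx + w] - cs[idx]) / w)
}

#' Detect slow-potential-change candidates on one channel
#'
#' Negative deflections of the slow trace with trough depth at least
#' `amp_threshold_mV`, measured duration (full width at half the trough
#' depth) inside the configured band, and onset at the interpolated leading
#' half-maximum crossing.  When an envelope is supplied, each candidate is
#' annotated with the concurrent high-frequency power depression relative to
#' a rolling median, giving it "confirmed" status (SPC + depression) or
#' "possible" (SPC alone).
#'
#' @param slow numeric slow-band trace (mV).
#' @param t time axis (s).
#' @param config an [ecog_config()].
#' @param envelope optional per-channel envelope from [band_envelope()]
#'   (list with `t`, `power` vector).
#' @param baseline_ok FALSE flags candidates "low_confidence" (no pre-event
#'   baseline available) instead of dropping them.
#' @return data.frame of candidates: onset_s, depth_mV, duration_s, status,
#'   depression_frac.
#' @export
detect_spc <- function(slow, t, config = ecog_config(), envelope = NULL,
                       baseline_ok = TRUE, lowpass = NULL) {
  thr <- config$amp_threshold_mV
  below <- slow < -thr / 2
  empty <- data.frame(onset_s = numeric(), depth_mV = numeric(),
                      duration_s = numeric(), status = character(),
                      depression_frac = numeric(), stringsAsFactors = FALSE)
  if (!any(below)) return(empty)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  segs <- which(r$values)
  out <- list()
  for (s in segs) {
    lo <- starts[s]; hi <- ends[s]
    i_tr <- lo - 1L + which.min(slow[lo:hi])
    depth <- -slow[i_tr]
    if (depth < thr) next
    # bound the half-max search by the segment, padded one sample
    hm <- half_max_crossings(t, slow, i_tr,
                             lo = max(1L, lo - 1L), hi = min(length(t), hi + 1L))
    if (!is.null(lowpass)) {
      # re-measure depth and timing on the undistorted low-passed trace with
      # a local linear baseline (the band-pass view is kept for detection
      # only; its high-pass edge slightly attenuates and delays minute-scale
      # deflections)
      ref <- refine_spc(lowpass, t, i_tr, config)
      if (!is.null(ref)) { depth <- ref$depth; hm <- ref$hm }
    }
    dur <- hm$fwhm
    if (is.na(dur)) dur <- t[hi] - t[lo]
    if (dur < config$min_duration_s || dur > config$max_duration_s) next
    dep <- NA_real_
    status <- if (baseline_ok) "possible" else "low_confidence"
    if (!is.null(envelope)) {
      dep <- depression_fraction_at(envelope, hm$onset, config)
      if (!is.na(dep) && dep <= config$depression_ratio) status <- "confirmed"
    }
    out[[length(out) + 1]] <- data.frame(
      onset_s = hm$onset, depth_mV = depth, duration_s = dur,
      status = status, depression_frac = dep, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# Local re-measurement of an SPC on the low-pass-only trace: fit a linear
# baseline over [trough-5 min, trough-2 min], subtract, and take the trough
# depth and half-max crossings of the corrected window.
refine_spc <- function(lowpass, t, i_near, config) {
  fs <- 1 / (t[2] - t[1])
  w_lo <- max(1L, i_near - as.integer(300 * fs))
  w_hi <- min(length(t), i_near + as.integer(300 * fs))
  b_hi <- max(w_lo + 1L, i_near - as.integer(120 * fs))
  bi <- w_lo:b_hi
  if (length(bi) < 5) return(NULL)
  cf <- stats::lm.fit(cbind(1, t[bi]), lowpass[bi])$coefficients
  seg <- w_lo:w_hi
  y <- lowpass[seg] - (cf[1] + cf[2] * t[seg])
  i_tr <- which.min(y)
  depth <- -y[i_tr]
  hm <- half_max_crossings(t[seg], y, i_tr)
  if (is.na(hm$onset)) return(NULL)
  list(depth = depth, hm = hm)
}

# Minimum ratio of envelope power to its rolling median, over the
# depression scoring window after an SPC onset; must stay below
# config$depression_ratio for >= depression_min_s to count as depression.
depression_fraction_at <- function(envelope, onset_s, config) {
  et <- envelope$t
  p <- envelope$power
  k <- round(config$median_window_s)
  if (k %% 2 == 0) k <- k + 1
  if (k >= length(p)) k <- max(3, length(p) - (1 - length(p) %% 2))
  med <- stats::runmed(p, k, endrule = "median")
  ratio <- p / pmax(med, 1e-12)
  win <- et >= onset_s & et <= onset_s + config$depression_scan_s
  if (!any(win)) return(NA_real_)
  rw <- ratio[win]
  # longest run below the depression ratio
  r <- rle(rw <= config$depression_ratio)
  if (!any(r$values)) return(min(rw))
  if (max(r$lengths[r$values]) < config$depression_min_s) return(min(rw))
  min(rw)
}

#' ECoG detection configuration
#'
#' Explicit, tunable SPC scoring criteria: deflection depth >= 2 mV
#' sustained 30 s - 5 min, depression of the 0.5-45 Hz envelope to <= 50% of
#' a 10 min rolling median for >= 2 min (candidates without depression are
#' kept as "possible"), propagation speed band 1-10 mm/min, and at least two
#' channels per event.
#'
#' @param amp_threshold_mV minimum SPC trough depth (mV).
#' @param min_duration_s,max_duration_s admissible SPC width band (s).
#' @param slow_band_hz slow band edges (Hz).
#' @param depression_band_hz spontaneous-activity band (Hz).
#' @param depression_ratio envelope fraction defining depression.
#' @param depression_min_s minimum depression duration (s).
#' @param depression_scan_s window after onset scanned for depression (s).
#' @param median_window_s rolling-median window for the envelope (s).
#' @param speed_band_mm_min plausible propagation speeds (mm/min).
#' @param min_sensors minimum sensors per event.
#' @param scope expansion denominator: "hemisphere" or "all".
#' @param require_depression drop candidates without depression if TRUE.
#' @return list of class `ecog_config`.
#' @export
ecog_config <- function(amp_threshold_mV = 2, min_duration_s = 30,
                        max_duration_s = 300, slow_band_hz = c(0.002, 0.5),
                        depression_band_hz = c(0.5, 45),
                        depression_ratio = 0.5, depression_min_s = 120,
                        depression_scan_s = 600, median_window_s = 600,
                        speed_band_mm_min = c(1, 10), min_sensors = 2,
                        scope = c("hemisphere", "all"),
                        require_depression = FALSE) {
  scope <- match.arg(scope)
  structure(as.list(environment()), class = "ecog_config")
}

#' Group per-sensor candidates into propagating SD events
#'
#' Greedy merge in onset order: a candidate joins the earliest open event of
#' its hemisphere whose sensors it is pairwise-consistent with (onset lag
#' and sensor distance implying a speed inside the plausibility band); one
#' candidate per sensor per event; events never span the midline.  Events
#' need at least `min_sensors` sensors; single-sensor groups are returned as
#' orphans.
#'
#' @param candidates data.frame with columns sensor_id, onset_s, amplitude
#'   (and optionally status/flags).
#' @param sensors sensor table (`id`, `hemisphere`, `x_mm`, `y_mm`).
#' @param config an [ecog_config()] or [optical_config()] (only the speed
#'   band and min_sensors are used).
#' @param modality label for the resulting events.
#' @param animal_id label for the resulting events.
#' @return list with `events` (list of [sd_event()]) and `orphans`
#'   (data.frame of unmerged candidates).
#' @export
group_events <- function(candidates, sensors, config = ecog_config(),
                         modality = "ECoG", animal_id = NA_character_) {
  if (!nrow(candidates))
    return(list(events = list(), orphans = candidates))
  candidates <- candidates[order(candidates$onset_s), , drop = FALSE]
  candidates$hemisphere <- sensors$hemisphere[match(candidates$sensor_id, sensors$id)]
  v <- config$speed_band_mm_min
  groups <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    placed <- FALSE
    for (g in seq_along(groups)) {
      grp <- groups[[g]]
      if (grp$hemisphere != cand$hemisphere) next
      if (cand$sensor_id %in% grp$members$sensor_id) next
      ok <- TRUE
      for (m in seq_len(nrow(grp$members))) {
        mem <- grp$members[m, ]
        d <- sensor_dist(sensors, cand$sensor_id, mem$sensor_id)
        dt_min <- abs(cand$onset_s - mem$onset_s) / 60
        # lag consistent with a wavefront at v in [v_min, v_max] over d
        if (dt_min < d / v[2] || dt_min > d / v[1]) { ok <- FALSE; break }
      }
      if (ok) {
        groups[[g]]$members <- rbind(grp$members, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      groups[[length(groups) + 1]] <- list(hemisphere = cand$hemisphere,
                                           members = cand)
  }
  keep <- vapply(groups, function(g) nrow(g$members) >= config$min_sensors, TRUE)
  orphans <- do.call(rbind, lapply(groups[!keep], `[[`, "members"))
  if (is.null(orphans)) orphans <- candidates[0, , drop = FALSE]
  events <- lapply(which(keep), function(g) {
    mem <- groups[[g]]$members
    flags <- character()
    if ("status" %in% names(mem) && any(mem$status == "low_confidence"))
      flags <- "low_confidence"
    sd_event(event_id = NA_character_, modality = modality,
             onsets = stats::setNames(mem$onset_s, mem$sensor_id),
             hemisphere = groups[[g]]$hemisphere,
             expansion_pct = expansion_pct(nrow(mem), groups[[g]]$hemisphere,
                                           sensors, config$scope),
             amplitude = max(mem$amplitude), flags = flags,
             animal_id = animal_id)
  })
  events <- events[order(vapply(events, event_onset, 0))]
  for (i in seq_along(events)) events[[i]]$event_id <- sprintf("%s%03d", substr(modality, 1, 1), i)
  list(events = events, orphans = orphans)
}

sensor_dist <- function(sensors, a, b) {
  i <- match(a, sensors$id); j <- match(b, sensors$id)
  sqrt((sensors$x_mm[i] - sensors$x_mm[j])^2 + (sensors$y_mm[i] - sensors$y_mm[j])^2)
}

#' Expansion of an SD event (% of sensors reached)
#'
#' 100 x reached / denominator, the denominator being the sensors of the
#' event's hemisphere (default) or all sensors.
#'
#' @param n_reached sensors with onsets.
#' @param hemisphere event hemisphere.
#' @param sensors sensor table.
#' @param scope "hemisphere" or "all".
#' @return percentage.
#' @export
expansion_pct <- function(n_reached, hemisphere, sensors,
                          scope = c("hemisphere", "all")) {
  scope <- match.arg(scope)
  denom <- if (scope == "hemisphere") sum(sensors$hemisphere == hemisphere)
           else nrow(sensors)
  100 * n_reached / denom
}

#' Detect spreading depolarizations in an ECoG recording
#'
#' Full pipeline: slow-band filtering, per-channel SPC detection with
#' depression annotation, and propagation grouping.
#'
#' @param recording a [ts_recording()].
#' @param config an [ecog_config()].
#' @return list with `events` (list of [sd_event()]), `candidates`
#'   (per-channel data.frame) and `orphans`.
#' @export
detect_sd_ecog <- function(recording, config = ecog_config()) {
  fs <- recording$sampling_rate
  span <- nrow(recording$samples) / fs
  if (fs < 10)
    stop("SD detection requires a sampling rate of at least 10 Hz")
  if (span < 10 / config$slow_band_hz[1])
    stop(sprintf("recording (%.0f s) shorter than 10x the low-cutoff period (%.0f s)",
                 span, 10 / config$slow_band_hz[1]))
  env_hi <- min(config$depression_band_hz[2], 0.45 * fs)
  t <- rec_time(recording)
  baseline_ok <- recording$occlusion_time_s >= 300
  cands <- list()
  for (j in seq_len(ncol(recording$samples))) {
    # one forward FFT per channel, three band views
    prep <- fft_prep(recording$samples[, j], fs, config$slow_band_hz[1])
    slow_j <- fft_apply(prep, config$slow_band_hz[1], config$slow_band_hz[2])
    lp <- fft_apply(prep, 0, config$slow_band_hz[2])
    envp <- rms_envelope(fft_apply(prep, config$depression_band_hz[1], env_hi), fs)
    cj <- detect_spc(slow_j, t, config,
                     envelope = list(t = seq_along(envp) - 1, power = envp),
                     baseline_ok = baseline_ok, lowpass = lp)
    if (nrow(cj)) {
      cj$sensor_id <- recording$channels$id[j]
      cands[[length(cands) + 1]] <- cj
    }
  }
  cands <- if (length(cands)) do.call(rbind, cands) else
    data.frame(onset_s = numeric(), depth_mV = numeric(), duration_s = numeric(),
               status = character(), depression_frac = numeric(),
               sensor_id = character(), stringsAsFactors = FALSE)
  if (config$require_depression && nrow(cands))
    cands <- cands[cands$status == "confirmed", , drop = FALSE]
  if (nrow(cands)) cands$amplitude <- cands$depth_mV
  grp <- group_events(cands, recording$channels, config, modality = "ECoG",
                      animal_id = recording$animal_id)
  c(grp, list(candidates = cands))
}
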