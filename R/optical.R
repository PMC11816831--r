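# IOS pipeline: baseline, CBV conversion, deviation detection, the >=2-ROI
# SD rule, component I-V decomposition and morphology classification.

#' IOS/LSCI analysis configuration
#'
#' @param k_sigma deviation threshold in robust baseline SDs.
#' @param min_len_s minimum deviation segment length (s).
#' @param smooth_s running-mean smoothing applied before segmentation (s).
#' @param merge_gap_s segments on one ROI closer than this belong to one
#'   response (bridges the gaps between components of a single SD response
#'   without merging successive SDs).
#' @param speed_band_mm_min plausible propagation speeds (mm/min).
#' @param min_sensors minimum ROIs per event (the "at least two ROIs" rule).
#' @param scope expansion denominator: "hemisphere" or "all".
#' @param refine_fit refine component amplitudes/durations by pulse fitting.
#' @param window_max_s decomposition window length after response onset (s).
#' @param sigma_floor_pct lower bound on the baseline robust SD (% of
#'   baseline), so that near-noiseless traces keep a finite threshold.
#' @return list of class `optical_config`.
#' @export
optical_config <- function(k_sigma = 3, min_len_s = 20, smooth_s = 5,
                           merge_gap_s = 75, speed_band_mm_min = c(1, 10),
                           min_sensors = 2, scope = c("hemisphere", "all"),
                           refine_fit = TRUE, window_max_s = 1800,
                           sigma_floor_pct = 0.05) {
  scope <- match.arg(scope)
  structure(as.list(environment()), class = "optical_config")
}

#' Convert an intensity trace to percent cerebral blood volume change
#'
#' Inverted sign convention of isosbestic-wavelength reflectance: an
#' intensity *decrease* means more hemoglobin in the tissue, i.e. hyperemia,
#' so \code{cbv_pct = -(I - I0) / I0 * 100} and hyperemia is positive.  A
#' linear baseline trend (lamp drift) is removed when the baseline carries
#' one.
#'
#' @param trace intensity trace (arbitrary units).
#' @param baseline list from [establish_baseline()] (or a single number I0).
#' @param t time axis (s); needed when the baseline has a trend.
#' @return numeric CBV trace in % of baseline, hyperemia positive.
#' @export
to_cbv <- function(trace, baseline, t = NULL) {
  if (is.numeric(baseline)) baseline <- list(I0 = baseline, slope_per_s = 0, t_ref = 0)
  if (baseline$I0 <= 0) stop("baseline intensity must be positive")
  ref <- baseline$I0
  if (!is.null(baseline$slope_per_s) && baseline$slope_per_s != 0) {
    if (is.null(t)) stop("time axis required for a trended baseline")
    ref <- baseline$I0 + baseline$slope_per_s * (t - baseline$t_ref)
  }
  -(trace - ref) / ref * 100
}

#' Establish an individual ROI baseline
#'
#' Robust location/scale of the event-free signal: median and 1.4826 * MAD
#' over the masked window, plus (optionally) a robust linear trend fitted by
#' iterative outlier-trimmed least squares over the whole trace so that slow
#' lamp drift does not masquerade as hemodynamics.  If the mask covers less
#' than `min_window_s` the window is widened with a warning.
#'
#' @param trace intensity trace.
#' @param t time axis (s).
#' @param mask logical event-free mask (default: all samples).
#' @param detrend fit and carry a linear trend.
#' @param min_window_s minimum usable baseline window (s).
#' @return list: `I0`, `sigma`, `slope_per_s`, `t_ref`.
#' @export
establish_baseline <- function(trace, t, mask = NULL, detrend = TRUE,
                               min_window_s = 300) {
  if (is.null(mask)) mask <- rep(TRUE, length(trace))
  dt <- if (length(t) > 1) t[2] - t[1] else 1
  if (sum(mask) * dt < min_window_s) {
    warning("baseline window shorter than ", min_window_s,
            " s; widening to the whole trace")
    mask <- rep(TRUE, length(trace))
  }
  slope <- 0
  if (detrend) {
    # the trend is fitted on the whole trace (outlier-trimmed, so event
    # deflections do not tilt it); a short masked window alone cannot
    # constrain a slope extrapolated over hours
    keep <- rep(TRUE, length(trace))
    for (it in 1:3) {
      fit <- stats::lm.fit(cbind(1, t[keep]), trace[keep])
      res <- trace - (fit$coefficients[1] + fit$coefficients[2] * t)
      med <- stats::median(res[keep])
      s <- 1.4826 * stats::median(abs(res[keep] - med))
      keep <- abs(res - med) <= 3 * max(s, 1e-12)
    }
    slope <- unname(fit$coefficients[2])
  }
  x_d <- trace[mask] - slope * t[mask]
  I0 <- stats::median(x_d)
  sigma <- 1.4826 * stats::median(abs(x_d - I0))
  list(I0 = I0, sigma = sigma, slope_per_s = slope, t_ref = 0)
}

running_mean <- function(x, w) {
  if (w <= 1) return(x)
  cs <- c(0, cumsum(x))
  n <- length(x)
  lo <- pmax(0, seq_len(n) - ((w + 1) %/% 2))
  hi <- pmin(n, seq_len(n) + (w %/% 2))
  (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
}

#' Detect supra-threshold deviations in a CBV trace
#'
#' Maximal contiguous segments where the (lightly smoothed) |CBV| exceeds
#' `k_sigma` baseline SDs for at least `min_len_s`.  Segments containing two
#' peaks separated by a valley below half the smaller peak are split, and
#' adjacent opposite-polarity segments are kept separate.  Onsets are
#' interpolated leading half-maximum crossings.
#'
#' @param cbv CBV trace (% of baseline).
#' @param t time axis (s).
#' @param sigma robust baseline SD (% of baseline).
#' @param config an [optical_config()].
#' @return data.frame: onset_s, peak_s, peak_pct, polarity, start_s, end_s.
#' @export
detect_deviations <- function(cbv, t, sigma, config = optical_config()) {
  dt <- if (length(t) > 1) t[2] - t[1] else 1
  sm <- running_mean(cbv, max(1L, round(config$smooth_s / dt)))
  thr <- config$k_sigma * sigma
  empty <- data.frame(onset_s = numeric(), peak_s = numeric(),
                      peak_pct = numeric(), polarity = integer(),
                      start_s = numeric(), end_s = numeric())
  out <- list()
  for (pol in c(1, -1)) {
    above <- pol * sm >= thr
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (s in which(r$values)) {
      lo <- starts[s]; hi <- ends[s]
      if ((hi - lo + 1) * dt < config$min_len_s) next
      for (piece in split_segment(sm, lo, hi, pol)) {
        i_pk <- piece[1] - 1L + which.max(pol * sm[piece[1]:piece[2]])
        hm <- half_max_crossings(t, sm, i_pk,
                                 lo = max(1L, piece[1] - 1L),
                                 hi = min(length(t), piece[2] + 1L))
        onset <- if (is.na(hm$onset)) t[piece[1]] else hm$onset
        out[[length(out) + 1]] <- data.frame(
          onset_s = onset, peak_s = t[i_pk], peak_pct = cbv[i_pk],
          polarity = pol, start_s = t[piece[1]], end_s = t[piece[2]])
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$onset_s), ]
}

# Split a same-polarity segment at interior valleys that drop below half of
# the smaller neighbouring peak (two overlapping responses).
split_segment <- function(sm, lo, hi, pol) {
  y <- pol * sm[lo:hi]
  n <- length(y)
  if (n < 5) return(list(c(lo, hi)))
  pk <- which(diff(sign(diff(y))) < 0) + 1L
  pk <- pk[y[pk] > 0]
  if (length(pk) < 2) return(list(c(lo, hi)))
  cuts <- integer()
  for (k in seq_len(length(pk) - 1)) {
    iv <- pk[k]:pk[k + 1]
    v <- iv[which.min(y[iv])]
    if (y[v] < 0.5 * min(y[pk[k]], y[pk[k + 1]])) cuts <- c(cuts, v)
  }
  if (!length(cuts)) return(list(c(lo, hi)))
  bounds <- c(lo, lo - 1L + cuts, hi)
  lapply(seq_len(length(cuts) + 1),
         function(i) c(bounds[i] + (i > 1), bounds[i + 1]))
}

#' Detect SD events in an IOS trace set
#'
#' Per ROI: baseline, CBV conversion and deviation detection; deviation
#' segments on one ROI separated by less than `merge_gap_s` are consolidated
#' into one response candidate (an SD response is a *sequence* of deflections
#' at a ROI); candidates are then grouped across ROIs with the same
#' propagation-plausibility rule as ECoG, and events require at least two
#' ROIs.
#'
#' @param traceset an IOS [roi_traceset()].
#' @param config an [optical_config()].
#' @param qc optional [motion_qc()] result; flagged intervals are excluded.
#' @return list: `events`, `orphans`, `candidates`, `baselines` (per-ROI),
#'   `cbv` (matrix of CBV traces).
#' @export
detect_sd_ios <- function(traceset, config = optical_config(), qc = NULL) {
  stopifnot(traceset$modality == "IOS")
  t <- traceset_time(traceset)
  pre <- t < traceset$occlusion_time_s
  n_roi <- nrow(traceset$rois)
  baselines <- vector("list", n_roi)
  cbv <- matrix(0, length(t), n_roi, dimnames = list(NULL, traceset$rois$id))
  cands <- list()
  for (j in seq_len(n_roi)) {
    x <- traceset$traces[, j]
    mask <- if (any(pre)) pre else NULL
    bl <- establish_baseline(x, t, mask = mask, detrend = TRUE)
    bl$sigma_pct <- max(100 * bl$sigma / bl$I0,    # robust SD on the CBV-% scale
                        config$sigma_floor_pct)
    baselines[[j]] <- bl
    cbv[, j] <- to_cbv(x, bl, t)
    dev <- detect_deviations(cbv[, j], t, bl$sigma_pct, config)
    if (!is.null(qc) && nrow(dev)) {
      bad <- vapply(dev$onset_s, function(o)
        any(qc$exclude & o >= qc$start_s & o < qc$end_s), TRUE)
      dev <- dev[!bad, , drop = FALSE]
    }
    if (!nrow(dev)) next
    resp <- consolidate_responses(dev, config$merge_gap_s)
    resp$sensor_id <- traceset$rois$id[j]
    cands[[length(cands) + 1]] <- resp
  }
  cands <- if (length(cands)) do.call(rbind, cands) else
    data.frame(onset_s = numeric(), amplitude = numeric(), end_s = numeric(),
               sensor_id = character())
  grp <- group_events(cands, traceset$rois, config, modality = "IOS",
                      animal_id = traceset$animal_id)
  c(grp, list(candidates = cands, baselines = baselines, cbv = cbv))
}

# Merge deviation segments separated by small gaps into response candidates.
consolidate_responses <- function(dev, merge_gap_s) {
  dev <- dev[order(dev$start_s), , drop = FALSE]
  gaps <- if (nrow(dev) > 1)
    dev$start_s[-1] - cummax(dev$end_s)[-nrow(dev)] else numeric()
  grp <- cumsum(c(1, gaps > merge_gap_s))
  do.call(rbind, lapply(split(dev, grp), function(d)
    data.frame(onset_s = d$onset_s[1],
               amplitude = max(abs(d$peak_pct)),
               end_s = max(d$end_s))))
}

#' Decompose an SD response window into vasomotor components
#'
#' Orders the supra-threshold extrema of the CBV window and labels them with
#' the component taxonomy: the largest positive peak is peak hyperemia
#' (III); a positive peak before III and before any trough is the brief
#' initial hyperemia (I); a trough before III is the initial hypoperfusion
#' (II); positive peaks after III are late hyperemia (IV); a sustained
#' terminal negative plateau is post-SD oligemia (V).  Amplitudes and
#' half-maximum durations are then optionally refined by least-squares
#' fitting of a sum of log-normal pulses (the fit also powers the
#' re-synthesis residual check).
#'
#' @param cbv CBV trace (% of baseline), full trace.
#' @param t time axis (s).
#' @param window c(start_s, end_s) response window.
#' @param sigma robust baseline SD.
#' @param config an [optical_config()].
#' @return data.frame: kind, onset_s, peak_pct, duration_min (half-max),
#'   peak_s; zero rows when nothing exceeds threshold.
#' @export
decompose_components <- function(cbv, t, window, sigma,
                                 config = optical_config()) {
  sel <- which(t >= window[1] & t <= window[2])
  empty <- data.frame(kind = character(), onset_s = numeric(),
                      peak_pct = numeric(), duration_min = numeric(),
                      peak_s = numeric(), stringsAsFactors = FALSE)
  if (length(sel) < 5) return(empty)
  dt <- t[2] - t[1]
  y <- running_mean(cbv[sel], max(1L, round(config$smooth_s / dt)))
  tw <- t[sel]
  thr <- config$k_sigma * sigma
  pe <- prominent_extrema(y, prom = thr)
  # maxima must rise above +threshold, minima fall below -threshold: a
  # shallow positive valley between two hyperemic peaks is not a component
  keep <- (pe$type == 1L & y[pe$idx] >= thr) | (pe$type == -1L & y[pe$idx] <= -thr)
  ext <- pe$idx[keep]
  if (!length(ext)) return(empty)
  kinds <- character(length(ext))
  pos <- y[ext] > 0
  i3 <- which(pos)[which.max(y[ext[pos]])]
  if (!length(i3)) return(empty)
  kinds[i3] <- "III"
  seen_trough <- FALSE
  for (k in seq_along(ext)) {
    if (k == i3) break
    if (!pos[k]) { kinds[k] <- "II"; seen_trough <- TRUE }
    else if (!seen_trough) kinds[k] <- "I"
  }
  if (i3 < length(ext)) {
    for (k in (i3 + 1):length(ext)) {
      if (pos[k]) kinds[k] <- "IV"
      else if (terminal_plateau(y, ext[k], thr, dt)) kinds[k] <- "V"
    }
  }
  keep <- nzchar(kinds)
  ext <- ext[keep]; kinds <- kinds[keep]
  # collapse duplicate labels (ripples) onto the largest extremum of each kind
  # except IV, where the first late peak is the component
  sel_k <- vapply(unique(kinds), function(kk) {
    ii <- which(kinds == kk)
    if (kk == "IV") ii[1] else ii[which.max(abs(y[ext[ii]]))]
  }, 1L)
  ext <- ext[sort(sel_k)]; kinds <- kinds[sort(sel_k)]
  comp <- do.call(rbind, lapply(seq_along(ext), function(k) {
    lo <- if (k == 1) 1L else ext[k - 1]
    hi <- if (k == length(ext)) length(y) else ext[k + 1]
    hm <- half_max_crossings(tw, y, ext[k], lo = lo, hi = hi)
    dur <- hm$fwhm
    data.frame(kind = kinds[k], onset_s = hm$onset, peak_pct = y[ext[k]],
               duration_min = dur / 60, peak_s = tw[ext[k]],
               stringsAsFactors = FALSE)
  }))
  if (config$refine_fit) comp <- refine_components(comp, tw, cbv[sel])
  comp[order(comp$peak_s), ]
}

# Turning points with a minimum reversal (prominence): an extremum is only
# committed once the trace has reversed away from it by at least `prom`, so
# noise ripples riding on a component's flank never count as components.
prominent_extrema <- function(y, prom) {
  n <- length(y)
  empty <- list(idx = integer(), type = integer())
  if (n < 3) return(empty)
  idx <- integer(); type <- integer()   # type: +1 maximum, -1 minimum
  hi_i <- 1L; lo_i <- 1L
  dir <- 0L
  for (i in 2:n) {
    if (y[i] > y[hi_i]) hi_i <- i
    if (y[i] < y[lo_i]) lo_i <- i
    if (dir <= 0L && y[i] - y[lo_i] >= prom) {
      if (dir < 0L) { idx <- c(idx, lo_i); type <- c(type, -1L) }
      dir <- 1L
      hi_i <- i
    } else if (dir >= 0L && y[hi_i] - y[i] >= prom) {
      if (dir > 0L) { idx <- c(idx, hi_i); type <- c(type, 1L) }
      dir <- -1L
      lo_i <- i
    }
  }
  list(idx = idx, type = type)
}

terminal_plateau <- function(y, i, thr, dt, min_s = 300) {
  run <- which(y[i:length(y)] > -thr / 2)
  len <- if (length(run)) run[1] - 1 else length(y) - i + 1
  len * dt >= min_s
}

# Joint least-squares refinement: fit sum of log-normal pulses initialized
# from the rule-based estimates; fall back to the rules if the fit fails.
refine_components <- function(comp, tw, yraw) {
  n <- nrow(comp)
  if (!n) return(comp)
  par0 <- unlist(lapply(seq_len(n), function(k)
    c(comp$peak_pct[k],
      max(comp$duration_min[k] * 60, 10, na.rm = TRUE),
      comp$onset_s[k])))
  model <- function(p) {
    yy <- numeric(length(tw))
    for (k in seq_len(n)) {
      a <- p[3 * k - 2]; f <- p[3 * k - 1]; o <- p[3 * k]
      if (f <= 0) f <- 1
      yy <- yy + lognormal_pulse(tw, o, a, f)
    }
    yy
  }
  fit <- tryCatch({
    minpack.lm::nls.lm(par = par0,
                       fn = function(p) yraw - model(p),
                       control = minpack.lm::nls.lm.control(maxiter = 60))
  }, error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 9)) return(comp)
  p <- fit$par
  for (k in seq_len(n)) {
    a <- p[3 * k - 2]; f <- p[3 * k - 1]; o <- p[3 * k]
    # accept only sane refinements (same sign, comparable scale)
    if (is.finite(a) && is.finite(f) && f > 0 &&
        sign(a) == sign(comp$peak_pct[k]) &&
        abs(a) < 3 * abs(comp$peak_pct[k]) + 5) {
      comp$peak_pct[k] <- a
      comp$duration_min[k] <- f / 60
      comp$onset_s[k] <- o
    }
  }
  attr(comp, "fitted") <- model(p)
  comp
}

#' Classify the morphology of a component sequence
#'
#' Pure function of the ordered component kinds: \code{III} monophasic;
#' \code{III,IV} biphasic; \code{II,III,IV} triphasic; \code{I,II,III,IV}
#' tetraphasic; anything else "other".
#'
#' @param components data.frame from [decompose_components()] (or a character
#'   vector of kinds).
#' @return one of "monophasic", "biphasic", "triphasic", "tetraphasic",
#'   "other".
#' @export
classify_morphology <- function(components) {
  kinds <- if (is.character(components)) components else components$kind
  if (!length(kinds))
    stop("cannot classify an empty component list (sub-threshold response)")
  key <- paste(kinds, collapse = ",")
  switch(key,
         "III" = "monophasic",
         "III,IV" = "biphasic",
         "II,III,IV" = "triphasic",
         "I,II,III,IV" = "tetraphasic",
         "other")
}

#' Amplitude and duration of the hyperemic response
#'
#' Component III's peak amplitude (% of baseline) and half-maximum duration
#' (min).  Because decomposition measures each component on its own pulse,
#' a superimposed late hyperemia (IV) does not inflate III's duration.
#'
#' @param components data.frame from [decompose_components()].
#' @return named numeric c(amplitude_pct, duration_min); NAs when III is
#'   absent.
#' @export
hyperemia_metrics <- function(components) {
  i <- which(components$kind == "III")
  if (!length(i))
    return(c(amplitude_pct = NA_real_, duration_min = NA_real_))
  c(amplitude_pct = components$peak_pct[i[1]],
    duration_min = components$duration_min[i[1]])
}

#' Motion quality control
#'
#' Scores frame-to-frame global change against the typical within-series
#' variability and flags intervals whose score exceeds the threshold;
#' detection skips flagged intervals.  Works on an image-stack list of
#' frames or on a [roi_traceset()] (simultaneous jumps across ROIs).
#'
#' @param x list of frames (matrices) or an IOS [roi_traceset()].
#' @param threshold flag score (multiples of the median score).
#' @param sampling_interval_s frame interval when `x` is a list of frames.
#' @return data.frame: start_s, end_s, score, exclude.
#' @export
motion_qc <- function(x, threshold = 8, sampling_interval_s = 1) {
  if (inherits(x, "roi_traceset")) {
    d <- abs(apply(x$traces, 2, diff))
    score <- apply(sweep(d, 2, pmax(apply(d, 2, stats::median), 1e-12), "/"), 1,
                   stats::median)
    dt <- x$sampling_interval_s
  } else {
    diffs <- vapply(seq_len(length(x) - 1), function(i)
      mean(abs(x[[i + 1]] - x[[i]])), 0)
    score <- diffs / pmax(stats::median(diffs), 1e-12)
    dt <- sampling_interval_s
  }
  data.frame(start_s = (seq_along(score) - 1) * dt,
             end_s = seq_along(score) * dt,
             score = score, exclude = score > threshold)
}

#' Decompose and classify every ROI response of detected IOS events
#'
#' For each event and each ROI it reached, builds the response window (onset
#' minus 2 min to the next response on that ROI or `window_max_s`), runs
#' [decompose_components()], [classify_morphology()] and
#' [hyperemia_metrics()].
#'
#' @param detection result of [detect_sd_ios()].
#' @param traceset the IOS [roi_traceset()] that was analyzed.
#' @param config an [optical_config()].
#' @return data.frame: event_id, roi_id, onset_s, morphology, amplitude_pct,
#'   duration_min, n_components.
#' @export
classify_responses <- function(detection, traceset, config = optical_config()) {
  empty <- data.frame(animal_id = character(), event_id = character(),
                      roi_id = character(), hemisphere = character(),
                      onset_s = numeric(), morphology = character(),
                      amplitude_pct = numeric(), duration_min = numeric(),
                      n_components = integer(), stringsAsFactors = FALSE)
  if (!length(detection$events)) return(empty)
  t <- traceset_time(traceset)
  rows <- list()
  for (ev in detection$events) {
    for (roi in names(ev$onsets)) {
      j <- match(roi, traceset$rois$id)
      onset <- ev$onsets[[roi]]
      later <- detection$candidates$onset_s[
        detection$candidates$sensor_id == roi &
          detection$candidates$onset_s > onset + 60]
      w_end <- min(onset + config$window_max_s,
                   if (length(later)) min(later) - 30 else Inf,
                   max(t))
      comp <- decompose_components(detection$cbv[, j], t,
                                   c(onset - 120, w_end),
                                   detection$baselines[[j]]$sigma_pct, config)
      if (!nrow(comp)) next
      hm <- hyperemia_metrics(comp)
      rows[[length(rows) + 1]] <- data.frame(
        animal_id = as.character(ev$animal_id), event_id = ev$event_id,
        roi_id = roi, hemisphere = ev$hemisphere, onset_s = onset,
        morphology = classify_morphology(comp),
        amplitude_pct = hm[["amplitude_pct"]],
        duration_min = hm[["duration_min"]],
        n_components = nrow(comp), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}
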