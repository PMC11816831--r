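# LSCI perfusion analysis: monophasic CBF elevations, oxy/deoxyhemoglobin
# coupling, and chronologic matching against ECoG events.

#' Percent CBF elevation of a perfusion response
#'
#' 100 x (peak - baseline) / baseline, with the baseline taken as the median
#' of the baseline window; the response is flagged as returning to baseline
#' when the post-peak trace re-enters +-2 robust SDs of the baseline.
#'
#' @param cbf CBF trace (APU).
#' @param t time axis (s).
#' @param baseline_window logical mask or index vector of baseline samples
#'   (at least 3).
#' @param window optional c(start_s, end_s) restricting the peak search.
#' @return list: `elevation_pct`, `baseline`, `peak`, `peak_s`,
#'   `returns_to_baseline`.
#' @export
percent_elevation <- function(cbf, t, baseline_window, window = NULL) {
  base <- cbf[baseline_window]
  if (length(base) < 3) stop("at least 3 baseline samples required")
  b0 <- stats::median(base)
  if (b0 <= 0) stop("baseline CBF must be positive")
  sigma <- 1.4826 * stats::mad(base, center = b0)
  sel <- if (is.null(window)) seq_along(cbf) else which(t >= window[1] & t <= window[2])
  i_pk <- sel[which.max(cbf[sel])]
  peak <- cbf[i_pk]
  after <- cbf[t > t[i_pk]]
  returns <- length(after) > 0 && any(abs(after - b0) <= 2 * max(sigma, 1e-9))
  list(elevation_pct = 100 * (peak - b0) / b0, baseline = b0, peak = peak,
       peak_s = t[i_pk], returns_to_baseline = returns)
}

#' Detect SD events in an LSCI trace set
#'
#' Runs the shared deviation-and-grouping path on the CBF traces (0.2 Hz
#' sampling) and reports, per event, the ROI onset order as a propagation
#' direction together with per-ROI percent elevations.
#'
#' @param traceset an LSCI [roi_traceset()].
#' @param config an [optical_config()]; the default `min_len_s` works at the
#'   5 s sampling interval.
#' @return list: `events`, `orphans`, `responses` (per-ROI data.frame with
#'   elevations and onset order), `baselines`.
#' @export
detect_sd_lsci <- function(traceset, config = optical_config()) {
  stopifnot(traceset$modality == "LSCI")
  t <- traceset_time(traceset)
  pre <- t < traceset$occlusion_time_s
  n_roi <- nrow(traceset$rois)
  baselines <- vector("list", n_roi)
  cands <- list()
  pct <- matrix(0, length(t), n_roi, dimnames = list(NULL, traceset$rois$id))
  for (j in seq_len(n_roi)) {
    x <- traceset$traces$cbf[, j]
    bl <- establish_baseline(x, t, mask = if (any(pre)) pre else NULL,
                             detrend = TRUE)
    bl$sigma_pct <- max(100 * bl$sigma / bl$I0, config$sigma_floor_pct)
    baselines[[j]] <- bl
    # percent change, elevation positive (no sign inversion for perfusion)
    pct[, j] <- -to_cbv(x, bl, t)
    dev <- detect_deviations(pct[, j], t, bl$sigma_pct, config)
    if (!nrow(dev)) next
    resp <- consolidate_responses(dev, config$merge_gap_s)
    resp$sensor_id <- traceset$rois$id[j]
    cands[[length(cands) + 1]] <- resp
  }
  cands <- if (length(cands)) do.call(rbind, cands) else
    data.frame(onset_s = numeric(), amplitude = numeric(), end_s = numeric(),
               sensor_id = character())
  grp <- group_events(cands, traceset$rois, config, modality = "LSCI",
                      animal_id = traceset$animal_id)
  responses <- list()
  for (ev in grp$events) {
    ord <- names(sort(ev$onsets))
    for (roi in names(ev$onsets)) {
      j <- match(roi, traceset$rois$id)
      pe <- percent_elevation(traceset$traces$cbf[, j], t,
                              baseline_window = which(pre),
                              window = c(ev$onsets[[roi]] - 60,
                                         ev$onsets[[roi]] + 600))
      responses[[length(responses) + 1]] <- data.frame(
        event_id = ev$event_id, roi_id = roi, onset_s = ev$onsets[[roi]],
        elevation_pct = pe$elevation_pct,
        returns_to_baseline = pe$returns_to_baseline,
        propagation_order = paste(ord, collapse = ">"),
        pattern = if (pe$returns_to_baseline) "monophasic" else "other",
        stringsAsFactors = FALSE)
    }
  }
  responses <- if (length(responses)) do.call(rbind, responses) else
    data.frame(event_id = character(), roi_id = character(),
               onset_s = numeric(), elevation_pct = numeric(),
               returns_to_baseline = logical(), propagation_order = character(),
               pattern = character(), stringsAsFactors = FALSE)
  c(grp, list(responses = responses, baselines = baselines))
}

#' Oxy-/deoxyhemoglobin coupling of a perfusion response
#'
#' Signs of the OxyHb and deOxyHb peak deltas inside the event window, and
#' the deOxyHb onset lag relative to the CBF onset (both onsets as leading
#' half-extremum crossings).  When either delta stays within 3 robust
#' baseline SDs the result carries a low-confidence flag.
#'
#' @param traceset an LSCI [roi_traceset()].
#' @param roi_id ROI to analyze.
#' @param window c(start_s, end_s) event window.
#' @return list: `oxy_sign`, `deoxy_sign`, `deoxy_lag_s`, `low_confidence`.
#' @export
oxy_coupling <- function(traceset, roi_id, window) {
  stopifnot(traceset$modality == "LSCI")
  t <- traceset_time(traceset)
  j <- match(roi_id, traceset$rois$id)
  if (is.na(j)) stop("unknown ROI: ", roi_id)
  pre <- t < traceset$occlusion_time_s
  if (!any(pre)) pre <- t < window[1]
  sel <- t >= window[1] & t <= window[2]
  delta_sign <- function(x) {
    b <- stats::median(x[pre]); s <- 1.4826 * stats::mad(x[pre], center = b)
    d <- x[sel] - b
    i <- which.max(abs(d))
    list(sign = sign(d[i]), strong = abs(d[i]) > 3 * max(s, 1e-9),
         onset = {
       full <- x - b
       i_glob <- which(sel)[i]
       half_max_crossings(t, full, i_glob, lo = which(sel)[1],
                          hi = utils::tail(which(sel), 1))$onset
     })
  }
  cbf <- delta_sign(traceset$traces$cbf[, j])
  oxy <- delta_sign(traceset$traces$oxyhb[, j])
  dxy <- delta_sign(traceset$traces$deoxyhb[, j])
  list(oxy_sign = oxy$sign, deoxy_sign = dxy$sign,
       deoxy_lag_s = dxy$onset - cbf$onset,
       low_confidence = !(oxy$strong && dxy$strong))
}

#' Match events across modalities by onset proximity
#'
#' Greedy nearest-onset matching inside a +-window; each event is matched at
#' most once and the pair set is symmetric in the argument order.
#'
#' @param events_a,events_b lists of [sd_event()].
#' @param window_min matching half-window (min).
#' @return data.frame: id_a, id_b, onset_a_s, onset_b_s, lag_s.
#' @export
match_modalities <- function(events_a, events_b, window_min = 5) {
  empty <- data.frame(id_a = character(), id_b = character(),
                      onset_a_s = numeric(), onset_b_s = numeric(),
                      lag_s = numeric(), stringsAsFactors = FALSE)
  if (!length(events_a) || !length(events_b)) return(empty)
  on_a <- vapply(events_a, event_onset, 0)
  on_b <- vapply(events_b, event_onset, 0)
  pairs <- expand.grid(i = seq_along(on_a), j = seq_along(on_b))
  pairs$lag <- abs(on_a[pairs$i] - on_b[pairs$j])
  pairs <- pairs[pairs$lag <= window_min * 60, , drop = FALSE]
  pairs <- pairs[order(pairs$lag, pairs$i, pairs$j), , drop = FALSE]
  used_a <- logical(length(on_a)); used_b <- logical(length(on_b))
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    out[[length(out) + 1]] <- data.frame(
      id_a = as.character(events_a[[i]]$event_id),
      id_b = as.character(events_b[[j]]$event_id),
      onset_a_s = on_a[i], onset_b_s = on_b[j],
      lag_s = on_b[j] - on_a[i], stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}
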