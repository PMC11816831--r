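#' Multichannel DC-coupled ECoG recording
#'
#' Samples are millivolts; time runs in seconds from recording start; the
#' occlusion time is carried in the object so that event times can be
#' reported relative to occlusion (minutes post-occlusion) as is conventional.
#'
#' @param samples numeric matrix, one column per channel (mV).
#' @param channels data.frame `id`, `hemisphere`, `x_mm`, `y_mm` matching the
#'   columns of `samples`.
#' @param sampling_rate Hz (> 0; default 1000).
#' @param occlusion_time_s seconds from record start (must lie in the span).
#' @param animal_id optional label.
#' @return object of class `ts_recording`.
#' @export
ts_recording <- function(samples, channels, sampling_rate = 1000,
                         occlusion_time_s = 0, animal_id = NA_character_) {
  samples <- as.matrix(samples)
  check_sensor_table(channels, "channels")
  if (ncol(samples) != nrow(channels))
    stop("samples must have one column per channel")
  if (!all(is.finite(samples)))
    stop("non-finite samples in recording (first at index ",
         which(!is.finite(samples))[1], ")")
  stopifnot(sampling_rate > 0)
  span_s <- nrow(samples) / sampling_rate
  if (occlusion_time_s < 0 || occlusion_time_s > span_s)
    stop("occlusion_time_s outside the recording span")
  colnames(samples) <- channels$id
  structure(list(samples = samples, channels = channels,
                 sampling_rate = sampling_rate,
                 occlusion_time_s = occlusion_time_s,
                 animal_id = animal_id),
            class = "ts_recording")
}

#' @export
print.ts_recording <- function(x, ...) {
  cat(sprintf("ECoG recording '%s': %d channels x %.2f h @ %g Hz (occlusion at %.1f min)\n",
              x$animal_id, ncol(x$samples),
              nrow(x$samples) / x$sampling_rate / 3600, x$sampling_rate,
              x$occlusion_time_s / 60))
  invisible(x)
}

#' Time axis of a recording (s from start)
#' @param rec a [ts_recording()].
#' @return numeric vector of sample times.
#' @export
rec_time <- function(rec) {
  (seq_len(nrow(rec$samples)) - 1) / rec$sampling_rate
}

#' ROI trace set (IOS intensity or LSCI perfusion/oxygenation)
#'
#' IOS sets hold one intensity trace per ROI (arbitrary units, 1 s sampling
#' interval by default); LSCI sets hold CBF/OxyHb/deOxyHb triplets in
#' arbitrary perfusion units (APU, 5 s sampling interval).  CBF must be
#' non-negative and all traces uniformly sampled and equal length.
#'
#' @param traces for IOS: numeric matrix, one column per ROI. For LSCI: named
#'   list with matrices `cbf`, `oxyhb`, `deoxyhb`.
#' @param rois ROI table (`id`, `hemisphere`, `x_mm`, `y_mm`).
#' @param modality "IOS" or "LSCI".
#' @param sampling_interval_s seconds between samples (IOS 1, LSCI 5).
#' @param occlusion_time_s seconds from trace start.
#' @param animal_id optional label.
#' @return object of class `roi_traceset`.
#' @export
roi_traceset <- function(traces, rois, modality = c("IOS", "LSCI"),
                         sampling_interval_s = NULL, occlusion_time_s = 0,
                         animal_id = NA_character_) {
  modality <- match.arg(modality)
  check_sensor_table(rois, "rois")
  if (is.null(sampling_interval_s))
    sampling_interval_s <- if (modality == "IOS") 1 else 5
  stopifnot(sampling_interval_s > 0, occlusion_time_s >= 0)
  if (modality == "IOS") {
    traces <- as.matrix(traces)
    if (ncol(traces) != nrow(rois)) stop("one trace per ROI required")
    if (nrow(rois) < 2) stop("IOS analysis requires at least two ROIs")
    if (!all(is.finite(traces))) stop("non-finite samples in IOS traces")
    colnames(traces) <- rois$id
  } else {
    need <- c("cbf", "oxyhb", "deoxyhb")
    if (!all(need %in% names(traces)))
      stop("LSCI traces must contain matrices: ", paste(need, collapse = ", "))
    traces[need] <- lapply(traces[need], as.matrix)
    ns <- vapply(traces[need], nrow, 1L)
    if (length(unique(ns)) != 1) stop("LSCI trace lengths differ")
    for (nm in need) {
      if (ncol(traces[[nm]]) != nrow(rois)) stop("one ", nm, " trace per ROI required")
      if (!all(is.finite(traces[[nm]]))) stop("non-finite samples in ", nm)
      colnames(traces[[nm]]) <- rois$id
    }
    if (any(traces$cbf < 0)) stop("negative CBF values are not allowed")
  }
  structure(list(traces = traces, rois = rois, modality = modality,
                 sampling_interval_s = sampling_interval_s,
                 occlusion_time_s = occlusion_time_s, animal_id = animal_id),
            class = "roi_traceset")
}

#' @export
print.roi_traceset <- function(x, ...) {
  n <- if (x$modality == "IOS") nrow(x$traces) else nrow(x$traces$cbf)
  cat(sprintf("%s trace set '%s': %d ROIs x %.2f h @ %g s/sample\n",
              x$modality, x$animal_id, nrow(x$rois),
              n * x$sampling_interval_s / 3600, x$sampling_interval_s))
  invisible(x)
}

#' Time axis of a trace set (s from start)
#' @param ts a [roi_traceset()].
#' @return numeric vector of sample times.
#' @export
traceset_time <- function(ts) {
  n <- if (ts$modality == "IOS") nrow(ts$traces) else nrow(ts$traces$cbf)
  (seq_len(n) - 1) * ts$sampling_interval_s
}

#' One detected spreading depolarization event
#'
#' @param event_id integer or character id.
#' @param modality "ECoG", "IOS" or "LSCI".
#' @param onsets named numeric vector of per-sensor onset times (s from
#'   recording start); sensors without an onset are simply absent. At least
#'   two sensors are required (the detection rule).
#' @param hemisphere "left" or "right".
#' @param expansion_pct percentage of the denominator sensors reached.
#' @param amplitude summary amplitude (mV trough depth for ECoG, peak CBV %
#'   for IOS, CBF % elevation for LSCI).
#' @param flags character vector ("truncated", "low_confidence", ...).
#' @param animal_id optional label.
#' @return object of class `sd_event`.
#' @export
sd_event <- function(event_id, modality, onsets, hemisphere, expansion_pct,
                     amplitude = NA_real_, flags = character(), animal_id = NA_character_) {
  if (length(onsets) < 2)
    stop("an SD event requires onsets on at least two sensors")
  if (is.null(names(onsets)) || any(!nzchar(names(onsets))))
    stop("onsets must be named by sensor id")
  stopifnot(expansion_pct >= 0, expansion_pct <= 100)
  structure(list(event_id = event_id, modality = modality,
                 onsets = sort(onsets), hemisphere = hemisphere,
                 expansion_pct = expansion_pct, amplitude = amplitude,
                 flags = flags, animal_id = animal_id),
            class = "sd_event")
}

#' Event onset (s from recording start) = earliest sensor onset
#' @param event an [sd_event()].
#' @return numeric scalar.
#' @export
event_onset <- function(event) unname(min(event$onsets))

#' Flatten a list of events to a data.frame (one row per event)
#' @param events list of [sd_event()].
#' @return data.frame with event_id, animal_id, modality, hemisphere,
#'   onset_s, n_sensors, expansion_pct, amplitude, flags.
#' @export
events_table <- function(events) {
  if (!length(events))
    return(data.frame(event_id = character(), animal_id = character(),
                      modality = character(), hemisphere = character(),
                      onset_s = numeric(), n_sensors = integer(),
                      expansion_pct = numeric(), amplitude = numeric(),
                      flags = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(events, function(e)
    data.frame(event_id = as.character(e$event_id),
               animal_id = as.character(e$animal_id), modality = e$modality,
               hemisphere = e$hemisphere, onset_s = event_onset(e),
               n_sensors = length(e$onsets), expansion_pct = e$expansion_pct,
               amplitude = e$amplitude,
               flags = paste(e$flags, collapse = ";"),
               stringsAsFactors = FALSE)))
}
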