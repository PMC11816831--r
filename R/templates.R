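#' Vasomotor component specification
#'
#' One phase of the canonical SD hemodynamic response, in the CBV-positive
#' sign convention (positive peak = hyperemia).  Kinds follow the standard
#' component taxonomy: I brief initial hyperemia, II initial hypoperfusion,
#' III peak hyperemia, IV late hyperemia, V post-SD oligemia.
#'
#' @param kind one of "I","II","III","IV","V".
#' @param peak_amplitude_pct signed peak, % of baseline. I/III/IV must be
#'   positive, II/V negative.
#' @param fwhm_min full width at half maximum, minutes.
#' @param lag_min onset lag (leading half-max) after the local wavefront
#'   arrival, minutes.
#' @return a `component_spec` list.
#' @export
component_spec <- function(kind, peak_amplitude_pct, fwhm_min, lag_min = 0) {
  kind <- match.arg(kind, c("I", "II", "III", "IV", "V"))
  stopifnot(is.finite(peak_amplitude_pct), fwhm_min > 0, lag_min >= 0)
  pos <- kind %in% c("I", "III", "IV")
  if (pos && peak_amplitude_pct <= 0)
    stop(sprintf("component %s must have a positive peak amplitude", kind))
  if (!pos && peak_amplitude_pct >= 0)
    stop(sprintf("component %s must have a negative peak amplitude", kind))
  structure(list(kind = kind, peak_amplitude_pct = peak_amplitude_pct,
                 fwhm_min = fwhm_min, lag_min = lag_min),
            class = "component_spec")
}

#' Spreading depolarization event template
#'
#' Ground-truth description of one SD wave used by the injectors: a kinematic
#' wavefront expanding from `origin` at `speed_mm_per_min`, reaching the
#' `target_expansion` fraction of the hemisphere's sensors nearest the origin.
#' Per-sensor arrival time is exactly `onset_min + distance(origin, sensor) /
#' speed`, with `onset_min` counted from the occlusion in minutes.
#'
#' @param origin length-2 numeric, wave origin (mm).
#' @param onset_min wave start at the origin, minutes post-occlusion.
#' @param speed_mm_per_min propagation speed; must lie inside `speed_band`.
#' @param hemisphere "left" or "right".
#' @param dc_amplitude_mV depth of the negative slow potential change (mV).
#' @param dc_duration_s FWHM of the slow potential change (s).
#' @param depression_fraction residual 0.5-45 Hz envelope fraction during the
#'   depression of spontaneous activity (0-1).
#' @param depression_duration_min duration of the depression (min).
#' @param components list of [component_spec()] (the optical response); may be
#'   empty for ECoG-only templates.
#' @param target_expansion fraction (0,1] of the hemisphere's sensors reached.
#' @param cbf_amplitude_pct LSCI CBF peak elevation (% of baseline; 0 = none).
#' @param speed_band plausibility band for the speed (mm/min).
#' @return an `sd_template` list.
#' @export
sd_template <- function(origin, onset_min, speed_mm_per_min, hemisphere,
                        dc_amplitude_mV = 5, dc_duration_s = 90,
                        depression_fraction = 0.3, depression_duration_min = 5,
                        components = list(), target_expansion = 1,
                        cbf_amplitude_pct = 0, speed_band = c(1, 10)) {
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  stopifnot(length(origin) == 2, all(is.finite(origin)), is.finite(onset_min),
            dc_amplitude_mV > 0, dc_duration_s > 0,
            depression_fraction >= 0, depression_fraction <= 1,
            depression_duration_min > 0)
  if (speed_mm_per_min < speed_band[1] || speed_mm_per_min > speed_band[2])
    stop(sprintf("speed %.2f mm/min outside the plausibility band [%g, %g]",
                 speed_mm_per_min, speed_band[1], speed_band[2]))
  if (target_expansion <= 0 || target_expansion > 1)
    stop("target_expansion must be in (0, 1]")
  if (length(components)) {
    stopifnot(all(vapply(components, inherits, TRUE, "component_spec")))
    kinds <- vapply(components, `[[`, "", "kind")
    lags <- vapply(components, `[[`, 0, "lag_min")
    if (is.unsorted(match(kinds, c("I", "II", "III", "IV", "V"))))
      stop("components must be listed in I < II < III < IV < V order")
    if (is.unsorted(lags))
      stop("component onset lags must be non-decreasing in kind order")
  }
  structure(list(origin = as.numeric(origin), onset_min = onset_min,
                 speed_mm_per_min = speed_mm_per_min, hemisphere = hemisphere,
                 dc_amplitude_mV = dc_amplitude_mV, dc_duration_s = dc_duration_s,
                 depression_fraction = depression_fraction,
                 depression_duration_min = depression_duration_min,
                 components = components, target_expansion = target_expansion,
                 cbf_amplitude_pct = cbf_amplitude_pct),
            class = "sd_template")
}

#' Sensors reached by a template and their arrival times
#'
#' The wavefront reaches the `round(target_expansion * n)` sensors of the
#' template's hemisphere nearest the origin; per-sensor arrival is
#' `onset_min + distance / speed` (minutes post-occlusion), exactly.
#'
#' @param template an [sd_template()].
#' @param sensors sensor table (contacts or ROIs) with hemisphere + positions.
#' @return data.frame: id, distance_mm, arrival_min.
#' @export
template_arrivals <- function(template, sensors) {
  hemi <- sensors[sensors$hemisphere == template$hemisphere, , drop = FALSE]
  d <- sensor_distances(hemi, template$origin)
  n_reach <- max(1L, round(template$target_expansion * nrow(hemi)))
  keep <- order(d)[seq_len(n_reach)]
  out <- data.frame(id = hemi$id[keep], distance_mm = d[keep],
                    arrival_min = template$onset_min + d[keep] / template$speed_mm_per_min,
                    stringsAsFactors = FALSE)
  out[order(out$arrival_min), ]
}
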