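#' Component layout for a response morphology
#'
#' Builds the ordered component list for one of the four canonical SD
#' hemodynamic morphologies, around a peak-hyperemia (component III) pulse of
#' given amplitude and width.  Accessory components use fixed conventions:
#' I +4.5% / 0.8 min, II -5% / 1.2 min, IV +6% / 2.5 min placed after III's
#' main lobe so that III's half-maximum width stays measurable.
#'
#' @param morphology "monophasic", "biphasic", "triphasic" or "tetraphasic".
#' @param amp_iii_pct component III peak amplitude (% of baseline, > 0).
#' @param fwhm_iii_min component III FWHM (min).
#' @return list of [component_spec()].
#' @export
morphology_components <- function(morphology, amp_iii_pct = 18, fwhm_iii_min = 3) {
  morphology <- match.arg(morphology,
                          c("monophasic", "biphasic", "triphasic", "tetraphasic"))
  # III's leading tail grows with its width; the hypoperfusion-to-peak gap
  # scales accordingly so that II stays visible in the summed response
  g23 <- max(2.2, 0.4 * fwhm_iii_min + 0.7)
  iv_lag <- function(lag3) lag3 + 1.7 * fwhm_iii_min + 1.0
  switch(morphology,
    monophasic = list(component_spec("III", amp_iii_pct, fwhm_iii_min, 2.0)),
    biphasic = list(component_spec("III", amp_iii_pct, fwhm_iii_min, 2.0),
                    component_spec("IV", 6, 2.5, iv_lag(2.0))),
    triphasic = list(component_spec("II", -5, 1.2, 0.2),
                     component_spec("III", amp_iii_pct, fwhm_iii_min, 0.2 + g23),
                     component_spec("IV", 6, 2.5, iv_lag(0.2 + g23))),
    tetraphasic = list(component_spec("I", 4.5, 0.8, 0.0),
                       component_spec("II", -5, 1.2, 1.2),
                       component_spec("III", amp_iii_pct, fwhm_iii_min, 1.2 + g23),
                       component_spec("IV", 6, 2.5, iv_lag(1.2 + g23))))
}

# Component III parameters by the role an event plays at a given ROI: the
# per-ROI first and last responses carry the cohort's first/last hyperemia
# amplitude and duration (18.5% / 3.1 min and 16.3% / 8.3 min); intermediate
# and sole responses use neutral values.
role_iii_params <- function(role) {
  switch(role,
         first = c(amp = 18.5, fwhm = 3.1),
         last = c(amp = 16.3, fwhm = 8.3),
         c(amp = 17.4, fwhm = 3.0))
}

#' Ground-truth roster of a simulated cohort
#'
#' Builds the per-animal event roster for a preset.  The
#' \code{"paper_replication"} roster is a fixed (seed-independent) design
#' whose self-statistics reproduce a published swine venous-occlusion
#' cohort's printed Results by construction: 12 ECoG animals monitored 95.3 h
#' with 26 ECoG SDs (17 in hour 1, none in hours 4-6, mean per-animal
#' expansion 69.4%, mean time to first SD 49.3 min, per-animal incidence mean
#' ~0.3 SDs/h), 6 IOS animals (38.3 h, 16 SDs, 9 in hour 1, mean per-animal
#' expansion ~85.8%, first-SD mean 101 min, morphology mix 5/5/3/3
#' mono/bi/tri/tetraphasic = 31.25% monophasic at the ROI-response level),
#' first/last hyperemia 18.5%/16.3% and 3.1/8.3 min, and one LSCI animal with
#' a single SD at 9 min post-occlusion (ROI order 4->3->2->1, mean CBF
#' elevation 61.5%) seen in its ECoG at 12 min.  The seed only drives the
#' noise streams of the signal synthesis, never the roster.
#'
#' @param preset "paper_replication" or "unit_test".
#' @param seed integer master seed (stored; used by the signal synthesis).
#' @return object of class `sd_roster`.
#' @seealso [roster_stats()], [simulate_cohort()]
#' @export
build_roster <- function(preset = c("paper_replication", "unit_test"), seed = 1) {
  preset <- match.arg(preset)
  if (length(seed) != 1 || !is.finite(seed) || seed != round(seed))
    stop("seed must be a single integer")
  seed <- as.integer(seed)
  if (preset == "paper_replication") replication_roster(seed) else unit_test_roster(seed)
}

replication_roster <- function(seed) {
  layout <- default_layout()
  animals <- data.frame(
    animal_id = c(sprintf("a%02d", 1:13)),
    group = c(rep(2L, 6), 1L, 1L, 1L, 2L, 1L, 2L, 3L),
    ecog_hours = c(6.5, 4.0, 8.0, 8.3, 9.0, 9.5, 6.0, 6.8, 7.2, 10.5, 8.0, 11.5, 3.2),
    ios_hours = c(5.2, 3.0, 8.0, 6.3, 9.0, 6.8, 0, 0, 0, 0, 0, 0, 0),
    lsci_hours = c(rep(0, 12), 2.5),
    ecog_analyzed = c(rep(TRUE, 12), FALSE),
    ios_analyzed = c(rep(TRUE, 6), rep(FALSE, 7)),
    lsci_analyzed = c(rep(FALSE, 12), TRUE),
    stringsAsFactors = FALSE)

  # ECoG events: time_min = arrival at the first reached contact (min
  # post-occlusion); reached_n of the 5 ipsilateral contacts.
  ee <- function(animal, times, hemis, reached)
    data.frame(animal_id = animal, time_min = times, hemisphere = hemis,
               reached_n = reached, stringsAsFactors = FALSE)
  ecog_events <- rbind(
    ee("a01", c(10, 25, 50, 75, 130), c("left", "right", "left", "right", "left"),
       c(4, 3, 3, 3, 3)),
    ee("a02", c(12, 40, 150), c("right", "left", "right"), c(3, 3, 3)),
    ee("a03", c(8, 30, 52, 390), c("left", "right", "left", "right"), c(4, 4, 3, 3)),
    ee("a04", c(15, 42, 450), c("right", "left", "right"), c(3, 3, 3)),
    ee("a05", c(11, 38, 510), c("left", "right", "left"), c(3, 3, 3)),
    ee("a06", c(14, 45, 80), c("right", "left", "right"), c(3, 3, 3)),
    ee("a07", 9, "left", 4),
    ee("a08", 18, "right", 4),
    ee("a09", 16, "left", 4),
    ee("a10", c(380, 460), c("right", "left"), c(4, 4)),
    ee("a13", 12, "right", 4))
  n_e <- nrow(ecog_events)
  ecog_events$event_id <- sprintf("E%02d", seq_len(n_e))
  ecog_events$speed_mm_min <- rep(c(3.0, 2.8, 3.2), length.out = n_e)
  ecog_events$dc_amplitude_mV <- rep(c(5, 6.5, 4.5, 7), length.out = n_e)
  ecog_events$dc_duration_s <- rep(c(90, 80, 100), length.out = n_e)
  ecog_events$depression_fraction <- 0.3
  ecog_events$depression_duration_min <- 5

  # IOS events: time_min = arrival at the first reached ROI; reached_n of the
  # 6 ipsilateral ROIs; one morphology per event (the 5/5/3/3 mix).
  ie <- function(animal, times, hemis, reached, morph)
    data.frame(animal_id = animal, time_min = times, hemisphere = hemis,
               reached_n = reached, morphology = morph, stringsAsFactors = FALSE)
  ios_events <- rbind(
    ie("a01", c(35, 55), c("left", "right"), c(6, 6), c("monophasic", "triphasic")),
    ie("a02", c(36, 150), c("right", "left"), c(6, 5), c("tetraphasic", "monophasic")),
    ie("a03", c(40, 48, 56, 70, 130), c("left", "right", "left", "right", "left"),
       c(5, 5, 5, 5, 4),
       c("monophasic", "biphasic", "biphasic", "triphasic", "tetraphasic")),
    ie("a04", 55, "right", 6, "biphasic"),
    ie("a05", c(50, 57, 365, 430, 500), c("left", "right", "left", "right", "left"),
       c(5, 5, 5, 4, 4),
       c("monophasic", "biphasic", "tetraphasic", "monophasic", "triphasic")),
    ie("a06", 390, "right", 4, "biphasic"))
  ios_events$event_id <- sprintf("I%02d", seq_len(nrow(ios_events)))
  ios_events$speed_mm_min <- rep(c(3.0, 3.2, 2.8), length.out = nrow(ios_events))

  lsci_events <- data.frame(
    animal_id = "a13", event_id = "P01", time_min = 9, hemisphere = "right",
    reached_n = 4, speed_mm_min = 3.0, stringsAsFactors = FALSE)
  lsci_rois <- data.frame(roi_id = paste0("p", 1:4),
                          cbf_amp_pct = c(40, 52, 71, 83),
                          cbf_fwhm_min = 2.5, stringsAsFactors = FALSE)

  roster <- structure(list(
    preset = "paper_replication", seed = seed, layout = layout,
    fs = list(ecog_fs = 10, ios_dt = 1, lsci_dt = 5, baseline_min = 10),
    noise = default_noise(),
    animals = animals, ecog_events = ecog_events, ios_events = ios_events,
    lsci_events = lsci_events, lsci_rois = lsci_rois),
    class = "sd_roster")
  roster$ios_responses <- build_ios_responses(roster)
  roster
}

unit_test_roster <- function(seed) {
  layout <- default_layout()
  animals <- data.frame(
    animal_id = "u01", group = 2L, ecog_hours = 2, ios_hours = 2,
    lsci_hours = 0, ecog_analyzed = TRUE, ios_analyzed = TRUE,
    lsci_analyzed = FALSE, stringsAsFactors = FALSE)
  ecog_events <- data.frame(
    animal_id = "u01", time_min = c(15, 60), hemisphere = c("left", "right"),
    reached_n = c(4, 5), event_id = c("E01", "E02"), speed_mm_min = 3.0,
    dc_amplitude_mV = c(5, 6), dc_duration_s = 90, depression_fraction = 0.3,
    depression_duration_min = 5, stringsAsFactors = FALSE)
  ios_events <- data.frame(
    animal_id = "u01", time_min = c(15, 60), hemisphere = c("left", "right"),
    reached_n = c(5, 6), morphology = c("triphasic", "monophasic"),
    event_id = c("I01", "I02"), speed_mm_min = 3.0, stringsAsFactors = FALSE)
  roster <- structure(list(
    preset = "unit_test", seed = as.integer(seed), layout = layout,
    fs = list(ecog_fs = 10, ios_dt = 1, lsci_dt = 5, baseline_min = 10),
    noise = default_noise(),
    animals = animals, ecog_events = ecog_events, ios_events = ios_events,
    lsci_events = ecog_events[0, c("animal_id", "time_min", "hemisphere",
                                   "reached_n", "event_id", "speed_mm_min")],
    lsci_rois = data.frame(roi_id = character(), cbf_amp_pct = numeric(),
                           cbf_fwhm_min = numeric())),
    class = "sd_roster")
  roster$ios_responses <- build_ios_responses(roster)
  roster
}

#' Default noise model of the generator
#'
#' Pink (1/f) broadband noise at 0.05 mV RMS plus a slow instrumental drift
#' (<= 0.2 mV/min) for ECoG; white noise at 0.5% of baseline plus a linear
#' drift of 0.1%/h for optical (IOS and LSCI) traces.
#'
#' @return named list of noise parameters.
#' @export
default_noise <- function() {
  list(ecog_rms_mV = 0.05, ecog_drift_amp_mV = 1.5, ecog_drift_period_s = 7200,
       ecog_drift_slope_mV_min = 0.02,
       optical_sigma_pct = 0.5, optical_drift_pct_h = 0.1,
       lsci_sigma_pct = 0.5)
}

#' @export
print.sd_roster <- function(x, ...) {
  cat(sprintf("SD roster (preset '%s', seed %d): %d animals, %d ECoG / %d IOS / %d LSCI events\n",
              x$preset, x$seed, nrow(x$animals), nrow(x$ecog_events),
              nrow(x$ios_events), nrow(x$lsci_events)))
  invisible(x)
}

# Per-(event, ROI) ground truth for the IOS injections: arrival time, the
# role the event plays in that ROI's response sequence (first / middle /
# last / only) and the component-III parameters that role carries.
build_ios_responses <- function(roster) {
  ev <- roster$ios_events
  if (!nrow(ev)) {
    return(data.frame(animal_id = character(), event_id = character(),
                      roi_id = character(), arrival_min = numeric(),
                      role = character(), morphology = character(),
                      amp_iii_pct = numeric(), fwhm_iii_min = numeric()))
  }
  rows <- lapply(seq_len(nrow(ev)), function(i) {
    tpl <- ios_template(roster, i)
    arr <- template_arrivals(tpl, roster$layout$rois_ios)
    data.frame(animal_id = ev$animal_id[i], event_id = ev$event_id[i],
               roi_id = arr$id, arrival_min = arr$arrival_min,
               morphology = ev$morphology[i], stringsAsFactors = FALSE)
  })
  resp <- do.call(rbind, rows)
  resp$role <- "middle"
  for (an in unique(resp$animal_id)) {
    for (roi in unique(resp$roi_id[resp$animal_id == an])) {
      idx <- which(resp$animal_id == an & resp$roi_id == roi)
      idx <- idx[order(resp$arrival_min[idx])]
      if (length(idx) == 1) {
        resp$role[idx] <- "only"
      } else {
        resp$role[idx[1]] <- "first"
        resp$role[idx[length(idx)]] <- "last"
      }
    }
  }
  pars <- t(vapply(resp$role, role_iii_params, c(amp = 0, fwhm = 0)))
  resp$amp_iii_pct <- pars[, "amp"]
  resp$fwhm_iii_min <- pars[, "fwhm"]
  rownames(resp) <- NULL
  resp
}

# Template constructors from roster rows.  Roster times are arrivals at the
# nearest reached sensor, so the kinematic onset at the origin is backed out
# through the nearest-sensor distance.
ecog_template <- function(roster, i) {
  ev <- roster$ecog_events[i, ]
  hemi_contacts <- roster$layout$contacts[
    roster$layout$contacts$hemisphere == ev$hemisphere, ]
  d_min <- min(sensor_distances(hemi_contacts, roster$layout$occlusion_site))
  sd_template(origin = roster$layout$occlusion_site,
              onset_min = ev$time_min - d_min / ev$speed_mm_min,
              speed_mm_per_min = ev$speed_mm_min, hemisphere = ev$hemisphere,
              dc_amplitude_mV = ev$dc_amplitude_mV,
              dc_duration_s = ev$dc_duration_s,
              depression_fraction = ev$depression_fraction,
              depression_duration_min = ev$depression_duration_min,
              target_expansion = ev$reached_n / sum(
                roster$layout$contacts$hemisphere == ev$hemisphere))
}

ios_template <- function(roster, i) {
  ev <- roster$ios_events[i, ]
  hemi_rois <- roster$layout$rois_ios[
    roster$layout$rois_ios$hemisphere == ev$hemisphere, ]
  d_min <- min(sensor_distances(hemi_rois, roster$layout$occlusion_site))
  sd_template(origin = roster$layout$occlusion_site,
              onset_min = ev$time_min - d_min / ev$speed_mm_min,
              speed_mm_per_min = ev$speed_mm_min, hemisphere = ev$hemisphere,
              components = morphology_components(ev$morphology),
              target_expansion = ev$reached_n / nrow(hemi_rois))
}

lsci_template <- function(roster, i) {
  ev <- roster$lsci_events[i, ]
  rois <- roster$layout$rois_lsci
  d_min <- min(sensor_distances(rois, roster$layout$occlusion_site))
  sd_template(origin = roster$layout$occlusion_site,
              onset_min = ev$time_min - d_min / ev$speed_mm_min,
              speed_mm_per_min = ev$speed_mm_min, hemisphere = ev$hemisphere,
              target_expansion = 1, cbf_amplitude_pct = 1)
}

#' Self-statistics of a ground-truth roster
#'
#' Computes, on the roster itself (no signal synthesis, no detection), the
#' cohort statistics the replication preset encodes: modality event counts,
#' hourly profile, per-animal mean expansion, per-animal incidence, time to
#' first SD, first/last component-III amplitude and duration means, and the
#' ROI-response morphology prevalence.
#'
#' @param roster an [build_roster()] object.
#' @return named list of statistics.
#' @export
roster_stats <- function(roster) {
  an <- roster$animals
  ecog_ids <- an$animal_id[an$ecog_analyzed]
  ee <- roster$ecog_events[roster$ecog_events$animal_id %in% ecog_ids, ]
  ie <- roster$ios_events
  hours <- function(tm) floor(tm / 60) + 1
  per_animal <- function(ids, events, denom) {
    vapply(ids, function(a) {
      r <- events$reached_n[events$animal_id == a]
      if (!length(r)) NA_real_ else mean(100 * r / denom)
    }, 0)
  }
  exp_ecog <- per_animal(ecog_ids, ee, 5)
  ios_ids <- an$animal_id[an$ios_analyzed]
  exp_ios <- per_animal(ios_ids, ie, 6)
  rate <- vapply(ecog_ids, function(a)
    sum(ee$animal_id == a) / an$ecog_hours[an$animal_id == a], 0)
  first_sd <- vapply(ecog_ids, function(a) {
    tm <- ee$time_min[ee$animal_id == a]
    if (!length(tm)) NA_real_ else min(tm)
  }, 0)
  first_ios <- vapply(ios_ids, function(a)
    min(ie$time_min[ie$animal_id == a]), 0)
  hour1 <- vapply(ecog_ids, function(a)
    sum(ee$animal_id == a & hours(ee$time_min) == 1), 0)
  resp <- roster$ios_responses
  list(
    ecog_total = nrow(ee),
    ios_total = nrow(ie),
    hourly_ecog = tabulate(hours(ee$time_min), nbins = 9),
    hourly_ios = tabulate(hours(ie$time_min), nbins = 9),
    ecog_expansion_mean = mean(exp_ecog, na.rm = TRUE),
    ios_expansion_mean = mean(exp_ios, na.rm = TRUE),
    incidence_mean = mean(rate),
    hour1_mean = mean(hour1),
    first_sd_ecog_mean_min = mean(first_sd, na.rm = TRUE),
    first_sd_ios_mean_min = mean(first_ios),
    first_amp_mean = mean(resp$amp_iii_pct[resp$role == "first"]),
    last_amp_mean = mean(resp$amp_iii_pct[resp$role == "last"]),
    first_dur_mean = mean(resp$fwhm_iii_min[resp$role == "first"]),
    last_dur_mean = mean(resp$fwhm_iii_min[resp$role == "last"]),
    morphology_prevalence = {
      tab <- table(resp$morphology)
      100 * as.vector(tab) / sum(tab) -> p
      stats::setNames(p, names(tab))
    },
    lsci_cbf_mean = if (nrow(roster$lsci_rois)) mean(roster$lsci_rois$cbf_amp_pct) else NA_real_)
}
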