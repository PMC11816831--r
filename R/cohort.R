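# Cohort-level statistics: incidence, expansion, hourly profiles,
# first-versus-last response comparisons, and the exact rank tests.

#' Incidence rates and hourly event profile
#'
#' Per-animal rate = events / monitored hours; hourly bins are anchored at
#' the occlusion time.  The cohort rate is reported both as the mean of the
#' per-animal rates and pooled (total events / total hours).
#'
#' @param events data.frame with `animal_id` and `onset_min` (minutes
#'   post-occlusion), e.g. from [events_table()] after subtracting occlusion.
#' @param monitored data.frame with `animal_id` and `hours`.
#' @param n_hours number of hourly bins to report.
#' @return list: `per_animal` (animal_id, n, hours, rate, hour1, hour2),
#'   `hourly` (cohort counts per hour), `rate_mean`, `rate_sd`,
#'   `rate_pooled`, `hour1_mean`, `hour1_sd`.
#' @export
incidence <- function(events, monitored, n_hours = 9) {
  per <- lapply(seq_len(nrow(monitored)), function(i) {
    a <- monitored$animal_id[i]
    tm <- events$onset_min[events$animal_id == a]
    hrs <- monitored$hours[i]
    data.frame(animal_id = a, n = length(tm), hours = hrs,
               rate = length(tm) / hrs,
               hour1 = sum(tm >= 0 & tm < 60),
               hour2 = sum(tm >= 60 & tm < 120), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  hourly <- tabulate(pmin(floor(events$onset_min / 60) + 1, n_hours + 1),
                     nbins = n_hours + 1)[seq_len(n_hours)]
  list(per_animal = per, hourly = hourly,
       rate_mean = mean(per$rate), rate_sd = stats::sd(per$rate),
       rate_pooled = sum(per$n) / sum(per$hours),
       hour1_mean = mean(per$hour1), hour1_sd = stats::sd(per$hour1))
}

#' Per-animal mean expansion
#'
#' Mean of per-event expansion within each animal; the cohort mean is taken
#' over animals with at least one event.
#'
#' @param events data.frame with `animal_id` and `expansion_pct`.
#' @return list: `per_animal` (animal_id, mean_expansion), `mean`, `sd`.
#' @export
expansion_summary <- function(events) {
  if (!nrow(events))
    return(list(per_animal = data.frame(animal_id = character(),
                                        mean_expansion = numeric()),
                mean = NA_real_, sd = NA_real_))
  agg <- stats::aggregate(expansion_pct ~ animal_id, events, mean)
  names(agg)[2] <- "mean_expansion"
  list(per_animal = agg, mean = mean(agg$mean_expansion),
       sd = stats::sd(agg$mean_expansion))
}

#' First-versus-last SD response comparison
#'
#' For every ROI that observed at least two SDs within one hemisphere, takes
#' the first and last response's hyperemia amplitude and duration, reports
#' their means and compares the first and last sets with the Mann-Whitney U
#' test (two-sided).
#'
#' @param responses data.frame from [classify_responses()] (needs animal_id,
#'   roi_id, onset_s, amplitude_pct, duration_min).
#' @return list: `pairs` (per-ROI first/last values), means/SDs, and
#'   `amplitude_test` / `duration_test` ([mann_whitney_u()] results).
#' @export
first_last_comparison <- function(responses) {
  keyed <- split(responses, paste(responses$animal_id, responses$roi_id))
  rows <- list()
  for (grp in keyed) {
    grp <- grp[!is.na(grp$amplitude_pct), , drop = FALSE]
    if (nrow(grp) < 2) next
    grp <- grp[order(grp$onset_s), ]
    rows[[length(rows) + 1]] <- data.frame(
      animal_id = grp$animal_id[1], roi_id = grp$roi_id[1],
      first_amp = grp$amplitude_pct[1], last_amp = grp$amplitude_pct[nrow(grp)],
      first_dur = grp$duration_min[1], last_dur = grp$duration_min[nrow(grp)],
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(list(pairs = NULL, first_amp_mean = NA_real_, last_amp_mean = NA_real_,
                first_dur_mean = NA_real_, last_dur_mean = NA_real_,
                amplitude_test = NULL, duration_test = NULL))
  pairs <- do.call(rbind, rows)
  list(pairs = pairs,
       first_amp_mean = mean(pairs$first_amp), first_amp_sd = stats::sd(pairs$first_amp),
       last_amp_mean = mean(pairs$last_amp), last_amp_sd = stats::sd(pairs$last_amp),
       first_dur_mean = mean(pairs$first_dur), first_dur_sd = stats::sd(pairs$first_dur),
       last_dur_mean = mean(pairs$last_dur), last_dur_sd = stats::sd(pairs$last_dur),
       amplitude_test = mann_whitney_u(pairs$first_amp, pairs$last_amp),
       duration_test = mann_whitney_u(pairs$first_dur, pairs$last_dur))
}

rank_with_ties <- function(x) rank(x, ties.method = "average")

#' Wilcoxon signed-rank test (exact tie-aware enumeration)
#'
#' Two-sided test for paired samples.  Zero differences are dropped (all-zero
#' input returns p = 1 with a warning); ties in |differences| get average
#' ranks.  For n <= `exact_n` the null distribution is enumerated over all
#' 2^n sign assignments of the observed ranks; above that a tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param x,y paired samples (or `x` = differences when `y` is NULL).
#' @param exact_n enumeration limit.
#' @return list: `W` (positive-rank sum), `p`, `n` (non-zero pairs),
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_n = 15) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; p = 1")
    return(list(W = 0, p = 1, n = 0L, method = "degenerate"))
  }
  r <- rank_with_ties(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_n) {
    # all sign assignments of the observed ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wnull <- as.vector(signs %*% r)
    mu <- n * (n + 1) / 4
    p <- mean(abs(Wnull - mu) >= abs(W - mu) - 1e-9)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(W = W, p = min(1, p), n = as.integer(n), method = method)
}

#' Mann-Whitney U test (exact tie-aware enumeration)
#'
#' Two-sided test for two independent samples.  For n_A + n_B <=
#' `exact_n` the null distribution of U is enumerated over all
#' choose(n_A+n_B, n_A) group assignments of the pooled (tie-averaged)
#' ranks; above that a tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param a,b samples.
#' @param exact_n enumeration limit on the pooled size.
#' @return list: `U` (of sample `a`), `p`, `method`.
#' @export
mann_whitney_u <- function(a, b, exact_n = 12) {
  n_a <- length(a); n_b <- length(b)
  if (!n_a || !n_b) stop("both groups must be non-empty")
  pooled <- c(a, b)
  r <- rank_with_ties(pooled)
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  n <- n_a + n_b
  if (n <= exact_n) {
    combos <- utils::combn(n, n_a)
    Unull <- apply(combos, 2, function(idx) sum(r[idx])) - n_a * (n_a + 1) / 2
    mu <- n_a * n_b / 2
    p <- mean(abs(Unull - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    mu <- n_a * n_b / 2
    tie_tab <- table(r)
    sig2 <- n_a * n_b / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(U = U, p = min(1, p), method = method)
}

#' Cohort summary report
#'
#' Aggregates detected events and classified responses into the cohort
#' summary: per-animal counts, incidence, expansion, hourly profile,
#' first/last comparison, morphology prevalence, and the hour-1 versus
#' hour-2 rank tests.  Deterministic given its inputs; optionally written to
#' JSON and CSV.
#'
#' @param ecog_events data.frame (animal_id, onset_min, expansion_pct).
#' @param ios_events same schema for IOS events.
#' @param responses data.frame from [classify_responses()].
#' @param monitored_ecog,monitored_ios data.frames (animal_id, hours).
#' @param out_prefix optional path prefix for `<prefix>_summary.json` and
#'   `<prefix>_events.csv`.
#' @return list of class `cohort_summary`.
#' @export
summarize_cohort <- function(ecog_events, ios_events = NULL, responses = NULL,
                             monitored_ecog = NULL, monitored_ios = NULL,
                             out_prefix = NULL) {
  out <- list()
  if (!is.null(monitored_ecog)) {
    inc <- incidence(ecog_events, monitored_ecog)
    out$ecog <- list(total = nrow(ecog_events), incidence = inc,
                     expansion = expansion_summary(ecog_events),
                     hour_test = wilcoxon_signed_rank(inc$per_animal$hour1,
                                                      inc$per_animal$hour2))
  }
  if (!is.null(ios_events) && !is.null(monitored_ios)) {
    inc <- incidence(ios_events, monitored_ios)
    out$ios <- list(total = nrow(ios_events), incidence = inc,
                    expansion = expansion_summary(ios_events))
  }
  if (!is.null(responses) && nrow(responses)) {
    tab <- table(responses$morphology)
    out$morphology <- list(counts = as.list(tab),
                           prevalence_pct = as.list(100 * as.vector(tab) / sum(tab)))
    names(out$morphology$prevalence_pct) <- names(tab)
    out$first_last <- first_last_comparison(responses)
  }
  class(out) <- "cohort_summary"
  if (!is.null(out_prefix)) {
    ser <- out
    class(ser) <- NULL
    if (!is.null(ser$first_last$amplitude_test))
      ser$first_last$pairs <- as.list(ser$first_last$pairs)
    jsonlite::write_json(ser, paste0(out_prefix, "_summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    utils::write.csv(ecog_events, paste0(out_prefix, "_events.csv"),
                     row.names = FALSE)
  }
  out
}

#' Run the full detection pipeline on a simulated cohort
#'
#' Generates each animal of the roster in turn (memory-light streaming),
#' runs the ECoG, IOS and LSCI detectors with the given configurations, and
#' returns the detected events, classified responses and cohort summaries.
#' This is the one-call "replicate the study" entry point.
#'
#' @param preset preset name or an `sd_roster`.
#' @param seed master seed for the synthesis noise.
#' @param ecog_cfg,opt_cfg detector configurations.
#' @param what modalities to run.
#' @param noise_scale noise multiplier (0 = noiseless).
#' @return list: `roster`, `ecog_events`, `ios_events`, `responses`,
#'   `lsci`, `summary`.
#' @export
replicate_study <- function(preset = "paper_replication", seed = 1,
                            ecog_cfg = ecog_config(), opt_cfg = optical_config(),
                            what = c("ecog", "ios", "lsci"), noise_scale = 1) {
  roster <- if (inherits(preset, "sd_roster")) preset else build_roster(preset, seed)
  an <- roster$animals
  ecog_rows <- list(); ios_rows <- list(); resp_rows <- list()
  lsci_out <- NULL
  for (i in seq_len(nrow(an))) {
    a <- an$animal_id[i]
    need <- c(if ("ecog" %in% what && an$ecog_analyzed[i]) "ecog",
              if ("ios" %in% what && an$ios_analyzed[i]) "ios",
              if ("lsci" %in% what && an$lsci_analyzed[i]) "lsci")
    if (!length(need)) next
    bundle <- simulate_animal(roster, a, what = need, noise_scale = noise_scale)
    if (!is.null(bundle$ecog)) {
      det <- detect_sd_ecog(bundle$ecog, ecog_cfg)
      tab <- events_table(det$events)
      if (nrow(tab)) {
        tab$onset_min <- (tab$onset_s - bundle$ecog$occlusion_time_s) / 60
        ecog_rows[[length(ecog_rows) + 1]] <- tab
      }
    }
    if (!is.null(bundle$ios)) {
      det <- detect_sd_ios(bundle$ios, opt_cfg)
      tab <- events_table(det$events)
      if (nrow(tab)) {
        tab$onset_min <- (tab$onset_s - bundle$ios$occlusion_time_s) / 60
        ios_rows[[length(ios_rows) + 1]] <- tab
      }
      resp <- classify_responses(det, bundle$ios, opt_cfg)
      if (nrow(resp)) resp_rows[[length(resp_rows) + 1]] <- resp
    }
    if (!is.null(bundle$lsci)) {
      det <- detect_sd_lsci(bundle$lsci, opt_cfg)
      det$occlusion_time_s <- bundle$lsci$occlusion_time_s
      lsci_out <- det
    }
    rm(bundle)
  }
  bind <- function(rows, template) if (length(rows)) do.call(rbind, rows) else template
  ecog_events <- bind(ecog_rows, cbind(events_table(list()), onset_min = numeric()))
  ios_events <- bind(ios_rows, cbind(events_table(list()), onset_min = numeric()))
  responses <- bind(resp_rows, classify_responses(list(events = list()), NULL))
  summary <- summarize_cohort(
    ecog_events, ios_events, responses,
    monitored_ecog = data.frame(animal_id = an$animal_id[an$ecog_analyzed & an$group %in% c(1, 2)],
                                hours = an$ecog_hours[an$ecog_analyzed & an$group %in% c(1, 2)]),
    monitored_ios = data.frame(animal_id = an$animal_id[an$ios_analyzed],
                               hours = an$ios_hours[an$ios_analyzed]))
  list(roster = roster, ecog_events = ecog_events, ios_events = ios_events,
       responses = responses, lsci = lsci_out, summary = summary)
}
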