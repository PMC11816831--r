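# Readers/writers for the artifact file types.  Every on-disk recording is a
# payload file (EDF or CSV) plus a JSON sidecar ("<path>.json") carrying the
# metadata the payload format cannot: sensor geometry, sampling rate,
# occlusion time, schema version.

SCHEMA_VERSION <- "1.0"

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  meta$schema_version <- SCHEMA_VERSION
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

read_sidecar <- function(path, required) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing metadata sidecar: ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  miss <- setdiff(required, names(meta))
  if (length(miss))
    stop("metadata sidecar ", sp, " is missing keys: ", paste(miss, collapse = ", "))
  if (!identical(meta$schema_version, SCHEMA_VERSION))
    stop("schema version mismatch in ", sp, ": found '", meta$schema_version,
         "', expected '", SCHEMA_VERSION, "'")
  meta
}

#' Write / read an ECoG recording (EDF with CSV fallback)
#'
#' `.edf` paths use 16-bit EDF (samples reproduced to the declared LSB);
#' `.csv` paths store full-precision text and round-trip exactly.  Geometry,
#' sampling rate and occlusion time travel in a JSON sidecar next to the
#' payload.
#'
#' @param rec a [ts_recording()].
#' @param path output path ending in `.edf` or `.csv`.
#' @return `write_ecog`: the path, invisibly. `read_ecog`: a [ts_recording()].
#' @export
write_ecog <- function(rec, path) {
  meta <- list(kind = "ecog", sampling_rate = rec$sampling_rate,
               occlusion_time_s = rec$occlusion_time_s,
               animal_id = rec$animal_id, channels = rec$channels)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    edf_write(rec$samples, rec$channels$id, rec$sampling_rate, path)
  } else {
    utils::write.csv(as.data.frame(rec$samples), path, row.names = FALSE)
  }
  write_sidecar(path, meta)
  invisible(path)
}

#' @rdname write_ecog
#' @export
read_ecog <- function(path) {
  meta <- read_sidecar(path, c("kind", "sampling_rate", "occlusion_time_s", "channels"))
  if (!identical(meta$kind, "ecog")) stop("not an ECoG payload: ", path)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    edf <- edf_read(path)
    samples <- edf$samples
  } else {
    samples <- as.matrix(utils::read.csv(path, check.names = FALSE))
  }
  if (any(!is.finite(samples)))
    stop("non-finite samples in ", path, " (first at row ",
         which(!is.finite(samples))[1], ")")
  ts_recording(samples, as.data.frame(meta$channels),
               sampling_rate = meta$sampling_rate,
               occlusion_time_s = meta$occlusion_time_s,
               animal_id = meta$animal_id %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read ROI trace sets (IOS or LSCI) as CSV + JSON sidecar
#'
#' IOS files have one column per ROI; LSCI files have `<roi>_cbf`,
#' `<roi>_oxyhb`, `<roi>_deoxyhb` columns.  Round-trips are exact up to text
#' formatting (15 significant digits).
#'
#' @param ts a [roi_traceset()].
#' @param path output `.csv` path.
#' @return `write_traces`: the path, invisibly; `read_traces`: a
#'   [roi_traceset()].
#' @export
write_traces <- function(ts, path) {
  meta <- list(kind = "roi_traces", modality = ts$modality,
               sampling_interval_s = ts$sampling_interval_s,
               occlusion_time_s = ts$occlusion_time_s,
               animal_id = ts$animal_id, rois = ts$rois)
  if (ts$modality == "IOS") {
    df <- as.data.frame(ts$traces)
  } else {
    df <- data.frame(row.names = seq_len(nrow(ts$traces$cbf)))
    for (i in seq_len(nrow(ts$rois))) {
      id <- ts$rois$id[i]
      df[[paste0(id, "_cbf")]] <- ts$traces$cbf[, i]
      df[[paste0(id, "_oxyhb")]] <- ts$traces$oxyhb[, i]
      df[[paste0(id, "_deoxyhb")]] <- ts$traces$deoxyhb[, i]
    }
  }
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  write_sidecar(path, meta)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  meta <- read_sidecar(path, c("kind", "modality", "sampling_interval_s",
                               "occlusion_time_s", "rois"))
  if (!identical(meta$kind, "roi_traces")) stop("not a ROI trace payload: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (any(!vapply(df, function(x) all(is.finite(x)), TRUE)))
    stop("non-finite samples in ", path)
  rois <- as.data.frame(meta$rois)
  if (meta$modality == "IOS") {
    traces <- as.matrix(df[, rois$id, drop = FALSE])
  } else {
    get <- function(sfx) as.matrix(df[, paste0(rois$id, "_", sfx), drop = FALSE])
    traces <- list(cbf = get("cbf"), oxyhb = get("oxyhb"), deoxyhb = get("deoxyhb"))
  }
  roi_traceset(traces, rois, meta$modality,
               sampling_interval_s = meta$sampling_interval_s,
               occlusion_time_s = meta$occlusion_time_s,
               animal_id = meta$animal_id %||% NA_character_)
}

#' Write / read detected SD events as JSON
#'
#' Lossless round-trip of [sd_event()] lists (schema-versioned).
#'
#' @param events list of [sd_event()].
#' @param path `.json` path.
#' @return `write_events`: the path, invisibly; `read_events`: list of
#'   [sd_event()].
#' @export
write_events <- function(events, path) {
  payload <- list(schema_version = SCHEMA_VERSION,
                  events = lapply(events, function(e)
                    list(event_id = e$event_id, modality = e$modality,
                         animal_id = e$animal_id, hemisphere = e$hemisphere,
                         expansion_pct = e$expansion_pct, amplitude = e$amplitude,
                         flags = as.list(e$flags),
                         onsets = as.list(e$onsets))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$schema_version, SCHEMA_VERSION))
    stop("schema version mismatch in ", path)
  lapply(payload$events, function(e)
    sd_event(event_id = e$event_id, modality = e$modality,
             onsets = unlist(e$onsets), hemisphere = e$hemisphere,
             expansion_pct = e$expansion_pct,
             amplitude = e$amplitude %||% NA_real_,
             flags = as.character(unlist(e$flags)),
             animal_id = e$animal_id %||% NA_character_))
}

#' Write / read a ground-truth roster as JSON
#' @param roster an `sd_roster`.
#' @param path `.json` path.
#' @return `write_roster`: the path, invisibly; `read_roster`: an `sd_roster`.
#' @export
write_roster <- function(roster, path) {
  payload <- list(schema_version = SCHEMA_VERSION, preset = roster$preset,
                  seed = roster$seed, fs = roster$fs, noise = roster$noise,
                  animals = roster$animals, ecog_events = roster$ecog_events,
                  ios_events = roster$ios_events,
                  ios_responses = roster$ios_responses,
                  lsci_events = roster$lsci_events, lsci_rois = roster$lsci_rois,
                  layout = list(contacts = roster$layout$contacts,
                                rois_ios = roster$layout$rois_ios,
                                rois_lsci = roster$layout$rois_lsci,
                                occlusion_site = roster$layout$occlusion_site,
                                contact_spacing_mm = roster$layout$contact_spacing_mm))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_roster
#' @export
read_roster <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema_version, SCHEMA_VERSION))
    stop("schema version mismatch in ", path)
  layout <- cortical_layout(as.data.frame(p$layout$contacts),
                            as.data.frame(p$layout$rois_ios),
                            as.data.frame(p$layout$rois_lsci),
                            p$layout$occlusion_site, p$layout$contact_spacing_mm)
  structure(list(preset = p$preset, seed = as.integer(p$seed), layout = layout,
                 fs = p$fs, noise = p$noise, animals = as.data.frame(p$animals),
                 ecog_events = as.data.frame(p$ecog_events),
                 ios_events = as.data.frame(p$ios_events),
                 ios_responses = as.data.frame(p$ios_responses),
                 lsci_events = as.data.frame(p$lsci_events),
                 lsci_rois = as.data.frame(p$lsci_rois)),
            class = "sd_roster")
}

#' Extract ROI traces from an IOS image stack
#'
#' Reads a multi-page grayscale TIFF and averages each ROI's circular pixel
#' mask per frame, producing an IOS [roi_traceset()].
#'
#' @param path TIFF stack path.
#' @param rois data.frame with `id`, `hemisphere`, `x_mm`, `y_mm`, `row`,
#'   `col`, `radius_px` (pixel-space ROI definitions).
#' @param sampling_interval_s frame interval (s), default 1.
#' @param occlusion_time_s occlusion time (s from first frame).
#' @return an IOS [roi_traceset()].
#' @export
read_ios_stack <- function(path, rois, sampling_interval_s = 1,
                           occlusion_time_s = 0) {
  need <- c("id", "row", "col", "radius_px")
  miss <- setdiff(need, names(rois))
  if (length(miss)) stop("rois is missing columns: ", paste(miss, collapse = ", "))
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  dims <- dim(frames[[1]])
  masks <- lapply(seq_len(nrow(rois)), function(i) {
    r0 <- rois$row[i]; c0 <- rois$col[i]; rad <- rois$radius_px[i]
    rr <- pmax(1, floor(r0 - rad)):pmin(dims[1], ceiling(r0 + rad))
    cc <- pmax(1, floor(c0 - rad)):pmin(dims[2], ceiling(c0 + rad))
    if (r0 < 1 || r0 > dims[1] || c0 < 1 || c0 > dims[2])
      stop("ROI ", rois$id[i], " lies outside the image bounds")
    sel <- expand.grid(row = rr, col = cc)
    keep <- (sel$row - r0)^2 + (sel$col - c0)^2 <= rad^2
    as.matrix(sel[keep, ])
  })
  traces <- vapply(frames, function(fr) {
    vapply(masks, function(m) mean(fr[m]), 0)
  }, numeric(nrow(rois)))
  traces <- if (is.matrix(traces)) t(traces) else matrix(traces, ncol = nrow(rois))
  if (!all(c("hemisphere", "x_mm", "y_mm") %in% names(rois))) {
    rois$hemisphere <- rois$hemisphere %||% "left"
    rois$x_mm <- rois$x_mm %||% rois$col
    rois$y_mm <- rois$y_mm %||% rois$row
  }
  roi_traceset(traces, rois[, c("id", "hemisphere", "x_mm", "y_mm")], "IOS",
               sampling_interval_s = sampling_interval_s,
               occlusion_time_s = occlusion_time_s)
}

#' Write an IOS trace set as an 8-bit grayscale TIFF stack
#'
#' Renders each ROI as a uniform disk on a noisy background, one frame per
#' sample; intensities are rescaled to the 8-bit range.  Mainly a fixture
#' generator for testing [read_ios_stack()] and [motion_qc()].
#'
#' @param ts an IOS [roi_traceset()].
#' @param path output TIFF path.
#' @param px_per_mm pixel scale.
#' @param radius_px ROI disk radius in pixels.
#' @return data.frame of the pixel-space ROI definitions, invisibly.
#' @export
write_ios_stack <- function(ts, path, px_per_mm = 1.2, radius_px = 2) {
  stopifnot(ts$modality == "IOS")
  x <- ts$rois$x_mm; y <- ts$rois$y_mm
  col <- round((x - min(x)) * px_per_mm) + 6
  row <- round((y - min(y)) * px_per_mm) + 6
  nr <- max(row) + 6; nc <- max(col) + 6
  lo <- min(ts$traces); hi <- max(ts$traces)
  if (hi - lo < 1e-12) hi <- lo + 1
  scale8 <- function(v) (v - lo) / (hi - lo) * 0.8 + 0.1
  frames <- lapply(seq_len(nrow(ts$traces)), function(k) {
    fr <- matrix(0.5, nr, nc)
    for (i in seq_along(col)) {
      rr <- (row[i] - radius_px):(row[i] + radius_px)
      cc <- (col[i] - radius_px):(col[i] + radius_px)
      for (r in rr) for (cl in cc)
        if ((r - row[i])^2 + (cl - col[i])^2 <= radius_px^2)
          fr[r, cl] <- scale8(ts$traces[k, i])
    }
    fr
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 8)
  invisible(data.frame(id = ts$rois$id, hemisphere = ts$rois$hemisphere,
                       x_mm = x, y_mm = y, row = row, col = col,
                       radius_px = radius_px, stringsAsFactors = FALSE))
}
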