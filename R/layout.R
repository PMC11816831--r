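#' Craniotomy sensor layout
#'
#' Geometry of the recording field: two parasagittal 5-contact ECoG strips,
#' the IOS regions of interest (ROIs) placed symmetrically in the left and
#' right hemispheres, the four LSCI ROIs, and the occlusion site on the
#' midline.  Coordinates are millimetres in a right-handed craniotomy plane
#' with the midline at x = 0; y increases away from the occlusion site.
#'
#' @param contacts data.frame with columns `id`, `hemisphere`
#'   ("left"/"right"), `x_mm`, `y_mm`.
#' @param rois_ios data.frame with the same columns for IOS ROIs (10-15 ROIs,
#'   equal counts per hemisphere).
#' @param rois_lsci data.frame with the same columns for the 4 LSCI ROIs.
#' @param occlusion_site numeric length-2 midline point (x must be 0).
#' @param contact_spacing_mm inter-contact spacing along a strip (mm).
#' @return object of class `cortical_layout`.
#' @seealso [default_layout()]
#' @export
cortical_layout <- function(contacts, rois_ios, rois_lsci, occlusion_site = c(0, 0),
                            contact_spacing_mm = 10) {
  check_sensor_table(contacts, "contacts")
  check_sensor_table(rois_ios, "rois_ios")
  check_sensor_table(rois_lsci, "rois_lsci")
  stopifnot(length(occlusion_site) == 2, all(is.finite(occlusion_site)),
            contact_spacing_mm > 0)
  if (abs(occlusion_site[1]) > 1e-9)
    stop("occlusion_site must lie on the midline (x = 0)")
  n_l <- sum(rois_ios$hemisphere == "left")
  n_r <- sum(rois_ios$hemisphere == "right")
  if (n_l != n_r)
    stop("IOS ROI counts must be equal in the left and right hemispheres")
  structure(list(contacts = contacts, rois_ios = rois_ios,
                 rois_lsci = rois_lsci,
                 occlusion_site = as.numeric(occlusion_site),
                 contact_spacing_mm = contact_spacing_mm),
            class = "cortical_layout")
}

check_sensor_table <- function(df, what) {
  need <- c("id", "hemisphere", "x_mm", "y_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s is missing columns: %s", what, paste(miss, collapse = ", ")))
  if (!all(df$hemisphere %in% c("left", "right")))
    stop(sprintf("%s: hemisphere must be 'left' or 'right'", what))
  if (!all(is.finite(df$x_mm)) || !all(is.finite(df$y_mm)))
    stop(sprintf("%s: positions must be finite", what))
  if (anyDuplicated(df$id))
    stop(sprintf("%s: sensor ids must be unique", what))
  invisible(df)
}

#' Default craniotomy layout
#'
#' Two parasagittal 5-contact strips (10 mm spacing, x = +-6 mm), 12 IOS ROIs
#' (6 per hemisphere at x = +-4 mm), 4 LSCI ROIs on the right hemisphere, and
#' the occlusion site at the midline origin.  The source study reports sensor
#' counts but no coordinates; these positions are package conventions chosen
#' so that all within-hemisphere sensors lie at distinct distances from the
#' occlusion site (a propagating wavefront then produces strictly ordered
#' arrival times).
#'
#' @return a [cortical_layout()] object.
#' @export
default_layout <- function() {
  strip_y <- c(4, 14, 24, 34, 44)
  contacts <- data.frame(
    id = c(paste0("L", 1:5), paste0("R", 1:5)),
    hemisphere = rep(c("left", "right"), each = 5),
    x_mm = rep(c(-6, 6), each = 5),
    y_mm = c(strip_y, strip_y),
    stringsAsFactors = FALSE)
  roi_y <- c(6, 12, 18, 24, 30, 36)
  rois_ios <- data.frame(
    id = c(paste0("iL", 1:6), paste0("iR", 1:6)),
    hemisphere = rep(c("left", "right"), each = 6),
    x_mm = rep(c(-4, 4), each = 6),
    y_mm = c(roi_y, roi_y),
    stringsAsFactors = FALSE)
  # LSCI ROI 4 is parietal (closest to the occlusion site), ROI 1 frontal.
  rois_lsci <- data.frame(
    id = paste0("p", 1:4),
    hemisphere = "right",
    x_mm = 5,
    y_mm = c(23, 17, 11, 5),
    stringsAsFactors = FALSE)
  cortical_layout(contacts, rois_ios, rois_lsci)
}

#' Distances (mm) from a point to each sensor of a table
#' @noRd
sensor_distances <- function(sensors, origin) {
  sqrt((sensors$x_mm - origin[1])^2 + (sensors$y_mm - origin[2])^2)
}

#' @export
print.cortical_layout <- function(x, ...) {
  cat("Cortical layout:", nrow(x$contacts), "ECoG contacts,",
      nrow(x$rois_ios), "IOS ROIs,", nrow(x$rois_lsci), "LSCI ROIs\n")
  cat("Occlusion site: (", x$occlusion_site[1], ",", x$occlusion_site[2],
      ") mm; contact spacing", x$contact_spacing_mm, "mm\n")
  invisible(x)
}
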