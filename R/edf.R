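# Minimal EDF (European Data Format) codec: fixed-layout ASCII header plus
# little-endian int16 data records.  Covers uniform-rate multichannel
# recordings (one record per second); no EDF+ annotations.

pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

# numeric -> at most 8 ASCII characters (the EDF header field width).
# `round_down`/`round_up` guarantee the parsed value still brackets the data
# so no sample is clipped by header truncation.
fmt8 <- function(x, direction = 0) {
  vapply(x, function(v) {
    for (p in 6:1) {
      vv <- v
      for (try in 1:3) {
        s <- sprintf("%.*g", p, vv)
        val <- as.numeric(s)
        if (nchar(s) <= 8 &&
            (direction == 0 || (direction < 0 && val <= v) ||
             (direction > 0 && val >= v)))
          return(s)
        # nudge toward the required side and retry at this precision
        step <- max(abs(v), 1e-6) * 10^(-p)
        vv <- vv + direction * step * try
      }
    }
    sprintf("%.0e", v)
  }, "")
}

edf_write <- function(samples, channel_ids, fs, path, start = "01.01.00",
                      time = "00.00.00") {
  n_ch <- ncol(samples)
  spr <- as.integer(round(fs))            # samples per 1 s record
  if (abs(spr - fs) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  n_rec <- nrow(samples) %/% spr
  if (n_rec * spr != nrow(samples))
    stop("EDF writer requires a whole number of 1 s records")
  phys_min <- apply(samples, 2, min)
  phys_max <- apply(samples, 2, max)
  fix <- phys_max - phys_min < 1e-9       # flat channels
  phys_max[fix] <- phys_min[fix] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("sdwave", 80), pad("simulated", 80),
                pad(start, 8), pad(time, 8),
                pad(256 * (n_ch + 1), 8), pad("", 44), pad(n_rec, 8),
                pad("1", 8), pad(n_ch, 4))
  writeChar(hdr, con, eos = NULL)
  writeChar(paste0(vapply(channel_ids, pad, "", width = 16), collapse = ""), con, eos = NULL)
  writeChar(strrep(" ", 80 * n_ch), con, eos = NULL)               # transducer
  writeChar(paste0(rep(pad("mV", 8), n_ch), collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(fmt8(phys_min, -1), pad, "", width = 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(fmt8(phys_max, 1), pad, "", width = 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad("-32768", 8), n_ch), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad("32767", 8), n_ch), collapse = ""), con, eos = NULL)
  writeChar(strrep(" ", 80 * n_ch), con, eos = NULL)               # prefilter
  writeChar(paste0(rep(pad(spr, 8), n_ch), collapse = ""), con, eos = NULL)
  writeChar(strrep(" ", 32 * n_ch), con, eos = NULL)
  # re-read header physical bounds exactly as a reader will, so the
  # quantization is defined by the written text, not the double
  pm <- as.numeric(fmt8(phys_min, -1))
  px <- as.numeric(fmt8(phys_max, 1))
  scale <- (px - pm) / 65535
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * spr + 1):(r * spr)
    block <- vapply(seq_len(n_ch), function(j) {
      d <- round((samples[rows, j] - pm[j]) / scale[j]) - 32768
      as.integer(pmin(32767, pmax(-32768, d)))
    }, integer(spr))
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

edf_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(k) readChar(con, k, useBytes = TRUE)
  version <- rd(8); rd(80); rd(80); rd(8); rd(8)
  if (!grepl("^0", version)) stop("not an EDF file: ", path)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  if (is.na(n_rec) || is.na(n_ch)) stop("malformed EDF header: ", path)
  ids <- trimws(vapply(seq_len(n_ch), function(i) rd(16), ""))
  rd(80 * n_ch); rd(8 * n_ch)
  pm <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  px <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  dm <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  dx <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  rd(80 * n_ch)
  spr <- as.integer(vapply(seq_len(n_ch), function(i) rd(8), ""))
  rd(32 * n_ch)
  if (length(unique(spr)) != 1) stop("EDF reader supports uniform rates only")
  scale <- (px - pm) / (dx - dm)
  total <- n_rec * spr[1]
  out <- matrix(0, total, n_ch)
  raw <- readBin(con, integer(), n = n_rec * spr[1] * n_ch, size = 2,
                 endian = "little")
  arr <- array(raw, dim = c(spr[1], n_ch, n_rec))
  for (j in seq_len(n_ch))
    out[, j] <- as.vector(arr[, j, ]) * scale[j] + pm[j] - dm[j] * scale[j]
  colnames(out) <- ids
  list(samples = out, channel_ids = ids, fs = spr[1] / rec_dur,
       lsb = scale)
}
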