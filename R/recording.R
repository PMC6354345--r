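#' EEG recording container
#'
#' A continuous multichannel recording: a channels x samples matrix in
#' microvolts, a sampling rate and a marker table.
#'
#' @param samples Numeric matrix, channels x samples (microvolts). Row names,
#'   if any, are ignored in favour of `channel_labels`.
#' @param rate Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row of `samples`.
#' @param markers Marker data frame (see [schedule_session()]); may be empty.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, rate, channel_labels,
                          markers = new_markers(numeric(0), character(0), numeric(0))) {
  samples <- as.matrix(samples)
  if (length(channel_labels) != nrow(samples)) {
    stopf("channel_labels has %d entries but samples has %d rows",
          length(channel_labels), nrow(samples))
  }
  if (rate <= 0) stopf("rate must be > 0")
  dur <- ncol(samples) / rate
  if (nrow(markers) && any(markers$onset >= dur)) {
    stopf("marker onset beyond recording end (%.3f s)", dur)
  }
  rownames(samples) <- channel_labels
  structure(list(samples = samples, rate = rate,
                 channel_labels = as.character(channel_labels),
                 markers = markers),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: %d ch x %d samples (%.1f s @ %g Hz), %d marker(s)>\n",
              nrow(x$samples), ncol(x$samples), ncol(x$samples) / x$rate,
              x$rate, nrow(x$markers)))
  invisible(x)
}

rec_duration <- function(rec) ncol(rec$samples) / rec$rate

#' Write and read recordings
#'
#' Two on-disk formats are supported: `"internal"`, a compressed serialized
#' container (`.rds`) holding the full object, and `"edf"`, a 16-bit
#' European Data Format file. EDF quantizes samples to 16 bits over each
#' channel's physical range; markers do not fit EDF's signal records and are
#' written to a sidecar TSV (`<path>.markers.tsv`), which `read_recording()`
#' picks up automatically when present.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @param format `"internal"` or `"edf"`.
#' @return `read_recording()` returns an `eeg_recording`.
#' @export
write_recording <- function(rec, path, format = c("internal", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "eeg_recording"))
  if (format == "internal") {
    saveRDS(rec, path)
  } else {
    write_edf(rec, path)
    write_markers(rec$markers, paste0(path, ".markers.tsv"))
  }
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, format = c("internal", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "internal") {
    rec <- readRDS(path)
    if (!inherits(rec, "eeg_recording")) stopf("not an eeg_recording: %s", path)
    return(rec)
  }
  rec <- read_edf(path)
  sidecar <- paste0(path, ".markers.tsv")
  if (file.exists(sidecar)) rec$markers <- read_markers(sidecar)
  rec
}

# --- minimal 16-bit EDF writer/reader -------------------------------------
# One data record per second (last record padded), physical units uV.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  ns <- nrow(rec$samples)
  spr <- as.integer(round(rec$rate))   # samples per 1 s record
  if (abs(spr - rec$rate) > 1e-9) stopf("EDF writer requires an integer sampling rate")
  n_rec <- as.integer(ceiling(ncol(rec$samples) / spr))
  total <- n_rec * spr
  x <- rec$samples
  if (total > ncol(x)) x <- cbind(x, matrix(0, ns, total - ncol(x)))
  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Synthetic recording", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(format(1, nsmall = 0), 8),
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    list(rec$channel_labels, 16),
    list(rep("synthetic EEG", ns), 80),
    list(rep("uV", ns), 8),
    list(formatC(pmin_, digits = 6, format = "g"), 8),
    list(formatC(pmax_, digits = 6, format = "g"), 8),
    list(rep(dmin, ns), 8),
    list(rep(dmax, ns), 8),
    list(rep("", ns), 80),
    list(rep(spr, ns), 8),
    list(rep("", ns), 32))
  for (f in fields) writeChar(paste0(edf_pad(f[[1]], f[[2]]), collapse = ""),
                              con, eos = NULL)
  # physical -> digital, row-wise gains
  gain <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    dig <- round((x[, idx, drop = FALSE] - pmin_) * gain + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stopf("unreadable EDF header in %s", path)
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  if (length(unique(spr)) != 1L) stopf("EDF reader supports a single sampling rate")
  rate <- spr[1] / rec_dur
  x <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw_ <- readBin(con, "integer", n = ns * spr[1], size = 2,
                    endian = "little", signed = TRUE)
    if (length(raw_) < ns * spr[1]) stopf("truncated EDF file: %s", path)
    dig <- matrix(raw_, nrow = spr[1], ncol = ns)
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    x[, idx] <- t((dig - matrix(dmin, spr[1], ns, byrow = TRUE)) /
                    matrix((dmax - dmin) / (pmax_ - pmin_), spr[1], ns, byrow = TRUE) +
                    matrix(pmin_, spr[1], ns, byrow = TRUE))
  }
  eeg_recording(x, rate, labels)
}
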