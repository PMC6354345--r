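#' Epoch container
#'
#' Trials cut around markers: a channels x samples x trials array with the
#' epoch window, sampling rate, per-trial condition labels and provenance.
#'
#' Sample indexing convention, used everywhere in the package: 0-based,
#' half-open windows; an epoch at marker onset `o` with window
#' `(start, end)` covers sample indices
#' `floor((o + start) * rate) .. floor((o + start) * rate) + floor((end - start) * rate) - 1`.
#'
#' @param data Numeric array, channels x samples x trials (microvolts).
#' @param window Length-2 numeric, epoch window relative to marker onset (s).
#' @param rate Sampling rate (Hz).
#' @param labels Per-trial condition labels.
#' @param channel_labels Channel labels.
#' @param trial_meta Optional data frame of per-trial provenance (`run`,
#'   `trial`).
#' @return Object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, window, rate, labels, channel_labels,
                       trial_meta = NULL) {
  stopifnot(length(dim(data)) == 3L)
  if (dim(data)[3] != length(labels)) {
    stopf("labels has %d entries but data has %d trials",
          length(labels), dim(data)[3])
  }
  if (dim(data)[1] != length(channel_labels)) {
    stopf("channel_labels has %d entries but data has %d channels",
          length(channel_labels), dim(data)[1])
  }
  if (is.null(trial_meta)) {
    trial_meta <- data.frame(run = rep(NA_integer_, length(labels)),
                             trial = seq_along(labels))
  }
  structure(list(data = data, window = as.numeric(window), rate = rate,
                 labels = as.character(labels),
                 channel_labels = as.character(channel_labels),
                 trial_meta = trial_meta),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs: %d trial(s) x %d ch x %d samples, window [%g, %g] s @ %g Hz>\n",
              n_trials(x), dim(x$data)[1], dim(x$data)[2],
              x$window[1], x$window[2], x$rate))
  tab <- table(x$labels)
  if (length(tab)) cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname eeg_epochs
#' @param ep An `eeg_epochs` object.
#' @export
n_trials <- function(ep) dim(ep$data)[3]

# Time axis of an epoch set (offsets from marker onset, s).
epoch_times <- function(ep) {
  ep$window[1] + (seq_len(dim(ep$data)[2]) - 1) / ep$rate
}

#' Subset an epoch set
#'
#' @param ep An [eeg_epochs()] object.
#' @param trials Trial indices or logical mask.
#' @param channels Channel indices, logical mask, or labels.
#' @return The subset `eeg_epochs`.
#' @export
subset_epochs <- function(ep, trials = NULL, channels = NULL) {
  stopifnot(inherits(ep, "eeg_epochs"))
  ti <- if (is.null(trials)) seq_len(n_trials(ep)) else seq_len(n_trials(ep))[trials]
  ci <- seq_along(ep$channel_labels)
  if (!is.null(channels)) {
    ci <- if (is.character(channels)) match(channels, ep$channel_labels)
          else seq_along(ep$channel_labels)[channels]
    if (anyNA(ci)) stopf("unknown channel(s): %s",
                         paste(channels[is.na(ci)], collapse = ", "))
  }
  eeg_epochs(ep$data[ci, , ti, drop = FALSE], ep$window, ep$rate,
             ep$labels[ti], ep$channel_labels[ci],
             ep$trial_meta[ti, , drop = FALSE])
}

#' Common average reference
#'
#' Re-references a recording by subtracting, at every sample, the mean over
#' all channels.
#'
#' @param rec An [eeg_recording()].
#' @return The re-referenced recording; channel means are zero at every
#'   sample.
#' @export
car_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$samples) < 2L) stopf("CAR needs at least 2 channels")
  rec$samples <- sweep(rec$samples, 2, colMeans(rec$samples))
  rec
}

#' Remove per-channel DC level
#'
#' @param rec An [eeg_recording()].
#' @return Recording with the time-series mean of each channel subtracted.
#' @export
remove_dc <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  rec$samples <- rec$samples - rowMeans(rec$samples)
  rec
}

# Forward-backward IIR filtering with odd-symmetric edge padding
# (pad length 3 x filter length), applied to one signal vector.
filtfilt_pad <- function(b, a, x) {
  np <- 3L * max(length(a), length(b))
  n <- length(x)
  if (np >= n) np <- n - 1L
  front <- 2 * x[1] - x[seq(np + 1L, 2L)]
  back <- 2 * x[n] - x[seq(n - 1L, n - np)]
  y <- c(front, x, back)
  y <- signal::filter(b, a, y)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(np + 1L):(np + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass of the given per-pass order and applies
#' it forward and backward (zero phase; effective magnitude response is the
#' squared design response). DC level is removed first. The filter runs on
#' the continuous recording, before epoching, with odd-symmetric padding at
#' the recording edges.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Cutoff frequencies in Hz, `0 < low < high < rate/2`.
#' @param order Per-pass Butterworth design order.
#' @return The filtered recording.
#' @export
bandpass_zero_phase <- function(rec, low, high, order = 3L) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stopf("cutoffs must satisfy 0 < low < high < Nyquist (%g Hz)", nyq)
  }
  rec <- remove_dc(rec)
  bt <- signal::butter(order, c(low, high) / nyq, type = "pass")
  for (ch in seq_len(nrow(rec$samples))) {
    rec$samples[ch, ] <- filtfilt_pad(bt$b, bt$a, rec$samples[ch, ])
  }
  rec
}

#' Cut epochs around markers
#'
#' Extracts fixed-length windows around marker onsets. See [eeg_epochs()]
#' for the sample-indexing convention (0-based, half-open, floor of
#' time x rate).
#'
#' @param rec An [eeg_recording()] with markers.
#' @param window Length-2 numeric `(start, end)` in seconds relative to
#'   marker onset (start may be negative).
#' @param label_filter Labels to epoch around; by default all markers
#'   except the `start`/`instruction` bookkeeping periods.
#' @return An [eeg_epochs()].
#' @export
epoch_recording <- function(rec, window,
                            label_filter = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (window[1] >= window[2]) stopf("window must satisfy start < end")
  mk <- rec$markers
  if (is.null(label_filter)) {
    mk <- mk[!mk$label %in% c("start", "instruction"), , drop = FALSE]
  } else {
    mk <- mk[mk$label %in% label_filter, , drop = FALSE]
  }
  nsamp <- floor((window[2] - window[1]) * rec$rate)
  n_total <- ncol(rec$samples)
  starts <- floor((mk$onset + window[1]) * rec$rate)   # 0-based
  bad <- which(starts < 0 | starts + nsamp > n_total)
  if (length(bad)) {
    stopf("epoch window exceeds recording bounds for marker(s): %s",
          paste(sprintf("#%d (%s @ %.3f s)", bad, mk$label[bad], mk$onset[bad]),
                collapse = ", "))
  }
  dat <- array(0, dim = c(nrow(rec$samples), nsamp, nrow(mk)))
  for (i in seq_len(nrow(mk))) {
    dat[, , i] <- rec$samples[, (starts[i] + 1L):(starts[i] + nsamp), drop = FALSE]
  }
  meta <- data.frame(
    run = if ("run" %in% names(mk)) mk$run else rep(NA_integer_, nrow(mk)),
    trial = if ("trial" %in% names(mk)) mk$trial else seq_len(nrow(mk)))
  eeg_epochs(dat, window, rec$rate, mk$label, rec$channel_labels, meta)
}

#' Baseline correction
#'
#' Subtracts, per trial and channel, the mean over the pre-stimulus interval
#' `[window_start, 0)`.
#'
#' @param ep An [eeg_epochs()] whose window starts before 0.
#' @return Corrected `eeg_epochs`; pre-stimulus means are zero.
#' @export
baseline_correct <- function(ep) {
  stopifnot(inherits(ep, "eeg_epochs"))
  pre <- epoch_times(ep) < 0
  if (!any(pre)) stopf("no pre-stimulus samples: window starts at %g s", ep$window[1])
  base <- apply(ep$data[, pre, , drop = FALSE], c(1, 3), mean)
  ep$data <- ep$data - aperm(array(base, dim = c(dim(base), dim(ep$data)[2])),
                             c(1, 3, 2))
  ep
}

#' Amplitude-based artifact screening
#'
#' Removes trials whose absolute amplitude exceeds the threshold on any
#' channel or sample.
#'
#' @param ep An [eeg_epochs()].
#' @param threshold Rejection threshold in microvolts (default 75).
#' @return List with `epochs` (kept trials) and `report`, a list holding
#'   `kept_indices`, `rejected_indices`, `threshold` and the per-trial
#'   `peak_amplitude` (microvolts).
#' @export
reject_artifacts <- function(ep, threshold = 75) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (threshold <= 0) stopf("threshold must be > 0")
  peak <- apply(abs(ep$data), 3, max)
  rejected <- which(peak > threshold)
  kept <- setdiff(seq_len(n_trials(ep)), rejected)
  list(epochs = subset_epochs(ep, trials = kept),
       report = list(kept_indices = kept, rejected_indices = rejected,
                     threshold = threshold, peak_amplitude = peak))
}

#' Integer-factor downsampling
#'
#' Applies a zero-phase anti-alias low-pass (order-8 Chebyshev-I at 0.8x the
#' new Nyquist, 0.02 dB passband ripple — the forward-backward pass doubles
#' the ripple attenuation, so the effective in-band droop stays below 1
#' percent) and keeps every `rate / target_rate`-th sample.
#'
#' @param ep An [eeg_epochs()].
#' @param target_rate Target rate in Hz; must divide the current rate.
#' @return Downsampled `eeg_epochs`.
#' @export
downsample_epochs <- function(ep, target_rate) {
  stopifnot(inherits(ep, "eeg_epochs"))
  factor <- ep$rate / target_rate
  if (abs(factor - round(factor)) > 1e-9) {
    stopf("rate %g is not an integer multiple of target %g", ep$rate, target_rate)
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(ep)
  ch <- signal::cheby1(8, 0.02, 0.8 / factor)
  dm <- dim(ep$data)
  keep <- seq(1L, dm[2], by = factor)
  out <- array(0, dim = c(dm[1], length(keep), dm[3]))
  for (i in seq_len(dm[3])) {
    for (c_ in seq_len(dm[1])) {
      out[c_, , i] <- filtfilt_pad(ch$b, ch$a, ep$data[c_, , i])[keep]
    }
  }
  ep$data <- out
  ep$rate <- target_rate
  ep
}

#' Preprocessing pipelines
#'
#' The two fixed preprocessing chains used by the analyses, exposed as
#' configured, replayable objects:
#'
#' * `"oddball"`: CAR, DC removal, 1-30 Hz order-3 zero-phase Butterworth,
#'   epoch -100..1000 ms around stimuli, baseline correction, +-75 uV
#'   artifact screen.
#' * `"imagery"`: CAR, DC removal, 4-45 Hz order-5 zero-phase Butterworth,
#'   epoch 0..5 s from task onset, downsample to 512 Hz.
#'
#' Pipelines serialize to JSON ([pipeline_to_json()]) and replay
#' bit-identically: they contain no randomness.
#'
#' @param kind `"oddball"` or `"imagery"`.
#' @param low,high,order Band-pass parameters.
#' @param window Epoch window (s).
#' @param label_filter Marker labels to epoch (default: all stimulus/task
#'   markers).
#' @param baseline Apply baseline correction?
#' @param reject_threshold Artifact threshold in microvolts; `NULL` disables
#'   screening.
#' @param target_rate Downsampling target; `NULL` keeps the native rate.
#' @return Object of class `preproc_pipeline`.
#' @export
preproc_pipeline <- function(kind = c("oddball", "imagery"),
                             low = NULL, high = NULL, order = NULL,
                             window = NULL, label_filter = NULL,
                             baseline = NULL, reject_threshold = NULL,
                             target_rate = NULL) {
  kind <- match.arg(kind)
  def <- if (kind == "oddball") {
    list(low = 1, high = 30, order = 3L, window = c(-0.1, 1.0),
         baseline = TRUE, reject_threshold = 75, target_rate = NULL)
  } else {
    list(low = 4, high = 45, order = 5L, window = c(0, 5),
         baseline = FALSE, reject_threshold = NULL, target_rate = 512)
  }
  structure(list(
    kind = kind,
    low = low %||% def$low, high = high %||% def$high,
    order = order %||% def$order,
    window = window %||% def$window,
    label_filter = label_filter,
    baseline = baseline %||% def$baseline,
    reject_threshold = reject_threshold %||% def$reject_threshold,
    target_rate = target_rate %||% def$target_rate
  ), class = "preproc_pipeline")
}

#' @export
print.preproc_pipeline <- function(x, ...) {
  cat(sprintf("<preproc_pipeline '%s': CAR + DC + %g-%g Hz order-%d zero-phase, epoch [%g, %g] s%s%s%s>\n",
              x$kind, x$low, x$high, x$order, x$window[1], x$window[2],
              if (isTRUE(x$baseline)) ", baseline" else "",
              if (!is.null(x$reject_threshold)) sprintf(", reject +-%g uV", x$reject_threshold) else "",
              if (!is.null(x$target_rate)) sprintf(", downsample to %g Hz", x$target_rate) else ""))
  invisible(x)
}

#' Run a preprocessing pipeline
#'
#' @param rec An [eeg_recording()].
#' @param pipeline A [preproc_pipeline()].
#' @return List with `epochs` (an [eeg_epochs()]) and `rejection` (the
#'   screening report, or `NULL` when screening is disabled).
#' @export
apply_preproc <- function(rec, pipeline) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(pipeline, "preproc_pipeline"))
  rec <- car_reference(rec)
  rec <- bandpass_zero_phase(rec, pipeline$low, pipeline$high, pipeline$order)
  ep <- epoch_recording(rec, pipeline$window, pipeline$label_filter)
  if (isTRUE(pipeline$baseline)) ep <- baseline_correct(ep)
  rejection <- NULL
  if (!is.null(pipeline$reject_threshold)) {
    res <- reject_artifacts(ep, pipeline$reject_threshold)
    ep <- res$epochs
    rejection <- res$report
  }
  if (!is.null(pipeline$target_rate)) ep <- downsample_epochs(ep, pipeline$target_rate)
  list(epochs = ep, rejection = rejection)
}

#' @rdname preproc_pipeline
#' @param pipeline A `preproc_pipeline`.
#' @param path Optional output file.
#' @param json JSON string or file path.
#' @export
pipeline_to_json <- function(pipeline, path = NULL) {
  js <- jsonlite::toJSON(unclass(pipeline), auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' @rdname preproc_pipeline
#' @export
pipeline_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- paste(readLines(json), collapse = "\n")
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  do.call(preproc_pipeline, obj)
}
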