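#' Synthetic recording specification
#'
#' Parameters of the synthetic-EEG generator: a seeded 1/f background per
#' channel, Gaussian-pulse ERP components tied to stimulus conditions, and
#' band-power modulations (ERD/ERS signatures) tied to task conditions.
#'
#' @param n_channels Number of channels.
#' @param channel_labels 10-20 labels, one per channel.
#' @param rate Sampling rate in Hz.
#' @param noise_exponent Spectral slope of the background: power ~ 1/f^a.
#' @param noise_rms Background RMS amplitude per channel, microvolts.
#' @param erp_components List of [erp_component()] entries.
#' @param erds_signatures List of [erds_signature()] entries.
#' @param session_drift Non-negative scalar; when positive, recorded samples
#'   are mixed by `W = I + drift * G` with `G` a seeded random symmetric
#'   matrix of unit Frobenius norm, so trial covariances undergo the
#'   congruence transform `W P W'`. Emulates between-session electrode and
#'   source drift.
#' @param seed Integer seed; all noise, rhythms and the drift matrix derive
#'   from it.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(n_channels = 19L,
                       channel_labels = montage_1020(),
                       rate = 2048,
                       noise_exponent = 1,
                       noise_rms = 10,
                       erp_components = list(),
                       erds_signatures = list(),
                       session_drift = 0,
                       seed = 1L) {
  if (length(channel_labels) != n_channels) {
    stopf("need %d channel labels, got %d", n_channels, length(channel_labels))
  }
  if (rate <= 0) stopf("rate must be > 0")
  if (session_drift < 0) stopf("session_drift must be >= 0")
  for (cmp in erp_components) {
    if (!inherits(cmp, "erp_component")) stopf("erp_components must be erp_component objects")
    if (cmp$width <= 0) stopf("erp component width must be > 0")
  }
  for (sg in erds_signatures) {
    if (!inherits(sg, "erds_signature")) stopf("erds_signatures must be erds_signature objects")
    if (sg$modulation <= -1) stopf("modulation must be > -1 (power cannot go negative)")
  }
  structure(list(
    n_channels = as.integer(n_channels),
    channel_labels = as.character(channel_labels),
    rate = rate,
    noise_exponent = noise_exponent,
    noise_rms = noise_rms,
    erp_components = erp_components,
    erds_signatures = erds_signatures,
    session_drift = session_drift,
    seed = as.integer(seed)
  ), class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf("<synth_spec: %d ch @ %g Hz, 1/f^%g noise %g uV RMS, %d ERP comp., %d ERD/ERS sig., drift %g>\n",
              x$n_channels, x$rate, x$noise_exponent, x$noise_rms,
              length(x$erp_components), length(x$erds_signatures),
              x$session_drift))
  invisible(x)
}

#' ERP component definition
#'
#' A Gaussian-windowed deflection added to the background whenever a marker
#' of `condition` occurs: `amplitude * exp(-(t - onset - latency)^2 / (2 width^2))`
#' on the listed channels (scaled by `weights`).
#'
#' @param condition Condition label the component is locked to.
#' @param latency Peak latency after marker onset, seconds.
#' @param width Gaussian standard deviation, seconds.
#' @param amplitude Peak amplitude, microvolts (negative for MMN-like
#'   deflections).
#' @param channels Channel labels carrying the component.
#' @param weights Per-channel scaling, recycled; default 1 on every listed
#'   channel.
#' @return Object of class `erp_component`.
#' @export
erp_component <- function(condition, latency, width, amplitude, channels,
                          weights = 1) {
  structure(list(condition = condition, latency = latency, width = width,
                 amplitude = amplitude, channels = as.character(channels),
                 weights = rep_len(weights, length(channels))),
            class = "erp_component")
}

#' ERD/ERS signature definition
#'
#' A band-power modulation locked to task markers of `condition`: within the
#' marker window, the in-band component of the listed channels is scaled so
#' that its power is multiplied by `1 + modulation` (negative modulation =
#' event-related desynchronization, positive = synchronization).
#'
#' `rhythm_gain` raises the resting in-band power above the 1/f floor by
#' that multiple at all times, emulating an ongoing rhythm (e.g. the
#' sensorimotor rhythm) that the task then modulates; the task-to-rest power
#' ratio remains exactly `1 + modulation`.
#'
#' @param condition Task label.
#' @param band Length-2 numeric, band edges in Hz.
#' @param channels Channel labels carrying the modulation.
#' @param modulation Fractional power change, > -1.
#' @param rhythm_gain Non-negative resting rhythm power, as a multiple of
#'   the floor's in-band power.
#' @return Object of class `erds_signature`.
#' @export
erds_signature <- function(condition, band, channels, modulation,
                           rhythm_gain = 1) {
  if (length(band) != 2L || band[1] >= band[2]) stopf("band must be (low, high) Hz")
  structure(list(condition = condition, band = as.numeric(band),
                 channels = as.character(channels), modulation = modulation,
                 rhythm_gain = rhythm_gain),
            class = "erds_signature")
}

# 1/f^a noise via frequency-domain shaping of white Gaussian noise,
# normalized to the requested RMS. DC is zeroed. The FFT length is padded
# to a 2-3-5-smooth size (mixed-radix FFTs are quadratic at large prime
# lengths) and the result truncated.
pink_noise <- function(n, rate, exponent, rms) {
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(m)
  if (exponent == 0) return(w[seq_len(n)] * rms / stats::sd(w[seq_len(n)]))
  spec <- stats::fft(w)
  f <- c(0, seq_len(m - 1)) / m * rate
  f <- pmin(f, rate - f)                      # two-sided frequency axis
  shape <- c(0, f[-1]^(-exponent / 2))
  x <- Re(stats::fft(spec * shape, inverse = TRUE))[seq_len(n)] / m
  x * rms / stats::sd(x)
}

# Split a signal into its [low, high] Hz component and the remainder using
# an ideal FFT-domain mask (zero-padded to a 2-3-5-smooth length). The
# decomposition x = band + rest is exact by construction.
band_split <- function(x, rate, band) {
  n <- length(x)
  m <- stats::nextn(n, c(2, 3, 5))
  spec <- stats::fft(c(x, rep(0, m - n)))
  f <- c(0, seq_len(m - 1)) / m * rate
  f <- pmin(f, rate - f)
  mask <- f >= band[1] & f <= band[2]
  inband <- Re(stats::fft(spec * mask, inverse = TRUE))[seq_len(n)] / m
  list(band = inband, rest = x - inband)
}

#' Generate a synthetic EEG recording
#'
#' Renders a marker schedule into a continuous multichannel recording:
#' independent seeded 1/f background per channel, plus the ERP components
#' and ERD/ERS band modulations configured in the [synth_spec()] for the
#' marker conditions present. Markers are embedded in the result.
#'
#' Condition labels that have neither an ERP component nor an ERD/ERS
#' signature are passed through as plain background; labels outside
#' `quiet_labels` trigger a warning so misspelled conditions surface.
#'
#' @param markers Marker data frame, sorted by onset.
#' @param spec A [synth_spec()].
#' @param duration Recording length in seconds; default covers all markers
#'   plus a 2 s tail.
#' @param quiet_labels Labels expected to carry no signal (no warning).
#' @return An [eeg_recording()].
#' @export
synth_recording <- function(markers, spec,
                            duration = NULL,
                            quiet_labels = c("start", "instruction", "noise",
                                             "beep_high", "beep_low")) {
  stopifnot(inherits(spec, "synth_spec"))
  if (is.unsorted(markers$onset)) stopf("markers must be sorted by onset")
  if (is.null(duration)) duration <- schedule_duration(markers)
  n <- floor(duration * spec$rate)
  if (nrow(markers) && any(markers$onset + markers$duration > duration)) {
    stopf("marker extends beyond requested duration (%.3f s)", duration)
  }
  comp_conds <- vapply(spec$erp_components, `[[`, "", "condition")
  sig_conds <- vapply(spec$erds_signatures, `[[`, "", "condition")
  unknown <- setdiff(unique(markers$label), c(comp_conds, sig_conds, quiet_labels))
  if (length(unknown)) {
    warnf("marker condition(s) with no configured signal: %s",
          paste(unknown, collapse = ", "))
  }

  t_axis <- (seq_len(n) - 1) / spec$rate
  x <- matrix(0, spec$n_channels, n)
  for (ch in seq_len(spec$n_channels)) {
    x[ch, ] <- with_rng(derive_seed(spec$seed, paste0("noise_ch", ch)),
                        pink_noise(n, spec$rate, spec$noise_exponent,
                                   spec$noise_rms))
  }
  rownames(x) <- spec$channel_labels

  # ERD/ERS: group signatures by (channel, band); split once per group and
  # apply a time-varying gain to the in-band component.
  if (length(spec$erds_signatures)) {
    key <- function(ch, band) paste(ch, band[1], band[2], sep = "|")
    groups <- list()
    for (sg in spec$erds_signatures) {
      for (ch in sg$channels) {
        k <- key(ch, sg$band)
        groups[[k]] <- c(groups[[k]], list(sg))
      }
    }
    for (k in names(groups)) {
      sgs <- groups[[k]]
      ch <- strsplit(k, "|", fixed = TRUE)[[1]][1]
      if (!ch %in% spec$channel_labels) {
        warnf("ERD/ERS signature channel '%s' not in montage; skipped", ch)
        next
      }
      band <- sgs[[1]]$band
      rg <- vapply(sgs, `[[`, 0, "rhythm_gain")
      if (length(unique(rg)) > 1L) {
        warnf("differing rhythm_gain for %s; using the first", k)
      }
      parts <- band_split(x[ch, ], spec$rate, band)
      gain <- rep(sqrt(1 + rg[1]), n)
      for (sg in sgs) {
        m <- markers[markers$label == sg$condition, , drop = FALSE]
        for (i in seq_len(nrow(m))) {
          i0 <- floor(m$onset[i] * spec$rate) + 1L
          i1 <- min(n, floor((m$onset[i] + m$duration[i]) * spec$rate))
          gain[i0:i1] <- sqrt(1 + rg[1]) * sqrt(1 + sg$modulation)
        }
      }
      x[ch, ] <- parts$rest + gain * parts$band
    }
  }

  # ERP components: Gaussian pulses locked to marker onsets.
  for (cmp in spec$erp_components) {
    m <- markers[markers$label == cmp$condition, , drop = FALSE]
    if (!nrow(m)) next
    ch_idx <- match(cmp$channels, spec$channel_labels)
    if (anyNA(ch_idx)) {
      warnf("ERP component channel(s) not in montage: %s",
            paste(cmp$channels[is.na(ch_idx)], collapse = ", "))
    }
    for (i in seq_len(nrow(m))) {
      peak <- m$onset[i] + cmp$latency
      lo <- max(1L, floor((peak - 5 * cmp$width) * spec$rate) + 1L)
      hi <- min(n, ceiling((peak + 5 * cmp$width) * spec$rate))
      pulse <- cmp$amplitude *
        exp(-0.5 * ((t_axis[lo:hi] - peak) / cmp$width)^2)
      for (j in seq_along(ch_idx)) {
        if (is.na(ch_idx[j])) next
        x[ch_idx[j], lo:hi] <- x[ch_idx[j], lo:hi] + cmp$weights[j] * pulse
      }
    }
  }

  if (spec$session_drift > 0) {
    G <- with_rng(derive_seed(spec$seed, "drift"), {
      g <- matrix(stats::rnorm(spec$n_channels^2), spec$n_channels)
      g <- (g + t(g)) / 2
      g / norm(g, "F")
    })
    W <- diag(spec$n_channels) + spec$session_drift * G
    x <- W %*% x
    rownames(x) <- spec$channel_labels
  }
  eeg_recording(x, spec$rate, spec$channel_labels, markers)
}

#' Default ERP components for the auditory-oddball generator
#'
#' Deviant beeps carry a mismatch-negativity deflection (-3 uV at 200 ms
#' over fronto-central sites); the attended high-pitch target additionally
#' carries a delayed P300 (+2.5 uV near 600 ms over midline/temporal sites),
#' matching the late positivity the oddball assessment looks for.
#'
#' @param mmn_amplitude,p300_amplitude Peak amplitudes in microvolts.
#' @return List of [erp_component()].
#' @export
oddball_components <- function(mmn_amplitude = -3, p300_amplitude = 2.5) {
  mmn_ch <- c("Fz", "FC1", "FC2", "Cz")
  p300_ch <- c("Fz", "Cz", "T7", "T8")
  list(
    erp_component("beep_high", latency = 0.2, width = 0.03,
                  amplitude = mmn_amplitude, channels = mmn_ch),
    erp_component("beep_low", latency = 0.2, width = 0.03,
                  amplitude = mmn_amplitude, channels = mmn_ch),
    erp_component("beep_high", latency = 0.6, width = 0.08,
                  amplitude = p300_amplitude, channels = p300_ch)
  )
}

#' Default ERD/ERS signatures for the mental-imagery tasks
#'
#' Encodes the class-conditional spectral patterns the imagery analyses
#' target: left-hand motor imagery (LMI) with strong low-beta ERD at C3/C4
#' and slight alpha ERS at C4; tongue motor imagery (TMI) with the same
#' low-beta ERD at C3/C4; mental subtraction (MS) with frontal theta ERS and
#' alpha ERD at AF3/AF4.
#'
#' @param modulation Magnitude of the principal modulations (fraction of
#'   baseline band power); the defaults scale secondary effects relative to
#'   it.
#' @param rhythm_gain Resting rhythm strength passed to [erds_signature()].
#' @return List of [erds_signature()].
#' @export
imagery_signatures <- function(modulation = 0.5, rhythm_gain = 1) {
  list(
    erds_signature("LMI", c(14, 20), c("C3", "C4"), -modulation, rhythm_gain),
    erds_signature("LMI", c(8, 13), "C4", 0.4 * modulation, rhythm_gain),
    erds_signature("TMI", c(14, 20), c("C3", "C4"), -modulation, rhythm_gain),
    erds_signature("MS", c(4, 7), c("AF3", "AF4"), modulation, rhythm_gain),
    erds_signature("MS", c(8, 13), c("AF3", "AF4"), -0.6 * modulation, rhythm_gain)
  )
}

#' One-call synthetic sessions
#'
#' Convenience wrappers bundling a paradigm schedule and a generator spec
#' into a ready recording. `synth_oddball_session()` defaults to the
#' assessment protocol (6 runs x 20 trials, 3 noise bursts + 2 beeps per
#' trial at 2048 Hz); `synth_imagery_session()` defaults to the offline
#' imagery protocol (10 runs x 6 trials over LMI/MS/TMI).
#'
#' @param seed Integer master seed for both schedule and signals.
#' @param paradigm A [paradigm_spec()]; a protocol default when `NULL`.
#' @param n_channels,channel_labels,rate,noise_exponent,noise_rms,session_drift
#'   Passed to [synth_spec()].
#' @param erp_components,erds_signatures Signal definitions; protocol
#'   defaults when `NULL`.
#' @return An [eeg_recording()] with embedded markers.
#' @export
synth_oddball_session <- function(seed = 1L, paradigm = NULL,
                                  n_channels = 19L,
                                  channel_labels = montage_1020(),
                                  rate = 2048, noise_exponent = 1,
                                  noise_rms = 10,
                                  erp_components = NULL) {
  if (is.null(paradigm)) {
    paradigm <- paradigm_spec("oddball", n_runs = 6L, trials_per_run = 20L,
                              seed = seed)
  }
  if (is.null(erp_components)) erp_components <- oddball_components()
  spec <- synth_spec(n_channels, channel_labels, rate, noise_exponent,
                     noise_rms, erp_components = erp_components, seed = seed)
  synth_recording(schedule_oddball(paradigm), spec)
}

#' @rdname synth_oddball_session
#' @param session_kind Imagery protocol kind, see [paradigm_spec()].
#' @param task_set Task labels.
#' @param modulation Principal modulation magnitude for
#'   [imagery_signatures()].
#' @export
synth_imagery_session <- function(seed = 1L, paradigm = NULL,
                                  session_kind = "imagery_offline",
                                  task_set = c("LMI", "MS", "TMI"),
                                  n_channels = 19L,
                                  channel_labels = montage_1020(),
                                  rate = 2048, noise_exponent = 1,
                                  noise_rms = 10, modulation = 0.5,
                                  erds_signatures = NULL,
                                  session_drift = 0) {
  if (is.null(paradigm)) {
    defaults <- switch(session_kind,
      imagery_offline = list(n_runs = 10L, trials_per_run = 6L),
      imagery_train   = list(n_runs = 10L, trials_per_run = 4L),
      imagery_test    = list(n_runs = 4L, trials_per_run = 10L),
      stopf("unknown imagery session kind '%s'", session_kind))
    paradigm <- paradigm_spec(session_kind, n_runs = defaults$n_runs,
                              trials_per_run = defaults$trials_per_run,
                              task_set = task_set, seed = seed)
  }
  if (is.null(erds_signatures)) erds_signatures <- imagery_signatures(modulation)
  spec <- synth_spec(n_channels, channel_labels, rate, noise_exponent,
                     noise_rms, erds_signatures = erds_signatures,
                     session_drift = session_drift, seed = seed)
  synth_recording(schedule_imagery(paradigm), spec)
}

#' Serialize generator specifications to JSON
#'
#' `spec_to_json()` writes a [paradigm_spec()] or [synth_spec()] to a JSON
#' string (or file); `spec_from_json()` restores it.
#'
#' @param spec The specification object.
#' @param path Optional file path; when given, JSON is written there.
#' @param json JSON string or path to a JSON file.
#' @return `spec_to_json()`: the JSON string, invisibly when writing to a
#'   file. `spec_from_json()`: the restored object.
#' @export
spec_to_json <- function(spec, path = NULL) {
  kind <- if (inherits(spec, "paradigm_spec")) "paradigm_spec"
          else if (inherits(spec, "synth_spec")) "synth_spec"
          else stopf("spec must be a paradigm_spec or synth_spec")
  payload <- unclass(spec)
  if (kind == "synth_spec") {
    payload$erp_components <- lapply(payload$erp_components, unclass)
    payload$erds_signatures <- lapply(payload$erds_signatures, unclass)
  }
  js <- jsonlite::toJSON(list(kind = kind, spec = payload),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' @rdname spec_to_json
#' @export
spec_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- paste(readLines(json), collapse = "\n")
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  sp <- obj$spec
  if (obj$kind == "paradigm_spec") {
    return(do.call(paradigm_spec, sp))
  }
  sp$erp_components <- lapply(sp$erp_components, function(e)
    erp_component(e$condition, e$latency, e$width, e$amplitude, e$channels,
                  e$weights))
  sp$erds_signatures <- lapply(sp$erds_signatures, function(s)
    erds_signature(s$condition, s$band, s$channels, s$modulation,
                   s$rhythm_gain))
  do.call(synth_spec, sp)
}
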