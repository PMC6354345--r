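#' Condition-average ERPs
#'
#' Arithmetic mean across trials, per condition and channel.
#'
#' @param ep An [eeg_epochs()].
#' @param conditions Condition labels to average; default: all present.
#' @return Object of class `erp_result`: list with `waveforms` (named list
#'   of channels x samples matrices, microvolts), `times` (s), `n_trials`
#'   (named counts), `channel_labels`.
#' @export
condition_average <- function(ep, conditions = NULL) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (is.null(conditions)) conditions <- unique(ep$labels)
  missing_ <- setdiff(conditions, ep$labels)
  if (length(missing_)) {
    stopf("condition(s) with no trials: %s", paste(missing_, collapse = ", "))
  }
  waveforms <- lapply(conditions, function(cond) {
    idx <- which(ep$labels == cond)
    w <- apply(ep$data[, , idx, drop = FALSE], c(1, 2), mean)
    rownames(w) <- ep$channel_labels
    w
  })
  names(waveforms) <- conditions
  structure(list(waveforms = waveforms, times = epoch_times(ep),
                 n_trials = vapply(conditions, function(cond) sum(ep$labels == cond), 0L),
                 channel_labels = ep$channel_labels),
            class = "erp_result")
}

#' @export
print.erp_result <- function(x, ...) {
  cat(sprintf("<erp_result: %d condition(s), %d ch, %d samples [%g, %g] s>\n",
              length(x$waveforms), length(x$channel_labels),
              length(x$times), min(x$times), max(x$times)))
  for (cond in names(x$waveforms)) {
    cat(sprintf("  %s: %d trial(s)\n", cond, x$n_trials[[cond]]))
  }
  invisible(x)
}

#' Subsample standard trials
#'
#' Seeded uniform sampling without replacement, preserving trial order; used
#' to match the standard-trial count to the deviant count before paired
#' statistics.
#'
#' @param ep An [eeg_epochs()].
#' @param n Number of trials to keep.
#' @param seed Integer seed.
#' @return The subsampled `eeg_epochs`.
#' @export
subsample_standards <- function(ep, n, seed = 1L) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (n > n_trials(ep)) stopf("cannot sample %d of %d trials", n, n_trials(ep))
  idx <- with_rng(derive_seed(seed, "subsample"),
                  sort(sample.int(n_trials(ep), n)))
  subset_epochs(ep, trials = idx)
}

#' Mismatch-negativity characterization
#'
#' On the deviant-minus-standard difference waveform, finds per channel the
#' minimum amplitude within the search window and its latency (ties broken
#' by the earliest latency).
#'
#' @param erp An `erp_result` from [condition_average()].
#' @param deviant,standard Condition names in `erp`.
#' @param window Search window in seconds (default 100-300 ms).
#' @return Data frame with columns `channel`, `latency` (s), `amplitude`
#'   (microvolts).
#' @export
detect_mmn <- function(erp, deviant, standard, window = c(0.100, 0.300)) {
  stopifnot(inherits(erp, "erp_result"))
  if (!all(c(deviant, standard) %in% names(erp$waveforms))) {
    stopf("conditions '%s'/'%s' not in ERP result", deviant, standard)
  }
  sel <- erp$times >= window[1] & erp$times <= window[2]
  if (!any(sel)) stopf("window [%g, %g] s outside the epoch", window[1], window[2])
  diffw <- erp$waveforms[[deviant]] - erp$waveforms[[standard]]
  t_win <- erp$times[sel]
  res <- t(apply(diffw[, sel, drop = FALSE], 1, function(w) {
    i <- which.min(w)          # which.min returns the earliest tie
    c(t_win[i], w[i])
  }))
  data.frame(channel = erp$channel_labels, latency = res[, 1],
             amplitude = res[, 2], row.names = NULL,
             stringsAsFactors = FALSE)
}

# Window start times for a moving window over [span1, span2]: start at
# span1, step window*(1-overlap), keep windows fully inside the span.
moving_window_starts <- function(span, window, overlap) {
  step <- window * (1 - overlap)
  n_win <- floor((span[2] - span[1] - window) / step + 1e-9) + 1L
  if (n_win < 1L) stopf("span shorter than one window")
  span[1] + step * (seq_len(n_win) - 1)
}

#' Moving-window paired t-tests between two conditions
#'
#' Segments the analysis span into overlapping windows (62.5 ms, 50 percent
#' overlap by default), takes each trial's mean amplitude per window as the
#' paired observation, runs a two-sided paired t-test per channel and
#' window, and Bonferroni-corrects over the whole family
#' (channels x windows). Trials are paired by position, so both epoch sets
#' must hold the same number of trials (use [subsample_standards()] to
#' match counts).
#'
#' @param epA,epB Paired [eeg_epochs()] with equal trial counts.
#' @param span Length-2 numeric, analysis span in seconds.
#' @param window Window length (s).
#' @param overlap Fractional overlap between consecutive windows.
#' @param alpha Family-wise significance level.
#' @return Data frame of class `window_test` with columns `channel`,
#'   `window_start`, `window_end`, `t`, `p_raw`, `p_bonf`, `significant`.
#' @export
moving_window_ttest <- function(epA, epB, span, window = 0.0625,
                                overlap = 0.5, alpha = 0.05) {
  stopifnot(inherits(epA, "eeg_epochs"), inherits(epB, "eeg_epochs"))
  if (n_trials(epA) != n_trials(epB)) {
    stopf(paste("paired design requires equal trial counts (%d vs %d);",
                "use subsample_standards() to match them"),
          n_trials(epA), n_trials(epB))
  }
  times <- epoch_times(epA)
  if (span[1] < times[1] - 1e-9 || span[2] > times[length(times)] + 1/epA$rate) {
    stopf("span [%g, %g] s outside the epoch window", span[1], span[2])
  }
  starts <- moving_window_starts(span, window, overlap)
  n_ch <- dim(epA$data)[1]
  n <- n_trials(epA)
  out <- vector("list", length(starts))
  for (w in seq_along(starts)) {
    sel <- times >= starts[w] - 1e-9 & times < starts[w] + window - 1e-9
    # per-trial mean amplitude in the window: channels x trials
    mA <- apply(epA$data[, sel, , drop = FALSE], c(1, 3), mean)
    mB <- apply(epB$data[, sel, , drop = FALSE], c(1, 3), mean)
    d <- mA - mB
    dm <- rowMeans(d)
    dsd <- sqrt(rowSums((d - dm)^2) / (n - 1))
    # degenerate pairs: identical -> t = 0; constant nonzero difference ->
    # infinitely consistent effect
    tstat <- ifelse(dsd > 0, dm / (dsd / sqrt(n)),
                    ifelse(dm == 0, 0, sign(dm) * Inf))
    p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
    out[[w]] <- data.frame(channel = epA$channel_labels,
                           window_start = starts[w],
                           window_end = starts[w] + window,
                           t = tstat, p_raw = p,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$p_bonf <- pmin(1, res$p_raw * nrow(res))
  res$significant <- res$p_bonf < alpha
  class(res) <- c("window_test", class(res))
  attr(res, "alpha") <- alpha
  attr(res, "n_comparisons") <- nrow(res)
  res
}

#' Export ERP results
#'
#' `write_window_test()` writes the moving-window statistics to a tidy CSV;
#' `write_erp_waveforms()` writes the condition-average waveforms in long
#' format (condition, channel, time_s, amplitude_uV).
#'
#' @param x A `window_test` or `erp_result`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_window_test <- function(x, path) {
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_test
#' @export
write_erp_waveforms <- function(x, path) {
  stopifnot(inherits(x, "erp_result"))
  rows <- lapply(names(x$waveforms), function(cond) {
    w <- x$waveforms[[cond]]
    data.frame(condition = cond,
               channel = rep(x$channel_labels, each = ncol(w)),
               time_s = rep(x$times, times = nrow(w)),
               amplitude_uV = as.vector(t(w)),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
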