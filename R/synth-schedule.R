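#' Paradigm specification
#'
#' Describes the timing and composition of an experimental session: either an
#' auditory-oddball assessment or one of the mental-imagery protocols
#' (offline screening, online training, online test).
#'
#' Defaults follow the study protocols this package models: 80 ms auditory
#' stimuli with inter-stimulus intervals drawn uniformly from 480-600 ms for
#' the oddball sessions; for imagery sessions a variable 3-8 s rest, a 6 s
#' auditory cue period and a 5 s task period.
#'
#' @param session_kind One of `"oddball"`, `"imagery_offline"`,
#'   `"imagery_train"`, `"imagery_test"`.
#' @param n_runs Number of runs in the session.
#' @param trials_per_run Trials per run. For imagery kinds this must be
#'   divisible by the number of tasks so runs can be counter-balanced.
#' @param task_set Character vector of condition labels (imagery kinds only).
#' @param stimulus_duration Oddball stimulus duration in seconds.
#' @param isi_range Length-2 numeric, min/max inter-stimulus interval (s).
#' @param rest_range Length-2 numeric, min/max pre-trial rest (s).
#' @param cue_duration Auditory cue period before the task (s).
#' @param task_duration Mental-task period (s).
#' @param noises_per_trial Number of standard (noise) stimuli per oddball
#'   trial, ahead of the two beeps.
#' @param start_duration Start-message period at the head of each run (s).
#' @param instruction_duration Instruction period after the start message (s).
#' @param seed Integer seed controlling all randomized ordering and timing.
#' @return An object of class `paradigm_spec`.
#' @seealso [schedule_session()], [synth_recording()]
#' @export
paradigm_spec <- function(session_kind = c("oddball", "imagery_offline",
                                           "imagery_train", "imagery_test"),
                          n_runs = 6L,
                          trials_per_run = 20L,
                          task_set = c("LMI", "MS"),
                          stimulus_duration = 0.08,
                          isi_range = c(0.48, 0.60),
                          rest_range = c(3, 8),
                          cue_duration = 6,
                          task_duration = 5,
                          noises_per_trial = 3L,
                          start_duration = 5,
                          instruction_duration = 4,
                          seed = 1L) {
  session_kind <- match.arg(session_kind)
  if (length(isi_range) != 2L || isi_range[1] > isi_range[2]) {
    stopf("isi_range must be (min, max) with min <= max")
  }
  if (length(rest_range) != 2L || rest_range[1] > rest_range[2]) {
    stopf("rest_range must be (min, max) with min <= max")
  }
  durs <- c(stimulus_duration, cue_duration, task_duration,
            start_duration, instruction_duration)
  if (any(durs <= 0)) stopf("all durations must be > 0")
  if (n_runs < 1L || trials_per_run < 1L) stopf("n_runs and trials_per_run must be >= 1")
  if (session_kind != "oddball" && trials_per_run %% length(task_set) != 0L) {
    stopf("trials_per_run (%d) must be divisible by the number of tasks (%d)",
          trials_per_run, length(task_set))
  }
  structure(list(
    session_kind = session_kind,
    n_runs = as.integer(n_runs),
    trials_per_run = as.integer(trials_per_run),
    task_set = as.character(task_set),
    stimulus_duration = stimulus_duration,
    isi_range = as.numeric(isi_range),
    rest_range = as.numeric(rest_range),
    cue_duration = cue_duration,
    task_duration = task_duration,
    noises_per_trial = as.integer(noises_per_trial),
    start_duration = start_duration,
    instruction_duration = instruction_duration,
    seed = as.integer(seed)
  ), class = "paradigm_spec")
}

#' @export
print.paradigm_spec <- function(x, ...) {
  cat(sprintf("<paradigm_spec: %s, %d run(s) x %d trial(s), seed %d>\n",
              x$session_kind, x$n_runs, x$trials_per_run, x$seed))
  if (x$session_kind != "oddball") {
    cat("  tasks:", paste(x$task_set, collapse = ", "), "\n")
  }
  invisible(x)
}

new_markers <- function(onset, label, duration) {
  data.frame(onset = onset, duration = duration, label = label,
             stringsAsFactors = FALSE)
}

#' Build the stimulus schedule of a session
#'
#' Lays out every event of a session as a marker table. For oddball sessions
#' each trial presents `noises_per_trial` standard noise bursts plus one
#' high-pitch and one low-pitch beep in seeded random order, separated by
#' ISIs drawn uniformly from `isi_range`. For imagery sessions each trial is
#' rest + cue + task; one marker per trial is emitted at task onset, with
#' tasks counter-balanced within every run.
#'
#' @param spec A [paradigm_spec()].
#' @return Data frame (markers) with columns `onset` (s), `duration` (s),
#'   `label`, `run` (run id), `trial` (session-level trial id; `NA` for
#'   bookkeeping events). Oddball stimulus labels are `noise`, `beep_high`,
#'   `beep_low`; imagery labels are the task names. Run start/instruction
#'   periods appear as `start` / `instruction` markers.
#' @export
schedule_session <- function(spec) {
  stopifnot(inherits(spec, "paradigm_spec"))
  if (spec$session_kind == "oddball") schedule_oddball(spec) else schedule_imagery(spec)
}

#' @rdname schedule_session
#' @export
schedule_oddball <- function(spec) {
  stopifnot(inherits(spec, "paradigm_spec"))
  if (spec$session_kind != "oddball") {
    stopf("schedule_oddball() requires session_kind = 'oddball', got '%s'",
          spec$session_kind)
  }
  with_rng(derive_seed(spec$seed, "schedule"), {
    rows <- vector("list", spec$n_runs)
    t <- 0
    trial_id <- 0L
    for (run in seq_len(spec$n_runs)) {
      head_rows <- new_markers(
        onset = c(t, t + spec$start_duration),
        label = c("start", "instruction"),
        duration = c(spec$start_duration, spec$instruction_duration))
      head_rows$run <- run
      head_rows$trial <- NA_integer_
      t <- t + spec$start_duration + spec$instruction_duration
      run_rows <- vector("list", spec$trials_per_run)
      for (k in seq_len(spec$trials_per_run)) {
        trial_id <- trial_id + 1L
        labs <- sample(c(rep("noise", spec$noises_per_trial),
                         "beep_high", "beep_low"))
        n_stim <- length(labs)
        isi <- stats::runif(n_stim, spec$isi_range[1], spec$isi_range[2])
        onset <- t + cumsum(c(0, rep(spec$stimulus_duration, n_stim - 1) +
                                isi[-n_stim]))
        m <- new_markers(onset, labs, spec$stimulus_duration)
        m$run <- run
        m$trial <- trial_id
        run_rows[[k]] <- m
        t <- onset[n_stim] + spec$stimulus_duration + isi[n_stim]
      }
      rows[[run]] <- rbind(head_rows, do.call(rbind, run_rows))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' @rdname schedule_session
#' @export
schedule_imagery <- function(spec) {
  stopifnot(inherits(spec, "paradigm_spec"))
  if (!spec$session_kind %in% c("imagery_offline", "imagery_train", "imagery_test")) {
    stopf("schedule_imagery() requires an imagery session kind, got '%s'",
          spec$session_kind)
  }
  per_run <- spec$trials_per_run / length(spec$task_set)
  with_rng(derive_seed(spec$seed, "schedule"), {
    rows <- vector("list", spec$n_runs)
    t <- 0
    trial_id <- 0L
    for (run in seq_len(spec$n_runs)) {
      head_rows <- new_markers(t, "start", spec$start_duration)
      head_rows$run <- run
      head_rows$trial <- NA_integer_
      t <- t + spec$start_duration
      labs <- sample(rep(spec$task_set, per_run))
      run_rows <- vector("list", spec$trials_per_run)
      for (k in seq_len(spec$trials_per_run)) {
        trial_id <- trial_id + 1L
        rest <- stats::runif(1, spec$rest_range[1], spec$rest_range[2])
        task_onset <- t + rest + spec$cue_duration
        m <- new_markers(task_onset, labs[k], spec$task_duration)
        m$run <- run
        m$trial <- trial_id
        run_rows[[k]] <- m
        t <- task_onset + spec$task_duration
      }
      rows[[run]] <- rbind(head_rows, do.call(rbind, run_rows))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# Total recording time implied by a marker table, with a small tail pad.
schedule_duration <- function(markers, pad = 2) {
  max(markers$onset + markers$duration) + pad
}

#' Read and write marker sidecar tables
#'
#' Markers travel alongside recordings as a plain TSV with columns
#' `onset` (s), `duration` (s), `label` (plus optional `run`, `trial`).
#'
#' @param markers Marker data frame.
#' @param path File path.
#' @return `read_markers()` returns the marker data frame.
#' @export
write_markers <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
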