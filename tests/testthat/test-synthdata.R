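test_that("oddball scheduler emits the protocol's stimulus counts and timing", {
  spec <- paradigm_spec("oddball", n_runs = 6, trials_per_run = 20, seed = 3)
  mk <- schedule_oddball(spec)
  stim <- mk[!mk$label %in% c("start", "instruction"), ]
  expect_equal(sum(stim$label == "noise"), 360)
  expect_equal(sum(stim$label == "beep_high"), 120)
  expect_equal(sum(stim$label == "beep_low"), 120)
  # per trial: exactly 3 noises and 2 beeps
  per_trial <- table(stim$trial, stim$label)
  expect_true(all(per_trial[, "noise"] == 3))
  expect_true(all(per_trial[, "beep_high"] == 1))
  expect_true(all(per_trial[, "beep_low"] == 1))
  # ISIs all within range
  for (tr in unique(stim$trial)) {
    on <- stim$onset[stim$trial == tr]
    isi <- diff(on) - spec$stimulus_duration
    expect_true(all(isi >= spec$isi_range[1] - 1e-9 &
                      isi <= spec$isi_range[2] + 1e-9))
  }
  # noises_per_trial knob reaches the alternative 600-standard reading
  mk5 <- schedule_oddball(paradigm_spec("oddball", n_runs = 6,
                                        trials_per_run = 20,
                                        noises_per_trial = 5, seed = 3))
  expect_equal(sum(mk5$label == "noise"), 600)
})

test_that("oddball scheduler minimal case and seeding", {
  spec <- paradigm_spec("oddball", n_runs = 1, trials_per_run = 1, seed = 9)
  mk <- schedule_oddball(spec)
  stim <- mk[!mk$label %in% c("start", "instruction"), ]
  expect_equal(nrow(stim), 5)
  instr_off <- mk$onset[mk$label == "instruction"] +
    mk$duration[mk$label == "instruction"]
  expect_true(min(stim$onset) >= instr_off)
  expect_identical(mk, schedule_oddball(spec))
  expect_error(schedule_oddball(paradigm_spec("imagery_offline", seed = 1,
                                              trials_per_run = 6,
                                              task_set = c("a", "b", "c"))),
               "oddball")
})

test_that("imagery scheduler balances tasks within runs and sessions", {
  spec <- paradigm_spec("imagery_offline", n_runs = 10, trials_per_run = 6,
                        task_set = c("LMI", "MS", "TMI"), seed = 5)
  mk <- schedule_imagery(spec)
  tasks <- mk[mk$label != "start", ]
  expect_equal(unname(table(tasks$label)[c("LMI", "MS", "TMI")]),
               rep(20L, 3), ignore_attr = TRUE)
  per_run <- table(tasks$run, tasks$label)
  expect_true(all(per_run == 2))

  test_spec <- paradigm_spec("imagery_test", n_runs = 4, trials_per_run = 10,
                             task_set = c("LMI", "MS"), seed = 5)
  mk2 <- schedule_imagery(test_spec)
  expect_equal(sum(mk2$label == "LMI"), 20)
  expect_equal(sum(mk2$label == "MS"), 20)

  tr_spec1 <- paradigm_spec("imagery_train", n_runs = 1, trials_per_run = 4,
                            task_set = c("LMI", "MS"), seed = 1)
  mk3 <- schedule_imagery(tr_spec1)
  expect_equal(sum(mk3$label == "LMI"), 2)
  orders <- vapply(1:8, function(s) {
    m <- schedule_imagery(paradigm_spec("imagery_train", n_runs = 1,
                                        trials_per_run = 4,
                                        task_set = c("LMI", "MS"), seed = s))
    paste(m$label[m$label != "start"], collapse = "")
  }, "")
  expect_gt(length(unique(orders)), 1)
  expect_error(paradigm_spec("imagery_train", trials_per_run = 5,
                             task_set = c("LMI", "MS")), "divisible")
})

test_that("noiseless ERP template is recovered exactly", {
  mk <- data.frame(onset = 1, duration = 0.08, label = "beep_low")
  spec <- synth_spec(n_channels = 2, channel_labels = c("Fz", "Cz"),
                     rate = 256, noise_rms = 0,
                     erp_components = list(
                       erp_component("beep_low", 0.2, 0.03, -3, "Fz")),
                     seed = 1)
  rec <- synth_recording(mk, spec, duration = 3)
  ep <- epoch_recording(rec, c(-0.1, 1), "beep_low")
  tms <- ep$window[1] + (seq_len(dim(ep$data)[2]) - 1) / ep$rate
  fz <- ep$data[1, , 1]
  expect_equal(min(fz), -3, tolerance = 1e-3)   # sample grid vs exact peak
  expect_equal(tms[which.min(fz)], 0.2, tolerance = 1 / 256)
  expect_equal(max(abs(ep$data[2, , 1])), 0)
})

test_that("band modulation halves in-band power against a Welch estimate", {
  # 20 LMI markers with -50% low-beta at C3 vs 20 unmodulated rest windows
  onsets <- seq(2, by = 7, length.out = 40)
  mk <- data.frame(onset = onsets, duration = 5,
                   label = rep(c("LMI", "OTHER"), 20))
  spec <- synth_spec(n_channels = 1, channel_labels = "C3", rate = 128,
                     erds_signatures = list(
                       erds_signature("LMI", c(14, 20), "C3", -0.5)),
                     seed = 21)
  rec <- suppressWarnings(synth_recording(mk, spec, duration = 287,
                                          quiet_labels = "OTHER"))
  band_power <- function(idx) {
    mean(vapply(idx, function(i) {
      x <- rec$samples[1, floor(onsets[i] * 128):(floor(onsets[i] * 128) + 639)]
      sp <- stats::spec.pgram(stats::ts(x, frequency = 128), spans = 5,
                              plot = FALSE, taper = 0.1)
      mean(sp$spec[sp$freq >= 14 & sp$freq <= 20])
    }, 0))
  }
  ratio <- band_power(which(mk$label == "LMI")) /
    band_power(which(mk$label == "OTHER"))
  expect_equal(ratio, 0.5, tolerance = 0.1)
})

test_that("generation is deterministic and drift-free runs are identical", {
  par <- paradigm_spec("imagery_train", n_runs = 1, trials_per_run = 4,
                       task_set = c("LMI", "MS"), seed = 4)
  r1 <- synth_imagery_session(seed = 4, paradigm = par, rate = 128,
                              n_channels = 4,
                              channel_labels = c("C3", "C4", "AF3", "AF4"))
  r2 <- synth_imagery_session(seed = 4, paradigm = par, rate = 128,
                              n_channels = 4,
                              channel_labels = c("C3", "C4", "AF3", "AF4"))
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$markers, r2$markers)
})

test_that("session drift applies a congruence transform to covariances", {
  par <- paradigm_spec("imagery_train", n_runs = 1, trials_per_run = 4,
                       task_set = c("LMI", "MS"), seed = 4)
  chs <- c("C3", "C4", "AF3", "AF4")
  r0 <- synth_imagery_session(seed = 4, paradigm = par, rate = 128,
                              n_channels = 4, channel_labels = chs)
  r1 <- synth_imagery_session(seed = 4, paradigm = par, rate = 128,
                              n_channels = 4, channel_labels = chs,
                              session_drift = 0.2)
  # drifted samples are a fixed linear mix W of the undrifted ones
  W <- r1$samples[, 1:50] %*% t(r0$samples[, 1:50]) %*%
    solve(r0$samples[, 1:50] %*% t(r0$samples[, 1:50]))
  expect_equal(W %*% r0$samples, r1$samples, tolerance = 1e-6)
  expect_equal(W, t(W), tolerance = 1e-6)   # I + drift * symmetric G
})

test_that("1/f noise has the configured spectral slope", {
  x <- lockbci:::pink_noise(128 * 80, 128, 1, 10)   # 80 s
  sp <- stats::spec.pgram(stats::ts(x, frequency = 128), plot = FALSE,
                          spans = 11)
  sel <- sp$freq >= 1 & sp$freq <= 45
  fit <- stats::lm(log10(sp$spec[sel]) ~ log10(sp$freq[sel]))
  expect_equal(unname(stats::coef(fit)[2]), -1, tolerance = 0.2)
})

test_that("specs round-trip through JSON", {
  p <- paradigm_spec("imagery_offline", n_runs = 10, trials_per_run = 6,
                     task_set = c("LMI", "MS", "TMI"), seed = 12)
  p2 <- spec_from_json(spec_to_json(p))
  expect_equal(p, p2)
  s <- synth_spec(n_channels = 4,
                  channel_labels = c("C3", "C4", "AF3", "AF4"), rate = 128,
                  erp_components = oddball_components(),
                  erds_signatures = imagery_signatures(0.4),
                  session_drift = 0.1, seed = 8)
  s2 <- spec_from_json(spec_to_json(s))
  expect_equal(s, s2)
  expect_identical(schedule_imagery(p)$onset, schedule_imagery(p2)$onset)
})

test_that("markers beyond the recording and unknown labels are handled", {
  spec <- synth_spec(n_channels = 1, channel_labels = "Cz", rate = 64, seed = 1)
  mk <- data.frame(onset = 10, duration = 1, label = "noise")
  expect_error(synth_recording(mk, spec, duration = 5), "beyond")
  mk2 <- data.frame(onset = 1, duration = 1, label = "mystery")
  expect_warning(synth_recording(mk2, spec, duration = 5), "mystery")
})
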