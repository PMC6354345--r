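test_that("common average reference zeroes the channel mean and is idempotent", {
  x <- matrix(c(1, 5, 2, 8, 0, 4), nrow = 2, byrow = TRUE)
  rec <- eeg_recording(x, 100, c("a", "b"))
  out <- car_reference(rec)
  expect_lt(max(abs(colSums(out$samples))), 1e-9)
  # two channels (a, b) -> ((a-b)/2, (b-a)/2)
  expect_equal(out$samples[1, ], (x[1, ] - x[2, ]) / 2)
  expect_equal(out$samples[2, ], (x[2, ] - x[1, ]) / 2)
  expect_equal(car_reference(out)$samples, out$samples)
  expect_error(car_reference(eeg_recording(x[1, , drop = FALSE], 100, "a")),
               "2 channels")
})

test_that("zero-phase band-pass preserves passband and attenuates by |H|^2", {
  rate <- 512
  t <- (0:(rate * 4 - 1)) / rate
  mk10 <- function(f) eeg_recording(rbind(sin(2 * pi * f * t),
                                          cos(2 * pi * f * t)), rate,
                                    c("a", "b"))
  out10 <- bandpass_zero_phase(mk10(10), 4, 45, 5)
  mid <- (rate):(3 * rate)
  expect_equal(sine_amplitude(out10$samples[1, mid], 10, rate), 1,
               tolerance = 0.01)
  # 60 Hz: attenuation equals the squared design magnitude response
  out60 <- bandpass_zero_phase(mk10(60), 4, 45, 5)
  bt <- signal::butter(5, c(4, 45) / (rate / 2), type = "pass")
  z <- exp(-1i * 2 * pi * 60 / rate * seq(0, length(bt$b) - 1))
  H <- abs(sum(bt$b * z) / sum(bt$a * z))
  expect_equal(sine_amplitude(out60$samples[1, mid], 60, rate), H^2,
               tolerance = 0.05 * H^2)
  # zero-phase: filtering commutes with time reversal (interior samples;
  # the 4 Hz low edge has a transient of roughly a second, so keep a 2 s
  # margin on an 8 s signal)
  set.seed(2)
  x <- rnorm(rate * 8)
  rec_f <- eeg_recording(rbind(x, x), rate, c("a", "b"))
  rec_r <- eeg_recording(rbind(rev(x), rev(x)), rate, c("a", "b"))
  yf <- bandpass_zero_phase(rec_f, 4, 45, 5)$samples[1, ]
  yr <- rev(bandpass_zero_phase(rec_r, 4, 45, 5)$samples[1, ])
  interior <- (2 * rate):(6 * rate)
  expect_lt(max(abs(yf[interior] - yr[interior])), 1e-6)
  expect_error(bandpass_zero_phase(rec_f, 0, 45, 5), "cutoffs")
  expect_error(bandpass_zero_phase(rec_f, 4, 500, 5), "cutoffs")
})

test_that("epoching follows the floor/half-open sample convention", {
  rate <- 2048
  mk <- data.frame(onset = c(1, 6.5), duration = 0.08,
                   label = c("noise", "task"))
  rec <- eeg_recording(matrix(rnorm(2 * rate * 13), 2), rate, c("a", "b"), mk)
  ep1 <- epoch_recording(rec, c(-0.1, 1.0), "noise")
  expect_equal(dim(ep1$data)[2], 2252)   # floor(1.1 * 2048)
  ep2 <- epoch_recording(rec, c(0, 5), "task")
  expect_equal(dim(ep2$data)[2], 10240)
  # empty label filter match: zero trials, shape metadata intact
  ep0 <- epoch_recording(rec, c(0, 1), "absent")
  expect_equal(n_trials(ep0), 0)
  expect_equal(dim(ep0$data)[1:2], c(2L, 2048L))
  expect_error(epoch_recording(rec, c(-2, 1), "noise"), "bounds")
})

test_that("epoch content is the exact sample slice", {
  rate <- 100
  x <- matrix(seq_len(500), nrow = 1)
  mk <- data.frame(onset = 2.0, duration = 0.1, label = "s")
  rec <- eeg_recording(x, rate, "a", mk)
  ep <- epoch_recording(rec, c(-0.1, 0.2), "s")
  # start index floor((2.0 - 0.1) * 100) = 190 (0-based), 30 samples
  expect_equal(ep$data[1, , 1], as.numeric(191:220))
})

test_that("baseline correction subtracts the pre-stimulus mean", {
  ep <- epochs_from_matrices(list(matrix(c(1, 1, 2, 4), 1)), c(-0.5, 0.5),
                             4, "s")
  out <- baseline_correct(ep)
  expect_equal(out$data[1, , 1], c(0, 0, 1, 3))
  # shift invariance
  ep2 <- ep; ep2$data <- ep2$data + 17.3
  expect_equal(baseline_correct(ep2)$data, out$data)
  ep_nopre <- epochs_from_matrices(list(matrix(1:4, 1)), c(0, 1), 4, "s")
  expect_error(baseline_correct(ep_nopre), "pre-stimulus")
})

test_that("artifact screening removes only above-threshold trials", {
  mats <- list(matrix(rnorm(100), 2), matrix(rnorm(100), 2),
               matrix(rnorm(100), 2))
  mats[[2]][1, 10] <- 80
  ep <- epochs_from_matrices(mats, c(0, 0.5), 100, c("a", "a", "a"))
  res <- reject_artifacts(ep, 75)
  expect_equal(res$report$rejected_indices, 2L)
  expect_equal(res$report$kept_indices, c(1L, 3L))
  expect_equal(n_trials(res$epochs), 2)
  expect_equal(res$report$peak_amplitude[2], 80)
  expect_equal(n_trials(reject_artifacts(ep, Inf)$epochs), 3)
})

test_that("downsampling decimates exactly and preserves in-band content", {
  rate <- 2048
  t <- (0:10239) / rate
  ep <- epochs_from_matrices(list(rbind(sin(2 * pi * 10 * t))), c(0, 5),
                             rate, "s")
  out <- downsample_epochs(ep, 512)
  expect_equal(dim(out$data)[2], 2560)
  expect_equal(out$rate, 512)
  mid <- 500:2000
  expect_equal(sine_amplitude(out$data[1, mid, 1], 10, 512), 1,
               tolerance = 0.01)
  expect_identical(downsample_epochs(ep, rate), ep)
  expect_error(downsample_epochs(ep, 600), "integer")
})

test_that("recordings round-trip through the internal and EDF formats", {
  set.seed(3)
  mk <- data.frame(onset = c(0.5, 1.2), duration = 0.08,
                   label = c("noise", "beep_high"))
  rec <- eeg_recording(matrix(rnorm(19 * 512, sd = 20), 19), 256,
                       montage_1020(), mk)
  p1 <- tempfile(fileext = ".rds")
  write_recording(rec, p1, "internal")
  r1 <- read_recording(p1, "internal")
  expect_equal(r1$samples, rec$samples)
  expect_equal(r1$markers, rec$markers)

  p2 <- tempfile(fileext = ".edf")
  write_recording(rec, p2, "edf")
  r2 <- read_recording(p2, "edf")
  expect_identical(r2$channel_labels, montage_1020())
  expect_equal(r2$rate, 256)
  # 16-bit quantization over the per-channel physical range
  expect_lt(max(abs(r2$samples[, 1:512] - rec$samples)), 0.01)
  expect_equal(r2$markers$label, rec$markers$label)

  # truncated file: error, no partial recording
  bytes <- readBin(p2, "raw", file.info(p2)$size)
  p3 <- tempfile(fileext = ".edf")
  writeBin(bytes[1:(length(bytes) - 400)], p3)
  expect_error(read_recording(p3, "edf"), "truncated")
  expect_error(read_recording(tempfile(), "internal"), "not found")
})

test_that("preprocessing pipelines serialize and replay identically", {
  pl <- preproc_pipeline("oddball")
  pl2 <- pipeline_from_json(pipeline_to_json(pl))
  expect_equal(pl, pl2)
  par <- paradigm_spec("oddball", n_runs = 1, trials_per_run = 3, seed = 2)
  spec <- synth_spec(n_channels = 4,
                     channel_labels = c("Fz", "Cz", "C3", "C4"), rate = 128,
                     erp_components = oddball_components(), seed = 2)
  rec <- suppressWarnings(synth_recording(schedule_oddball(par), spec))
  e1 <- apply_preproc(rec, pl)$epochs
  e2 <- apply_preproc(rec, pl2)$epochs
  expect_identical(e1$data, e2$data)
  expect_identical(e1$labels, e2$labels)
})

test_that("epoching is invariant to marker translation", {
  rate <- 128
  set.seed(5)
  seg <- matrix(rnorm(2 * rate * 2), 2)     # 2 s of signal
  x <- cbind(seg, seg)                      # identical copy, shifted 2 s
  mk <- data.frame(onset = c(0.5, 2.5), duration = 0.1,
                   label = c("s", "s"))
  rec <- eeg_recording(x, rate, c("a", "b"), mk)
  ep <- epoch_recording(rec, c(0, 1), "s")
  expect_equal(ep$data[, , 1], ep$data[, , 2])
})
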