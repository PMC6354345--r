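# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# Epochs from a list of channels x samples matrices.
epochs_from_matrices <- function(mats, window, rate, labels,
                                 channel_labels = NULL) {
  dm <- dim(mats[[1]])
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(dm[1]))
  dat <- array(unlist(mats), dim = c(dm[1], dm[2], length(mats)))
  eeg_epochs(dat, window, rate, labels, channel_labels)
}

# Random SPD matrix with moderate conditioning.
rand_spd <- function(n, scale = 1) {
  A <- matrix(stats::rnorm(n * n), n)
  scale * (crossprod(A) / n + diag(n) * 0.5)
}

# Small two-class imagery session run through the full imagery chain:
# 8 channels, 256 Hz, 12 trials (6 LMI / 6 MS), default modulation 0.5.
small_imagery_epochs <- function() {
  fixture("small_imagery_epochs", function() {
    chs <- c("C3", "C4", "AF3", "AF4", "Cz", "Fz", "T7", "T8")
    par <- paradigm_spec("imagery_train", n_runs = 3, trials_per_run = 4,
                         task_set = c("LMI", "MS"), seed = 7)
    rec <- synth_imagery_session(seed = 7, paradigm = par, rate = 256,
                                 n_channels = 8, channel_labels = chs)
    apply_preproc(rec, preproc_pipeline("imagery", target_rate = 256))$epochs
  })
}

# Trivially separable two-class epochs: class A low-variance noise, class B
# high-variance noise (strong covariance and band-power contrast).
separable_epochs <- function(n_per_class = 6, n_ch = 4, n_samp = 512,
                             rate = 128, seed = 1) {
  set.seed(seed)
  mats <- c(
    lapply(seq_len(n_per_class), function(i) matrix(rnorm(n_ch * n_samp, sd = 1), n_ch)),
    lapply(seq_len(n_per_class), function(i) matrix(rnorm(n_ch * n_samp, sd = 3), n_ch)))
  epochs_from_matrices(mats, c(0, n_samp / rate), rate,
                       rep(c("A", "B"), each = n_per_class),
                       c("C3", "C4", "AF3", "AF4")[seq_len(n_ch)])
}

# Amplitude of a sinusoid at frequency f in signal x (least squares).
sine_amplitude <- function(x, f, rate) {
  t <- (seq_along(x) - 1) / rate
  2 * Mod(mean(x * exp(-2i * pi * f * t)))
}
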