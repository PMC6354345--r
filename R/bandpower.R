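#' Segment epochs into overlapping windows
#'
#' Splits each trial into fixed-length segments starting at the epoch start
#' and stepping `seg_len * (1 - overlap)`; only full segments are kept
#' (a 5 s epoch at 1 s / 50 percent overlap yields 9 segments).
#'
#' @param ep An [eeg_epochs()].
#' @param seg_len Segment length in seconds.
#' @param overlap Fractional overlap.
#' @return List with `starts` (segment start offsets, samples, 0-based) and
#'   `n_samples` (samples per segment).
#' @export
segment_epoch <- function(ep, seg_len = 1, overlap = 0.5) {
  stopifnot(inherits(ep, "eeg_epochs"))
  n_t <- dim(ep$data)[2]
  seg_n <- floor(seg_len * ep$rate)
  if (seg_n > n_t) stopf("segment length %g s exceeds the epoch", seg_len)
  step <- seg_len * (1 - overlap) * ep$rate
  n_seg <- floor((n_t - seg_n) / step + 1e-9) + 1L
  list(starts = as.integer(round(step * (seq_len(n_seg) - 1))),
       n_samples = as.integer(seg_n))
}

# Hamming-windowed periodogram band powers of one segment matrix
# (channels x samples); returns channels x n_bands. Band-edge bins are
# inclusive; when bands abut, the shared bin belongs to the lower band.
segment_band_power <- function(X, rate, bands) {
  n <- ncol(X)
  w <- signal::hamming(n)
  Xw <- X * matrix(w, nrow(X), n, byrow = TRUE)
  spec <- Mod(t(stats::mvfft(t(Xw))))^2 / sum(w^2)
  freqs <- (seq_len(n) - 1) / n * rate
  out <- matrix(0, nrow(X), nrow(bands))
  upper_used <- -Inf
  for (b in seq_len(nrow(bands))) {
    lo <- bands$low[b]
    sel <- freqs >= lo & freqs <= bands$high[b] & freqs > upper_used
    if (!any(sel)) stopf("band %s (%g-%g Hz) contains no frequency bins",
                         bands$name[b], bands$low[b], bands$high[b])
    out[, b] <- rowMeans(spec[, sel, drop = FALSE])
    upper_used <- bands$high[b]
  }
  out
}

#' Spectral band-power features
#'
#' Per trial: 1 s Hamming-windowed FFT periodograms on 50 percent
#' overlapping segments, averaged over segments, then averaged over the
#' frequency bins of each band. With the default five bands and the full
#' 19-channel montage this yields 95 power features per trial
#' (electrode-major, band-minor ordering: `C3_theta, C3_alpha, ...`), to
#' which [asymmetry()] appends 5 inter-hemispheric ratios.
#'
#' @param ep An [eeg_epochs()].
#' @param bands Band table (`name`, `low`, `high`); default
#'   [standard_bands()].
#' @param seg_len,overlap Segmentation parameters (see [segment_epoch()]).
#' @param hemispheres Hemisphere map for the asymmetry features; default
#'   [hemisphere_map()].
#' @return Object of class `bandpower_features`: list with `vectors`
#'   (trials x (powers + ratios)), `power` (trials x channels x bands
#'   array), `bands`, `hemispheres`, `labels`, `channel_labels`,
#'   `feature_names`, `trial_meta`.
#' @export
band_powers <- function(ep, bands = standard_bands(), seg_len = 1,
                        overlap = 0.5, hemispheres = hemisphere_map()) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (any(bands$low >= bands$high) || any(bands$low <= 0) ||
      any(bands$high >= ep$rate / 2)) {
    stopf("bands must satisfy 0 < low < high < Nyquist")
  }
  seg <- segment_epoch(ep, seg_len, overlap)
  dm <- dim(ep$data)
  pow <- array(0, dim = c(dm[3], dm[1], nrow(bands)))
  for (i in seq_len(dm[3])) {
    acc <- matrix(0, dm[1], nrow(bands))
    for (s0 in seg$starts) {
      X <- ep$data[, (s0 + 1L):(s0 + seg$n_samples), i, drop = FALSE]
      dim(X) <- c(dm[1], seg$n_samples)
      acc <- acc + segment_band_power(X, ep$rate, bands)
    }
    pow[i, , ] <- acc / length(seg$starts)
  }
  feats <- build_bp_features(pow, ep$channel_labels, bands, hemispheres)
  structure(list(vectors = feats$vectors, power = pow, bands = bands,
                 hemispheres = hemispheres, labels = ep$labels,
                 channel_labels = ep$channel_labels,
                 feature_names = feats$names, trial_meta = ep$trial_meta),
            class = "bandpower_features")
}

# Assemble the flat feature matrix (powers then asymmetry ratios) from the
# trials x channels x bands power array.
build_bp_features <- function(pow, channel_labels, bands, hemispheres) {
  n_tr <- dim(pow)[1]; n_ch <- dim(pow)[2]; n_b <- dim(pow)[3]
  V <- matrix(0, n_tr, n_ch * n_b)
  nm <- character(n_ch * n_b)
  k <- 0L
  for (ch in seq_len(n_ch)) {
    for (b in seq_len(n_b)) {
      k <- k + 1L
      V[, k] <- pow[, ch, b]
      nm[k] <- paste0(channel_labels[ch], "_", bands$name[b])
    }
  }
  li <- match(intersect(hemispheres$left, channel_labels), channel_labels)
  ri <- match(intersect(hemispheres$right, channel_labels), channel_labels)
  if (length(li) && length(ri)) {
    A <- matrix(0, n_tr, n_b)
    for (b in seq_len(n_b)) {
      L <- rowMeans(pow[, li, b, drop = FALSE])
      R <- rowMeans(pow[, ri, b, drop = FALSE])
      tot <- R + L
      bad <- tot <= 0
      if (any(bad)) warnf("zero hemispheric power in band %s; ratio set to 0", bands$name[b])
      A[, b] <- ifelse(bad, 0, (R - L) / tot)
    }
    V <- cbind(V, A)
    nm <- c(nm, paste0("asym_", bands$name))
  }
  list(vectors = V, names = nm)
}

#' @export
print.bandpower_features <- function(x, ...) {
  cat(sprintf("<bandpower_features: %d trial(s) x %d features (%d channels x %d bands + %d ratios)>\n",
              nrow(x$vectors), ncol(x$vectors), length(x$channel_labels),
              nrow(x$bands), ncol(x$vectors) - length(x$channel_labels) * nrow(x$bands)))
  invisible(x)
}

#' Inter-hemispheric asymmetry ratios
#'
#' Per band, `(R - L) / (R + L)` where `R` and `L` are the band powers
#' averaged over the right- and left-hemisphere electrodes. These ratios
#' are already included in [band_powers()] vectors; this accessor returns
#' them alone (trials x bands).
#'
#' @param feat A `bandpower_features` object.
#' @return Trials x bands matrix of ratios in `[-1, 1]`.
#' @export
asymmetry <- function(feat) {
  stopifnot(inherits(feat, "bandpower_features"))
  n_b <- nrow(feat$bands)
  n_pow <- length(feat$channel_labels) * n_b
  if (ncol(feat$vectors) == n_pow) stopf("no asymmetry features present (hemisphere map empty)")
  out <- feat$vectors[, (n_pow + 1):(n_pow + n_b), drop = FALSE]
  colnames(out) <- paste0("asym_", feat$bands$name)
  out
}

#' Export band-power features
#'
#' @param feat A `bandpower_features` object.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_bandpower_csv <- function(feat, path) {
  stopifnot(inherits(feat, "bandpower_features"))
  df <- data.frame(trial_id = feat$trial_meta$trial, label = feat$labels)
  V <- as.data.frame(feat$vectors)
  names(V) <- feat$feature_names
  utils::write.csv(cbind(df, V), path, row.names = FALSE)
  invisible(path)
}

# Leave-one-out 1-nearest-neighbour error on standardized features.
# Deterministic: distance ties resolve to the lowest trial index.
knn1_loo_error <- function(V, labels) {
  V <- as.matrix(V)
  mu <- colMeans(V)
  sd_ <- apply(V, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Z <- sweep(sweep(V, 2, mu), 2, sd_, "/")
  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  mean(labels[nn] != labels)
}

#' Sequential floating forward feature selection
#'
#' Greedy forward selection with conditional backward steps, using the
#' leave-one-out 1-nearest-neighbour error on standardized features as the
#' criterion. At each step the feature whose addition minimizes the
#' criterion is added (ties broken by the lowest feature index); after each
#' addition, any feature whose removal strictly improves on the best
#' criterion previously seen at that subset size is floated out. Selection
#' stops at `max_k` features, when the criterion reaches zero, or when no
#' addition strictly improves it. Fully deterministic.
#'
#' @param vectors Trials x features matrix.
#' @param labels Class labels.
#' @param max_k Maximum subset size (default 10, guarding against
#'   over-fitting on small trial counts).
#' @return Sorted integer vector of selected feature indices.
#' @export
sffs_select <- function(vectors, labels, max_k = 10L) {
  if (max_k < 1L) stopf("max_k must be >= 1")
  vectors <- as.matrix(vectors)
  labels <- as.character(labels)
  if (nrow(vectors) < 4L) stopf("need at least 4 trials for SFFS")
  p <- ncol(vectors)
  selected <- integer(0)
  current <- Inf
  best_at_size <- rep(Inf, min(max_k, p))
  repeat {
    if (length(selected) >= min(max_k, p)) break
    cand <- setdiff(seq_len(p), selected)
    errs <- vapply(cand, function(j)
      knn1_loo_error(vectors[, c(selected, j), drop = FALSE], labels), 0)
    best <- min(errs)
    if (length(selected) && best >= current) break   # no strict improvement
    j <- cand[which(abs(errs - best) < 1e-15)[1]]    # lowest index on ties
    selected <- c(selected, j)
    current <- best
    k <- length(selected)
    if (current < best_at_size[k]) best_at_size[k] <- current
    # conditional backward (floating) steps
    while (length(selected) > 2L) {
      rem_errs <- vapply(seq_along(selected), function(i)
        knn1_loo_error(vectors[, selected[-i], drop = FALSE], labels), 0)
      rb <- min(rem_errs)
      k1 <- length(selected) - 1L
      if (rb < best_at_size[k1]) {
        i <- which(abs(rem_errs - rb) < 1e-15)[1]
        selected <- selected[-i]
        current <- rb
        best_at_size[k1] <- rb
      } else break
    }
    if (current == 0) break
  }
  sort(selected)
}

#' Linear support vector machine
#'
#' Soft-margin linear SVM (`C = 1`) on features standardized by training
#' statistics; a thin wrapper shaping [e1071::svm()] to the package's
#' fit/predict conventions.
#'
#' @param vectors Trials x features matrix.
#' @param labels Two-class labels.
#' @param cost Soft-margin penalty.
#' @return Object of class `svm_model`.
#' @export
svm_fit <- function(vectors, labels, cost = 1) {
  labels <- as.character(labels)
  if (length(unique(labels)) != 2L) stopf("SVM here is two-class")
  vectors <- as.matrix(vectors)
  mu <- colMeans(vectors)
  sd_ <- apply(vectors, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Z <- sweep(sweep(vectors, 2, mu), 2, sd_, "/")
  fit <- e1071::svm(Z, factor(labels), kernel = "linear", cost = cost,
                    scale = FALSE)
  structure(list(fit = fit, center = mu, scale = sd_),
            class = "svm_model")
}

#' @rdname svm_fit
#' @param model An `svm_model`.
#' @export
svm_predict <- function(model, vectors) {
  stopifnot(inherits(model, "svm_model"))
  Z <- sweep(sweep(as.matrix(vectors), 2, model$center), 2, model$scale, "/")
  as.character(stats::predict(model$fit, Z))
}
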