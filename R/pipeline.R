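#' Classification pipeline specification
#'
#' Declares one of the two classification frameworks:
#'
#' * `"riemann"`: trial spatial covariance matrices, tangent-space mapping
#'   at the Riemannian mean of the training trials, one-way ANOVA variable
#'   screening, then a linear classifier (LDA by default).
#' * `"bandpower"`: five-band spectral powers per electrode plus
#'   inter-hemispheric asymmetry ratios, sequential floating forward
#'   selection (1-NN criterion, at most `max_k` features), then LDA or a
#'   linear SVM.
#'
#' The pipeline object only stores configuration; [bci_train()] fits it to
#' data, and every evaluation protocol (see [loocv()]) refits it - including
#' the tangent reference and the feature selection - inside each training
#' fold.
#'
#' @param method `"riemann"` or `"bandpower"`.
#' @param classifier `"lda"` or `"svm"` (back-end for the feature vectors).
#' @param alpha ANOVA screening level (riemann method).
#' @param max_k SFFS feature cap (bandpower method).
#' @param bands,hemispheres Band table and hemisphere map (bandpower
#'   method).
#' @param mean_tol,mean_max_iter Riemannian-mean convergence controls.
#' @return Object of class `bci_pipeline`.
#' @export
bci_pipeline <- function(method = c("riemann", "bandpower"),
                         classifier = c("lda", "svm"),
                         alpha = 0.05, max_k = 10L,
                         bands = standard_bands(),
                         hemispheres = hemisphere_map(),
                         mean_tol = 1e-9, mean_max_iter = 50L) {
  method <- match.arg(method)
  classifier <- match.arg(classifier)
  structure(list(method = method, classifier = classifier, alpha = alpha,
                 max_k = as.integer(max_k), bands = bands,
                 hemispheres = hemispheres, mean_tol = mean_tol,
                 mean_max_iter = as.integer(mean_max_iter),
                 id = paste(method, classifier, sep = "_")),
            class = "bci_pipeline")
}

#' @export
print.bci_pipeline <- function(x, ...) {
  cat(sprintf("<bci_pipeline '%s'>\n", x$id))
  invisible(x)
}

#' Precompute per-trial features for a pipeline
#'
#' Computes the per-trial descriptors a pipeline needs (covariance matrices
#' or band-power vectors). These are strictly per-trial quantities, so they
#' can be computed once and reused across cross-validation folds and
#' electrode subsets without information leakage; everything that depends
#' on other trials (the tangent reference, feature screening/selection,
#' classifier weights) is refit per fold by [bci_train()].
#'
#' @param pipeline A [bci_pipeline()].
#' @param ep An [eeg_epochs()].
#' @return Object of class `bci_features`.
#' @export
bci_prepare <- function(pipeline, ep) {
  stopifnot(inherits(pipeline, "bci_pipeline"), inherits(ep, "eeg_epochs"))
  base <- list(pipeline = pipeline, labels = ep$labels,
               channel_labels = ep$channel_labels, trial_meta = ep$trial_meta)
  if (pipeline$method == "riemann") {
    base$cov <- scm(ep)
  } else {
    base$bp <- band_powers(ep, pipeline$bands,
                           hemispheres = pipeline$hemispheres)
  }
  structure(base, class = "bci_features")
}

#' @export
print.bci_features <- function(x, ...) {
  cat(sprintf("<bci_features (%s): %d trial(s)>\n", x$pipeline$id,
              length(x$labels)))
  invisible(x)
}

# Restrict prepared features to a subset of trials and/or channels.
subset_features <- function(feats, trials = NULL, channels = NULL) {
  stopifnot(inherits(feats, "bci_features"))
  ti <- if (is.null(trials)) seq_along(feats$labels) else trials
  out <- feats
  out$labels <- feats$labels[ti]
  out$trial_meta <- feats$trial_meta[ti, , drop = FALSE]
  if (!is.null(feats$cov)) {
    ci <- if (is.null(channels)) NULL else channels
    out$cov <- subset_cov(feats$cov, trials = ti, channels = ci)
    if (!is.null(ci)) out$channel_labels <- feats$channel_labels[ci]
  } else {
    bp <- feats$bp
    pow <- bp$power[ti, , , drop = FALSE]
    ch_labels <- feats$channel_labels
    if (!is.null(channels)) {
      pow <- pow[, channels, , drop = FALSE]
      ch_labels <- ch_labels[channels]
      out$channel_labels <- ch_labels
    }
    fb <- build_bp_features(pow, ch_labels, bp$bands, bp$hemispheres)
    bp$power <- pow
    bp$vectors <- fb$vectors
    bp$feature_names <- fb$names
    bp$labels <- feats$labels[ti]
    bp$channel_labels <- ch_labels
    bp$trial_meta <- out$trial_meta
    out$bp <- bp
  }
  out
}

#' Fit a classification pipeline
#'
#' Fits the full pipeline on training data: for the Riemannian method,
#' covariance extraction, Riemannian mean of the training trials as tangent
#' reference, tangent-space mapping, ANOVA screening and the linear
#' classifier; for the band-power method, feature extraction, SFFS on the
#' training trials only, and the classifier. The returned model freezes the
#' reference, the selected variables and the classifier for prediction on
#' new epochs.
#'
#' @param x Training data: an [eeg_epochs()] or a [bci_prepare()] result.
#' @param pipeline A [bci_pipeline()]; ignored (taken from `x`) when `x` is
#'   already prepared.
#' @return Object of class `bci_model`.
#' @export
bci_train <- function(x, pipeline = bci_pipeline()) {
  feats <- if (inherits(x, "bci_features")) x else bci_prepare(pipeline, x)
  pipeline <- feats$pipeline
  labels <- feats$labels
  if (length(unique(labels)) < 2L) stopf("training data must contain both classes")
  if (pipeline$method == "riemann") {
    ref <- riemann_mean(feats$cov$matrices, tol = pipeline$mean_tol,
                        max_iter = pipeline$mean_max_iter)
    tf <- tangent_map(feats$cov, ref)
    sel <- anova_select(tf$vectors, labels, pipeline$alpha)
    V <- tf$vectors[, sel, drop = FALSE]
    core <- list(reference = ref, selected = sel)
  } else {
    V_all <- feats$bp$vectors
    sel <- sffs_select(V_all, labels, pipeline$max_k)
    V <- V_all[, sel, drop = FALSE]
    core <- list(selected = sel,
                 feature_names = feats$bp$feature_names[sel])
  }
  clf <- if (pipeline$classifier == "lda") lda_fit(V, labels) else svm_fit(V, labels)
  structure(c(core, list(classifier = clf, pipeline = pipeline,
                         channel_labels = feats$channel_labels,
                         classes = sort(unique(labels)))),
            class = "bci_model")
}

#' @export
print.bci_model <- function(x, ...) {
  cat(sprintf("<bci_model '%s': classes %s, %d feature(s) selected>\n",
              x$pipeline$id, paste(x$classes, collapse = " vs "),
              length(x$selected)))
  invisible(x)
}

#' @export
summary.bci_model <- function(object, ...) {
  print(object)
  if (!is.null(object$feature_names)) {
    cat("  selected features:", paste(object$feature_names, collapse = ", "), "\n")
  } else {
    cat(sprintf("  tangent dimension: %d; selected indices: %s\n",
                length(object$channel_labels) * (length(object$channel_labels) + 1) / 2,
                paste(utils::head(object$selected, 10), collapse = ", ")))
  }
  invisible(object)
}

#' Predict task labels for new epochs
#'
#' @param object A [bci_train()] model.
#' @param newdata An [eeg_epochs()] or [bci_prepare()] result (prepared
#'   with the same pipeline).
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.bci_model <- function(object, newdata, ...) {
  feats <- if (inherits(newdata, "bci_features")) newdata
           else bci_prepare(object$pipeline, newdata)
  if (!identical(feats$channel_labels, object$channel_labels)) {
    stopf("channel montage of new data does not match the fitted model")
  }
  if (object$pipeline$method == "riemann") {
    tf <- tangent_map(feats$cov, object$reference)
    V <- tf$vectors[, object$selected, drop = FALSE]
  } else {
    V <- feats$bp$vectors[, object$selected, drop = FALSE]
  }
  if (object$pipeline$classifier == "lda") {
    lda_predict(object$classifier, V)
  } else {
    svm_predict(object$classifier, V)
  }
}
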