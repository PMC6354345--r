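new_eval_report <- function(true, predicted, run, pipeline_id, config, seed = NA) {
  correct <- true == predicted
  per_trial <- data.frame(true = true, predicted = predicted,
                          correct = correct, run = run,
                          stringsAsFactors = FALSE)
  runs <- sort(unique(run[!is.na(run)]))
  per_run <- data.frame(
    run = runs,
    accuracy = vapply(runs, function(r) mean(correct[!is.na(run) & run == r]), 0),
    n = vapply(runs, function(r) sum(!is.na(run) & run == r), 0L))
  structure(list(per_trial = per_trial, per_run = per_run,
                 accuracy = mean(correct), pipeline_id = pipeline_id,
                 config_hash = config_hash(config), seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report '%s': overall accuracy %.1f%% (%d trials)>\n",
              x$pipeline_id, 100 * x$accuracy, nrow(x$per_trial)))
  if (nrow(x$per_run) > 1) {
    cat("  per-run:", paste(sprintf("%.0f%%", 100 * x$per_run$accuracy),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' For every trial, the complete pipeline - including the Riemannian
#' tangent reference and the ANOVA/SFFS feature selection - is refit on the
#' remaining trials and the held-out trial is predicted. Per-trial
#' descriptors (covariances, band powers) are computed once up front, which
#' is leak-free because they involve no other trials.
#'
#' @param x An [eeg_epochs()] or [bci_prepare()] result.
#' @param pipeline A [bci_pipeline()] (ignored when `x` is prepared).
#' @return An `eval_report` with per-trial predictions, per-run and overall
#'   accuracy, plus a `fold_selected` attribute listing the feature indices
#'   selected in each fold.
#' @export
loocv <- function(x, pipeline = bci_pipeline()) {
  feats <- if (inherits(x, "bci_features")) x else bci_prepare(pipeline, x)
  n <- length(feats$labels)
  if (min(table(feats$labels)) < 2L) stopf("need >= 2 trials per class")
  preds <- character(n)
  fold_selected <- vector("list", n)
  for (i in seq_len(n)) {
    model <- tryCatch(bci_train(subset_features(feats, trials = setdiff(seq_len(n), i))),
                      error = function(e) stopf("pipeline failed on fold %d: %s",
                                                i, conditionMessage(e)))
    preds[i] <- predict(model, subset_features(feats, trials = i))
    fold_selected[[i]] <- model$selected
  }
  rep_ <- new_eval_report(feats$labels, preds, feats$trial_meta$run,
                          feats$pipeline$id,
                          config = feats$pipeline[c("method", "classifier",
                                                    "alpha", "max_k")])
  attr(rep_, "fold_selected") <- fold_selected
  rep_
}

#' Pairwise task-combination comparison
#'
#' LOOCV accuracy for every requested pair of tasks and every pipeline,
#' plus the across-pipeline average (the task-combination bar chart of the
#' offline analysis).
#'
#' @param ep An [eeg_epochs()] containing all named tasks.
#' @param task_pairs List of length-2 character vectors; default: all pairs
#'   of the labels present.
#' @param pipelines Named list of [bci_pipeline()] objects.
#' @return Data frame with one row per pair: `task_a`, `task_b`, one
#'   accuracy column per pipeline, and `mean_accuracy`.
#' @export
pairwise_task_comparison <- function(ep, task_pairs = NULL,
                                     pipelines = list(rg = bci_pipeline("riemann"))) {
  stopifnot(inherits(ep, "eeg_epochs"))
  tasks <- unique(ep$labels)
  if (is.null(task_pairs)) {
    task_pairs <- utils::combn(sort(tasks), 2, simplify = FALSE)
  }
  for (pair in task_pairs) {
    if (!all(pair %in% tasks)) {
      stopf("task(s) not present: %s", paste(setdiff(pair, tasks), collapse = ", "))
    }
  }
  if (is.null(names(pipelines))) names(pipelines) <- paste0("pipeline", seq_along(pipelines))
  rows <- lapply(task_pairs, function(pair) {
    sub <- subset_epochs(ep, trials = ep$labels %in% pair)
    accs <- vapply(pipelines, function(pl) loocv(sub, pl)$accuracy, 0)
    out <- data.frame(task_a = pair[1], task_b = pair[2],
                      stringsAsFactors = FALSE)
    for (nm in names(accs)) out[[nm]] <- accs[[nm]]
    out$mean_accuracy <- mean(accs)
    out
  })
  do.call(rbind, rows)
}

#' Accuracy as a function of electrode count
#'
#' For each montage size `k`, evaluates the LOOCV accuracy on channel
#' subsets of that size and averages. All subsets are enumerated when there
#' are at most `max_subsets` of them; otherwise `max_subsets` distinct
#' subsets are drawn by seeded sampling.
#'
#' @param x An [eeg_epochs()] or [bci_prepare()] result.
#' @param pipeline A [bci_pipeline()].
#' @param sizes Electrode counts to evaluate.
#' @param max_subsets Cap on subsets per size.
#' @param seed Integer seed for subset sampling.
#' @return Data frame with columns `size`, `mean_accuracy`, `n_subsets`.
#' @export
electrode_curve <- function(x, pipeline = bci_pipeline(), sizes = NULL,
                            max_subsets = 100L, seed = 1L) {
  feats <- if (inherits(x, "bci_features")) x else bci_prepare(pipeline, x)
  n_ch <- length(feats$channel_labels)
  if (is.null(sizes)) sizes <- seq_len(n_ch)
  if (any(sizes > n_ch)) stopf("requested size exceeds %d channels", n_ch)
  rows <- lapply(sizes, function(k) {
    n_comb <- choose(n_ch, k)
    subsets <- if (n_comb <= max_subsets) {
      utils::combn(n_ch, k, simplify = FALSE)
    } else {
      with_rng(derive_seed(seed, paste0("electrodes", k)), {
        seen <- new.env()
        out <- list()
        while (length(out) < max_subsets) {
          s <- sort(sample.int(n_ch, k))
          key <- paste(s, collapse = ",")
          if (is.null(seen[[key]])) {
            seen[[key]] <- TRUE
            out[[length(out) + 1L]] <- s
          }
        }
        out
      })
    }
    accs <- vapply(subsets, function(s)
      loocv(subset_features(feats, channels = s))$accuracy, 0)
    data.frame(size = k, mean_accuracy = mean(accs), n_subsets = length(subsets))
  })
  do.call(rbind, rows)
}

#' Simulated online run
#'
#' Fits the pipeline once on the training session, then predicts each test
#' trial in chronological order, emitting the per-trial feedback record and
#' per-run accuracies of an online session.
#'
#' @param train_ep,test_ep Training and test [eeg_epochs()] (or prepared
#'   features from the same pipeline).
#' @param pipeline A [bci_pipeline()].
#' @return An `eval_report`; `per_run` holds one accuracy per test run.
#' @export
online_simulation <- function(train_ep, test_ep, pipeline = bci_pipeline()) {
  tr <- if (inherits(train_ep, "bci_features")) train_ep else bci_prepare(pipeline, train_ep)
  te <- if (inherits(test_ep, "bci_features")) test_ep else bci_prepare(pipeline, test_ep)
  unseen <- setdiff(unique(te$labels), unique(tr$labels))
  if (length(unseen)) stopf("test contains class(es) unseen in training: %s",
                            paste(unseen, collapse = ", "))
  model <- bci_train(tr)
  ord <- order(te$trial_meta$trial)
  preds <- character(length(te$labels))
  for (i in ord) {   # trial-wise, as delivered online
    preds[i] <- predict(model, subset_features(te, trials = i))
  }
  new_eval_report(te$labels, preds, te$trial_meta$run, tr$pipeline$id,
                  config = tr$pipeline[c("method", "classifier", "alpha", "max_k")])
}

#' Test-retest evaluation with stale and combined training sets
#'
#' Evaluates the same test session against three models: trained on an old
#' session (e.g. recorded months earlier), on the new session, and on the
#' concatenation of both.
#'
#' @param old_train,new_train,test [eeg_epochs()] with identical montages.
#' @param pipeline A [bci_pipeline()].
#' @return Named list of three `eval_report`s: `old`, `new`, `combined`.
#' @export
test_retest <- function(old_train, new_train, test, pipeline = bci_pipeline()) {
  for (ep in list(old_train, new_train, test)) stopifnot(inherits(ep, "eeg_epochs"))
  if (n_trials(old_train) == 0L) stopf("old training set is empty")
  if (n_trials(new_train) == 0L) stopf("new training set is empty")
  if (!identical(old_train$channel_labels, new_train$channel_labels) ||
      !identical(old_train$channel_labels, test$channel_labels)) {
    stopf("montage mismatch between training and test sets")
  }
  combined <- bind_epochs(old_train, new_train)
  list(old = online_simulation(old_train, test, pipeline),
       new = online_simulation(new_train, test, pipeline),
       combined = online_simulation(combined, test, pipeline))
}

#' Concatenate epoch sets
#'
#' @param a,b [eeg_epochs()] with identical window, rate and montage.
#' @return The combined `eeg_epochs`.
#' @export
bind_epochs <- function(a, b) {
  stopifnot(inherits(a, "eeg_epochs"), inherits(b, "eeg_epochs"))
  if (!identical(a$channel_labels, b$channel_labels) ||
      !isTRUE(all.equal(a$window, b$window)) || a$rate != b$rate) {
    stopf("epoch sets are not compatible (window/rate/montage differ)")
  }
  dat <- array(c(a$data, b$data),
               dim = c(dim(a$data)[1], dim(a$data)[2],
                       dim(a$data)[3] + dim(b$data)[3]))
  eeg_epochs(dat, a$window, a$rate, c(a$labels, b$labels), a$channel_labels,
             rbind(a$trial_meta, b$trial_meta))
}

#' Chance-level accuracy bound for a binary classifier
#'
#' Upper confidence bound on the accuracy achievable by guessing, for `n`
#' trials at the given confidence level. `"wald"` uses the normal
#' approximation `0.5 + z * sqrt(0.25 / n)`; `"exact_binomial"` returns the
#' smallest `k/n` whose upper binomial tail under `p = 0.5` falls below
#' `(1 - confidence) / 2`.
#'
#' @param n_trials Number of test trials.
#' @param confidence Confidence level in (0, 1).
#' @param method `"wald"` or `"exact_binomial"`.
#' @return Accuracy bound as a fraction.
#' @export
chance_level <- function(n_trials, confidence = 0.99,
                         method = c("wald", "exact_binomial")) {
  method <- match.arg(method)
  if (n_trials < 1L) stopf("n_trials must be >= 1")
  if (confidence <= 0 || confidence >= 1) stopf("confidence must be in (0, 1)")
  tail_p <- (1 - confidence) / 2
  if (method == "wald") {
    0.5 + stats::qnorm(1 - tail_p) * sqrt(0.25 / n_trials)
  } else {
    for (k in 0:n_trials) {
      if (stats::pbinom(k - 1, n_trials, 0.5, lower.tail = FALSE) < tail_p) {
        return(k / n_trials)
      }
    }
    1
  }
}

#' Export an evaluation report
#'
#' Writes the per-trial table to CSV and the summary (overall and per-run
#' accuracies, pipeline id, config hash, seed) to JSON.
#'
#' @param report An `eval_report`.
#' @param csv_path,json_path Output paths (`NULL` skips the file).
#' @return The report, invisibly.
#' @export
write_eval_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  if (!is.null(csv_path)) {
    utils::write.csv(report$per_trial, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    writeLines(jsonlite::toJSON(list(
      pipeline_id = report$pipeline_id, accuracy = report$accuracy,
      per_run = report$per_run, config_hash = report$config_hash,
      seed = report$seed), auto_unbox = TRUE, digits = NA, null = "null"),
      json_path)
  }
  invisible(report)
}
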