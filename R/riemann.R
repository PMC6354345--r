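# --- SPD primitives -------------------------------------------------------

sym <- function(P) (P + t(P)) / 2

# Eigen-based matrix function of a symmetric matrix.
spd_fun <- function(P, f) {
  e <- eigen(sym(P), symmetric = TRUE)
  sym(e$vectors %*% (f(e$values) * t(e$vectors)))
}

spd_sqrt <- function(P) spd_fun(P, sqrt)
spd_invsqrt <- function(P) spd_fun(P, function(v) 1 / sqrt(v))
spd_log <- function(P) spd_fun(P, log)
spd_exp <- function(P) spd_fun(P, exp)

min_eigval <- function(P) min(eigen(sym(P), symmetric = TRUE, only.values = TRUE)$values)

check_spd <- function(P, name = "matrix", tol = 0) {
  mev <- min_eigval(P)
  if (mev <= tol) {
    stopf("%s is not symmetric positive-definite (minimum eigenvalue %.3e)",
          name, mev)
  }
  invisible(mev)
}

# Add eps*trace/n*I, escalating tenfold until the matrix is numerically SPD
# (smallest eigenvalue above rel_floor times the mean diagonal). Needed after
# common-average referencing, which leaves every trial covariance with an
# exact null direction shared across trials.
condition_spd <- function(P, eps = 1e-10, rel_floor = 1e-12, max_tries = 12L) {
  P <- sym(P)
  n <- nrow(P)
  base <- max(sum(diag(P)) / n, .Machine$double.eps)
  if (min_eigval(P) > rel_floor * base) return(P)
  for (k in seq_len(max_tries)) {
    Pc <- P + eps * base * diag(n)
    if (min_eigval(Pc) > rel_floor * base) return(Pc)
    eps <- eps * 10
  }
  stopf("could not condition matrix to SPD")
}

#' Trial spatial covariance matrices
#'
#' Per trial, the sample spatial covariance `X X' / (N_t - 1)` of the
#' (already mean-free, band-pass filtered) channels x samples matrix `X`.
#' Matrices are symmetrized and, if a trial is rank-deficient (fewer
#' samples than channels), conditioned to positive definiteness by adding a
#' small multiple of the identity.
#'
#' @param ep An [eeg_epochs()].
#' @return Object of class `cov_set`: list with `matrices` (channels x
#'   channels x trials array), `labels`, `channel_labels`, `trial_meta`.
#' @export
scm <- function(ep) {
  stopifnot(inherits(ep, "eeg_epochs"))
  dm <- dim(ep$data)
  if (dm[2] <= dm[1]) {
    warnf("trials have %d samples for %d channels; covariances conditioned to SPD",
          dm[2], dm[1])
  }
  mats <- array(0, dim = c(dm[1], dm[1], dm[3]))
  for (i in seq_len(dm[3])) {
    X <- ep$data[, , i]
    P <- sym(tcrossprod(X) / (dm[2] - 1))
    # rel_floor 1e-5: a ~0.001% diagonal ridge, enough to keep the
    # eigendecompositions of CAR-referenced (rank-deficient) covariances
    # accurate for the log/exp maps and the mean iteration.
    mats[, , i] <- condition_spd(P, rel_floor = 1e-5)
  }
  dimnames(mats) <- list(ep$channel_labels, ep$channel_labels, NULL)
  structure(list(matrices = mats, labels = ep$labels,
                 channel_labels = ep$channel_labels,
                 trial_meta = ep$trial_meta),
            class = "cov_set")
}

#' @export
print.cov_set <- function(x, ...) {
  cat(sprintf("<cov_set: %d trial(s) of %d x %d SPD matrices>\n",
              dim(x$matrices)[3], dim(x$matrices)[1], dim(x$matrices)[2]))
  invisible(x)
}

#' Subset a covariance set
#'
#' Restricts a `cov_set` to a subset of trials and/or channels. A principal
#' submatrix of an SPD matrix is SPD, so electrode-subset analyses reuse
#' the full-montage covariances directly.
#'
#' @param cov A `cov_set` from [scm()].
#' @param trials Trial indices (or logical mask).
#' @param channels Channel indices (or logical mask).
#' @return The subset `cov_set`.
#' @export
subset_cov <- function(cov, trials = NULL, channels = NULL) {
  ti <- if (is.null(trials)) seq_len(dim(cov$matrices)[3]) else trials
  ci <- if (is.null(channels)) seq_along(cov$channel_labels) else channels
  structure(list(matrices = cov$matrices[ci, ci, ti, drop = FALSE],
                 labels = cov$labels[ti],
                 channel_labels = cov$channel_labels[ci],
                 trial_meta = cov$trial_meta[ti, , drop = FALSE]),
            class = "cov_set")
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' `sqrt(sum_i log^2 lambda_i)` with `lambda_i` the eigenvalues of
#' `P1^-1 P2` (computed as a symmetric generalized eigenvalue problem via
#' Cholesky whitening).
#'
#' @param P1,P2 SPD matrices of equal size.
#' @return Non-negative scalar distance.
#' @export
riemann_distance <- function(P1, P2) {
  if (!all(dim(P1) == dim(P2))) stopf("matrices must have equal size")
  check_spd(P1, "P1")
  check_spd(P2, "P2")
  R <- chol(sym(P1))                        # P1 = R'R
  Ri <- backsolve(R, diag(nrow(R)))
  S <- sym(t(Ri) %*% P2 %*% Ri)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(ev)^2))
}

#' Riemannian (geometric/Karcher) mean of SPD matrices
#'
#' The minimizer of the summed squared affine-invariant distances, computed
#' by fixed-point iteration in the tangent space: starting from the
#' arithmetic mean, repeatedly map all matrices to the tangent space at the
#' current estimate, average, and map back, halving the step when the
#' objective increases. Converged when the Frobenius norm of the tangent
#' mean falls below `tol`.
#'
#' @param mats List of SPD matrices, or the channels x channels x trials
#'   array of a `cov_set`.
#' @param tol Convergence tolerance on the tangent-mean norm.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   final gradient norm.
#' @return The SPD mean matrix.
#' @export
riemann_mean <- function(mats, tol = 1e-9, max_iter = 50L) {
  if (is.array(mats) && length(dim(mats)) == 3L) {
    mats <- lapply(seq_len(dim(mats)[3]), function(i) mats[, , i])
  }
  M <- length(mats)
  if (M == 0L) stopf("empty matrix set")
  for (i in seq_len(M)) check_spd(mats[[i]], sprintf("matrix %d", i))
  if (M == 1L) return(sym(mats[[1]]))
  est <- sym(Reduce(`+`, mats) / M)
  step <- 1
  prev_nrm <- Inf
  nrm <- Inf
  for (it in seq_len(max_iter)) {
    Eis <- spd_invsqrt(est)
    Es <- spd_sqrt(est)
    Tm <- Reduce(`+`, lapply(mats, function(P) spd_log(Eis %*% P %*% Eis))) / M
    nrm <- norm(Tm, "F")
    if (nrm < tol) return(est)
    if (nrm > prev_nrm) step <- max(step / 2, 1 / 64)  # diverging: damp
    est <- sym(Es %*% spd_exp(step * Tm) %*% Es)
    prev_nrm <- nrm
  }
  stopf("Riemannian mean did not converge in %d iterations (gradient norm %.3e)",
        max_iter, nrm)
}

# Half-vectorization with sqrt(2) off-diagonal weighting: the Euclidean norm
# of the vector equals the Frobenius norm of the symmetric matrix.
vech_weighted <- function(L) {
  idx <- upper.tri(L, diag = FALSE)
  c(diag(L), sqrt(2) * L[idx])
}

#' Tangent-space mapping of covariance trials
#'
#' Maps every SPD matrix to the tangent space at the reference point
#' (normally the Riemannian mean of the training trials):
#' `L_i = logm(ref^-1/2 P_i ref^-1/2)`, then half-vectorizes `L_i` with
#' off-diagonal entries weighted by `sqrt(2)` so the Euclidean vector norm
#' equals the affine-invariant distance from the reference. The feature
#' dimension is `S = n (n + 1) / 2` for `n` channels.
#'
#' @param cov A `cov_set` from [scm()].
#' @param reference SPD reference matrix.
#' @return Object of class `tangent_features`: list with `vectors`
#'   (trials x S matrix), `reference`, `labels`, `selected` (initially all
#'   columns), `n_channels`.
#' @export
tangent_map <- function(cov, reference) {
  stopifnot(inherits(cov, "cov_set"))
  n <- dim(cov$matrices)[1]
  if (!all(dim(reference) == c(n, n))) {
    stopf("reference is %d x %d but covariances are %d x %d",
          nrow(reference), ncol(reference), n, n)
  }
  check_spd(reference, "reference")
  Ris <- spd_invsqrt(reference)
  n_tr <- dim(cov$matrices)[3]
  S <- n * (n + 1) / 2
  V <- matrix(0, n_tr, S)
  for (i in seq_len(n_tr)) {
    L <- spd_log(Ris %*% cov$matrices[, , i] %*% Ris)
    V[i, ] <- vech_weighted(L)
  }
  structure(list(vectors = V, reference = reference, labels = cov$labels,
                 selected = seq_len(S), n_channels = n),
            class = "tangent_features")
}

#' @export
print.tangent_features <- function(x, ...) {
  cat(sprintf("<tangent_features: %d trial(s) x %d (%d selected), %d channels>\n",
              nrow(x$vectors), ncol(x$vectors), length(x$selected),
              x$n_channels))
  invisible(x)
}

#' One-way ANOVA variable screening
#'
#' Per feature, a one-way ANOVA F-test of the class effect; features with
#' `p < alpha` are retained. If no feature passes, the single smallest-p
#' feature is retained so downstream classifiers always receive input.
#'
#' @param vectors Trials x features matrix (or a `tangent_features`).
#' @param labels Class labels (ignored when `vectors` carries its own).
#' @param alpha Per-feature significance level.
#' @return Sorted integer vector of retained feature indices.
#' @export
anova_select <- function(vectors, labels = NULL, alpha = 0.05) {
  if (inherits(vectors, "tangent_features")) {
    labels <- vectors$labels
    vectors <- vectors$vectors
  }
  labels <- as.character(labels)
  classes <- unique(labels)
  k <- length(classes)
  if (k < 2L) stopf("ANOVA screening needs at least 2 classes")
  n <- nrow(vectors)
  grand <- colMeans(vectors)
  ssb <- numeric(ncol(vectors))
  ssw <- numeric(ncol(vectors))
  for (cl in classes) {
    sel <- labels == cl
    m <- colMeans(vectors[sel, , drop = FALSE])
    ssb <- ssb + sum(sel) * (m - grand)^2
    ssw <- ssw + colSums(sweep(vectors[sel, , drop = FALSE], 2, m)^2)
  }
  Fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  Fstat[ssw == 0 & ssb == 0] <- 0
  Fstat[ssw == 0 & ssb > 0] <- Inf
  p <- stats::pf(Fstat, k - 1, n - k, lower.tail = FALSE)
  p[is.nan(p)] <- 1
  keep <- which(p < alpha)
  if (!length(keep)) keep <- which.min(p)
  sort(keep)
}

#' Two-class linear discriminant analysis
#'
#' Standard LDA with pooled within-class covariance. When the pooled
#' covariance is ill-conditioned (condition number above 1e8, e.g. with
#' duplicated features), it is shrunk toward its diagonal by the smallest
#' amount restoring invertibility.
#'
#' @param vectors Trials x features matrix.
#' @param labels Two-class labels.
#' @return Object of class `lda_model` with fields `weights`, `bias`,
#'   `classes`, `means`, `shrinkage`.
#' @export
lda_fit <- function(vectors, labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stopf("LDA here is two-class; got %d class(es)", length(classes))
  vectors <- as.matrix(vectors)
  i1 <- labels == classes[1]; i2 <- labels == classes[2]
  if (sum(i1) < 2L || sum(i2) < 2L) stopf("need >= 2 trials per class")
  m1 <- colMeans(vectors[i1, , drop = FALSE])
  m2 <- colMeans(vectors[i2, , drop = FALSE])
  Sw <- (crossprod(sweep(vectors[i1, , drop = FALSE], 2, m1)) +
           crossprod(sweep(vectors[i2, , drop = FALSE], 2, m2))) /
    (nrow(vectors) - 2)
  shrink <- 0
  for (lam in c(0, 1e-10, 1e-8, 1e-6, 1e-4, 1e-3, 1e-2, 1e-1, 0.5)) {
    D <- diag(pmax(diag(Sw), max(diag(Sw)) * 1e-12), nrow(Sw))
    Ss <- (1 - lam) * Sw + lam * D
    kap <- tryCatch(kappa(Ss, exact = TRUE), error = function(e) Inf)
    if (is.finite(kap) && kap < 1e8) { shrink <- lam; Sw <- Ss; break }
    if (lam == 0.5) { shrink <- lam; Sw <- Ss + max(diag(Ss)) * 1e-6 * diag(nrow(Ss)) }
  }
  w <- solve(Sw, m2 - m1)
  b <- sum(w * (m1 + m2) / 2)
  structure(list(weights = w, bias = b, classes = classes,
                 means = rbind(m1, m2), shrinkage = shrink),
            class = "lda_model")
}

#' @rdname lda_fit
#' @param model An `lda_model`.
#' @export
lda_predict <- function(model, vectors) {
  stopifnot(inherits(model, "lda_model"))
  score <- as.matrix(vectors) %*% model$weights - model$bias
  model$classes[ifelse(score > 0, 2L, 1L)]
}

#' Riemannian distances to the two class means
#'
#' For every trial covariance, the distance to each class-mean covariance;
#' the `dist_a = dist_b` diagonal is the minimum-distance decision border
#' (the manifold scatter plot of the offline analysis).
#'
#' @param cov A `cov_set`.
#' @param mean_a,mean_b Class-mean SPD matrices.
#' @return Data frame with columns `label`, `dist_a`, `dist_b`.
#' @export
distance_scatter <- function(cov, mean_a, mean_b) {
  stopifnot(inherits(cov, "cov_set"))
  n_tr <- dim(cov$matrices)[3]
  da <- vapply(seq_len(n_tr), function(i) riemann_distance(mean_a, cov$matrices[, , i]), 0)
  db <- vapply(seq_len(n_tr), function(i) riemann_distance(mean_b, cov$matrices[, , i]), 0)
  data.frame(label = cov$labels, dist_a = da, dist_b = db,
             stringsAsFactors = FALSE)
}
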