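test_that("trial covariances follow the sample-covariance formula", {
  X <- matrix(c(1, 0, -1, 0, 1, 0), nrow = 2, byrow = TRUE)
  ep <- epochs_from_matrices(list(X), c(0, 3), 1, "a")
  cov <- scm(ep)
  expect_equal(cov$matrices[, , 1], rbind(c(1, 0), c(0, 0.5)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # scaling X by c scales P by c^2
  ep3 <- ep; ep3$data <- ep3$data * 3
  expect_equal(scm(ep3)$matrices, 9 * cov$matrices, tolerance = 1e-6)
  # zero channel: conditioned to SPD, tiny but positive eigenvalue
  X0 <- rbind(c(1, 0, -1), c(0, 0, 0))
  ep0 <- epochs_from_matrices(list(X0), c(0, 3), 1, "a")
  expect_warning(cov0 <- scm(subset_epochs(ep0, channels = 1:2)), NA)
  ev <- eigen(cov0$matrices[, , 1], symmetric = TRUE)$values
  expect_true(all(ev > 0))
  expect_lt(ev[2] / ev[1], 1e-4)
})

test_that("the affine-invariant distance matches its closed forms", {
  set.seed(41)
  P <- rand_spd(4)
  expect_equal(riemann_distance(P, P), 0, tolerance = 1e-7)
  expect_equal(riemann_distance(diag(2), exp(2) * diag(2)), 2 * sqrt(2),
               tolerance = 1e-12)
  # congruence invariance
  P1 <- rand_spd(5); P2 <- rand_spd(5)
  W <- matrix(rnorm(25), 5)
  expect_equal(riemann_distance(W %*% P1 %*% t(W), W %*% P2 %*% t(W)),
               riemann_distance(P1, P2), tolerance = 1e-8)
  bad <- diag(c(1, -1, 1))
  expect_error(riemann_distance(bad, diag(3)), "positive-definite")
  expect_error(riemann_distance(diag(3), diag(2)), "equal size")
})

test_that("distance axioms hold on random SPD triples", {
  set.seed(42)
  for (i in 1:20) {
    A <- rand_spd(4); B <- rand_spd(4); C <- rand_spd(4)
    dab <- riemann_distance(A, B)
    expect_gt(dab, 0)
    expect_equal(dab, riemann_distance(B, A), tolerance = 1e-9)
    expect_lte(dab, riemann_distance(A, C) + riemann_distance(C, B) + 1e-9)
  }
})

test_that("the Riemannian mean matches its closed forms", {
  set.seed(43)
  P <- rand_spd(4)
  expect_equal(riemann_mean(list(P)), P, tolerance = 1e-10)
  expect_equal(riemann_mean(list(diag(2), 4 * diag(2))), 2 * diag(2),
               tolerance = 1e-7)
  # two-matrix mean is the geodesic midpoint
  P1 <- rand_spd(5); P2 <- rand_spd(5)
  P1s <- lockbci:::spd_sqrt(P1); P1is <- lockbci:::spd_invsqrt(P1)
  midpoint <- P1s %*% lockbci:::spd_fun(P1is %*% P2 %*% P1is, sqrt) %*% P1s
  expect_equal(riemann_mean(list(P1, P2)), midpoint, tolerance = 1e-8)
  # congruence equivariance
  mats <- replicate(4, rand_spd(4), simplify = FALSE)
  W <- matrix(rnorm(16), 4)
  m1 <- riemann_mean(lapply(mats, function(P) W %*% P %*% t(W)))
  m2 <- W %*% riemann_mean(mats) %*% t(W)
  expect_equal(m1, m2, tolerance = 1e-7 * norm(m2, "F"))
})

test_that("the mean minimizes the summed squared distances", {
  set.seed(44)
  mats <- replicate(3, rand_spd(3), simplify = FALSE)
  M <- riemann_mean(mats)
  f <- function(M_) sum(vapply(mats, function(P) riemann_distance(M_, P)^2, 0))
  f0 <- f(M)
  for (i in 1:10) {     # random SPD perturbations all increase the objective
    D <- matrix(rnorm(9, sd = 0.05), 3); D <- (D + t(D)) / 2
    Mp <- lockbci:::spd_exp(lockbci:::spd_fun(M, log) + D)
    expect_gt(f(Mp), f0)
  }
})

test_that("tangent mapping is norm-preserving and centred at the mean", {
  set.seed(45)
  mats <- replicate(6, rand_spd(4), simplify = FALSE)
  cov <- structure(list(matrices = array(unlist(mats), c(4, 4, 6)),
                        labels = rep(c("a", "b"), 3),
                        channel_labels = paste0("c", 1:4),
                        trial_meta = data.frame(run = 1, trial = 1:6)),
                   class = "cov_set")
  ref <- riemann_mean(mats)
  tf <- tangent_map(cov, ref)
  expect_equal(ncol(tf$vectors), 10)        # 4 * 5 / 2
  # vector norm equals the distance from the reference
  for (i in 1:6) {
    expect_equal(sqrt(sum(tf$vectors[i, ]^2)),
                 riemann_distance(ref, mats[[i]]), tolerance = 1e-8)
  }
  # first-order centring at the set's own mean
  expect_lt(max(abs(colMeans(tf$vectors))), 1e-6)
  # mapping the reference itself gives the zero vector
  cov1 <- subset_cov(cov, trials = 1)
  cov1$matrices[, , 1] <- ref
  expect_lt(max(abs(tangent_map(cov1, ref)$vectors)), 1e-10)
  expect_error(tangent_map(cov, diag(3)), "reference")
})

test_that("the 19-channel montage yields 190 tangent features", {
  set.seed(46)
  mats <- replicate(3, rand_spd(19), simplify = FALSE)
  cov <- structure(list(matrices = array(unlist(mats), c(19, 19, 3)),
                        labels = c("a", "b", "a"),
                        channel_labels = montage_1020(),
                        trial_meta = data.frame(run = 1, trial = 1:3)),
                   class = "cov_set")
  expect_equal(ncol(tangent_map(cov, diag(19))$vectors), 190)
})

test_that("ANOVA screening keeps discriminant variables", {
  set.seed(47)
  n <- 30
  lab <- rep(c("a", "b"), each = n / 2)
  V <- matrix(rnorm(n * 20), n)
  V[, 7] <- as.numeric(lab == "a")          # the label itself
  sel <- anova_select(V, lab, 0.05)
  expect_true(7 %in% sel)
  expect_lt(length(sel), 10)
  # all-identical features: fallback returns exactly one variable
  Vsame <- matrix(1, n, 5)
  expect_length(anova_select(Vsame, lab, 0.05), 1)
  expect_equal(sort(anova_select(V, lab, 1)), 1:20)
  expect_error(anova_select(V, rep("a", n)), "2 classes")
  # F statistic agrees with stats::aov
  ft <- summary(stats::aov(V[, 3] ~ factor(lab)))[[1]]
  grand <- mean(V[, 3])
  p_mine <- {
    ssb <- sum(tapply(V[, 3], lab, function(v) length(v) * (mean(v) - grand)^2))
    ssw <- sum(tapply(V[, 3], lab, function(v) sum((v - mean(v))^2)))
    stats::pf((ssb / 1) / (ssw / (n - 2)), 1, n - 2, lower.tail = FALSE)
  }
  expect_equal(p_mine, ft[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("two-class LDA separates, symmetrizes, and survives rank deficiency", {
  set.seed(48)
  n <- 20
  A <- matrix(rnorm(2 * n), n) + 5
  B <- matrix(rnorm(2 * n), n) - 5
  V <- rbind(A, B)
  lab <- rep(c("a", "b"), each = n)
  m <- lda_fit(V, lab)
  expect_equal(mean(lda_predict(m, V) == lab), 1)
  # mirror-symmetric clouds: boundary passes through the means' midpoint
  mid <- (colMeans(A) + colMeans(B)) / 2
  expect_lt(abs(sum(m$weights * mid) - m$bias), 1e-6)
  # duplicated feature: shrinkage engages, predictions unchanged
  V2 <- cbind(V, V[, 1])
  m2 <- lda_fit(V2, lab)
  expect_equal(lda_predict(m2, V2), lda_predict(m, V))
  # agreement with MASS::lda on a well-conditioned problem
  ml <- MASS::lda(V, grouping = factor(lab))
  expect_equal(as.character(stats::predict(ml, V)$class), lda_predict(m, V))
  expect_error(lda_fit(V, rep("a", 2 * n)), "two-class")
})

test_that("distance scatter places trials against the class means", {
  set.seed(49)
  A <- rand_spd(4); B <- rand_spd(4)
  cov <- structure(list(matrices = array(A, c(4, 4, 1)),
                        labels = "a", channel_labels = paste0("c", 1:4),
                        trial_meta = data.frame(run = 1, trial = 1)),
                   class = "cov_set")
  ds <- distance_scatter(cov, A, B)
  expect_equal(ds$dist_a, 0, tolerance = 1e-7)
  expect_equal(ds$dist_b, riemann_distance(A, B), tolerance = 1e-9)
  # geodesic midpoint is equidistant
  As <- lockbci:::spd_sqrt(A); Ais <- lockbci:::spd_invsqrt(A)
  mid <- As %*% lockbci:::spd_fun(Ais %*% B %*% Ais, sqrt) %*% As
  cov$matrices[, , 1] <- mid
  ds2 <- distance_scatter(cov, A, B)
  expect_equal(ds2$dist_a, ds2$dist_b, tolerance = 1e-8)
})

test_that("the fitted Riemannian pipeline behaves as a classifier should", {
  ep <- separable_epochs()
  rep_ <- loocv(ep, bci_pipeline("riemann"))
  expect_equal(rep_$accuracy, 1)
  # affine invariance: a common uV -> V rescaling of training and test data
  # leaves every prediction unchanged
  model <- bci_train(ep, bci_pipeline("riemann"))
  ep_v <- ep; ep_v$data <- ep_v$data * 1e-6
  model_v <- bci_train(ep_v, bci_pipeline("riemann"))
  expect_equal(predict(model_v, ep_v), predict(model, ep))
  expect_error(bci_train(subset_epochs(ep, trials = 1:6)), "both classes")
})
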