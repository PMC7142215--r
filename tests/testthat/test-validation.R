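test_that("accuracy vanishes at full rank and equals mean-deviation at t = 0", {
  X <- tiny_training(p = 8, K = 3, seed = 41)
  fit <- kinetic_pca(X)
  r <- length(fit$eigenvalues)
  expect_lt(max(model_accuracy(fit, X, r)$rmse), 1e-9)

  a0 <- model_accuracy(fit, X, 0)
  # mean-only model: RMSE is the per-channel RMS deviation from the mean
  res <- unclass(X) - rowMeans(unclass(X))
  byhand <- sapply(1:6, function(c)
    sqrt(colMeans(res[((c - 1) * 101 + 1):(c * 101), ]^2)))
  expect_equal(unname(a0$rmse), unname(byhand), tolerance = 1e-12)
})

test_that("accuracy matches a naive per-subject, per-channel loop", {
  X <- noise_training(p = 8, seed = 42)
  fit <- kinetic_pca(X)
  t <- 3L
  acc <- model_accuracy(fit, X, t)
  z <- subject_scores(fit)
  for (i in c(1, 5, 8)) {
    xhat <- fit$mean + fit$row_sd *
      drop(fit$modes[, 1:t] %*% z[i, 1:t])
    for (c in c(1, 4, 6)) {
      rows <- ((c - 1) * 101 + 1):(c * 101)
      expect_equal(acc$rmse[i, c],
                   sqrt(mean((X[rows, i] - xhat[rows])^2)),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
  expect_equal(acc$median, median(acc$rmse))
})

test_that("median accuracy is non-increasing in the number of modes", {
  X <- tiny_training(p = 20, K = 10, seed = 43)
  fit <- kinetic_pca(X)
  r <- length(fit$eigenvalues)
  med <- vapply(0:r, function(t) model_accuracy(fit, X, t)$median,
                numeric(1))
  expect_true(all(diff(med) <= 1e-12))
})

test_that("generalization is reproducible under a fixed seed", {
  X <- tiny_training(p = 10, K = 3, seed = 44)
  g1 <- generalization_curve(X, n_values = c(4, 8), T_g = 3, seed = 99)
  g2 <- generalization_curve(X, n_values = c(4, 8), T_g = 3, seed = 99)
  expect_identical(g1$draws, g2$draws)
  g3 <- generalization_curve(X, n_values = c(4, 8), T_g = 3, seed = 100)
  expect_false(identical(g1$draws, g2$draws) && identical(g1$draws, g3$draws))
  expect_error(generalization_curve(X, n_values = 10, T_g = 1),
               "n must be in 4..p-1")
})

test_that("near-identical cohorts generalize with proportionally small error", {
  set.seed(45)
  base <- as.vector(t(make_ground_truth("squat", K = 1, seed = 45)$mean))
  eps <- 1e-3
  X <- base + matrix(rnorm(606 * 10, sd = eps / 2), 606, 10)
  # pairwise channel RMS differences are at most ~eps
  g <- generalization_curve(X, n_values = c(4, 9), T_g = 20, seed = 46)
  expect_lt(max(g$draws), 5 * eps)
})

test_that("generalization error shrinks from n = 4 to n = p - 1", {
  X <- tiny_training(p = 16, K = 5, seed = 47)
  g <- generalization_curve(X, n_values = c(4, 15), T_g = 60, seed = 48)
  med <- with(g$summary, tapply(median, n, median))
  expect_lt(med["15"], med["4"])
})

test_that("virtual subjects reduce to the mean at zero scores and reproduce
           the model covariance", {
  X <- tiny_training(p = 10, K = 4, seed = 49)
  fit <- kinetic_pca(X)
  r <- length(fit$eigenvalues)
  expect_equal(sample_virtual_subject(fit, scores = rep(0, r)),
               fit$mean, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(simulate(fit, nsim = 3, seed = 7),
                   simulate(fit, nsim = 3, seed = 7))

  # sample covariance of many draws approaches D U diag(lambda) U^T D
  V <- simulate(fit, nsim = 20000, seed = 8)
  rows <- seq(1, 606, by = 16)
  emp <- cov(t(V[rows, ]))
  DU <- fit$row_sd * fit$modes
  theo <- (DU %*% (fit$eigenvalues * t(DU)))[rows, rows]
  expect_lt(norm(emp - theo, "F") / norm(theo, "F"), 0.05)
})

test_that("specificity matches a brute-force nearest-neighbour loop", {
  X <- tiny_training(p = 8, K = 3, seed = 50)
  fit <- kinetic_pca(X)
  spec <- model_specificity(fit, X, variance_levels = 0.95, T_s = 100,
                            seed = 51)
  # regenerate the identical virtual subjects from the derived substream
  V <- simulate(fit, nsim = 100,
                seed = kineticsm:::.kin_substream(51, 701L),
                ncomp = length(fit$eigenvalues))
  rmse <- vapply(seq_len(100), function(i) {
    min(vapply(seq_len(8), function(j)
      sqrt(mean((V[, i] - X[, j])^2)), numeric(1)))
  }, numeric(1))
  expect_equal(spec$median, median(rmse), tolerance = 1e-12)
  expect_equal(spec$iqr, IQR(rmse), tolerance = 1e-12)
})

test_that("a zero-variance model generates only the mean subject", {
  X <- tiny_training(p = 8, K = 3, seed = 52)
  fit <- kinetic_pca(X)
  fit$eigenvalues[] <- 0
  spec <- model_specificity(fit, X, variance_levels = 0.95, T_s = 10,
                            seed = 53)
  nn <- min(sqrt(colMeans((unclass(X) - fit$mean)^2)))
  expect_equal(spec$median, nn, tolerance = 1e-9)
})

test_that("specificity estimates are stable when T_s doubles", {
  X <- tiny_training(p = 12, K = 5, seed = 54)
  fit <- kinetic_pca(X)
  s1 <- model_specificity(fit, X, variance_levels = 0.95, T_s = 5000,
                          seed = 55)
  s2 <- model_specificity(fit, X, variance_levels = 0.95, T_s = 10000,
                          seed = 56)
  expect_lt(abs(s1$median - s2$median) / s1$median, 0.01)
})

test_that("permutation test reports the add-one p-value floor on strong modes", {
  X <- tiny_training(p = 30, K = 2, spectrum = c(14, 8), noise_sd = 0.02,
                     seed = 57)
  perm <- permutation_component_test(X, n_pc = 4, B = 99, seed = 58)
  expect_equal(perm$rank_of_roots_p[1:2], rep(1 / 100, 2))
  expect_gt(min(perm$rank_of_roots_p[3:4]), 0.05)
  expect_true(all(perm$rank_of_roots_p >= 1 / 100))
  expect_true(all(perm$equality_of_roots_p <= 1))
  expect_error(permutation_component_test(X, B = 50), "at least 99")
})

test_that("within-row permutation preserves rows and destroys columns", {
  set.seed(59)
  M <- matrix(rnorm(40), 8, 5)
  P <- kineticsm:::.kin_permute_rows(M)
  expect_identical(dim(P), dim(M))
  for (i in 1:8) expect_identical(sort(P[i, ]), sort(M[i, ]))
})
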