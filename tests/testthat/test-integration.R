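test_that("RV coefficient identities and independent formula evaluation", {
  set.seed(61)
  X <- matrix(rnorm(40 * 6), 40, 6)
  expect_equal(rv_coefficient(X, X), 1, tolerance = 1e-12)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  expect_equal(rv_coefficient(X, X %*% Q), 1, tolerance = 1e-12)
  Y <- matrix(rnorm(40 * 4), 40, 4)
  # direct trace-formula evaluation
  xc <- scale(X, scale = FALSE)
  yc <- scale(Y, scale = FALSE)
  s12 <- t(xc) %*% yc
  s21 <- t(yc) %*% xc
  rv_direct <- sum(diag(s12 %*% s21)) /
    sqrt(sum(diag((t(xc) %*% xc) %*% (t(xc) %*% xc))) *
           sum(diag((t(yc) %*% yc) %*% (t(yc) %*% yc))))
  expect_equal(rv_coefficient(X, Y), rv_direct, tolerance = 1e-12)
  expect_error(rv_coefficient(X, matrix(1, 40, 3)), "zero-variance")
  # large-n null RV is small
  set.seed(62)
  A <- matrix(rnorm(2000 * 6), 2000, 6)
  B <- matrix(rnorm(2000 * 6), 2000, 6)
  expect_lt(rv_coefficient(A, B), 0.02)
})

test_that("PLS recovers perfect covariation and sums axis covariances to the total", {
  set.seed(63)
  X <- matrix(rnorm(50 * 6), 50, 6)
  L <- matrix(rnorm(36), 6, 6)
  dat <- tibble::tibble(b1 = X, b2 = X %*% L)
  pls <- pls_two_block(dat, "b1", "b2", n_perm = 99, seed = 1)
  expect_equal(pls$P, 1 / 100)
  # axis covariances sum to the Frobenius norm of the cross-covariance
  s12 <- cov(scale(X, scale = FALSE), X %*% L)
  expect_equal(sum(pls$singular_values^2), sum(s12^2), tolerance = 1e-8)
  expect_equal(sum(pls$percent_covariance), 100, tolerance = 1e-8)

  # single shared factor -> dominant first axis, factor recovered
  set.seed(64)
  f <- rnorm(100)
  u <- rnorm(8); u <- u / sqrt(sum(u^2))
  v <- rnorm(8); v <- v / sqrt(sum(v^2))
  b1 <- outer(f, u) + matrix(rnorm(800, 0, 1), 100, 8)
  b2 <- outer(f, v) + matrix(rnorm(800, 0, 1), 100, 8)
  pls2 <- pls_two_block(tibble::tibble(b1 = b1, b2 = b2), "b1", "b2",
                        n_perm = 199, seed = 2)
  expect_gt(pls2$percent_covariance[1], 3 * pls2$percent_covariance[2])
  expect_gt(abs(sum(pls2$axes1[, 1] * u)), 0.9)
  expect_gt(abs(sum(pls2$axes2[, 1] * v)), 0.9)
  expect_equal(pls2$P, 1 / 200)
})

test_that("pooled PLS centers within cells and permutes within cells", {
  set.seed(65)
  g <- rep(c("A", "B"), each = 30)
  # group mean covariation only: vanishes after pooling
  b1 <- matrix(rnorm(60 * 4), 60, 4)
  b2 <- matrix(rnorm(60 * 4), 60, 4)
  b1[g == "B", 1] <- b1[g == "B", 1] + 5
  b2[g == "B", 1] <- b2[g == "B", 1] + 5
  dat <- tibble::tibble(b1 = b1, b2 = b2, species = g)
  total <- pls_two_block(dat, "b1", "b2", n_perm = 199, seed = 3)
  pooled <- pls_two_block(dat, "b1", "b2", pool_by = "species", n_perm = 199, seed = 3)
  expect_gt(total$rv, pooled$rv + 0.1)
  expect_gt(pooled$P, 0.05)
})

test_that("matrix correlation is 1 against itself and drops without shared structure", {
  set.seed(66)
  C1 <- cov(matrix(rnorm(300 * 20), 300, 20))
  res <- matrix_correlation_ind_fa(C1, C1, n_perm = 99, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$P, 1 / 100)

  # matrices sharing only diagonal structure: excluding diagonal blocks drops r
  d1 <- diag(c(rep(5, 10), rep(1, 10)))
  C2 <- d1 + 0.01 * cov(matrix(rnorm(300 * 20), 300, 20))
  C3 <- d1 + 0.01 * cov(matrix(rnorm(300 * 20), 300, 20))
  with_diag <- matrix_correlation_ind_fa(C2, C3, TRUE, n_perm = 9, seed = 1)
  without_diag <- matrix_correlation_ind_fa(C2, C3, FALSE, n_perm = 9, seed = 1)
  expect_gt(with_diag$r, 0.9)
  expect_lt(abs(without_diag$r), 0.5)
  expect_error(matrix_correlation_ind_fa(C1, C1[1:10, 1:10]), "differ")
})

test_that("modularity alternatives enumerate C(6,3)/2 distinct equal partitions", {
  set.seed(67)
  shapes <- matrix(rnorm(50 * 12), 50, 12)
  mt <- modularity_test(shapes, 1:3, n_alternatives = 1000, seed = 1)
  expect_equal(mt$n_alternatives, 10L)
  expect_true(mt$enumerated)
  expect_error(modularity_test(shapes, 1L), "at least 2")
})

test_that("injected two-module structure is supported; uniform integration is not", {
  set.seed(68)
  k <- 8
  # independent modules 1-4 and 5-8 with strong within-module covariance
  f1 <- rnorm(100)
  f2 <- rnorm(100)
  m1 <- outer(f1, rep(1, 8)) + matrix(rnorm(800, 0, 0.4), 100, 8)
  m2 <- outer(f2, rep(1, 8)) + matrix(rnorm(800, 0, 0.4), 100, 8)
  shapes <- cbind(m1, m2)   # landmarks 1-4 cols 1-8; landmarks 5-8 cols 9-16
  mt <- modularity_test(shapes, 1:4, n_alternatives = 1000, seed = 2)
  expect_lte(mt$proportion_leq, 0.05)

  # uniform integration: observed partition unexceptional
  g <- rnorm(100)
  unif <- outer(g, rep(1, 16)) + matrix(rnorm(1600, 0, 0.4), 100, 16)
  mtu <- modularity_test(unif, 1:4, n_alternatives = 1000, seed = 3)
  expect_gte(mtu$proportion_leq, 0.1)
  expect_lte(mtu$proportion_leq, 0.95)
})

test_that("contiguous mode only admits connected partitions", {
  set.seed(69)
  k <- 8
  ring <- cbind(1:8, c(2:8, 1))
  shapes <- matrix(rnorm(40 * 16), 40, 16)
  mt <- modularity_test(shapes, 1:4, adjacency = ring, n_alternatives = 1000,
                        contiguous_only = TRUE, seed = 4)
  # on a ring, contiguous equal splits are the 8 rotations of an arc of 4
  expect_equal(mt$n_alternatives, 4L)
  for (i in seq_len(mt$n_alternatives)) expect_true(is.finite(mt$alternatives[i]))
})

test_that("sampled and enumerated alternative distributions agree for small k", {
  set.seed(70)
  shapes <- matrix(rnorm(60 * 14), 60, 14)  # k = 7, subsets of 3
  enum <- modularity_test(shapes, 1:3, n_alternatives = 10000, seed = 5)
  expect_true(enum$enumerated)
  samp <- modularity_test(shapes, 1:3, n_alternatives = 30, seed = 6)
  expect_false(samp$enumerated)
  expect_equal(mean(samp$alternatives), mean(enum$alternatives),
               tolerance = 0.15)
})
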