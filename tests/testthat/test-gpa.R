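test_that("centroid size matches hand computation and is scale-equivariant", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(sq), sqrt(2))
  set.seed(1)
  m <- random_config(10)
  expect_equal(centroid_size(3.7 * m), 3.7 * centroid_size(m))
  # independent formula evaluation
  ctr <- colMeans(m)
  expect_equal(centroid_size(m),
               sqrt(sum((m[, 1] - ctr[1])^2 + (m[, 2] - ctr[2])^2)),
               tolerance = 1e-12)
  expect_error(centroid_size(matrix(1, 5, 2)), "degenerate")
})

test_that("pairwise Procrustes recovers a known rotation and handles reflection", {
  tri <- rbind(c(0, 0), c(2, 0), c(1, 1.5))
  th <- 37 * pi / 180
  R <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  fit <- procrustes_align_pair(tri %*% R, tri)
  expect_lt(fit$residual, 1e-10)
  expect_equal(acos(max(-1, min(1, fit$rotation[1, 1]))) * 180 / pi, 37, tolerance = 1e-8)

  mirror <- tri
  mirror[, 1] <- -mirror[, 1]
  f_no <- procrustes_align_pair(mirror, tri, allow_reflection = FALSE)
  f_yes <- procrustes_align_pair(mirror, tri, allow_reflection = TRUE)
  expect_gt(f_no$residual, 0.1)
  expect_lt(f_yes$residual, 1e-10)
  expect_error(procrustes_align_pair(matrix(0, 3, 2), tri), "degenerate")
})

test_that("pairwise residual matches a brute-force rotation grid on random triangles", {
  set.seed(21)
  grid <- seq(0, 2 * pi, by = 0.01 * pi / 180)
  cosg <- cos(grid)
  sing <- sin(grid)
  for (i in 1:10) {
    X <- center_config_test(random_config(3))
    Y <- center_config_test(random_config(3))
    fit <- procrustes_align_pair(X, Y)
    # residual^2 at optimal scale for rotation angle t: |Y|^2 - max(0,a cos t + b sin t)^2/|X|^2
    a <- sum(X * Y)
    b <- X[, 1] %*% Y[, 2] - X[, 2] %*% Y[, 1]
    best <- max(a * cosg + drop(b) * sing)
    res_grid <- sqrt(max(0, sum(Y^2) - best^2 / sum(X^2)))
    expect_equal(fit$residual, res_grid, tolerance = 1e-6)
  }
})

test_that("GPA collapses similarity-transformed copies and is input-invariant", {
  set.seed(3)
  base <- random_config(8)
  cfgs <- lapply(1:6, function(i) similarity_transform(base))
  fit <- gpa(cfgs)
  X <- do.call(rbind, lapply(fit$coords, flat))
  expect_lt(max(dist(X)), 1e-8)
  # invariants: unit centroid size, centered, consensus = mean
  for (m in fit$coords) {
    expect_lt(max(abs(colMeans(m))), 1e-9)
    expect_equal(sum(m^2), 1, tolerance = 1e-9)
  }
  expect_equal(fit$tangent_dim, 2 * 8 - 4)

  # invariance: transform inputs, compare aligned output
  cfgs2 <- lapply(cfgs, similarity_transform)
  fit2 <- gpa(cfgs2)
  A <- do.call(rbind, lapply(fit$coords, flat))
  B <- do.call(rbind, lapply(fit2$coords, flat))
  # allow a global rotation between the two fits
  pr <- procrustes_align_pair(unflatten_config_test(B[1, ]), unflatten_config_test(A[1, ]))
  B_rot <- t(apply(B, 1, function(v) flat(unflatten_config_test(v) %*% pr$rotation)))
  expect_lt(max(abs(A - B_rot)), 1e-7)
})

test_that("two-configuration consensus is equidistant from both", {
  set.seed(4)
  fit <- gpa(list(random_config(6), random_config(6)))
  d1 <- sqrt(sum((fit$coords[[1]] - fit$consensus)^2))
  d2 <- sqrt(sum((fit$coords[[2]] - fit$consensus)^2))
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("GPA consensus beats random consensus candidates (Monte-Carlo minimality)", {
  set.seed(9)
  cfgs <- lapply(1:5, function(i) random_config(7))
  fit <- gpa(cfgs)
  pre <- lapply(cfgs, function(m) {
    m <- center_config_test(m)
    m / sqrt(sum(m^2))
  })
  # rotation-only squared distance, via the closed form with proper rotation
  rot_ssd <- function(m, cons) {
    M <- crossprod(m, cons)
    s <- svd(M)
    dsum <- if (det(M) < 0) s$d[1] - s$d[2] else sum(s$d)
    sum(m^2) + sum(cons^2) - 2 * dsum
  }
  obj <- function(cons) {
    cons <- center_config_test(cons)
    cons <- cons / sqrt(sum(cons^2))
    sum(vapply(pre, rot_ssd, numeric(1), cons = cons))
  }
  attained <- obj(fit$consensus)
  cands <- replicate(2000, obj(fit$consensus + matrix(rnorm(14, 0, 0.1), 7, 2)))
  expect_true(all(attained <= cands + 1e-10))
})
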