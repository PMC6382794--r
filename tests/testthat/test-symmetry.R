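# small object-symmetric scheme: pairs (1,2), (3,4), midline 5, 6
obj_scheme <- function() {
  landmark_scheme("somite", 6, symmetry = "object",
                  pairs = rbind(c(1L, 2L), c(3L, 4L)), midline = c(5L, 6L))
}

symmetric_config <- function() {
  rbind(c(-1, 1), c(1, 1), c(-0.6, -1), c(0.6, -1), c(0, 0.5), c(0, -0.5))
}

test_that("a perfectly symmetric configuration has zero asymmetric component", {
  sch <- obj_scheme()
  cfgs <- config_tibble(lapply(1:5, function(i) similarity_transform(symmetric_config())))
  res <- decompose_object_symmetry(cfgs, sch)
  expect_lt(max(abs(res$decomposition$asymmetric)), 1e-10)
})

test_that("a one-landmark offset splits into +/- delta/2 at the paired landmarks", {
  sch <- obj_scheme()
  base <- symmetric_config()
  delta <- c(0.03, 0.01)
  pert <- base
  pert[1, ] <- pert[1, ] + delta
  cfgs <- config_tibble(c(lapply(1:4, function(i) base), list(pert)))
  res <- decompose_object_symmetry(cfgs, sch)
  asym <- unflatten_config_test(res$decomposition$asymmetric[5, ])
  # after alignment the asymmetric component concentrates delta/2 at landmark 1
  # and the reflected -delta/2 at its pair (x negated by the reflection)
  expect_equal(asym[1, ], delta / 2, tolerance = 0.15)
  # anti-symmetry: the paired landmark carries the mirrored opposite offset
  expect_equal(asym[2, ], c(delta[1] / 2, -delta[2] / 2), tolerance = 0.15)
  expect_equal(sqrt(sum(asym[1:2, ]^2)), sqrt(sum((delta / 2)^2) * 2), tolerance = 0.05)
})

test_that("symmetric + asymmetric reconstructs every aligned configuration exactly", {
  set.seed(33)
  sch <- obj_scheme()
  cfgs <- config_tibble(lapply(1:8, function(i) {
    similarity_transform(symmetric_config() + matrix(rnorm(12, 0, 0.05), 6, 2))
  }))
  res <- decompose_object_symmetry(cfgs, sch)
  dec <- res$decomposition
  expect_equal(dec$aligned, dec$symmetric + dec$asymmetric, tolerance = 1e-12)
  # symmetric component is invariant under reflect-relabel
  for (i in 1:8) {
    s <- unflatten_config_test(dec$symmetric[i, ])
    expect_equal(reflect_config(s, sch), s, tolerance = 1e-9)
  }
})

test_that("object-symmetry components are orthogonal over the joint set", {
  set.seed(34)
  sch <- obj_scheme()
  cfgs <- config_tibble(lapply(1:10, function(i) {
    similarity_transform(symmetric_config() + matrix(rnorm(12, 0, 0.05), 6, 2))
  }))
  res <- decompose_object_symmetry(cfgs, sch)
  dec <- res$decomposition
  cons <- flat(res$fit$consensus)
  X <- do.call(rbind, lapply(res$fit$coords, flat))
  total <- sum(sweep(X, 2, cons)^2)
  sym_ss <- 2 * sum(sweep(dec$symmetric, 2, cons)^2)
  asym_ss <- 2 * sum(dec$asymmetric^2)
  expect_equal(total, sym_ss + asym_ss, tolerance = 1e-8)
})

test_that("identical left and right sides give zero side deviation", {
  sch <- acanthocyclops_schemes()$P4Enp3
  base <- base_shape(sch)
  cfgs <- dplyr::bind_rows(
    config_tibble(lapply(1:4, function(i) similarity_transform(base)),
                  specimen = sprintf("s%d", 1:4), side = "left"),
    config_tibble(lapply(1:4, function(i) similarity_transform(reflect_config(base, sch))),
                  specimen = sprintf("s%d", 1:4), side = "right")
  )
  res <- assemble_matching_symmetry(cfgs, sch)
  expect_lt(max(abs(res$decomposition$asymmetric)), 1e-8)
})

test_that("injected directional asymmetry is recovered as the mean side contrast", {
  d <- small_matching_sim(n_ind = 50, da = 0.02, seed = 77, n_image = 1L)
  sch <- acanthocyclops_schemes()$P4Enp3
  res <- assemble_matching_symmetry(d$configs, sch)
  dec <- res$decomposition
  contrast <- colMeans(dec$aligned[dec$info$side == "left", ]) -
    colMeans(dec$aligned[dec$info$side == "right", ])
  expect_equal(sqrt(sum(contrast^2)), 0.02, tolerance = 0.2)

  # with the side offset dominating the noise, the direction is recovered too
  d2 <- small_matching_sim(n_ind = 20, da = 0.02, seed = 78, n_image = 1L,
                           sigma_fa = 1e-4, sigma_imaging = 1e-4)
  res2 <- assemble_matching_symmetry(d2$configs, sch)
  dec2 <- res2$decomposition
  contrast2 <- colMeans(dec2$aligned[dec2$info$side == "left", ]) -
    colMeans(dec2$aligned[dec2$info$side == "right", ])
  mu_ref <- (d2$truth$spec$species_means$A + d2$truth$spec$species_means$B) / 2
  contrast2 <- to_generator_frame(contrast2, res2$fit$consensus, mu_ref)
  da_true <- d2$truth$spec$da_vector
  expect_gt(abs(sum(contrast2 * da_true)) / sqrt(sum(contrast2^2) * sum(da_true^2)), 0.95)
})

test_that("swapping the left/right labels leaves Procrustes distances unchanged", {
  d <- small_matching_sim(n_ind = 8, da = 0.02, seed = 12, n_image = 1L)
  sch <- acanthocyclops_schemes()$P4Enp3
  res1 <- assemble_matching_symmetry(d$configs, sch)
  flipped <- d$configs
  flipped$side <- ifelse(flipped$side == "left", "right", "left")
  res2 <- assemble_matching_symmetry(flipped, sch)
  d1 <- dist(res1$decomposition$aligned)
  d2 <- dist(res2$decomposition$aligned)
  expect_equal(as.vector(d1), as.vector(d2), tolerance = 1e-6)
})

test_that("an unpaired non-midline landmark is a scheme error", {
  expect_error(landmark_scheme("bad", 5, symmetry = "object",
                               pairs = rbind(c(1L, 2L)), midline = 5L),
               "paired or on the midline")
})
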