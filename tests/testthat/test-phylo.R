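paper_tree <- function() {
  ape::read.tree(text = "((vernalis:1,europensis:1):1,(robustus:1,americanus:1):1);")
}

test_that("group mean shapes are tangent-space arithmetic means", {
  X <- rbind(c(0, 0, 0), c(2, 2, 2), c(10, 10, 10))
  dat <- tibble::tibble(shape = X, species = c("a", "a", "b"))
  gm <- group_mean_shapes(dat, by = "species")
  expect_equal(gm$mean_shape[gm$species == "a", ], c(1, 1, 1), ignore_attr = TRUE)
  expect_equal(gm$mean_shape[gm$species == "b", ], c(10, 10, 10), ignore_attr = TRUE)
  expect_equal(gm$n, c(2L, 1L))
})

test_that("generator species means are recovered by group averaging", {
  sch <- acanthocyclops_schemes()$P4Enp3
  spec <- simulation_spec(
    sch, species_means = default_species_means(sch, c("A", "B"), effect = 0.1, seed = 2),
    sigma_individual = 0.005, sigma_fa = 0.002, sigma_imaging = 0.001,
    n_per_cell = 30L, n_image = 1L, seed = 2L
  )
  d <- simulate_dataset(spec)
  res <- assemble_matching_symmetry(d$configs, sch)
  ind <- individual_symmetric_shapes(res$decomposition)
  dat <- dplyr::left_join(ind, d$classifiers, by = c(individual = "specimen_id"))
  gm <- group_mean_shapes(dat, by = "species")
  # compare the A-B mean contrast with the generator's injected contrast
  est <- gm$mean_shape[1, ] - gm$mean_shape[2, ]
  mu_ref <- (spec$species_means$A + spec$species_means$B) / 2
  est <- to_generator_frame(est, res$fit$consensus, mu_ref)
  tru <- flat(spec$species_means$A) - flat(spec$species_means$B)
  cc <- abs(sum(est * tru)) / sqrt(sum(est^2) * sum(tru^2))
  expect_gt(cc, 0.99)
})

test_that("identical tips give zero tree length and constant ancestors", {
  tr <- paper_tree()
  v <- c(vernalis = 3, europensis = 3, robustus = 3, americanus = 3)
  res <- squared_change_parsimony(tr, v)
  expect_equal(res$tree_length, 0)
  expect_true(all(abs(res$ancestral - 3) < 1e-12))
})

test_that("reconstruction matches direct numeric minimization on random trees", {
  set.seed(71)
  for (n in c(4, 6, 8)) {
    tr <- ape::rtree(n)
    vals <- stats::setNames(rnorm(n), tr$tip.label)
    res <- squared_change_parsimony(tr, vals)
    obj <- function(a) {
      all_vals <- c(vals[tr$tip.label], a)
      sum((all_vals[tr$edge[, 1]] - all_vals[tr$edge[, 2]])^2 / tr$edge.length)
    }
    opt <- stats::optim(rep(mean(vals), tr$Nnode), obj, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 1000))
    expect_equal(res$tree_length, opt$value, tolerance = 1e-8)
    expect_equal(as.vector(res$ancestral), opt$par, tolerance = 1e-4)
  }
})

test_that("reconstruction is the exact minimizer (random perturbations increase length)", {
  set.seed(72)
  tr <- ape::rtree(6)
  vals <- stats::setNames(rnorm(6), tr$tip.label)
  res <- squared_change_parsimony(tr, vals)
  len_with <- function(a) {
    all_vals <- c(vals[tr$tip.label], a)
    sum((all_vals[tr$edge[, 1]] - all_vals[tr$edge[, 2]])^2 / tr$edge.length)
  }
  base <- len_with(as.vector(res$ancestral))
  for (i in 1:50) {
    expect_gte(len_with(as.vector(res$ancestral) + rnorm(tr$Nnode, 0, 0.1)),
               base - 1e-12)
  }
})

test_that("star tree root is the branch-length-weighted tip mean", {
  tr <- ape::read.tree(text = "(a:2,b:1,c:1,d:4);")
  v <- c(a = 1, b = 2, c = 3, d = 4)
  res <- squared_change_parsimony(tr, v)
  w <- 1 / c(2, 1, 1, 4)
  expect_equal(unname(res$ancestral[1, 1]), sum(w * v) / sum(w), tolerance = 1e-12)
})

test_that("multivariate tree length separates into per-coordinate lengths", {
  set.seed(73)
  tr <- ape::rtree(7)
  Y <- matrix(rnorm(21), 7, 3, dimnames = list(tr$tip.label, NULL))
  total <- squared_change_parsimony(tr, Y)$tree_length
  percol <- sum(vapply(1:3, function(j) {
    squared_change_parsimony(tr, stats::setNames(Y[, j], rownames(Y)))$tree_length
  }, numeric(1)))
  expect_equal(total, percol, tolerance = 1e-10)
})

test_that("tree length is invariant under swapping sister subtrees", {
  tr <- paper_tree()
  v <- c(vernalis = 1, europensis = 4, robustus = 2, americanus = 9)
  l1 <- squared_change_parsimony(tr, v)$tree_length
  tr2 <- ape::read.tree(text = "((robustus:1,americanus:1):1,(europensis:1,vernalis:1):1);")
  l2 <- squared_change_parsimony(tr2, v)$tree_length
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("four-tip permutation test enumerates all 24 assignments", {
  set.seed(74)
  tr <- paper_tree()
  Y <- matrix(rnorm(8), 4, 2, dimnames = list(tr$tip.label, NULL))
  suppressMessages(res <- phylo_signal_test(tr, Y, n_perm = 10000, seed = 1))
  expect_true(res$enumerated)
  expect_equal(res$n_perm_effective, 24L)
  expect_equal(res$P * 24, round(res$P * 24), tolerance = 1e-9)
  expect_gte(res$P, 1 / 24)
})

test_that("Brownian tips on a structured tree carry signal; iid tips do not", {
  set.seed(75)
  tr <- ape::rtree(16)
  rej_bm <- 0
  rej_iid <- 0
  for (i in 1:20) {
    Ybm <- simulate_bm_tips(tr, 1, rep(0, 3), seed = 100 + i)
    p1 <- phylo_signal_test(tr, Ybm, n_perm = 99, seed = i)$P
    rej_bm <- rej_bm + (p1 <= 0.05)
    Yiid <- matrix(rnorm(48), 16, 3, dimnames = list(tr$tip.label, NULL))
    p0 <- phylo_signal_test(tr, Yiid, n_perm = 99, seed = i)$P
    rej_iid <- rej_iid + (p0 <= 0.05)
  }
  expect_gt(rej_bm, 10)
  expect_lt(rej_iid, 6)
})

test_that("missing tip values and short trees are rejected", {
  tr <- paper_tree()
  expect_error(squared_change_parsimony(tr, c(vernalis = 1, europensis = 2, robustus = 3)),
               "americanus")
  expect_error(phylo_signal_test(ape::read.tree(text = "(a:1,b:1,c:1);"),
                                 c(a = 1, b = 2, c = 3)), "4 tips")
})

test_that("sister tips under Brownian motion are closer than distant tips", {
  # expected squared distance between two tips is proportional to path length
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):2,(c:0.1,d:0.1):2);")
  d_ab <- numeric(200)
  d_ac <- numeric(200)
  for (i in 1:200) {
    Y <- simulate_bm_tips(tr, 1, 0, seed = i)
    d_ab[i] <- (Y["a", 1] - Y["b", 1])^2
    d_ac[i] <- (Y["a", 1] - Y["c", 1])^2
  }
  expect_equal(mean(d_ab), 0.2, tolerance = 0.25)
  expect_equal(mean(d_ac), 4.2, tolerance = 0.25)
})
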