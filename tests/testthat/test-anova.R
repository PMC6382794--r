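test_that("Goodall's F arithmetic and edge cases", {
  expect_equal(goodall_f(1, 5, 1, 5), 1)
  expect_equal(goodall_f(2, 1 * 86, 1, 2 * 86), 4)
  set.seed(2)
  for (i in 1:20) {
    ss_e <- runif(1)
    ss_r <- runif(1)
    df_e <- sample(1:200, 1)
    df_r <- sample(1:200, 1)
    expect_equal(goodall_f(ss_e, df_e, ss_r, df_r), (ss_e / df_e) / (ss_r / df_r))
  }
  expect_equal(goodall_f(1, 2, 0, 2), Inf)
  expect_error(goodall_f(1, 0, 1, 2), "positive")
})

test_that("permutation P uses the +1 correction and is seeded-deterministic", {
  set.seed(6)
  # huge species separation: observed F beats every permutation
  shapes <- rbind(matrix(rnorm(10 * 8, 0, 0.01), 10, 8),
                  matrix(rnorm(10 * 8, 5, 0.01), 10, 8))
  dat <- tibble::tibble(shape = shapes, species = rep(c("A", "B"), each = 10))
  an <- procrustes_anova_shape(dat, n_perm = 199, seed = 9)
  expect_equal(tidy(an)$P, 1 / 200)
  an2 <- procrustes_anova_shape(dat, n_perm = 199, seed = 9)
  expect_identical(tidy(an), tidy(an2))
  expect_true(all(tidy(an)$P >= 1 / 200 & tidy(an)$P <= 1))
})

test_that("species dominates the table when the group offset dwarfs the scatter", {
  sch <- acanthocyclops_schemes()$P4Enp3
  spec <- simulation_spec(
    sch, species_means = default_species_means(sch, c("A", "B"), effect = 0.3, seed = 21),
    da_vector = 0.005, sigma_individual = 0.005, sigma_fa = 0.003,
    sigma_imaging = 0.001, n_per_cell = 6L, seed = 21L
  )
  d <- simulate_dataset(spec)
  dec <- assemble_matching_symmetry(d$configs, sch)$decomposition
  an <- suppressWarnings(
    procrustes_anova_shape(dec, d$classifiers, n_perm = 99, seed = 1))
  tab <- tidy(an)
  expect_equal(tab$effect[which.max(tab$F)], "species")
  expect_equal(tab$P[tab$effect == "species"], 1 / 100)
  # shape dfs carry the 2k - 4 multiplier
  expect_equal(tab$df[tab$effect == "species"], (2 - 1) * (2 * 7 - 4))
})

test_that("component sums of squares add up within each stratum decomposition", {
  d <- small_matching_sim(n_ind = 10, seed = 31)
  sch <- acanthocyclops_schemes()$P4Enp3
  dec <- assemble_matching_symmetry(d$configs, sch)$decomposition
  y <- dec$aligned
  ind <- d$configs$specimen
  side <- d$configs$side
  cells <- morphodelim:::rowmeans_by(y, interaction(ind, side))
  key <- do.call(rbind, strsplit(rownames(cells) %||% levels(interaction(ind, side)), ".", fixed = TRUE))
  tw <- morphodelim:::ss_twoway_cells(cells, key[, 1], key[, 2])
  grand <- colMeans(cells)
  total <- sum(sweep(cells, 2, grand)^2)
  expect_equal(tw$ss_a + tw$ss_b + tw$ss_ab, total, tolerance = 1e-8)
})

test_that("size ANOVA agrees with classical one-way F in the balanced two-group case", {
  set.seed(12)
  sizes <- tibble::tibble(
    specimen = sprintf("s%02d", 1:20), side = "none",
    image_rep = 1L, digit_rep = 1L,
    size = c(rnorm(10, 10, 1), rnorm(10, 12, 1))
  )
  cls <- tibble::tibble(specimen_id = sizes$specimen,
                        species = rep(c("A", "B"), each = 10),
                        locality = "loc1", sex = "female",
                        individual = sizes$specimen)
  an <- suppressWarnings(anova_size(sizes, cls, n_perm = 199, seed = 4))
  f_pkg <- tidy(an)$F[tidy(an)$effect == "species"]
  f_classic <- summary(stats::aov(size ~ species,
                                  data = dplyr::left_join(sizes, cls,
                                                          by = c(specimen = "specimen_id"))))[[1]]$`F value`[1]
  expect_equal(f_pkg, f_classic, tolerance = 1e-10)
})

test_that("injected sex size dimorphism is detected in the size ANOVA", {
  sch <- acanthocyclops_schemes()$P4Enp3
  spec <- simulation_spec(
    sch, species_means = default_species_means(sch, "A", effect = 0),
    sexes = c("female", "male"), sex_size_ratio = 0.8, size_sdlog = 0.05,
    sigma_individual = 0.01, sigma_fa = 0.005, sigma_imaging = 0.002,
    n_per_cell = 15L, seed = 5L
  )
  d <- simulate_dataset(spec)
  fit <- assemble_matching_symmetry(d$configs, sch)$fit
  an <- suppressWarnings(anova_size(fit, d$classifiers, n_perm = 199, seed = 2))
  tab <- tidy(an)
  expect_gt(tab$F[tab$effect == "sex"], 10)
  expect_equal(tab$P[tab$effect == "sex"], 1 / 200)
})

test_that("all-equal sizes give flagged F with P near 1", {
  sizes <- tibble::tibble(
    specimen = rep(sprintf("s%02d", 1:8), each = 2), side = "none",
    image_rep = rep(1:2, 8), digit_rep = 1L, size = 5
  )
  cls <- tibble::tibble(specimen_id = sprintf("s%02d", 1:8),
                        species = rep(c("A", "B"), each = 4), locality = "l",
                        sex = "female", individual = sprintf("s%02d", 1:8))
  an <- suppressWarnings(anova_size(sizes, cls, n_perm = 49, seed = 1))
  tab <- tidy(an)
  expect_true(all(tab$SS < 1e-20))
  expect_true(all(tab$P[!is.na(tab$P)] > 0.9))
})
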