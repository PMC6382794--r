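# shared fixture builders (all in-code, seeded)

random_config <- function(k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(2 * k), k, 2)
}

similarity_transform <- function(m, angle = NULL, scale = NULL, shift = NULL) {
  angle <- angle %||% runif(1, 0, 2 * pi)
  scale <- scale %||% runif(1, 0.5, 2)
  shift <- shift %||% runif(2, -5, 5)
  R <- rbind(c(cos(angle), sin(angle)), c(-sin(angle), cos(angle)))
  sweep(scale * (m %*% R), 2, shift, "+")
}

flat <- function(m) as.vector(t(m))

config_tibble <- function(coords_list, specimen = NULL, side = "none") {
  n <- length(coords_list)
  tibble::tibble(
    specimen = specimen %||% sprintf("s%03d", seq_len(n)),
    side = rep_len(side, n), image_rep = 1L, digit_rep = 1L,
    coords = coords_list
  )
}

# a small matching-symmetry simulation used by several test files
small_matching_sim <- function(n_ind = 12, da = 0.02, seed = 42,
                               sigma_fa = 0.01, sigma_imaging = 0.003,
                               n_image = 2L, n_digit = 1L, species = c("A", "B")) {
  sch <- acanthocyclops_schemes()$P4Enp3
  spec <- simulation_spec(
    sch,
    species_means = default_species_means(sch, species, effect = 0.08, seed = seed),
    da_vector = da, sigma_individual = 0.02, sigma_fa = sigma_fa,
    sigma_imaging = sigma_imaging, n_per_cell = ceiling(n_ind / length(species)),
    n_image = n_image, n_digit = n_digit, seed = seed
  )
  simulate_dataset(spec)
}

center_config_test <- function(m) sweep(m, 2, colMeans(m), "-")
unflatten_config_test <- function(v) matrix(v, ncol = 2, byrow = TRUE)

# rotate a flat estimate from the GPA frame into the generator frame, using
# the optimal rotation of the fit consensus onto a reference mean shape
to_generator_frame <- function(v, consensus, reference) {
  ref <- center_config_test(reference)
  ref <- ref / sqrt(sum(ref^2))
  R <- morphodelim:::optimal_rotation(consensus, ref)
  flat(unflatten_config_test(v) %*% R)
}
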