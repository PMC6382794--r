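# Flat-vector symmetry helpers used by the generator.
reflect_flat <- function(v, scheme) flatten_config(reflect_config(unflatten_config(v), scheme))
sym_project <- function(v, scheme) (v + reflect_flat(v, scheme)) / 2
asym_project <- function(v, scheme) v - sym_project(v, scheme)

# Project a flat deviation onto the shape tangent space at a centered,
# unit-centroid-size reference: remove the translation, scale and rotation
# directions, so injected effect norms are Procrustes norms that survive
# superimposition.
shape_tangent_project_at <- function(v, mu) {
  k <- nrow(mu)
  dirs <- cbind(
    rep(c(1, 0), k) / sqrt(k),
    rep(c(0, 1), k) / sqrt(k),
    flatten_config(mu),
    flatten_config(cbind(-mu[, 2L], mu[, 1L]))
  )
  dirs[, 4L] <- dirs[, 4L] / sqrt(sum(dirs[, 4L]^2))
  for (j in seq_len(ncol(dirs))) v <- v - sum(v * dirs[, j]) * dirs[, j]
  v
}

#' Base (template) shape for a scheme
#'
#' A deterministic non-degenerate k x 2 template: a hand-crafted bilaterally
#' symmetric somite outline for the `Gs` scheme (midline on x = 0, sliders on
#' bulged lateral edges), and an elongated ellipse of equally spaced points
#' for other schemes. Centered, unit centroid size.
#'
#' @param scheme A [landmark_scheme].
#' @return k x 2 matrix.
#' @export
base_shape <- function(scheme) {
  k <- scheme$k
  if (scheme$name == "Gs" && k == 45L) {
    left <- rbind(
      c(-0.15, 1.00),   # 1 anterior corner
      c(-0.45, 0.85),   # 2 anterolateral corner (curve anchor)
      c(-0.30, -0.70),  # 3 sixth-leg seta
      c(-0.25, 0.60), c(-0.25, 0.35), c(-0.25, 0.10),  # 4-6 sensilla
      c(-0.25, -0.15), c(-0.25, -0.40),                # 7-8 sensilla
      c(-0.40, -0.95)   # 9 posterior corner (curve anchor)
    )
    right <- left
    right[, 1L] <- -right[, 1L]
    t <- seq_len(13L) / 14
    lcurve <- cbind(-((1 - t) * 0.45 + t * 0.40 + 0.08 * sin(pi * t)),
                    (1 - t) * 0.85 - t * 0.95)
    rcurve <- lcurve
    rcurve[, 1L] <- -rcurve[, 1L]
    m <- rbind(left, right, c(0, -0.85), lcurve, rcurve)
  } else {
    ang <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
    m <- cbind(cos(ang), 0.45 * sin(ang))
  }
  m <- center_config(m)
  m / sqrt(sum(m^2))
}

#' Default species mean shapes
#'
#' The template shape plus a species-specific tangent offset of norm
#' `effect` (symmetrized for object-symmetric schemes), drawn once from the
#' given seed so the means are reproducible study conditions.
#'
#' @param scheme A [landmark_scheme].
#' @param species Character vector of species names.
#' @param effect Procrustes norm of each species offset.
#' @param seed Seed for the offsets.
#' @return Named list of k x 2 mean shapes (unit centroid size).
#' @export
default_species_means <- function(scheme, species, effect = 0.08, seed = 1L) {
  base <- base_shape(scheme)
  with_seed_local(seed, {
    out <- lapply(species, function(s) {
      v <- rnorm(2L * scheme$k)
      if (scheme$symmetry == "object") v <- sym_project(v, scheme)
      v <- v / sqrt(sum(v^2)) * effect
      m <- base + unflatten_config(v)
      m <- center_config(m)
      m / sqrt(sum(m^2))
    })
    stats::setNames(out, species)
  })
}

#' Specify a simulated landmark study
#'
#' Collects the generative parameters of a synthetic landmark dataset with
#' the statistical structure the analyses assume: species x sex mean shapes,
#' locality and allometric effects on a log-normal size distribution,
#' directional asymmetry, and nested variance components (individual,
#' fluctuating asymmetry, imaging, digitizing; isotropic per coordinate, in
#' Procrustes units of the unit-centroid-size mean shape).
#'
#' @param scheme A [landmark_scheme].
#' @param species_means Named list of k x 2 mean shapes (see
#'   [default_species_means()]).
#' @param sexes Character vector, `c("female", "male")` or `"female"`.
#' @param sex_shape_offset Tangent vector (length 2k) added to male mean
#'   shapes, or a single number taken as the norm of a reproducible random
#'   offset.
#' @param sex_size_ratio Male/female median size ratio.
#' @param localities Named numeric vector of locality size multipliers.
#' @param locality_shape_effect Norm of per-locality shape offsets (0 for
#'   none).
#' @param allometry_vector Unit tangent vector of the allometric direction
#'   (default: reproducible random direction).
#' @param allometry_coef Shape change per unit centroid size.
#' @param da_vector Tangent vector of directional asymmetry (the mean
#'   left-right contrast; for object symmetry its asymmetric projection is
#'   used), or a single number taken as its norm.
#' @param sigma_individual,sigma_fa,sigma_imaging,sigma_digitizing Standard
#'   deviations per coordinate of the nested components.
#' @param size_meanlog,size_sdlog Log-normal size distribution (female).
#' @param species_size Named size multipliers per species.
#' @param n_per_cell Individuals per species x sex x locality cell.
#' @param n_image,n_digit Imaging and digitizing replicates per side.
#' @param spinule_intercept,spinule_slope,spinule_sd Count model:
#'   `round(a + b * size + N(0, sd))`, truncated at 0.
#' @param seed Integer seed driving all randomness of [simulate_dataset()].
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(scheme,
                            species_means = default_species_means(scheme, c("sp1", "sp2")),
                            sexes = "female",
                            sex_shape_offset = 0,
                            sex_size_ratio = 0.9,
                            localities = c(loc1 = 1),
                            locality_shape_effect = 0,
                            allometry_vector = NULL,
                            allometry_coef = 0,
                            da_vector = 0,
                            sigma_individual = 0.01,
                            sigma_fa = 0.005,
                            sigma_imaging = 0.002,
                            sigma_digitizing = 0,
                            size_meanlog = 0,
                            size_sdlog = 0.08,
                            species_size = NULL,
                            n_per_cell = 5L,
                            n_image = 2L,
                            n_digit = 1L,
                            spinule_intercept = 5,
                            spinule_slope = 20,
                            spinule_sd = 2,
                            seed = 1L) {
  k <- scheme$k
  p <- 2L * k
  for (m in species_means) {
    if (nrow(m) != k) abort("species mean shape has wrong landmark count")
    if (is_degenerate_config(m)) abort("degenerate species mean shape")
  }
  mu_ref <- species_means[[1L]]
  mu_ref <- center_config(mu_ref)
  mu_ref <- mu_ref / sqrt(sum(mu_ref^2))
  tangentize <- function(v, extra = NULL) {
    v <- shape_tangent_project_at(v, mu_ref)
    if (!is.null(extra)) v <- extra(v)
    v
  }
  expand_vec <- function(v, label, salt, extra = NULL) {
    if (length(v) == 1L && is.numeric(v)) {
      vv <- tangentize(with_seed_local(seed + salt, rnorm(p)), extra)
      if (sqrt(sum(vv^2)) < 1e-12) abort(sprintf("%s projection degenerate", label))
      return(vv / sqrt(sum(vv^2)) * v)
    }
    if (length(v) != p) abort(sprintf("%s must have length %d", label, p))
    v
  }
  if (is.null(allometry_vector)) {
    allometry_vector <- tangentize(with_seed_local(seed + 102L, rnorm(p)),
                                   if (scheme$symmetry == "object") function(v) sym_project(v, scheme))
    allometry_vector <- allometry_vector / sqrt(sum(allometry_vector^2))
  }
  sex_shape_offset <- expand_vec(sex_shape_offset, "sex_shape_offset", 101L,
                                 if (scheme$symmetry == "object") function(v) sym_project(v, scheme))
  da_vector <- expand_vec(da_vector, "da_vector", 103L,
                          if (scheme$symmetry == "object") function(v) asym_project(v, scheme))
  sig <- c(sigma_individual, sigma_fa, sigma_imaging, sigma_digitizing)
  if (any(sig < 0)) abort("variance components must be >= 0")
  if (n_per_cell < 1L || n_image < 1L || n_digit < 1L) abort("counts must be >= 1")
  if (is.null(species_size)) {
    species_size <- stats::setNames(rep(1, length(species_means)), names(species_means))
  }
  structure(
    list(scheme = scheme, species_means = species_means, sexes = sexes,
         sex_shape_offset = sex_shape_offset, sex_size_ratio = sex_size_ratio,
         localities = localities, locality_shape_effect = locality_shape_effect,
         allometry_vector = allometry_vector, allometry_coef = allometry_coef,
         da_vector = da_vector,
         sigma_individual = sigma_individual, sigma_fa = sigma_fa,
         sigma_imaging = sigma_imaging, sigma_digitizing = sigma_digitizing,
         size_meanlog = size_meanlog, size_sdlog = size_sdlog,
         species_size = species_size,
         n_per_cell = as.integer(n_per_cell), n_image = as.integer(n_image),
         n_digit = as.integer(n_digit),
         spinule_intercept = spinule_intercept, spinule_slope = spinule_slope,
         spinule_sd = spinule_sd, seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' Simulate a landmark dataset
#'
#' Draws a full dataset under the spec's generative model. Individual shape
#' (in the tangent space of the species x sex mean) is
#' mean + allometry * (size - mean size) + N(0, sigma_individual^2);
#' for matching symmetry each side adds +/- DA/2 and a fluctuating-asymmetry
#' deviation N(0, sigma_fa^2); for object symmetry the DA vector and
#' per-individual FA deviations enter as asymmetric components of the single
#' configuration. Each imaging replicate adds N(0, sigma_imaging^2) and each
#' digitization N(0, sigma_digitizing^2). Configurations are emitted in
#' random similarity poses (rotation, translation, scale = centroid size),
#' and spinule counts as `round(a + b * size + noise)`.
#'
#' All randomness flows from `spec$seed` (or the `seed` override); identical
#' seeds give identical output.
#'
#' @param spec A [simulation_spec].
#' @param seed Optional override of `spec$seed`.
#' @param specimen_prefix Prefix for specimen IDs.
#' @return A list: `configs` (configuration tibble as from [read_tps()]),
#'   `classifiers` (classifier tibble), `covariates` (spinule counts),
#'   `truth` (every injected parameter plus per-individual sizes and tangent
#'   shapes, for recovery tests).
#' @export
simulate_dataset <- function(spec, seed = NULL, specimen_prefix = "ind") {
  seed <- seed %||% spec$seed
  cells <- expand.grid(species = names(spec$species_means), sex = spec$sexes,
                       locality = names(spec$localities),
                       stringsAsFactors = FALSE)
  cells <- cells[rep(seq_len(nrow(cells)), each = spec$n_per_cell), , drop = FALSE]
  ids <- sprintf("%s%04d", specimen_prefix, seq_len(nrow(cells)))
  classifiers <- tibble::tibble(
    specimen_id = ids,
    species = factor(cells$species),
    locality = factor(cells$locality),
    sex = factor(cells$sex),
    individual = ids
  )
  out <- simulate_structure(spec, classifiers, seed = seed)
  list(configs = out$configs, classifiers = classifiers,
       covariates = out$covariates, truth = out$truth)
}

#' Simulate Brownian-motion tip values on a tree
#'
#' Gaussian increments along each branch with variance `rate * branch
#' length` per coordinate; the substrate for calibrating the
#' phylogenetic-signal test.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param rate Per-unit-branch-length variance (> 0).
#' @param root Numeric vector: the root value (any length).
#' @param seed Optional seed.
#' @return Matrix of tip values (rows named by tip labels).
#' @export
simulate_bm_tips <- function(tree, rate, root, seed = NULL) {
  if (rate <= 0) abort("`rate` must be positive")
  tree <- validate_phylo(tree)
  with_seed_local(seed, {
    n_tip <- length(tree$tip.label)
    p <- length(root)
    vals <- matrix(NA_real_, n_tip + tree$Nnode, p)
    root_node <- n_tip + 1L
    vals[root_node, ] <- root
    ord <- ape::reorder.phylo(tree, "postorder")
    for (e in rev(seq_len(nrow(ord$edge)))) {
      a <- ord$edge[e, 1L]
      b <- ord$edge[e, 2L]
      vals[b, ] <- vals[a, ] + rnorm(p, 0, sqrt(rate * ord$edge.length[e]))
    }
    out <- vals[seq_len(n_tip), , drop = FALSE]
    rownames(out) <- tree$tip.label
    out
  })
}

#' The synthetic study fixture
#'
#' A deterministic bundle emulating the design of the Acanthocyclops
#' delimitation study: five landmark schemes (45/7/10/7/15 landmarks, 84 in
#' total), 147 specimens of 4 species x 2 sexes over 7 localities, the
#' 4-taxon tree `((vernalis,europensis),(robustus,americanus))` with unit
#' branch lengths, object symmetry with 26 sliding semilandmarks on the
#' genital somite (digitized for females only, twice), matching symmetry
#' with two imaging replicates per side on the other structures, and
#' duplicate digitizations for P4Enp3 (eight configurations per individual).
#' Injected effects are ordered species > sex > locality and fluctuating
#' asymmetry > imaging > digitizing.
#'
#' @param seed Seed of the bundle (one seed drives everything).
#' @return A list: `schemes`, `tree`, `classifiers`, `covariates`,
#'   `datasets` (named list of configuration tibbles per scheme), `specs`
#'   (the per-structure [simulation_spec]s), `truth`.
#' @export
acanthocyclops_fixture <- function(seed = 2019L) {
  schemes <- acanthocyclops_schemes()
  species <- c("vernalis", "europensis", "robustus", "americanus")
  tree <- ape::read.tree(
    text = "((vernalis:1,europensis:1):1,(robustus:1,americanus:1):1);")

  # 147 specimens: females/males per species
  n_f <- c(vernalis = 22L, europensis = 25L, robustus = 21L, americanus = 20L)
  n_m <- c(vernalis = 15L, europensis = 14L, robustus = 15L, americanus = 15L)
  stopifnot(sum(n_f) + sum(n_m) == 147L)
  localities <- paste0("loc", 1:7)
  loc_size <- stats::setNames(1 + 0.02 * c(-3, -2, -1, 0, 1, 2, 3) / 3, localities)
  species_size <- c(vernalis = 1.00, europensis = 1.05, robustus = 1.15,
                    americanus = 0.85)

  with_seed_local(seed, {
    rows <- list()
    counter <- 0L
    for (sp in species) {
      for (sx in c("female", "male")) {
        n <- if (sx == "female") n_f[[sp]] else n_m[[sp]]
        locs <- rep(localities, length.out = n)
        for (i in seq_len(n)) {
          counter <- counter + 1L
          rows[[counter]] <- tibble::tibble(
            specimen_id = sprintf("acn%03d", counter), species = sp,
            locality = locs[i], sex = sx,
            individual = sprintf("acn%03d", counter))
        }
      }
    }
    classifiers <- dplyr::bind_rows(rows)
    classifiers$species <- factor(classifiers$species, levels = species)
    classifiers$locality <- factor(classifiers$locality, levels = localities)
    classifiers$sex <- factor(classifiers$sex, levels = c("female", "male"))

    specs <- list()
    datasets <- list()
    covariates <- NULL
    for (nm in names(schemes)) {
      sch <- schemes[[nm]]
      this_cls <- classifiers
      if (nm == "Gs") this_cls <- dplyr::filter(classifiers, .data$sex == "female")
      sp_seed <- seed + match(nm, names(schemes))
      # allometry strength per structure: chosen so that size predicts about
      # 30% of within-group shape variance for Cr, 12% for Gs and 8% for the
      # leg segments (the qualitative pattern of the study system), given the
      # individual scatter sigma_ind per coordinate and within-cell size
      # scatter of about 0.08
      allom_share <- c(Gs = 0.12, Cr = 0.30, P4Exp3 = 0.08, P4Enp3 = 0.08,
                       P4CxBp = 0.08)[[nm]]
      sigma_ind <- 0.02
      allom_coef <- sqrt(allom_share / (1 - allom_share)) *
        sigma_ind * sqrt(2 * sch$k) / 0.08
      spec <- simulation_spec(
        scheme = sch,
        species_means = default_species_means(sch, species, effect = 0.12,
                                              seed = sp_seed),
        sexes = if (nm == "Gs") "female" else c("female", "male"),
        sex_shape_offset = if (nm == "Gs") 0 else 0.04,
        sex_size_ratio = 0.9,
        localities = loc_size,
        locality_shape_effect = 0.015,
        allometry_coef = allom_coef,
        da_vector = 0.01,
        sigma_individual = 0.02, sigma_fa = 0.010, sigma_imaging = 0.003,
        sigma_digitizing = if (nm == "P4Enp3") 0.001 else 0,
        species_size = species_size,
        n_image = 2L,
        n_digit = if (nm == "P4Enp3") 2L else 1L,
        seed = sp_seed
      )
      specs[[nm]] <- spec
      datasets[[nm]] <- simulate_structure(spec, this_cls, seed = sp_seed)
      if (nm == "Cr") {
        covariates <- datasets[[nm]]$covariates
      }
    }
    configs_only <- lapply(datasets, `[[`, "configs")
    list(schemes = schemes, tree = tree, classifiers = classifiers,
         covariates = covariates, datasets = configs_only,
         specs = specs,
         truth = lapply(datasets, `[[`, "truth"))
  })
}

# Generate one structure for a fixed classifier table.

simulate_structure <- function(spec, classifiers, seed) {
  scheme <- spec$scheme
  k <- scheme$k
  p <- 2L * k
  sides <- if (scheme$symmetry == "matching") c("left", "right") else "none"
  mu_ref <- center_config(spec$species_means[[1L]])
  mu_ref <- mu_ref / sqrt(sum(mu_ref^2))
  with_seed_local(seed, {
    loc_shape <- lapply(stats::setNames(names(spec$localities), names(spec$localities)),
                        function(l) {
                          if (spec$locality_shape_effect == 0) return(numeric(p))
                          v <- shape_tangent_project_at(rnorm(p), mu_ref)
                          if (scheme$symmetry == "object") v <- sym_project(v, scheme)
                          v / sqrt(sum(v^2)) * spec$locality_shape_effect
                        })
    mean_size <- exp(spec$size_meanlog + spec$size_sdlog^2 / 2)
    configs <- list()
    truth_rows <- list()
    for (r in seq_len(nrow(classifiers))) {
      sp <- as.character(classifiers$species[r])
      sx <- as.character(classifiers$sex[r])
      loc <- as.character(classifiers$locality[r])
      id <- classifiers$specimen_id[r]
      mu <- flatten_config(spec$species_means[[sp]])
      if (sx != spec$sexes[1L]) mu <- mu + spec$sex_shape_offset
      mu <- mu + loc_shape[[loc]]
      size <- rlnorm(1, spec$size_meanlog, spec$size_sdlog) *
        spec$species_size[[sp]] * spec$localities[[loc]] *
        (if (sx != spec$sexes[1L]) spec$sex_size_ratio else 1)
      ind_dev <- rnorm(p, 0, spec$sigma_individual)
      if (scheme$symmetry == "object") ind_dev <- sym_project(ind_dev, scheme)
      ind_shape <- mu + spec$allometry_vector * spec$allometry_coef * (size - mean_size) +
        ind_dev
      if (scheme$symmetry == "object") {
        fa <- asym_project(rnorm(p, 0, spec$sigma_fa), scheme)
        side_shapes <- list(none = ind_shape + spec$da_vector + fa)
      } else {
        side_shapes <- list(
          left = ind_shape + spec$da_vector / 2 + rnorm(p, 0, spec$sigma_fa),
          right = ind_shape - spec$da_vector / 2 + rnorm(p, 0, spec$sigma_fa)
        )
      }
      for (sd_name in names(side_shapes)) {
        for (im in seq_len(spec$n_image)) {
          img_shape <- side_shapes[[sd_name]] + rnorm(p, 0, spec$sigma_imaging)
          for (dg in seq_len(spec$n_digit)) {
            v <- img_shape + rnorm(p, 0, spec$sigma_digitizing)
            m <- unflatten_config(v)
            if (sd_name == "right") m <- reflect_config(m, scheme)
            m <- center_config(m)
            # scale directly: digitizing/imaging noise then perturbs measured
            # centroid size too, as it does in real data
            m <- m * size
            th <- runif(1, 0, 2 * pi)
            R <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
            m <- m %*% R
            m <- sweep(m, 2L, runif(2, -5, 5), "+")
            configs[[length(configs) + 1L]] <- tibble::tibble(
              specimen = id, side = sd_name, image_rep = im, digit_rep = dg,
              id = format_config_id(id, sd_name, im, dg), coords = list(m))
          }
        }
      }
      truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
        specimen_id = id, size = size, shape = list(ind_shape))
    }
    truth_ind <- dplyr::bind_rows(truth_rows)
    covariates <- tibble::tibble(
      specimen_id = truth_ind$specimen_id,
      spinules_total = pmax(0, round(spec$spinule_intercept +
                                       spec$spinule_slope * truth_ind$size +
                                       rnorm(nrow(truth_ind), 0, spec$spinule_sd))))
    list(configs = dplyr::bind_rows(configs), covariates = covariates,
         truth = list(spec = spec, individuals = truth_ind,
                      da_norm = sqrt(sum(spec$da_vector^2)), mean_size = mean_size))
  })
}
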