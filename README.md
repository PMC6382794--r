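# morphodelim

Landmark-based geometric morphometrics for delimiting closely related
species — built for the kind of problem posed by morphologically
hypervariable crustaceans such as the *Acanthocyclops vernalis* complex,
where classical characters fail and species boundaries must be read from
quantitative shape.

Given 2D landmark configurations (TPS files), a specimen classifier table
and, optionally, a phylogeny, the package provides the full pipeline:

* **Superimposition** — generalized Procrustes analysis (GPA) with sliding
  semilandmarks (minimum Procrustes distance criterion) and decomposition
  of bilateral symmetry, both *object* symmetry (a structure with an
  internal midline) and *matching* symmetry (left/right paired structures).
  Shape lives in the tangent space of dimension 2k − 4; size is centroid
  size.
* **Hierarchical Procrustes ANOVA** — species, locality, sex, individual,
  directional asymmetry, fluctuating asymmetry, imaging and digitizing
  error, each tested one-way against its denominator stratum with
  Goodall's F and permutation P-values, P = (#{F\* ≥ F} + 1)/(n_perm + 1).
* **Allometry** — multivariate regression of shape on centroid size,
  percent of variance predicted, permutation test, and idempotent size
  correction on regression residuals.
* **Ordination & classification** — PCA of per-individual symmetric shapes
  with convex species hulls, and pairwise discriminant analysis with
  honest leave-one-out cross-validation (projection refitted per fold).
* **Integration & modularity** — two-block partial least squares with the
  RV coefficient, RV = trace(S₁₂S₂₁)/√(trace(S₁₁²)·trace(S₂₂²)), matrix
  correlation between individual variation and fluctuating asymmetry, and
  RV-based tests of landmark modularity against enumerated or sampled
  alternative partitions (optionally contiguous on the scheme's adjacency
  graph).
* **Phylogenetic signal** — squared-change parsimony mapping of mean shapes
  onto a supplied tree (exact Laplacian solver) with a tip-permutation
  test, enumerated exhaustively when the tip count allows.
* **Synthetic data** — a seeded generator of landmark datasets with nested
  variance components (individual, FA, imaging, digitizing), allometry,
  directional asymmetry and similarity-transformed poses, plus
  `acanthocyclops_fixture()`, a deterministic 147-specimen, five-structure,
  84-landmark study bundle.

Everything is tidyverse-shaped: configuration tables are tibbles with a
`coords` list-column, shapes travel as matrix columns, results have
`tidy()`/`glance()` methods and `autoplot()` graphics.

## Worked example

Simulate a two-species dataset of the third endopodal segment of the fourth
leg (7 landmarks, matching left/right symmetry, two imaging replicates),
then run superimposition, Procrustes ANOVA, size correction, PCA and
cross-validated discriminant analysis:

```r
library(morphodelim)
library(dplyr)

sch <- acanthocyclops_schemes()$P4Enp3
spec <- simulation_spec(
  sch,
  species_means = default_species_means(sch, c("vernalis", "europensis"),
                                        effect = 0.1, seed = 7),
  da_vector = 0.02, sigma_individual = 0.015, sigma_fa = 0.008,
  sigma_imaging = 0.003, n_per_cell = 15L, seed = 7L
)
d <- simulate_dataset(spec)

res <- assemble_matching_symmetry(d$configs, sch)
res$fit
#> <gpa_fit> 120 configurations, 7 landmarks, tangent dim 10, 5 iteration(s)

procrustes_anova_shape(res$decomposition, d$classifiers,
                       n_perm = 999, seed = 1)
#> <procrustes_anova> response = shape, 999 permutations
#>                  effect       SS  df        MS      F     P
#> 1               species 0.087755  10 8.775e-03 34.180 0.001
#> 2            individual 0.319287 290 1.101e-03 15.624 0.001
#> 3 directional asymmetry 0.010961  10 1.096e-03 15.555 0.001
#> 4 fluctuating asymmetry 0.020435 290 7.047e-05  8.592 0.001
#> 5               imaging 0.004921 600 8.201e-06     NA    NA
```

Species is the dominant shape effect (F = 34.2 at 10 tangent dimensions,
P = 0.001, the smallest attainable value with 999 permutations); the
injected directional asymmetry is detected against fluctuating asymmetry,
and FA in turn stands far above imaging error. Downstream, per-individual
symmetric shapes are size-corrected and ordinated:

```r
ind <- individual_symmetric_shapes(res$decomposition)
dat <- left_join(ind, d$classifiers, by = c(individual = "specimen_id"))
dat$size <- as.vector(tapply(res$fit$centroid_sizes,
                             d$configs$specimen, mean)[dat$individual])
dat <- size_correct(dat, groups = "species")

pca_shapes(dat, groups = "species")
#> <shape_pca> 11 axes; PC1 61.9%, PC2 8.6%

dfa_pairwise(dat, "shape", "species")
#> <shape_dfa> europensis vs vernalis
#> resubstitution % correct:
#> europensis   vernalis    overall
#>        100        100        100
#> leave-one-out % correct:
#> europensis   vernalis    overall
#>        100        100        100
```

The first principal component carries the species contrast (61.9% of
variance) and the two synthetic species classify perfectly even under
leave-one-out cross-validation — the pattern a well-separated species pair
shows in morphospace. `autoplot()` on the PCA, PLS or modularity objects
draws the corresponding scatter, hull or null-distribution figures.

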