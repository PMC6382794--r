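---
title: "Methods: landmark morphometrics for species delimitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark morphometrics for species delimitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

morphodelim implements a complete landmark-based geometric-morphometrics
pipeline for delimiting closely related species from 2D digitizations of
rigid structures, of the kind used for cyclopoid copepods: generalized
Procrustes superimposition with sliding semilandmarks and bilateral-symmetry
decomposition, hierarchical Procrustes ANOVA, allometry regression and size
correction, ordination and discriminant analysis, two-block PLS and
modularity tests, and squared-change parsimony mapping of mean shapes onto a
phylogeny. This vignette explains the models, the parameters that matter,
the numerical choices, and what the synthetic-data generator does and does
not emulate.

## Superimposition

A digitized structure is a configuration of $k$ planar landmarks. Shape is
what remains after removing position, scale and orientation: each
configuration is centered, scaled to unit centroid size (the square root of
the summed squared distances of landmarks from their centroid), and rotated
to minimize its summed squared distance to a consensus; the consensus is the
renormalized mean of the aligned configurations and the two steps alternate
until the consensus moves by less than `tol` (default `1e-10`, maximum 100
iterations). Tangent-space coordinates are the orthogonal projection of the
aligned configurations onto the plane tangent to the unit sphere at the
consensus, stored as deviations from the consensus; for $k$ landmarks in 2D
this space has $2k - 4$ dimensions. The orientation of the consensus — and
hence of all tangent coordinates — is arbitrary; every statistic the package
computes is invariant to it.

Semilandmarks digitized along outlines carry no point-to-point homology
along their curve. `slide_semilandmarks()` lets each interior curve point
slip along its local tangent (the chord between its two curve neighbours) to
the position nearest the consensus — the minimum-Procrustes-distance
criterion — then refits the superimposition, for a fixed number of cycles
(default 5). The total Procrustes sum of squares is non-increasing across
cycles, which the test suite checks. Bending-energy sliding would need
thin-plate-spline machinery and is deliberately out of scope; for the
short, gently curved lateral edges this package targets, the two criteria
move sliders by similar amounts.

## Symmetry decomposition

Two kinds of bilateral symmetry are handled. *Object symmetry* (a somite
with an internal midline): each configuration and its reflected-and-
relabelled copy (x negated, paired landmarks swapped, midline landmarks
fixed) enter one joint superimposition. The joint consensus is
reflection-invariant only up to a rotation; if reflecting it equals rotating
it by $\theta$, rotating the consensus by $\theta/2$ makes it exactly
invariant (conjugating a rotation by a reflection inverts it), and the whole
solution is realigned to that symmetric consensus. The symmetric component
of a configuration is the average of its aligned original and aligned
reflected copy; the asymmetric component is the difference from the
original, so reconstruction is exact by construction and the two components
are orthogonal over the joint set.

*Matching symmetry* (left and right copies of a paired structure): right
sides are reflected into left orientation and all configurations enter one
joint fit. A specimen's symmetric component is its mean aligned shape over
sides and replicates; side deviations carry directional asymmetry (the mean
left−right contrast) and fluctuating asymmetry (individual-specific
left−right deviations). Specimens lacking one side are excluded from the
asymmetry analyses but keep their symmetric mean — the policy
`validate_dataset()` reports.

## Hierarchical Procrustes ANOVA

Shape variation is quantified stratum by stratum, following the classical
measurement design: species, locality and sex (among individual mean
shapes), individual variation, directional asymmetry (the side main
effect), fluctuating asymmetry (the individual × side interaction), and
imaging and digitizing error. Each effect is tested one-way against the
denominator stratum below it with Goodall's F — the ratio of mean squares of
Procrustes sums of squares under an isotropic variation model, with shape
degrees of freedom equal to the univariate ones times $2k-4$. Sums of
squares are computed from the means at each stratum's aggregation level
(individual means, individual × side cell means, image means), and adjacent
strata are compared directly at that scale. Under mild unbalance this is an
approximation to the classical weighted decomposition; the generator's
designs are balanced, where it is exact.

P-values come from permutations with the +1 correction,
$P = (\#\{F^\ast \ge F\} + 1)/(n_{perm} + 1)$, so $P$ is never zero and
always in $[1/(n_{perm}+1),\,1]$. The permutation unit is the experimental
unit of the denominator stratum, never raw residual coordinates:

* species / locality / sex — whole individuals permuted across groups
  (exact under the null);
* directional asymmetry — side labels flipped within individuals (exact,
  by reflection exchangeability; for object symmetry, random sign flips of
  each individual's asymmetric mean);
* individual — cell-mean records permuted across individuals within sides;
* fluctuating asymmetry and imaging — replicate-level records (image means,
  digitizations) permuted within their nesting level after removing the
  additive structure above them. These last schemes are approximate
  residual-unit permutations; the type-I calibration in the test suite
  covers the group-effect test, which is the one used for inference about
  species.

The size ANOVA is the univariate analogue (degrees of freedom not
multiplied by $2k-4$). Size is reflection-invariant, so object-symmetric
structures have no size asymmetry strata.

## Allometry

Allometry is the component of shape predicted by size.
`regress_shape_on_covariate()` fits the multivariate least-squares slope of
tangent shape on centroid size (raw size, not log — log-size is available
by transforming the covariate) and reports
`percent_predicted = 100 · SS_predicted / SS_total`, with a permutation
test shuffling covariate values across units. With `groups` (default
recommendation: species × sex) both sides are centered within groups first,
so the estimate is the common within-group allometry, and permutations stay
within groups. `size_correct()` removes allometry for downstream ordination:
it fits the regression *per group* and returns residuals plus the group
mean, so corrected shapes have exactly zero within-group sample covariance
with size and the operation is idempotent. The two choices differ
deliberately: the pooled slope is the better *estimate* of a shared
allometric trend; per-group correction is the safer *adjustment*, since it
cannot leak group differences through a common slope.

## Ordination and discrimination

PCA is the eigendecomposition of the covariance of per-individual shapes
(conventionally the size-corrected symmetric component averaged by
individual). Axis signs follow a fixed convention — the largest-magnitude
loading of each axis is positive — so results are reproducible across
platforms. Per-group convex hulls in the PC1–PC2 plane summarize species
separation in morphospace.

Pairwise discriminant analysis handles the $p \gg n$ geometry of shape data
by projecting onto the principal subspace of the total covariance (axes
with eigenvalue above $10^{-12}$ of the largest, capped at $n-2$ so the
pooled within-group covariance stays invertible) and computing Fisher's
linear discriminant there; a tiny ridge is added only if the within-group
covariance is still numerically singular, and the event is logged.
Leave-one-out cross-validation refits *both* the projection and the
discriminant without the held-out specimen — refitting only the
discriminant would leak the held-out point through the subspace.

## Integration and modularity

The RV coefficient between two blocks of variables is
$\mathrm{trace}(S_{12}S_{21}) / \sqrt{\mathrm{trace}(S_{11}^2)\,
\mathrm{trace}(S_{22}^2)}$ on centered blocks — a multivariate
generalization of a squared correlation, in $[0,1]$ and invariant to
rotations of either block. Two-block PLS decomposes the between-block
covariance by SVD into paired axes of maximal covariation; the percent of
total squared covariance per axis is $d_i^2/\sum d^2$. Significance of the
RV permutes the individuals of one block (within species × sex cells when
pooled). The two structures are superimposed *separately*; a joint fit
would mix within-structure shape with relative size and position.

The modularity test asks whether a hypothesized two-module landmark
partition has *lower* RV between modules than alternative partitions of the
same subset sizes: the support statistic is the proportion of alternatives
with RV at or below the observed value. Alternatives are enumerated
exhaustively when their number does not exceed `n_alternatives` (default
10,000) and otherwise sampled uniformly without duplicates; in contiguous
mode both induced subgraphs of the scheme's adjacency graph must be
connected. One caveat specific to object-symmetric structures: in the
symmetric component, mirror-pair landmarks are perfectly correlated, so
partitions that keep pairs together (as anatomical hypotheses do) have
systematically lower between-module RV than pair-splitting alternatives;
the contiguous mode and a pair-respecting null would be the conservative
comparison.

The matrix correlation between individual variation and fluctuating
asymmetry correlates the entries of the two 2k × 2k covariance matrices
(optionally excluding the diagonal 2 × 2 landmark blocks), with significance
from permuting landmark identities — whole 2 × 2 blocks — in one matrix.

## Phylogenetic signal

Species (or species × sex) mean shapes are mapped onto a user-supplied
rooted tree by weighted squared-change parsimony: internal-node values
minimize the sum over branches of squared change divided by branch length.
The minimizer solves the linear system of the branch-weighted tree
Laplacian; the attained minimum ("tree length") is zero iff all tips are
equal, separates across coordinates, and is computed for permutations via
the Schur-complement quadratic form, so each relabeling costs one small
matrix product. Missing branch lengths default to 1 with a warning;
non-positive lengths are floored at $10^{-9}$.

The signal test permutes whole multivariate tip records among the terminal
nodes and reports the proportion of relabelings with tree length at or
below the observed one. With $n$ tips there are only $n!$ distinct
relabelings; when $n! \le n_{perm}$ the test enumerates all of them exactly
and says so — with 4 species the attainable P-values are multiples of 1/24,
a resolution warning the user should take seriously.

## The synthetic-data generator

No raw landmark data are deposited for the study system this package
emulates, so the generator is a first-class, tested module: every analysis
is validated by closing the loop injected parameter → pipeline → estimate.
The generative model draws, per individual, size from a log-normal
distribution (multiplied by species, sex and locality factors) and tangent
shape as species × sex mean + allometry × (size − mean size) + isotropic
Gaussian individual deviation; sides add ±DA/2 and a fluctuating-asymmetry
deviation (for object symmetry, DA and FA enter as asymmetric components of
the single configuration); imaging and digitizing replicates add their own
isotropic noise. All injected effect vectors are projected onto the shape
tangent space at the mean (and onto the symmetric or asymmetric subspace
where the scheme requires it), so their norms are Procrustes norms that
survive superimposition exactly. Configurations are emitted in random
similarity poses, and digitizing noise perturbs measured centroid size as
it does in real data. One seed drives everything; identical seeds give
byte-identical TPS output.

`acanthocyclops_fixture()` instantiates the study design: five schemes of
45/7/10/7/15 landmarks (84 in total; the 45-landmark genital somite with
object symmetry, 26 lateral-edge sliders and an 86-dimensional tangent
space), 147 specimens of 4 species × 2 sexes over 7 localities, the
4-taxon tree, two imaging replicates everywhere, duplicate digitizations
for the third endopodal segment (8 configurations per individual), and the
genital somite digitized for females only. Effect magnitudes are declared
study conditions, ordered as the system's published pattern: species
(0.12 Procrustes units) > sex (0.04) > locality (0.015);
σ(FA) = 0.010 > σ(imaging) = 0.003 > σ(digitizing) = 0.001 per coordinate;
allometry scaled per structure so size predicts roughly 30% of within-group
shape variance for the caudal ramus, 12% for the genital somite and 8% for
the leg segments; male/female size ratio 0.9 and species size factors
0.85–1.15 with the largest species also the largest structure.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: noise is isotropic (real landmark covariance is
structured), the five structures are simulated independently (so
between-structure RV is at its null level, and the published
between-structure covariation is not reproduced), there is no injected
modular structure, landmark digitization order errors and outliers are
absent, and designs are balanced. The published F-values, PC percentages
and RV coefficients of the source system are not reproducible without its
raw data; the pipeline's correctness is instead established by
property-based tests and parameter recovery.

## Problem sizes and runtime

The test suite calibrates type-I error with 500 null replicates at
n_perm = 199 for four tests (Procrustes ANOVA species effect, allometry
regression, PLS RV, phylogenetic signal at 16 tips), and recovers injected
parameters at n = 50–100 individuals; the full suite runs in under two
minutes on one CPU. The acceptance script analyses the full 147-specimen
fixture (999 ANOVA and regression permutations, 9,999 PLS permutations,
10,000 alternative modularity partitions) in well under a minute. Scaling
n_perm to the 10,000 of a publication-grade analysis changes only runtime.

## Known limitations

3D landmarks, bending-energy sliding, missing-landmark estimation,
canonical variates for more than two groups, non-isotropic (per-landmark
covariance) Procrustes ANOVA, REML variance components, and
covariance-ratio modularity statistics are out of scope. The permutation
schemes for the measurement-error strata are approximate (see above). The
four-taxon phylogenetic-signal test is reported honestly as a
low-resolution test.
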