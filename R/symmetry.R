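#' Reflect a configuration across the vertical axis and relabel
#'
#' Negates the x coordinate and then swaps the rows of each landmark pair in
#' the scheme (midline landmarks keep their row). For object symmetry this
#' maps a configuration onto its mirror image in the same landmark numbering;
#' for matching symmetry it maps a right-side configuration into left-side
#' orientation.
#'
#' @param coords k x 2 matrix.
#' @param scheme [landmark_scheme] supplying `pairs`.
#' @return k x 2 matrix.
#' @export
reflect_config <- function(coords, scheme) {
  out <- coords
  out[, 1L] <- -out[, 1L]
  if (nrow(scheme$pairs) > 0L) {
    perm <- seq_len(scheme$k)
    perm[scheme$pairs[, 1L]] <- scheme$pairs[, 2L]
    perm[scheme$pairs[, 2L]] <- scheme$pairs[, 1L]
    out <- out[perm, , drop = FALSE]
  }
  out
}

new_symmetry_decomposition <- function(mode, info, aligned, symmetric, asymmetric,
                                       consensus, tangent_dim, complete = NULL) {
  structure(
    list(mode = mode, info = info, aligned = aligned, symmetric = symmetric,
         asymmetric = asymmetric, consensus = consensus,
         tangent_dim = tangent_dim, complete = complete),
    class = "symmetry_decomposition"
  )
}

#' Decompose object symmetry into symmetric and asymmetric components
#'
#' For a structure with an internal midline, each configuration and its
#' reflected-and-relabelled copy enter one joint generalized Procrustes fit.
#' The symmetric component of a configuration is the average of its aligned
#' original and aligned reflected copy; the asymmetric component is the
#' aligned original minus the symmetric component, so reconstruction is exact
#' by construction. Over the joint set (originals plus reflections) the two
#' components are orthogonal, so their sums of squares add up to the total
#' deviation from the consensus.
#'
#' @param configs Configuration tibble (one configuration per specimen x
#'   replicate; `side` is `"none"` for object symmetry).
#' @param scheme [landmark_scheme] with `symmetry = "object"`.
#' @param tol,max_iter Passed to [gpa()].
#' @return A list with `fit` (the joint `gpa_fit` over 2n configurations; its
#'   `info` gains a logical `reflected` column) and `decomposition` (class
#'   `symmetry_decomposition`) whose rows follow the n original
#'   configurations: `aligned`, `symmetric`, `asymmetric` are n x 2k flat
#'   coordinate matrices.
#' @export
decompose_object_symmetry <- function(configs, scheme, tol = 1e-10, max_iter = 100L) {
  if (scheme$symmetry != "object") abort("scheme does not declare object symmetry")
  n <- nrow(configs)
  mirrored <- configs
  mirrored$coords <- lapply(configs$coords, reflect_config, scheme = scheme)
  joint <- dplyr::bind_rows(
    dplyr::mutate(configs, reflected = FALSE),
    dplyr::mutate(mirrored, reflected = TRUE)
  )
  fit <- gpa(joint, scheme = scheme, tol = tol, max_iter = max_iter)
  # The joint consensus is reflection-invariant only up to a rotation: if
  # reflect-relabel(c) = c rotated by theta, then rotating c by theta/2 makes
  # it exactly invariant (conjugation by the reflection inverts rotations).
  cons <- fit$consensus
  for (it in seq_len(max_iter)) {
    consR <- reflect_config(cons, scheme)
    Q <- optimal_rotation(cons, consR)
    theta <- atan2(Q[2L, 1L], Q[1L, 1L])
    H <- rbind(c(cos(theta / 2), -sin(theta / 2)),
               c(sin(theta / 2), cos(theta / 2)))
    cons <- cons %*% H
    cons2 <- (cons + reflect_config(cons, scheme)) / 2
    cons2 <- cons2 / sqrt(sum(cons2^2))
    moved <- max(abs(cons2 - cons))
    cons <- cons2
    if (moved < tol) break
  }
  fit$coords <- lapply(fit$coords, function(m) m %*% optimal_rotation(m, cons))
  fit$consensus <- cons
  fit$tangent <- tangent_project(fit$coords, cons)
  X <- do.call(rbind, lapply(fit$coords, flatten_config))
  orig <- X[seq_len(n), , drop = FALSE]
  refl <- X[n + seq_len(n), , drop = FALSE]
  symmetric <- (orig + refl) / 2
  asymmetric <- orig - symmetric
  decomp <- new_symmetry_decomposition(
    mode = "object",
    info = dplyr::select(configs, -dplyr::any_of("coords")),
    aligned = orig, symmetric = symmetric, asymmetric = asymmetric,
    consensus = fit$consensus, tangent_dim = fit$tangent_dim
  )
  list(fit = fit, decomposition = decomp)
}

#' Assemble matching (left/right) symmetry
#'
#' For paired structures digitized separately on the two body sides, the
#' right-side configurations are reflected into left orientation and all
#' configurations enter one joint generalized Procrustes fit. The symmetric
#' component of a specimen is its mean aligned shape over sides and
#' replicates; each configuration's asymmetric component is its deviation
#' from that mean. Side deviations feed the directional/fluctuating
#' asymmetry ANOVA.
#'
#' Specimens lacking one side are excluded from the asymmetric component (the
#' [validate_dataset()] policy) but keep their symmetric mean.
#'
#' @param configs Configuration tibble with `side` in `"left"`/`"right"`.
#' @param scheme [landmark_scheme] with `symmetry = "matching"`.
#' @param tol,max_iter Passed to [gpa()].
#' @return A list with `fit` (joint `gpa_fit`; `info` gains `reflected`
#'   marking reflected right sides) and `decomposition`
#'   (`symmetry_decomposition`; one row per configuration, with `complete`
#'   flagging specimens having both sides).
#' @export
assemble_matching_symmetry <- function(configs, scheme, tol = 1e-10, max_iter = 100L) {
  if (scheme$symmetry != "matching") abort("scheme does not declare matching symmetry")
  if (!all(configs$side %in% c("left", "right"))) {
    abort("matching symmetry needs every configuration labelled left or right")
  }
  work <- configs
  is_right <- work$side == "right"
  work$coords <- lapply(seq_len(nrow(work)), function(i) {
    if (is_right[i]) reflect_config(work$coords[[i]], scheme) else work$coords[[i]]
  })
  work$reflected <- is_right
  fit <- gpa(work, scheme = scheme, tol = tol, max_iter = max_iter)
  X <- do.call(rbind, lapply(fit$coords, flatten_config))

  spec <- as.factor(configs$specimen)
  spec_means <- rowmeans_by(X, spec)
  symmetric <- spec_means[as.integer(droplevels(spec)), , drop = FALSE]
  asymmetric <- X - symmetric
  sides_per <- tapply(configs$side, spec, function(s) length(unique(s)))
  complete <- as.vector(sides_per[as.character(spec)] == 2L)
  if (any(!complete)) {
    inform(sprintf("%d specimen(s) lack one side; excluded from asymmetry analyses",
                   length(unique(configs$specimen[!complete]))))
  }
  decomp <- new_symmetry_decomposition(
    mode = "matching",
    info = dplyr::select(configs, -dplyr::any_of("coords")),
    aligned = X, symmetric = symmetric, asymmetric = asymmetric,
    consensus = fit$consensus, tangent_dim = fit$tangent_dim,
    complete = complete
  )
  list(fit = fit, decomposition = decomp)
}

#' Per-individual symmetric mean shapes
#'
#' Averages the symmetric component over all configurations of each
#' individual — the analysis unit for PCA, regressions and group means.
#'
#' @param decomposition A `symmetry_decomposition`.
#' @param individuals Optional vector mapping configurations to individuals;
#'   defaults to the decomposition's `specimen` column.
#' @return A tibble with `individual` and a matrix column `shape` (flat
#'   aligned coordinates).
#' @export
individual_symmetric_shapes <- function(decomposition, individuals = NULL) {
  ind <- individuals %||% decomposition$info$specimen
  f <- as.factor(ind)
  m <- rowmeans_by(decomposition$symmetric, f)
  tibble::tibble(individual = levels(droplevels(f)), shape = m)
}

#' @export
print.symmetry_decomposition <- function(x, ...) {
  cat(sprintf("<symmetry_decomposition> mode = %s, %d configurations, %d landmarks\n",
              x$mode, nrow(x$aligned), ncol(x$aligned) / 2L))
  invisible(x)
}
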