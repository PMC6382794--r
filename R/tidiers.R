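#' Broom-style tidiers for morphodelim results
#'
#' `tidy()` returns the per-row content of a result (effects, axes,
#' assignments) as a tibble; `glance()` returns a one-row summary.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name morphodelim-tidiers
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname morphodelim-tidiers
#' @export
tidy.gpa_fit <- function(x, ...) {
  k <- nrow(x$consensus)
  purrr::map2_dfr(seq_along(x$coords), x$coords, function(i, m) {
    tibble::tibble(x$info[i, , drop = FALSE], landmark = seq_len(k),
                   x = m[, 1L], y = m[, 2L])
  })
}

#' @rdname morphodelim-tidiers
#' @export
glance.gpa_fit <- function(x, ...) {
  tibble::tibble(
    n = length(x$coords), k = nrow(x$consensus), tangent_dim = x$tangent_dim,
    iterations = x$iterations, converged = x$converged,
    rms_procrustes = sqrt(mean(vapply(x$coords, function(m)
      sum((m - x$consensus)^2), numeric(1))))
  )
}

#' @rdname morphodelim-tidiers
#' @export
tidy.procrustes_anova <- function(x, ...) x$table

#' @rdname morphodelim-tidiers
#' @export
glance.procrustes_anova <- function(x, ...) {
  tibble::tibble(response = x$response, n_effects = nrow(x$table),
                 n_perm = x$n_perm,
                 largest_effect = x$table$effect[which.max(x$table$F)])
}

#' @rdname morphodelim-tidiers
#' @export
tidy.shape_regression <- function(x, ...) {
  tibble::tibble(coordinate = seq_along(x$coefficients), estimate = x$coefficients)
}

#' @rdname morphodelim-tidiers
#' @export
glance.shape_regression <- function(x, ...) {
  tibble::tibble(percent_predicted = x$percent_predicted, P = x$P,
                 pooling = x$pooling, n = x$n, n_perm = x$n_perm)
}

#' @rdname morphodelim-tidiers
#' @export
tidy.shape_pca <- function(x, ...) {
  tibble::tibble(axis = seq_along(x$eigenvalues), eigenvalue = x$eigenvalues,
                 percent_variance = x$percent_variance,
                 cumulative_percent = cumsum(x$percent_variance))
}

#' @rdname morphodelim-tidiers
#' @export
glance.shape_pca <- function(x, ...) {
  tibble::tibble(n = nrow(x$scores), n_axes = length(x$eigenvalues),
                 pc1_percent = x$percent_variance[1L],
                 pc12_percent = sum(x$percent_variance[1:min(2L, length(x$percent_variance))]))
}

#' @rdname morphodelim-tidiers
#' @export
tidy.shape_dfa <- function(x, ...) x$assignments

#' @rdname morphodelim-tidiers
#' @export
glance.shape_dfa <- function(x, ...) {
  tibble::tibble(
    group1 = x$groups[1L], group2 = x$groups[2L],
    percent_correct = unname(x$percent_correct$resubstitution["overall"]),
    percent_correct_loo = if (is.null(x$percent_correct$loo)) NA_real_ else
      unname(x$percent_correct$loo["overall"])
  )
}

#' @rdname morphodelim-tidiers
#' @export
tidy.shape_pls <- function(x, ...) {
  tibble::tibble(axis = seq_along(x$singular_values),
                 singular_value = x$singular_values,
                 percent_covariance = x$percent_covariance)
}

#' @rdname morphodelim-tidiers
#' @export
glance.shape_pls <- function(x, ...) {
  tibble::tibble(rv = x$rv, P = x$P, n = x$n, pooling = x$pooling,
                 axis1_percent = x$percent_covariance[1L])
}

#' @rdname morphodelim-tidiers
#' @export
tidy.modularity_test <- function(x, ...) {
  tibble::tibble(alternative = seq_along(x$alternatives), rv = x$alternatives)
}

#' @rdname morphodelim-tidiers
#' @export
glance.modularity_test <- function(x, ...) {
  tibble::tibble(observed_rv = x$observed_rv, proportion_leq = x$proportion_leq,
                 n_alternatives = x$n_alternatives, enumerated = x$enumerated,
                 contiguous_only = x$contiguous_only)
}

#' @rdname morphodelim-tidiers
#' @export
tidy.phylo_signal <- function(x, ...) {
  tibble::tibble(permutation = seq_along(x$null_lengths),
                 tree_length = x$null_lengths)
}

#' @rdname morphodelim-tidiers
#' @export
glance.phylo_signal <- function(x, ...) {
  tibble::tibble(tree_length = x$tree_length, P = x$P,
                 n_assignments = x$n_perm_effective, enumerated = x$enumerated)
}
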