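#' Multivariate regression of shape on a covariate
#'
#' Fits the least-squares regression of tangent-space shape on a scalar
#' covariate (typically centroid size, for allometry; or a count such as a
#' spinule total). The fraction of shape variation the covariate predicts is
#' `100 * SS_predicted / SS_total`, and significance comes from permuting the
#' covariate values across analysis units, with the +1 correction.
#'
#' When `groups` is given, shapes and covariate are centered within groups
#' before pooling (and permutations stay within groups), so the regression
#' estimates the common within-group allometry rather than group differences.
#'
#' @param data Data frame with a matrix column holding the shapes (flat
#'   coordinates or any numeric response block) and a numeric covariate
#'   column.
#' @param shape,covariate Column names (strings) of the shape matrix and the
#'   covariate.
#' @param groups Optional character vector of grouping column names (e.g.
#'   `c("species", "sex")`) for within-group pooling.
#' @param n_perm Number of permutations; `0` skips the test.
#' @param seed Optional seed, local to the call.
#' @return A `shape_regression` object: `coefficients` (slope vector, shape
#'   change per unit covariate), `percent_predicted`, `P`, `fitted`,
#'   `residuals` (centered scale), `pooling`, `n`.
#' @export
regress_shape_on_covariate <- function(data, shape = "shape", covariate = "size",
                                       groups = NULL, n_perm = 999L, seed = NULL) {
  Y <- data[[shape]]
  x <- data[[covariate]]
  assert_shape_matrix(Y, shape)
  if (sd(x) < 1e-14) abort("covariate has zero variance")
  g <- if (is.null(groups)) {
    factor(rep("all", nrow(Y)))
  } else {
    interaction(data[groups], drop = TRUE)
  }
  Yc <- Y - rowmeans_by(Y, g)[as.integer(droplevels(g)), , drop = FALSE]
  xc <- x - tapply(x, g, mean)[as.character(g)]
  if (sum(xc^2) < 1e-14) abort("covariate has zero within-group variance")

  b <- drop(crossprod(Yc, xc)) / sum(xc^2)
  fitted <- outer(xc, b)
  ss_total <- sum(Yc^2)
  ss_pred <- sum(fitted^2)
  percent <- 100 * ss_pred / ss_total

  p <- NA_real_
  if (n_perm > 0L) {
    p <- with_seed_local(seed, {
      # SS_pred for permuted covariates via one crossproduct per batch
      Xp <- vapply(seq_len(n_perm), function(i) {
        xp <- xc
        for (j in split(seq_along(xc), g)) xp[j] <- xp[sample(j)]
        xp
      }, numeric(length(xc)))
      cp <- crossprod(Yc, Xp)                       # p x n_perm
      ss_perm <- colSums(cp^2) / colSums(Xp^2)
      (sum(ss_perm >= ss_pred) + 1L) / (n_perm + 1L)
    })
  }
  structure(
    list(coefficients = b, percent_predicted = percent, P = p,
         fitted = fitted, residuals = Yc - fitted,
         pooling = if (is.null(groups)) "total" else "within-groups",
         groups = groups, n = nrow(Y), n_perm = n_perm, seed = seed),
    class = "shape_regression"
  )
}

#' @export
print.shape_regression <- function(x, ...) {
  cat(sprintf("<shape_regression> n = %d, %s pooling: %.2f%% predicted, P = %s\n",
              x$n, x$pooling, x$percent_predicted, format.pval(x$P)))
  invisible(x)
}

#' Remove allometry by size correction
#'
#' Regresses shapes on centroid size and replaces each shape by its residual
#' plus the group mean, i.e. the shape the specimen would have at its group's
#' mean size. When `groups` is given the regression is fitted per group, so
#' residual shapes have exactly zero sample covariance with size within each
#' group (the least-squares identity). The operation is idempotent.
#'
#' @inheritParams regress_shape_on_covariate
#' @param shape Column name of the shape matrix.
#' @param size Column name of the centroid sizes.
#' @return `data` with the shape column replaced by size-corrected shapes.
#' @export
size_correct <- function(data, shape = "shape", size = "size", groups = NULL) {
  Y <- data[[shape]]
  x <- data[[size]]
  g <- if (is.null(groups)) factor(rep("all", nrow(Y))) else interaction(data[groups], drop = TRUE)
  g <- droplevels(as.factor(g))
  out <- Y
  for (l in levels(g)) {
    i <- which(g == l)
    xc <- x[i] - mean(x[i])
    gm <- colMeans(Y[i, , drop = FALSE])
    Yc <- sweep(Y[i, , drop = FALSE], 2L, gm, "-")
    if (sum(xc^2) < 1e-14) abort(sprintf("zero size variance in group '%s'", l))
    b <- drop(crossprod(Yc, xc)) / sum(xc^2)
    out[i, ] <- sweep(Yc - outer(xc, b), 2L, gm, "+")
  }
  data[[shape]] <- out
  data
}

#' Regress a count on size
#'
#' Ordinary least-squares regression of an integer count (e.g. total
#' spinules) on centroid size, with a permutation test of the slope via the
#' correlation statistic.
#'
#' @param counts Non-negative integer counts.
#' @param sizes Positive sizes, same length.
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `P`, `n`.
#' @export
regress_count_on_size <- function(counts, sizes, n_perm = 999L, seed = NULL) {
  if (length(counts) != length(sizes)) abort("lengths differ")
  if (length(counts) < 3L) abort("need at least 3 observations")
  fit <- lm(counts ~ sizes)
  r2 <- summary(fit)$r.squared
  p <- with_seed_local(seed, {
    r_obs <- abs(cor(counts, sizes))
    r_perm <- vapply(seq_len(n_perm), function(i) abs(cor(sample(counts), sizes)),
                     numeric(1))
    (sum(r_perm >= r_obs) + 1L) / (n_perm + 1L)
  })
  tibble::tibble(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
                 r_squared = r2, P = p, n = length(counts))
}
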