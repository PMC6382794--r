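#' Principal component analysis of shapes
#'
#' Eigen-decomposition of the sample covariance of per-individual shapes
#' (conventionally the size-corrected symmetric component averaged by
#' individual). Axis signs follow the convention that each axis's
#' largest-magnitude loading is positive. When all axes are retained the
#' scores reproduce the tangent-space inter-individual distances exactly.
#'
#' @param data Data frame with a matrix column of shapes; or a bare matrix.
#' @param shape Column name of the shape matrix.
#' @param groups Optional column name of a grouping factor; when given, the
#'   per-group convex hull in the (PC1, PC2) plane is computed.
#' @return A `shape_pca` object: `eigenvalues` (descending),
#'   `percent_variance`, `scores` (n x axes), `loadings` (axes in columns),
#'   `center`, `hulls` (tibble of hull vertices per group, or `NULL`),
#'   `groups`.
#' @export
pca_shapes <- function(data, shape = "shape", groups = NULL) {
  X <- if (is.matrix(data)) data else data[[shape]]
  assert_shape_matrix(X, shape)
  n <- nrow(X)
  if (n < 3L) abort("PCA needs at least 3 individuals")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr, "-")
  sv <- svd(Xc / sqrt(n - 1))
  keep <- sv$d^2 > 1e-14 * max(sv$d^2, 1e-300)
  eig <- sv$d[keep]^2
  load <- sv$v[, keep, drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  scores <- Xc %*% load
  pct <- 100 * eig / sum(eig)
  hulls <- NULL
  grp <- NULL
  if (!is.null(groups) && !is.matrix(data)) {
    grp <- as.factor(data[[groups]])
    hulls <- dplyr::bind_rows(lapply(levels(grp), function(l) {
      pts <- scores[grp == l, 1:2, drop = FALSE]
      if (nrow(pts) < 3L) return(NULL)
      h <- grDevices::chull(pts)
      tibble::tibble(group = l, vertex = seq_along(h),
                     PC1 = pts[h, 1L], PC2 = pts[h, 2L])
    }))
  }
  structure(
    list(eigenvalues = eig, percent_variance = pct, scores = scores,
         loadings = load, center = ctr, hulls = hulls, groups = grp),
    class = "shape_pca"
  )
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("<shape_pca> %d axes; PC1 %.1f%%, PC2 %.1f%%\n",
              length(x$eigenvalues), x$percent_variance[1L],
              if (length(x$percent_variance) > 1L) x$percent_variance[2L] else NA))
  invisible(x)
}

#' Pairwise discriminant analysis of two groups with cross-validation
#'
#' Linear discriminant analysis between exactly two groups of shapes. Because
#' shape data usually have more variables than specimens, shapes are first
#' projected onto the principal subspace of the total covariance (axes with
#' eigenvalue above `1e-12` of the largest, capped so the pooled within-group
#' covariance stays invertible), and the discriminant is computed there.
#' Leave-one-out classification refits the projection and the discriminant
#' without the held-out individual.
#'
#' @param data Data frame with a matrix shape column and a group column.
#' @param shape Column name of the shape matrix.
#' @param group Column name of the two-level grouping factor.
#' @param cv `"loo"` (leave-one-out, the default) or `"none"`.
#' @return A `shape_dfa` object: `percent_correct` (per group and overall,
#'   resubstitution and LOO), `assignments` (tibble: true group, assigned
#'   group, LOO assignment, discriminant score), `axis` (discriminant vector
#'   in the original coordinates).
#' @export
dfa_pairwise <- function(data, shape = "shape", group = "group", cv = c("loo", "none")) {
  cv <- match.arg(cv)
  X <- data[[shape]]
  g <- droplevels(as.factor(data[[group]]))
  if (nlevels(g) != 2L) abort("exactly two groups required")
  if (any(table(g) < 3L)) abort("each group needs at least 3 individuals")

  fit1 <- lda_two_group(X, g)
  assigned <- fit1$assigned
  loo <- rep(NA_character_, nrow(X))
  if (cv == "loo") {
    for (i in seq_len(nrow(X))) {
      f <- lda_two_group(X[-i, , drop = FALSE], g[-i])
      loo[i] <- predict_lda_two_group(f, X[i, , drop = FALSE])
    }
  }
  pc <- function(pred) {
    ok <- pred == as.character(g)
    c(tapply(ok, g, mean) * 100, overall = mean(ok) * 100)
  }
  structure(
    list(
      groups = levels(g),
      percent_correct = list(
        resubstitution = pc(assigned),
        loo = if (cv == "loo") pc(loo) else NULL
      ),
      assignments = tibble::tibble(true = as.character(g), assigned = assigned,
                                   loo = loo, score = fit1$scores),
      axis = fit1$axis_full
    ),
    class = "shape_dfa"
  )
}

# Two-group LDA in the rank-controlled principal subspace.
lda_two_group <- function(X, g) {
  g <- droplevels(as.factor(g))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr, "-")
  sv <- svd(Xc)
  tolv <- 1e-12 * max(sv$d^2, 1e-300)
  keep <- which(sv$d^2 > tolv)
  # pooled within-group covariance must be invertible: rank <= n - 2
  keep <- keep[seq_len(min(length(keep), nrow(X) - 2L))]
  V <- sv$v[, keep, drop = FALSE]
  Z <- Xc %*% V
  m1 <- colMeans(Z[g == levels(g)[1L], , drop = FALSE])
  m2 <- colMeans(Z[g == levels(g)[2L], , drop = FALSE])
  W <- matrix(0, ncol(Z), ncol(Z))
  for (l in levels(g)) {
    Zl <- Z[g == l, , drop = FALSE]
    W <- W + crossprod(sweep(Zl, 2L, colMeans(Zl), "-"))
  }
  W <- W / (nrow(Z) - 2L)
  w <- tryCatch(solve(W, m1 - m2), error = function(e) {
    solve(W + diag(1e-8 * mean(diag(W)), ncol(W)), m1 - m2)
  })
  scores <- drop(Z %*% w)
  cut <- (sum(m1 * w) + sum(m2 * w)) / 2
  assigned <- ifelse(scores > cut, levels(g)[1L], levels(g)[2L])
  list(V = V, w = w, center = ctr, cut = cut, levels = levels(g),
       scores = scores - cut, assigned = assigned, axis_full = drop(V %*% w))
}

predict_lda_two_group <- function(fit, newX) {
  z <- sweep(newX, 2L, fit$center, "-") %*% fit$V
  s <- drop(z %*% fit$w)
  ifelse(s > fit$cut, fit$levels[1L], fit$levels[2L])
}

#' @export
print.shape_dfa <- function(x, ...) {
  cat(sprintf("<shape_dfa> %s vs %s\n", x$groups[1L], x$groups[2L]))
  cat("resubstitution % correct:\n")
  print(round(x$percent_correct$resubstitution, 1))
  if (!is.null(x$percent_correct$loo)) {
    cat("leave-one-out % correct:\n")
    print(round(x$percent_correct$loo, 1))
  }
  invisible(x)
}
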