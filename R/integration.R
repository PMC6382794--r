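#' RV coefficient between two blocks of variables
#'
#' Multivariate generalization of the squared correlation: for centered
#' blocks X (n x p) and Y (n x q) with cross-covariance S12 and
#' within-block covariances S11, S22,
#' `RV = trace(S12 S21) / sqrt(trace(S11^2) * trace(S22^2))`.
#' It lies in `[0, 1]` and is invariant under orthogonal rotation of either
#' block.
#'
#' @param x,y Numeric matrices with the same number of rows (n >= 3).
#' @return Scalar in `[0, 1]`.
#' @export
rv_coefficient <- function(x, y) {
  if (nrow(x) != nrow(y)) abort("blocks must have the same number of rows")
  if (nrow(x) < 3L) abort("need at least 3 rows")
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  s11 <- sum(crossprod(xc)^2)
  s22 <- sum(crossprod(yc)^2)
  if (s11 < 1e-300 || s22 < 1e-300) abort("zero-variance block")
  sum(crossprod(xc, yc)^2) / sqrt(s11 * s22)
}

#' Two-block partial least squares of two shape blocks
#'
#' Singular value decomposition of the between-block covariance of two
#' (separately superimposed) structures measured on the same individuals,
#' yielding paired axes of maximal covariation, the percent of total squared
#' covariance per axis, and the RV coefficient with a permutation test
#' against the null hypothesis of complete independence (rows of one block
#' permuted, within pooling cells when `pool_by` is given).
#'
#' @param data Data frame with two matrix columns of shapes measured on the
#'   same individuals (one row per individual).
#' @param block1,block2 Column names of the two shape matrices.
#' @param pool_by Optional character vector of grouping columns (e.g.
#'   `c("species", "sex")`): blocks are centered within these cells before
#'   analysis and permutations stay within cells.
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @return A `shape_pls` object: `singular_values`, `percent_covariance`,
#'   `scores1`, `scores2` (axis scores), `axes1`, `axes2` (loading vectors in
#'   columns), `rv`, `P`, `pooling`.
#' @export
pls_two_block <- function(data, block1, block2, pool_by = NULL,
                          n_perm = 999L, seed = NULL) {
  X <- data[[block1]]
  Y <- data[[block2]]
  if (nrow(X) != nrow(Y)) abort("blocks must cover the same individuals")
  g <- if (is.null(pool_by)) {
    factor(rep("all", nrow(X)))
  } else {
    interaction(data[pool_by], drop = TRUE)
  }
  Xc <- X - rowmeans_by(X, g)[as.integer(droplevels(g)), , drop = FALSE]
  Yc <- Y - rowmeans_by(Y, g)[as.integer(droplevels(g)), , drop = FALSE]

  S12 <- crossprod(Xc, Yc) / (nrow(Xc) - 1L)
  sv <- svd(S12)
  keep <- sv$d > 1e-14 * max(sv$d, 1e-300)
  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  rv_obs <- rv_coefficient(Xc, Yc)
  p <- with_seed_local(seed, {
    s11 <- sum(crossprod(Xc)^2)
    s22 <- sum(crossprod(Yc)^2)
    rv_perm <- vapply(seq_len(n_perm), function(i) {
      idx <- seq_len(nrow(Yc))
      for (j in split(idx, g)) idx[j] <- sample(j)
      sum(crossprod(Xc, Yc[idx, , drop = FALSE])^2) / sqrt(s11 * s22)
    }, numeric(1))
    (sum(rv_perm >= rv_obs) + 1L) / (n_perm + 1L)
  })
  structure(
    list(singular_values = d, percent_covariance = 100 * d^2 / sum(d^2),
         scores1 = Xc %*% U, scores2 = Yc %*% V, axes1 = U, axes2 = V,
         rv = rv_obs, P = p,
         pooling = if (is.null(pool_by)) "total" else paste(pool_by, collapse = " x "),
         n = nrow(X), n_perm = n_perm, seed = seed),
    class = "shape_pls"
  )
}

#' @export
print.shape_pls <- function(x, ...) {
  cat(sprintf("<shape_pls> RV = %.4f (P = %s); axis 1 carries %.1f%% of covariance\n",
              x$rv, format.pval(x$P), x$percent_covariance[1L]))
  invisible(x)
}

#' Matrix correlation between individual variation and fluctuating asymmetry
#'
#' Element-wise correlation between two landmark-block covariance matrices
#' (e.g. the covariance of individual symmetric variation vs the covariance
#' of fluctuating asymmetry), optionally excluding the diagonal 2 x 2
#' landmark blocks (the per-landmark variances). Significance is assessed by
#' permuting landmark identities — whole 2 x 2 blocks of rows and columns —
#' in one matrix, with the +1 correction.
#'
#' @param cov_ind,cov_fa Square 2k x 2k covariance matrices over the same
#'   landmark scheme (columns ordered x1, y1, x2, y2, ...).
#' @param include_diagonal_blocks Include the diagonal landmark blocks?
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @return A one-row tibble: `r`, `P`, `k`, `included_entries`.
#' @export
matrix_correlation_ind_fa <- function(cov_ind, cov_fa,
                                      include_diagonal_blocks = TRUE,
                                      n_perm = 999L, seed = NULL) {
  if (!all(dim(cov_ind) == dim(cov_fa))) abort("matrix dimensions differ")
  p <- nrow(cov_ind)
  if (p %% 2L != 0L) abort("matrices must be 2k x 2k")
  k <- p %/% 2L
  block_of <- rep(seq_len(k), each = 2L)
  mask <- upper.tri(cov_ind, diag = TRUE)
  if (!include_diagonal_blocks) {
    same_block <- outer(block_of, block_of, "==")
    mask <- mask & !same_block
  }
  r_for <- function(m2) cor(cov_ind[mask], m2[mask])
  r_obs <- r_for(cov_fa)
  p_val <- with_seed_local(seed, {
    r_perm <- vapply(seq_len(n_perm), function(i) {
      perm <- sample(k)
      idx <- landmark_cols(perm)
      r_for(cov_fa[idx, idx])
    }, numeric(1))
    (sum(r_perm >= r_obs) + 1L) / (n_perm + 1L)
  })
  tibble::tibble(r = r_obs, P = p_val, k = k, included_entries = sum(mask))
}

#' Test a two-module landmark partition against alternative partitions
#'
#' Computes the RV coefficient between the coordinate blocks of the two
#' hypothesized landmark modules, then compares it with the RVs of
#' alternative partitions of the same subset sizes. A hypothesis of
#' modularity is supported when the observed RV is lower than (almost) all
#' alternatives. When the number of distinct alternatives does not exceed
#' `n_alternatives` they are enumerated exhaustively; otherwise they are
#' sampled uniformly without duplicates. In contiguous mode only partitions
#' whose subsets induce connected subgraphs of the scheme's adjacency graph
#' are admitted.
#'
#' @param shapes n x 2k matrix of shape values (columns x1, y1, ...), e.g.
#'   individual symmetric means or fluctuating-asymmetry values.
#' @param partition Integer vector: the landmark indices of the first module
#'   (the second is its complement).
#' @param adjacency Two-column edge matrix over landmarks (required for
#'   `contiguous_only`), e.g. `scheme$adjacency`.
#' @param n_alternatives Number of alternative partitions (default 10000).
#' @param contiguous_only Restrict to spatially contiguous partitions?
#' @param seed Optional seed.
#' @return A `modularity_test` object: `observed_rv`, `alternatives` (RV
#'   values), `proportion_leq` (share of alternatives with RV <= observed;
#'   small values support modularity), `enumerated`, `contiguous_only`,
#'   `partition`.
#' @export
modularity_test <- function(shapes, partition, adjacency = NULL,
                            n_alternatives = 10000L, contiguous_only = FALSE,
                            seed = NULL) {
  assert_shape_matrix(shapes)
  k <- ncol(shapes) %/% 2L
  partition <- sort(as.integer(partition))
  m <- length(partition)
  if (m < 2L || k - m < 2L) abort("each module needs at least 2 landmarks")
  if (contiguous_only && is.null(adjacency)) abort("contiguous mode needs `adjacency`")

  g <- NULL
  if (!is.null(adjacency)) {
    g <- igraph::graph_from_edgelist(matrix(as.integer(adjacency), ncol = 2L),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, k - igraph::vcount(g)))
  }
  is_contig <- function(sub) {
    igraph::is_connected(igraph::induced_subgraph(g, sub)) &&
      igraph::is_connected(igraph::induced_subgraph(g, setdiff(seq_len(k), sub)))
  }
  rv_of <- function(sub) {
    rv_coefficient(shapes[, landmark_cols(sub), drop = FALSE],
                   shapes[, landmark_cols(setdiff(seq_len(k), sub)), drop = FALSE])
  }
  observed <- rv_of(partition)

  n_total <- choose(k, m) / (if (2L * m == k) 2 else 1)
  with_seed_local(seed, {
    if (n_total <= n_alternatives) {
      subs <- combn(k, m, simplify = FALSE)
      if (2L * m == k) subs <- subs[vapply(subs, function(s) 1L %in% s, logical(1))]
      enumerated <- TRUE
    } else {
      seen <- new.env(hash = TRUE)
      subs <- list()
      tries <- 0L
      max_tries <- n_alternatives * 50L
      while (length(subs) < n_alternatives && tries < max_tries) {
        tries <- tries + 1L
        s <- sort(sample.int(k, m))
        if (2L * m == k && !(1L %in% s)) s <- sort(setdiff(seq_len(k), s))
        key <- paste(s, collapse = ",")
        if (!is.null(seen[[key]])) next
        if (contiguous_only && !is_contig(s)) {
          seen[[key]] <- FALSE
          next
        }
        seen[[key]] <- TRUE
        subs[[length(subs) + 1L]] <- s
      }
      enumerated <- FALSE
    }
    if (contiguous_only) {
      subs <- subs[vapply(subs, is_contig, logical(1))]
      if (length(subs) == 0L) abort("no contiguous alternative partitions exist")
    }
    rvs <- vapply(subs, rv_of, numeric(1))
    structure(
      list(observed_rv = observed, alternatives = rvs,
           proportion_leq = mean(rvs <= observed),
           n_alternatives = length(rvs), enumerated = enumerated,
           contiguous_only = contiguous_only, partition = partition, k = k),
      class = "modularity_test"
    )
  })
}

#' @export
print.modularity_test <- function(x, ...) {
  cat(sprintf(
    "<modularity_test> observed RV = %.4f; %.1f%% of %d %s partitions have RV <= observed\n",
    x$observed_rv, 100 * x$proportion_leq, x$n_alternatives,
    if (x$contiguous_only) "contiguous" else "alternative"))
  invisible(x)
}

#' Landmark-block covariance matrices for integration analyses
#'
#' Convenience builders for [matrix_correlation_ind_fa()]: the covariance of
#' rows of a shape matrix, optionally centered within groups.
#'
#' @param shapes n x 2k matrix.
#' @param groups Optional grouping factor for within-group centering.
#' @return 2k x 2k covariance matrix.
#' @export
shape_covariance <- function(shapes, groups = NULL) {
  if (!is.null(groups)) {
    g <- droplevels(as.factor(groups))
    shapes <- shapes - rowmeans_by(shapes, g)[as.integer(g), , drop = FALSE]
    stats::cov(shapes) * (nrow(shapes) - 1L) / (nrow(shapes) - nlevels(g))
  } else {
    stats::cov(shapes)
  }
}
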