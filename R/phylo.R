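#' Group mean shapes
#'
#' Arithmetic means of tangent-space shape rows per group (species or
#' species x sex) — the tip values for mapping shapes onto a phylogeny. For
#' object-symmetric structures pass the symmetric component.
#'
#' @param data Data frame with a matrix column of shapes and grouping
#'   columns.
#' @param shape Column name of the shape matrix.
#' @param by Character vector of grouping columns (e.g. `"species"` or
#'   `c("species", "sex")`).
#' @return A tibble with the grouping columns and a matrix column `mean_shape`.
#' @export
group_mean_shapes <- function(data, shape = "shape", by = "species") {
  g <- interaction(data[by], drop = TRUE, sep = "\r")
  m <- rowmeans_by(data[[shape]], g)
  key <- do.call(rbind, strsplit(levels(droplevels(g)), "\r", fixed = TRUE))
  out <- tibble::as_tibble(stats::setNames(as.data.frame(key), by))
  out$n <- attr(m, "n")
  out$mean_shape <- m
  out
}

# Weighted tree Laplacian machinery.  Returns the list of edges (node ids per
# ape convention: tips 1..n, internals n+1..), weights 1/branch length, and
# the quadratic form Q over tip values such that the minimized tree length of
# a tip vector y is t(y) %*% Q %*% y (Schur complement of the Laplacian).
tree_quadratic_form <- function(tree) {
  bl <- tree$edge.length
  if (any(bl <= 0)) {
    warn("non-positive branch lengths floored at 1e-9")
    bl <- pmax(bl, 1e-9)
  }
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  w <- 1 / bl
  L <- matrix(0, n_node, n_node)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]
    b <- tree$edge[e, 2L]
    L[a, a] <- L[a, a] + w[e]
    L[b, b] <- L[b, b] + w[e]
    L[a, b] <- L[a, b] - w[e]
    L[b, a] <- L[b, a] - w[e]
  }
  tips <- seq_len(n_tip)
  internals <- seq.int(n_tip + 1L, n_node)
  Ltt <- L[tips, tips, drop = FALSE]
  Lti <- L[tips, internals, drop = FALSE]
  Lii <- L[internals, internals, drop = FALSE]
  Lii_inv_Lit <- solve(Lii, t(Lti))
  list(Q = Ltt - Lti %*% Lii_inv_Lit, solve_internal = function(Y) {
    -Lii_inv_Lit %*% Y
  }, n_tip = n_tip, internals = internals)
}

#' Squared-change parsimony reconstruction of ancestral values
#'
#' Reconstructs internal-node values of a continuous (possibly multivariate)
#' character on a rooted tree by minimizing the sum over branches of the
#' squared change divided by branch length (weighted squared-change
#' parsimony; set `weighted = FALSE` for unit weights). The minimizer solves
#' the linear system of the branch-weighted tree Laplacian exactly, and the
#' attained minimum — the "tree length" — measures how much change the tree
#' requires, which is the statistic of the phylogenetic-signal permutation
#' test.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @param tip_values Named numeric vector, or matrix with one named row per
#'   tip (multivariate characters in columns).
#' @param weighted Divide squared changes by branch lengths? (default TRUE)
#' @return A list: `ancestral` (matrix of internal-node values, rows named
#'   by ape node ids), `tree_length` (the attained minimum, >= 0, zero iff
#'   all tips are identical).
#' @export
squared_change_parsimony <- function(tree, tip_values, weighted = TRUE) {
  tree <- validate_phylo(tree)
  if (!weighted) tree$edge.length <- rep(1, nrow(tree$edge))
  Y <- if (is.matrix(tip_values)) tip_values else matrix(tip_values, ncol = 1L,
                                                         dimnames = list(names(tip_values), NULL))
  missing <- setdiff(tree$tip.label, rownames(Y))
  if (length(missing) > 0L) {
    abort(paste0("no value for tip(s): ", paste(missing, collapse = ", ")))
  }
  Y <- Y[tree$tip.label, , drop = FALSE]
  qf <- tree_quadratic_form(tree)
  anc <- qf$solve_internal(Y)
  rownames(anc) <- as.character(qf$internals)
  len <- sum(Y * (qf$Q %*% Y))
  list(ancestral = anc, tree_length = max(0, len))
}

# all permutations of 1..n (n <= 8) in lexicographic order
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1L)
    for (r in rest) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[r])
  }
  out
}

#' Permutation test of phylogenetic signal in shape data
#'
#' Maps multivariate tip values (e.g. species mean shapes or PCA scores)
#' onto the tree with [squared_change_parsimony()] and asks whether the
#' observed tree length is smaller than expected under the null hypothesis
#' of no phylogenetic signal, simulated by randomly swapping whole tip
#' records among the terminal nodes. P is the proportion of permutations
#' with tree length less than or equal to the observed one. When the number
#' of distinct tip relabelings (n!) does not exceed `n_perm` the test
#' enumerates all of them exactly (4 tips give 24 assignments, so attainable
#' P values are coarse multiples of 1/24, and a low-resolution warning is
#' issued); otherwise it samples `n_perm` random relabelings and applies the
#' +1 correction.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param tip_values Named numeric vector or tip-named matrix.
#' @param n_perm Number of permutations (default 10000).
#' @param weighted As in [squared_change_parsimony()].
#' @param seed Optional seed.
#' @return A `phylo_signal` object: `tree_length`, `ancestral`, `P`,
#'   `n_perm_effective`, `enumerated`, `null_lengths`.
#' @export
phylo_signal_test <- function(tree, tip_values, n_perm = 10000L,
                              weighted = TRUE, seed = NULL) {
  tree <- validate_phylo(tree)
  n <- length(tree$tip.label)
  if (n < 4L) abort("need at least 4 tips")
  scp <- squared_change_parsimony(tree, tip_values, weighted = weighted)
  Y <- if (is.matrix(tip_values)) tip_values else matrix(tip_values, ncol = 1L,
                                                         dimnames = list(names(tip_values), NULL))
  Y <- Y[tree$tip.label, , drop = FALSE]
  work_tree <- tree
  if (!weighted) work_tree$edge.length <- rep(1, nrow(work_tree$edge))
  qf <- tree_quadratic_form(work_tree)
  len_for <- function(perm) sum(Y[perm, , drop = FALSE] * (qf$Q %*% Y[perm, , drop = FALSE]))
  obs <- scp$tree_length

  enumerate <- factorial(n) <= n_perm
  res <- with_seed_local(seed, {
    if (enumerate) {
      perms <- all_permutations(n)
      lens <- vapply(perms, len_for, numeric(1))
      list(p = mean(lens <= obs + 1e-12), n_eff = length(lens), lens = lens)
    } else {
      lens <- vapply(seq_len(n_perm), function(i) len_for(sample(n)), numeric(1))
      list(p = (sum(lens <= obs + 1e-12) + 1L) / (n_perm + 1L),
           n_eff = n_perm, lens = lens)
    }
  })
  if (enumerate) {
    inform(sprintf(
      "exhaustive enumeration over %d tip assignments; attainable P values are multiples of 1/%d",
      res$n_eff, res$n_eff))
  }
  structure(
    list(tree_length = obs, ancestral = scp$ancestral, P = res$p,
         n_perm_effective = res$n_eff, enumerated = enumerate,
         null_lengths = res$lens, n_tips = n, seed = seed),
    class = "phylo_signal"
  )
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat(sprintf("<phylo_signal> tree length = %.6g, P = %.4g (%s, %d assignments)\n",
              x$tree_length, x$P,
              if (x$enumerated) "exact enumeration" else "sampled", x$n_perm_effective))
  invisible(x)
}
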