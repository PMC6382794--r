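# Internal coordinate conventions.
#
# A configuration is a k x 2 matrix of planar landmarks.  Its flat (tangent
# space) representation is the length-2k vector x1, y1, x2, y2, ..., so that
# landmark j occupies columns 2j-1 and 2j of an n x 2k shape matrix.  Keeping
# the two coordinates of a landmark adjacent makes landmark-block operations
# (modularity partitions, matrix-correlation blocks) simple column slices.

flatten_config <- function(m) as.vector(t(m))

unflatten_config <- function(v) matrix(v, ncol = 2L, byrow = TRUE)

#' @noRd
landmark_cols <- function(idx) {
  as.vector(rbind(2L * idx - 1L, 2L * idx))
}

center_config <- function(m) {
  sweep(m, 2L, colMeans(m), "-")
}

is_degenerate_config <- function(m, tol = 1e-12) {
  any(!is.finite(m)) || sum(scale(m, scale = FALSE)^2) < tol
}

#' Sum of squared entries
#' @noRd
ss <- function(x) sum(x^2)

# Row-wise mean shapes by a grouping factor; returns a matrix with one row per
# level (level order of the factor) and an attribute "n" of level counts.
rowmeans_by <- function(mat, f) {
  f <- droplevels(as.factor(f))
  n <- as.vector(table(f))
  out <- rowsum(mat, f, reorder = TRUE) / n
  attr(out, "n") <- n
  out
}

assert_shape_matrix <- function(x, arg = "shapes") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix (rows = units, cols = flat coordinates)", arg))
  }
  if (any(!is.finite(x))) abort(sprintf("`%s` contains non-finite values", arg))
  invisible(x)
}

# Seed handling: functions that take `seed` evaluate their randomness inside a
# local RNG scope so callers' RNG streams are untouched.
with_seed_local <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

new_bare_tibble <- function(...) tibble::tibble(...)
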