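#' Centroid size of a configuration
#'
#' The standard size measure in geometric morphometrics: the square root of
#' the summed squared distances of the landmarks from their centroid. It is
#' scale-equivariant (`centroid_size(c * X) == c * centroid_size(X)`).
#'
#' @param coords A k x 2 numeric matrix (k >= 3).
#' @return A positive scalar.
#' @examples
#' centroid_size(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # sqrt(2)
#' @export
centroid_size <- function(coords) {
  if (!is.matrix(coords) || ncol(coords) != 2L || nrow(coords) < 3L) {
    abort("`coords` must be a k x 2 matrix with k >= 3")
  }
  if (any(!is.finite(coords))) abort("non-finite coordinates")
  cs <- sqrt(sum(center_config(coords)^2))
  if (cs < 1e-12) abort("degenerate configuration: all landmarks coincide")
  cs
}

# Optimal rotation (2x2 orthogonal, det +1 unless reflections allowed) taking
# centered X onto centered Y in the least-squares sense.
optimal_rotation <- function(X, Y, allow_reflection = FALSE) {
  M <- crossprod(X, Y)
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  if (!allow_reflection && det(R) < 0) {
    u <- sv$u
    u[, 2L] <- -u[, 2L]
    R <- u %*% t(sv$v)
  }
  R
}

#' Optimal similarity superimposition of one configuration onto another
#'
#' Finds the translation, rotation and scale minimizing the summed squared
#' landmark distances between `moving` (transformed) and `target`. By default
#' the rotation is proper (determinant +1); `allow_reflection = TRUE` permits
#' an improper one.
#'
#' @param moving,target k x 2 coordinate matrices over the same landmarks.
#' @param allow_reflection Allow an improper rotation (reflection)?
#' @return A list: `rotation` (2 x 2), `scale`, `translation` (length 2),
#'   `residual` (the full Procrustes distance, i.e. the RMS-free Euclidean
#'   distance between the superimposed configurations), and `aligned` (the
#'   transformed `moving` matrix). The fit is
#'   `aligned = scale * center(moving) %*% rotation + translation`.
#' @examples
#' tri <- rbind(c(0, 0), c(2, 0), c(1, 1.5))
#' th <- 37 * pi / 180
#' R <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
#' fit <- procrustes_align_pair(tri %*% R, tri)
#' fit$residual  # ~0
#' @export
procrustes_align_pair <- function(moving, target, allow_reflection = FALSE) {
  if (is_degenerate_config(moving) || is_degenerate_config(target)) {
    abort("degenerate configuration (zero spread or non-finite values)")
  }
  Xc <- center_config(moving)
  Yc <- center_config(target)
  R <- optimal_rotation(Xc, Yc, allow_reflection)
  num <- sum((Xc %*% R) * Yc)
  s <- num / sum(Xc^2)
  translation <- colMeans(target)
  aligned <- s * (Xc %*% R)
  residual <- sqrt(max(0, sum(Yc^2) - s * num))
  aligned <- sweep(aligned, 2L, translation, "+")
  list(rotation = R, scale = s, translation = translation,
       residual = residual, aligned = aligned)
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of a set of configurations: each is centered and
#' scaled to unit centroid size, rotated onto the running consensus, and the
#' consensus (the mean configuration, renormalized) is updated until it moves
#' by less than `tol` or `max_iter` is reached. The result is invariant (to
#' tolerance) under arbitrary similarity transforms of the inputs.
#'
#' Tangent-space coordinates are the orthogonal projection of the aligned
#' configurations onto the tangent plane at the consensus, stored as
#' deviations from the consensus in an n x 2k matrix (columns x1, y1, x2, y2,
#' ...). The tangent space has dimension 2k - 4 (position, scale and rotation
#' removed).
#'
#' @param configs Configuration tibble (columns `specimen`, `side`,
#'   `image_rep`, `digit_rep`, `coords`), e.g. from [read_tps()] or
#'   [simulate_dataset()]; or a bare list of k x 2 matrices.
#' @param scheme Optional [landmark_scheme] (checked against the data). When
#'   it defines slider curves, pass the result to [slide_semilandmarks()].
#' @param tol Convergence tolerance on consensus displacement.
#' @param max_iter Maximum number of consensus updates.
#' @return An object of class `gpa_fit`: list with `info` (metadata tibble),
#'   `coords` (list of aligned k x 2 matrices, centroid at origin, unit
#'   centroid size), `tangent` (n x 2k matrix of tangent-space deviations
#'   from the consensus), `consensus` (k x 2), `centroid_sizes`,
#'   `tangent_dim` (= 2k - 4), `iterations`, `converged`, `scheme`.
#' @export
gpa <- function(configs, scheme = NULL, tol = 1e-10, max_iter = 100L) {
  if (is.data.frame(configs)) {
    info <- dplyr::select(configs, -dplyr::any_of("coords"))
    coords <- configs$coords
  } else {
    coords <- configs
    info <- tibble::tibble(specimen = paste0("config_", seq_along(coords)),
                           side = "none", image_rep = 1L, digit_rep = 1L)
  }
  n <- length(coords)
  if (n < 2L) abort("GPA needs at least 2 configurations")
  ks <- vapply(coords, nrow, integer(1))
  if (length(unique(ks)) != 1L) abort("configurations differ in landmark count")
  k <- ks[1L]
  if (!is.null(scheme) && k != scheme$k) {
    abort(sprintf("configurations have %d landmarks but scheme '%s' expects %d",
                  k, scheme$name, scheme$k))
  }
  bad <- which(vapply(coords, is_degenerate_config, logical(1)))
  if (length(bad) > 0L) {
    abort(paste0("degenerate configuration(s) at row(s): ", paste(bad, collapse = ", ")))
  }

  sizes <- vapply(coords, centroid_size, numeric(1))
  pre <- lapply(coords, function(m) center_config(m) / sqrt(sum(center_config(m)^2)))

  consensus <- pre[[1L]]
  it <- 0L
  converged <- FALSE
  aligned <- pre
  while (it < max_iter) {
    it <- it + 1L
    aligned <- lapply(pre, function(m) m %*% optimal_rotation(m, consensus))
    new_cons <- Reduce("+", aligned) / n
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    # fix rotational gauge: align new consensus onto old before comparing
    new_cons <- new_cons %*% optimal_rotation(new_cons, consensus)
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  aligned <- lapply(pre, function(m) m %*% optimal_rotation(m, consensus))

  tangent <- tangent_project(aligned, consensus)
  structure(
    list(info = tibble::as_tibble(info), coords = aligned, tangent = tangent,
         consensus = consensus, centroid_sizes = sizes,
         tangent_dim = 2L * k - 4L, iterations = it, converged = converged,
         scheme = scheme),
    class = "gpa_fit"
  )
}

# Orthogonal projection onto the tangent plane at the consensus; returns the
# n x 2k matrix of projected deviations from the consensus.
tangent_project <- function(aligned, consensus) {
  cvec <- flatten_config(consensus)
  cvec <- cvec / sqrt(sum(cvec^2))
  X <- do.call(rbind, lapply(aligned, flatten_config))
  dev <- sweep(X, 2L, flatten_config(consensus), "-")
  dev - (dev %*% cvec) %*% t(cvec)
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat(sprintf("<gpa_fit> %d configurations, %d landmarks, tangent dim %d, %d iteration(s)%s\n",
              length(x$coords), nrow(x$consensus), x$tangent_dim, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

# Procrustes distance between two rows of a gpa_fit (unit-size aligned)
procrustes_distance <- function(a, b) sqrt(sum((a - b)^2))
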