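#' Slide semilandmarks along their curves
#'
#' Semilandmarks have no exact point homology along their curve; they are
#' allowed to slip tangentially so that differences along the curve do not
#' count as shape variation. Each sliding cycle displaces every interior
#' curve point only along its local tangent direction (the chord between its
#' two curve neighbours) by the amount minimizing its distance to the
#' consensus (the minimum-Procrustes-distance criterion), then re-runs the
#' generalized Procrustes fit. The total Procrustes sum of squares about the
#' consensus is non-increasing across cycles.
#'
#' @param fit A [gpa()] result whose scheme defines slider curves.
#' @param scheme A [landmark_scheme] with non-empty `curves`; defaults to
#'   `fit$scheme`.
#' @param n_cycles Number of slide-and-refit cycles.
#' @return An updated `gpa_fit` (same class and fields), with an extra field
#'   `slide_ss` recording the total Procrustes sum of squares after each
#'   cycle (element 0 = before sliding).
#' @export
slide_semilandmarks <- function(fit, scheme = fit$scheme, n_cycles = 5L) {
  if (is.null(scheme) || length(scheme$sliders) == 0L) {
    abort("scheme defines no slider curves")
  }
  for (cv in scheme$curves) {
    if (length(cv) < 3L) abort("slider without two neighbours on its curve")
  }
  total_ss <- function(f) {
    cons <- f$consensus
    sum(vapply(f$coords, function(m) sum((m - cons)^2), numeric(1)))
  }
  ss_trace <- total_ss(fit)
  coords <- fit$coords
  for (cycle in seq_len(n_cycles)) {
    cons <- fit$consensus
    coords <- lapply(coords, function(m) {
      for (cv in scheme$curves) {
        for (j in seq(2L, length(cv) - 1L)) {
          i <- cv[j]
          tng <- m[cv[j + 1L], ] - m[cv[j - 1L], ]
          nt <- sqrt(sum(tng^2))
          if (nt < 1e-12) next
          tng <- tng / nt
          lambda <- sum((cons[i, ] - m[i, ]) * tng)
          m[i, ] <- m[i, ] + lambda * tng
        }
      }
      m
    })
    info_coords <- fit$info
    info_coords$coords <- coords
    fit <- gpa(info_coords, scheme = scheme)
    coords <- fit$coords
    ss_trace <- c(ss_trace, total_ss(fit))
  }
  fit$slide_ss <- ss_trace
  fit
}
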