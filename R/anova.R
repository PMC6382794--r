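#' Goodall's F statistic
#'
#' ANOVA-style F ratio on Procrustes sums of squares under the isotropic
#' variation model: `(ss_effect/df_effect) / (ss_error/df_error)`, where for
#' shape data the degrees of freedom are the univariate ones multiplied by
#' the tangent-space dimension 2k - 4.
#'
#' @param ss_effect,df_effect,ss_error,df_error Sums of squares and degrees
#'   of freedom of the effect and its error stratum.
#' @return The F ratio (>= 0). A zero error sum of squares yields `Inf`
#'   rather than an error.
#' @examples
#' goodall_f(2, 1 * 86, 1, 2 * 86)  # 4
#' @export
goodall_f <- function(ss_effect, df_effect, ss_error, df_error) {
  if (df_effect <= 0 || df_error <= 0) abort("degrees of freedom must be positive")
  ms_e <- ss_effect / df_effect
  ms_err <- ss_error / df_error
  if (ms_err == 0) return(if (ms_e == 0) 0 else Inf)
  ms_e / ms_err
}

# ---- internal SS helpers ----------------------------------------------------

# One-way between/within decomposition over unit rows U grouped by g.
ss_oneway <- function(U, g) {
  g <- droplevels(as.factor(g))
  grand <- colMeans(U)
  m <- rowmeans_by(U, g)
  n_g <- attr(m, "n")
  ss_b <- sum(n_g * rowSums(sweep(m, 2L, grand, "-")^2))
  ss_w <- sum((U - m[as.integer(g), , drop = FALSE])^2)
  list(ss_b = ss_b, df_b = nlevels(g) - 1L, ss_w = ss_w, df_w = nrow(U) - nlevels(g))
}

# Unweighted two-way decomposition of cell-mean rows indexed by (a, b).
ss_twoway_cells <- function(cells, a, b) {
  a <- droplevels(as.factor(a))
  b <- droplevels(as.factor(b))
  grand <- colMeans(cells)
  ma <- rowmeans_by(cells, a)[as.integer(a), , drop = FALSE]
  mb <- rowmeans_by(cells, b)[as.integer(b), , drop = FALSE]
  dev_a <- sweep(ma, 2L, grand, "-")
  dev_b <- sweep(mb, 2L, grand, "-")
  inter <- cells - ma - mb + matrix(grand, nrow(cells), ncol(cells), byrow = TRUE)
  list(ss_a = sum(dev_a^2), df_a = nlevels(a) - 1L,
       ss_b = sum(dev_b^2), df_b = nlevels(b) - 1L,
       ss_ab = sum(inter^2), df_ab = (nlevels(a) - 1L) * (nlevels(b) - 1L))
}

# Within-group SS of rows y grouped by g (replicate scatter about group means).
ss_within <- function(y, g) {
  g <- droplevels(as.factor(g))
  m <- rowmeans_by(y, g)
  list(ss = sum((y - m[as.integer(g), , drop = FALSE])^2),
       df = nrow(y) - nlevels(g))
}

perm_p <- function(f_perm, f_obs) (sum(f_perm >= f_obs) + 1L) / (length(f_perm) + 1L)

anova_row <- function(effect, ss, df, ss_err, df_err, p = NA_real_) {
  tibble::tibble(effect = effect, SS = ss, df = df, MS = ss / df,
                 F = goodall_f(ss, df, ss_err, df_err), P = p)
}

new_procrustes_anova <- function(table, response, n_perm, seed) {
  structure(list(table = table, response = response, n_perm = n_perm, seed = seed),
            class = "procrustes_anova")
}

#' @export
print.procrustes_anova <- function(x, ...) {
  cat(sprintf("<procrustes_anova> response = %s, %d permutations\n", x$response, x$n_perm))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

# ---- between-individual effects (species / locality / sex) ------------------

# U: unit rows (one per individual), cls: tibble of labels per unit.
between_individual_rows <- function(U, cls, D, n_perm) {
  out <- list()
  for (eff in intersect(c("species", "locality", "sex"), names(cls))) {
    g <- cls[[eff]]
    if (dplyr::n_distinct(g) < 2L) {
      warn(sprintf("effect '%s' has a single level; row omitted", eff))
      next
    }
    dec <- ss_oneway(U, g)
    if (dec$df_w <= 0) abort(sprintf("effect '%s': zero residual degrees of freedom", eff))
    f_obs <- goodall_f(dec$ss_b, dec$df_b * D, dec$ss_w, dec$df_w * D)
    f_perm <- vapply(seq_len(n_perm), function(i) {
      d <- ss_oneway(U, sample(as.character(g)))
      goodall_f(d$ss_b, d$df_b * D, d$ss_w, d$df_w * D)
    }, numeric(1))
    out[[eff]] <- anova_row(eff, dec$ss_b, dec$df_b * D, dec$ss_w, dec$df_w * D,
                            p = perm_p(f_perm, f_obs))
  }
  dplyr::bind_rows(out)
}

# ---- main entry: Procrustes ANOVA of shape ----------------------------------

#' Hierarchical Procrustes ANOVA of shape
#'
#' Quantifies shape variation at the levels of a nested measurement design:
#' species, locality and sex (tested among individual mean shapes), individual
#' variation, directional asymmetry (the side main effect), fluctuating
#' asymmetry (the individual x side interaction), and imaging/digitizing
#' measurement error. Each effect is tested one-way against its denominator
#' stratum with Goodall's F (shape degrees of freedom are the univariate ones
#' times the tangent dimension 2k - 4) and a permutation P-value with the +1
#' correction, P = (#\{F_perm >= F_obs\} + 1) / (n_perm + 1).
#'
#' Sums of squares are computed from the means at each stratum's aggregation
#' level (individual means for group effects; individual x side cell means
#' for asymmetry; image means for imaging), and adjacent strata are compared
#' directly. Permutation units are the experimental units of the denominator
#' stratum: individuals are permuted across groups, side labels are flipped
#' within individuals, and replicate-level records are permuted within their
#' nesting level for the error strata (the latter is an approximate
#' residual-unit scheme).
#'
#' For object symmetry the group and individual effects are computed on the
#' symmetric component and the asymmetry effects on the asymmetric component;
#' for matching symmetry the cell means of the joint fit carry both.
#'
#' @param x Either a `symmetry_decomposition` (from
#'   [decompose_object_symmetry()] or [assemble_matching_symmetry()]), or a
#'   data frame of per-individual shapes with a matrix column `shape` plus
#'   classifier columns (`species`, optionally `locality`, `sex`), in which
#'   case only the between-individual effects are testable.
#' @param classifiers Classifier tibble ([read_classifier_table()] format);
#'   ignored when `x` already carries classifier columns.
#' @param n_perm Number of permutations per effect.
#' @param seed Optional integer seed (local to this call).
#' @param tangent_dim Override for the shape degrees-of-freedom multiplier;
#'   defaults to the decomposition's 2k - 4 (or the column count minus 4).
#' @return A `procrustes_anova` object; `tidy()` returns the effect table
#'   (effect, SS, df, MS, F, P).
#' @export
procrustes_anova_shape <- function(x, classifiers = NULL, n_perm = 999L,
                                   seed = NULL, tangent_dim = NULL) {
  with_seed_local(seed, {
    if (is.data.frame(x)) {
      D <- tangent_dim %||% (ncol(x$shape) - 4L)
      tab <- between_individual_rows(x$shape, x, D, n_perm)
      if (nrow(tab) == 0L) abort("no testable effect found")
      return(new_procrustes_anova(tab, "shape", n_perm, seed))
    }
    if (!inherits(x, "symmetry_decomposition")) {
      abort("`x` must be a symmetry_decomposition or a data frame with a `shape` column")
    }
    D <- tangent_dim %||% x$tangent_dim
    meta <- join_classifiers(x$info, classifiers)
    tab <- if (x$mode == "matching") {
      anova_matching(x, meta, D, n_perm)
    } else {
      anova_object(x, meta, D, n_perm)
    }
    new_procrustes_anova(tab, "shape", n_perm, seed)
  })
}

join_classifiers <- function(info, classifiers) {
  if (is.null(classifiers)) abort("`classifiers` required")
  meta <- dplyr::left_join(info, classifiers,
                           by = c(specimen = "specimen_id"))
  if (anyNA(meta$species)) {
    abort("classifier table does not cover every specimen")
  }
  if (!"individual" %in% names(info)) meta$individual <- meta$individual %||% meta$specimen
  meta$individual[is.na(meta$individual)] <- meta$specimen[is.na(meta$individual)]
  meta
}

per_individual_labels <- function(meta) {
  meta |>
    dplyr::distinct(.data$individual, .keep_all = TRUE) |>
    dplyr::select(dplyr::any_of(c("individual", "species", "locality", "sex")))
}

# Matching symmetry: full hierarchy from the joint-fit aligned values.
anova_matching <- function(decomp, meta, D, n_perm) {
  y <- decomp$aligned
  keep <- decomp$complete %||% rep(TRUE, nrow(y))
  y <- y[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  ind <- as.factor(meta$individual)

  # individual means -> group effects
  U <- rowmeans_by(y, ind)
  cls <- per_individual_labels(meta)
  cls <- cls[match(levels(droplevels(ind)), cls$individual), , drop = FALSE]
  rows <- between_individual_rows(U, cls, D, n_perm)

  # cell means -> individual, DA, FA
  sep <- "\r"
  cell_f <- interaction(meta$individual, meta$side, drop = TRUE, sep = sep)
  cells <- rowmeans_by(y, cell_f)
  cell_key <- do.call(rbind, strsplit(levels(cell_f), sep, fixed = TRUE))
  cell_ind <- factor(cell_key[, 1L])
  cell_side <- factor(cell_key[, 2L])
  tw <- ss_twoway_cells(cells, cell_ind, cell_side)

  # imaging stratum: image means about their cell means
  img_f <- interaction(meta$individual, meta$side, meta$image_rep, drop = TRUE, sep = sep)
  img_means <- rowmeans_by(y, img_f)
  img_key <- do.call(rbind, strsplit(levels(img_f), sep, fixed = TRUE))
  img_ind <- img_key[, 1L]
  img_side <- img_key[, 2L]
  img_cell <- paste(img_ind, img_side, sep = sep)
  has_img <- nlevels(img_f) > nlevels(cell_f)
  sw_img <- if (has_img) ss_within(img_means, img_cell) else NULL

  # digitizing stratum: records about their image means
  has_dig <- nrow(y) > nlevels(img_f)
  sw_dig <- if (has_dig) ss_within(y, img_f) else NULL

  # individual vs FA: permute individual labels of cells within side strata
  f_obs_ind <- goodall_f(tw$ss_a, tw$df_a * D, tw$ss_ab, tw$df_ab * D)
  f_perm_ind <- vapply(seq_len(n_perm), function(i) {
    pind <- cell_ind
    for (s in levels(cell_side)) {
      j <- which(cell_side == s)
      pind[j] <- pind[sample(j)]
    }
    d <- ss_twoway_cells(cells, pind, cell_side)
    goodall_f(d$ss_a, d$df_a * D, d$ss_ab, d$df_ab * D)
  }, numeric(1))
  rows <- dplyr::bind_rows(rows,
    anova_row("individual", tw$ss_a, tw$df_a * D, tw$ss_ab, tw$df_ab * D,
              perm_p(f_perm_ind, f_obs_ind)))

  # DA vs FA: flip side labels within individuals
  f_obs_da <- goodall_f(tw$ss_b, tw$df_b * D, tw$ss_ab, tw$df_ab * D)
  f_perm_da <- vapply(seq_len(n_perm), function(i) {
    flip <- stats::setNames(sample(c(TRUE, FALSE), nlevels(cell_ind), replace = TRUE),
                            levels(cell_ind))
    ps <- as.character(cell_side)
    j <- flip[as.character(cell_ind)]
    ps[j] <- ifelse(ps[j] == "left", "right", "left")
    d <- ss_twoway_cells(cells, cell_ind, ps)
    goodall_f(d$ss_b, d$df_b * D, d$ss_ab, d$df_ab * D)
  }, numeric(1))
  rows <- dplyr::bind_rows(rows,
    anova_row("directional asymmetry", tw$ss_b, tw$df_b * D, tw$ss_ab, tw$df_ab * D,
              perm_p(f_perm_da, f_obs_da)))

  # FA vs imaging
  if (has_img && sw_img$df > 0) {
    f_obs_fa <- goodall_f(tw$ss_ab, tw$df_ab * D, sw_img$ss, sw_img$df * D)
    # permute image-mean deviations from the additive (individual + side) fit
    grand <- colMeans(cells)
    ma <- rowmeans_by(cells, cell_ind)
    mb <- rowmeans_by(cells, cell_side)
    add_pred <- ma[match(img_ind, levels(cell_ind)), , drop = FALSE] +
      mb[match(img_side, levels(cell_side)), , drop = FALSE] -
      matrix(grand, nlevels(img_f), ncol(y), byrow = TRUE)
    e_img <- img_means - add_pred
    img_cell_f <- factor(img_cell)
    key <- do.call(rbind, strsplit(levels(img_cell_f), sep, fixed = TRUE))
    key_ind <- factor(key[, 1L])
    key_side <- factor(key[, 2L])
    f_perm_fa <- vapply(seq_len(n_perm), function(i) {
      im_p <- add_pred + e_img[sample(nrow(e_img)), , drop = FALSE]
      cells_p <- rowmeans_by(im_p, img_cell_f)
      d <- ss_twoway_cells(cells_p, key_ind, key_side)
      w <- ss_within(im_p, img_cell_f)
      goodall_f(d$ss_ab, d$df_ab * D, w$ss, w$df * D)
    }, numeric(1))
    rows <- dplyr::bind_rows(rows,
      anova_row("fluctuating asymmetry", tw$ss_ab, tw$df_ab * D, sw_img$ss, sw_img$df * D,
                perm_p(f_perm_fa, f_obs_fa)))
  } else {
    rows <- dplyr::bind_rows(rows,
      tibble::tibble(effect = "fluctuating asymmetry", SS = tw$ss_ab,
                     df = tw$df_ab * D, MS = tw$ss_ab / (tw$df_ab * D),
                     F = NA_real_, P = NA_real_))
  }

  # imaging vs digitizing
  if (has_img && has_dig && sw_dig$df > 0) {
    f_obs_img <- goodall_f(sw_img$ss, sw_img$df * D, sw_dig$ss, sw_dig$df * D)
    f_perm_img <- vapply(seq_len(n_perm), function(i) {
      idx <- seq_len(nrow(y))
      for (cf in split(idx, cell_f)) idx[cf] <- sample(cf)
      yp <- y[idx, , drop = FALSE]
      im <- rowmeans_by(yp, img_f)
      wi <- ss_within(im, img_cell)
      wd <- ss_within(yp, img_f)
      goodall_f(wi$ss, wi$df * D, wd$ss, wd$df * D)
    }, numeric(1))
    rows <- dplyr::bind_rows(rows,
      anova_row("imaging", sw_img$ss, sw_img$df * D, sw_dig$ss, sw_dig$df * D,
                perm_p(f_perm_img, f_obs_img)))
  } else if (has_img) {
    rows <- dplyr::bind_rows(rows,
      tibble::tibble(effect = "imaging", SS = sw_img$ss, df = sw_img$df * D,
                     MS = sw_img$ss / (sw_img$df * D), F = NA_real_, P = NA_real_))
  }
  rows
}

# Object symmetry: group/individual effects on the symmetric component,
# asymmetry effects on the asymmetric component.
anova_object <- function(decomp, meta, D, n_perm) {
  S <- decomp$symmetric
  A <- decomp$asymmetric
  ind <- as.factor(meta$individual)

  U <- rowmeans_by(S, ind)
  cls <- per_individual_labels(meta)
  cls <- cls[match(levels(droplevels(ind)), cls$individual), , drop = FALSE]
  rows <- between_individual_rows(U, cls, D, n_perm)

  a_i <- rowmeans_by(A, ind)
  I <- nrow(a_i)
  abar <- colMeans(a_i)
  ss_da <- I * sum(abar^2)
  ss_fa <- sum(sweep(a_i, 2L, abar, "-")^2)
  df_da <- 1L
  df_fa <- I - 1L

  # individual vs FA: permute config-level symmetric rows across individuals
  grand_s <- colMeans(U)
  ss_ind <- sum(sweep(U, 2L, grand_s, "-")^2)
  df_ind <- I - 1L
  f_obs_ind <- goodall_f(ss_ind, df_ind * D, ss_fa, df_fa * D)
  f_perm_ind <- vapply(seq_len(n_perm), function(i) {
    Up <- rowmeans_by(S, sample(as.character(ind)))
    goodall_f(sum(sweep(Up, 2L, colMeans(Up), "-")^2), df_ind * D, ss_fa, df_fa * D)
  }, numeric(1))
  rows <- dplyr::bind_rows(rows,
    anova_row("individual", ss_ind, df_ind * D, ss_fa, df_fa * D,
              perm_p(f_perm_ind, f_obs_ind)))

  # DA vs FA: reflection exchangeability — random sign flips of individual
  # asymmetric means
  f_obs_da <- goodall_f(ss_da, df_da * D, ss_fa, df_fa * D)
  f_perm_da <- vapply(seq_len(n_perm), function(i) {
    sgn <- sample(c(-1, 1), I, replace = TRUE)
    ap <- a_i * sgn
    ab <- colMeans(ap)
    goodall_f(I * sum(ab^2), df_da * D, sum(sweep(ap, 2L, ab, "-")^2), df_fa * D)
  }, numeric(1))
  rows <- dplyr::bind_rows(rows,
    anova_row("directional asymmetry", ss_da, df_da * D, ss_fa, df_fa * D,
              perm_p(f_perm_da, f_obs_da)))

  # FA vs imaging (within-individual replicate scatter of the asymmetric
  # component); permute asymmetric rows across individuals
  sw_img <- ss_within(A, ind)
  if (sw_img$df > 0) {
    f_obs_fa <- goodall_f(ss_fa, df_fa * D, sw_img$ss, sw_img$df * D)
    f_perm_fa <- vapply(seq_len(n_perm), function(i) {
      indp <- sample(as.character(ind))
      ap <- rowmeans_by(A, indp)
      ab <- colMeans(ap)
      wi <- ss_within(A, indp)
      goodall_f(sum(sweep(ap, 2L, ab, "-")^2), df_fa * D, wi$ss, wi$df * D)
    }, numeric(1))
    rows <- dplyr::bind_rows(rows,
      anova_row("fluctuating asymmetry", ss_fa, df_fa * D, sw_img$ss, sw_img$df * D,
                perm_p(f_perm_fa, f_obs_fa)))
    rows <- dplyr::bind_rows(rows,
      tibble::tibble(effect = "imaging", SS = sw_img$ss, df = sw_img$df * D,
                     MS = sw_img$ss / (sw_img$df * D), F = NA_real_, P = NA_real_))
  } else {
    rows <- dplyr::bind_rows(rows,
      tibble::tibble(effect = "fluctuating asymmetry", SS = ss_fa, df = df_fa * D,
                     MS = ss_fa / (df_fa * D), F = NA_real_, P = NA_real_))
  }
  rows
}

#' Hierarchical ANOVA of centroid size
#'
#' The univariate analogue of [procrustes_anova_shape()]: same strata, same
#' permutation schemes, degrees of freedom not multiplied by the tangent
#' dimension. Size is reflection-invariant, so object-symmetric structures
#' have no size asymmetry strata; for matching symmetry the side effect is
#' directional asymmetry of size.
#'
#' @param sizes Either a `gpa_fit` (centroid sizes and metadata taken from
#'   it) or a tibble with columns `specimen`, `side`, `image_rep`,
#'   `digit_rep`, `size`.
#' @param classifiers Classifier tibble.
#' @param n_perm,seed As in [procrustes_anova_shape()].
#' @return A `procrustes_anova` object with `response = "size"`.
#' @export
anova_size <- function(sizes, classifiers, n_perm = 999L, seed = NULL) {
  if (inherits(sizes, "gpa_fit")) {
    info <- sizes$info
    if ("reflected" %in% names(info) && all(c(TRUE, FALSE) %in% info$reflected) &&
        all(info$side == "none")) {
      # object-symmetry joint fit: drop mirrored duplicates
      sel <- !info$reflected
      info <- info[sel, , drop = FALSE]
      sz <- sizes$centroid_sizes[sel]
    } else {
      sz <- sizes$centroid_sizes
    }
    sizes <- dplyr::mutate(dplyr::select(info, dplyr::any_of(
      c("specimen", "side", "image_rep", "digit_rep"))), size = sz)
  }
  with_seed_local(seed, {
    meta <- join_classifiers(sizes, classifiers)
    y <- matrix(sizes$size, ncol = 1L)
    has_sides <- all(c("left", "right") %in% sizes$side)
    tab <- if (has_sides) {
      fake <- new_symmetry_decomposition("matching", NULL, y, NULL, NULL, NULL, 1L,
                                         complete = size_complete_sides(meta))
      anova_matching(fake, meta, 1L, n_perm)
    } else {
      anova_size_object(y, meta, n_perm)
    }
    new_procrustes_anova(tab, "size", n_perm, seed)
  })
}

size_complete_sides <- function(meta) {
  sides_per <- tapply(meta$side, meta$individual, function(s) length(unique(s)))
  as.vector(sides_per[as.character(meta$individual)] == 2L)
}

anova_size_object <- function(y, meta, n_perm) {
  ind <- as.factor(meta$individual)
  U <- rowmeans_by(y, ind)
  cls <- per_individual_labels(meta)
  cls <- cls[match(levels(droplevels(ind)), cls$individual), , drop = FALSE]
  rows <- between_individual_rows(U, cls, 1L, n_perm)
  sw <- ss_within(y, ind)
  ss_ind <- sum(sweep(U, 2L, colMeans(U), "-")^2)
  df_ind <- nrow(U) - 1L
  if (sw$df > 0) {
    f_obs <- goodall_f(ss_ind, df_ind, sw$ss, sw$df)
    f_perm <- vapply(seq_len(n_perm), function(i) {
      indp <- sample(as.character(ind))
      Up <- rowmeans_by(y, indp)
      wi <- ss_within(y, indp)
      goodall_f(sum(sweep(Up, 2L, colMeans(Up), "-")^2), df_ind, wi$ss, wi$df)
    }, numeric(1))
    rows <- dplyr::bind_rows(rows,
      anova_row("individual", ss_ind, df_ind, sw$ss, sw$df, perm_p(f_perm, f_obs)),
      tibble::tibble(effect = "imaging", SS = sw$ss, df = sw$df, MS = sw$ss / sw$df,
                     F = NA_real_, P = NA_real_))
  } else {
    rows <- dplyr::bind_rows(rows,
      tibble::tibble(effect = "individual", SS = ss_ind, df = df_ind,
                     MS = ss_ind / df_ind, F = NA_real_, P = NA_real_))
  }
  rows
}
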