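#' Define a landmark digitization scheme
#'
#' A scheme is the template for one digitized structure: how many landmarks it
#' has, which of them are semilandmarks allowed to slide along a curve, how the
#' structure is bilaterally symmetric, and which landmarks are adjacent (used
#' by the modularity test to decide whether a partition is spatially
#' contiguous).
#'
#' Symmetry comes in two flavours. *Object* symmetry means the structure
#' itself has an internal midline (e.g. a somite viewed dorsally): paired
#' landmarks map onto each other under reflection and `midline` landmarks map
#' onto themselves. *Matching* symmetry means the structure exists as separate
#' left and right copies (e.g. a leg segment), each digitized with the same
#' landmark numbering; reflection then maps a whole left configuration onto a
#' right one.
#'
#' @param name Scheme identifier (single string).
#' @param k Number of landmarks (integer, at least 3).
#' @param curves Optional list of integer vectors describing semilandmark
#'   curves. Each vector lists landmark indices in order along the curve; the
#'   first and last entries are fixed anchors and every interior entry is a
#'   sliding semilandmark.
#' @param symmetry One of `"none"`, `"object"`, `"matching"`.
#' @param pairs Two-column integer matrix of landmark pairs mapped onto each
#'   other by reflection. Required for object symmetry; optional for matching
#'   symmetry (when the left/right numbering already coincides it is empty).
#' @param midline Integer vector of landmarks lying on the symmetry axis
#'   (object symmetry only).
#' @param adjacency Optional two-column integer matrix of undirected edges
#'   between landmarks. When supplied the graph must be connected.
#'
#' @return An object of class `landmark_scheme`.
#' @examples
#' sq <- landmark_scheme("square", 4)
#' sq$k
#' @export
landmark_scheme <- function(name, k,
                            curves = NULL,
                            symmetry = c("none", "object", "matching"),
                            pairs = NULL,
                            midline = integer(),
                            adjacency = NULL) {
  symmetry <- match.arg(symmetry)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 3L) abort("`k` must be a single integer >= 3")

  sliders <- integer()
  if (!is.null(curves)) {
    curves <- lapply(curves, as.integer)
    for (cv in curves) {
      if (length(cv) < 3L) abort("each curve needs at least 3 landmarks (two anchors and one slider)")
      if (any(cv < 1L | cv > k)) abort("curve indices outside [1, k]")
      sliders <- c(sliders, cv[-c(1L, length(cv))])
    }
    if (anyDuplicated(sliders)) abort("a landmark may slide on at most one curve")
  }

  if (symmetry == "object") {
    if (is.null(pairs) || nrow(pairs) == 0L) {
      abort("object symmetry requires `pairs`")
    }
  }
  if (!is.null(pairs)) {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    idx <- c(pairs)
    if (any(idx < 1L | idx > k)) abort("pair indices outside [1, k]")
    if (anyDuplicated(idx)) abort("a landmark may appear in at most one pair")
    if (any(midline %in% idx)) abort("midline landmarks cannot also be paired")
  } else {
    pairs <- matrix(integer(), ncol = 2L)
  }
  midline <- as.integer(midline)
  if (symmetry == "object") {
    covered <- sort(c(c(pairs), midline))
    if (!identical(covered, seq_len(k))) {
      abort("object symmetry: every landmark must be paired or on the midline")
    }
  }

  if (!is.null(adjacency)) {
    adjacency <- matrix(as.integer(adjacency), ncol = 2L)
    if (any(adjacency < 1L | adjacency > k)) abort("adjacency indices outside [1, k]")
    g <- igraph::graph_from_edgelist(adjacency, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, k - igraph::vcount(g)))
    if (!igraph::is_connected(g)) abort("adjacency graph must be connected over all k landmarks")
  }

  structure(
    list(name = as.character(name), k = k, curves = curves, sliders = sort(sliders),
         symmetry = symmetry, pairs = pairs, midline = midline, adjacency = adjacency),
    class = "landmark_scheme"
  )
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat(sprintf("<landmark_scheme> %s: %d landmarks, %d sliders, symmetry = %s\n",
              x$name, x$k, length(x$sliders), x$symmetry))
  invisible(x)
}

#' Landmark schemes of the Acanthocyclops study design
#'
#' The five digitization templates used throughout the package's worked
#' examples and its synthetic study fixture, modelled on the rigid structures
#' classically scored in cyclopoid copepods: the female genital somite (`Gs`,
#' 45 landmarks with object symmetry and 26 equally spaced sliding
#' semilandmarks on the lateral edges), the caudal ramus (`Cr`, 7), the third
#' exopodal (`P4Exp3`, 10) and endopodal (`P4Enp3`, 7) segments of the fourth
#' leg, and the fourth-leg protopod (`P4CxBp`, 15); the last four have
#' matching left/right symmetry. Landmark counts sum to 84.
#'
#' For `Gs`, landmarks 1-9 sit on the left half, 10-18 mirror them on the
#' right (so sensilla 4-8 pair with 13-17 and the sixth-leg setae 3 with 12),
#' landmark 19 is the median pore, and sliders 20-32 / 33-45 run along the
#' left / right lateral edge between outline corners. Adjacency graphs connect
#' each structure's outline and attach interior points to their nearest
#' corners; they are used only for contiguity in modularity tests.
#'
#' @return Named list of [landmark_scheme] objects.
#' @examples
#' sum(vapply(acanthocyclops_schemes(), function(s) s$k, integer(1)))
#' @export
acanthocyclops_schemes <- function() {
  ring <- function(idx) cbind(idx, c(idx[-1L], idx[1L]))

  # Gs: left half 1-9, right half 10-18, median pore 19, sliders 20-45.
  gs_pairs <- rbind(cbind(1:9, 10:18), cbind(20:32, 33:45))
  gs_curves <- list(c(2L, 20:32, 9L), c(11L, 33:45, 18L))
  gs_adj <- rbind(
    ring(c(1L, 2L, 20:32, 9L, 19L, 18L, 33:45, 11L, 10L)),  # outline + median pore
    cbind(c(3L, 4L, 5L, 6L, 7L, 8L), c(2L, 3L, 4L, 5L, 6L, 9L)),   # left sensilla chain
    cbind(c(12L, 13L, 14L, 15L, 16L, 17L), c(11L, 12L, 13L, 14L, 15L, 18L)), # right chain
    cbind(c(19L, 19L), c(8L, 17L))
  )
  gs <- landmark_scheme("Gs", 45L, curves = gs_curves, symmetry = "object",
                        pairs = gs_pairs, midline = 19L, adjacency = gs_adj)

  cr <- landmark_scheme("Cr", 7L, symmetry = "matching",
                        adjacency = rbind(ring(1:6), c(7L, 4L)))
  p4exp3 <- landmark_scheme("P4Exp3", 10L, symmetry = "matching",
                            adjacency = ring(1:10))
  p4enp3 <- landmark_scheme("P4Enp3", 7L, symmetry = "matching",
                            adjacency = ring(1:7))
  # P4CxBp: outline corners 1-9 plus two pores (12, 15) and four spinule-row
  # landmarks (10, 11, 13, 14) on the surface.
  p4cxbp <- landmark_scheme("P4CxBp", 15L, symmetry = "matching",
                            adjacency = rbind(ring(1:9),
                                              cbind(10:15, c(2L, 3L, 4L, 6L, 7L, 8L))))

  list(Gs = gs, Cr = cr, P4Exp3 = p4exp3, P4Enp3 = p4enp3, P4CxBp = p4cxbp)
}
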