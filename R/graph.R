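#' @include AllGenerics.R
NULL

## canonicalize an edge matrix: (min,max) pairs, lexicographic order, unique
.canonEdges <- function(pairs, n) {
  pairs <- as.matrix(pairs)
  if (length(pairs) == 0L)
    return(matrix(integer(0), ncol = 2L))
  if (ncol(pairs) != 2L)
    stop("edge pairs must have two columns", call. = FALSE)
  if (any(is.na(pairs)) || any(pairs != round(pairs)))
    stop("edge pairs must be integer area indices", call. = FALSE)
  storage.mode(pairs) <- "integer"
  if (any(pairs < 1L) || any(pairs > n))
    stop("edge index out of range [1, n]", call. = FALSE)
  if (any(pairs[, 1L] == pairs[, 2L]))
    stop("self-loops are not allowed", call. = FALSE)
  pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]),
                 pmax(pairs[, 1L], pairs[, 2L]))
  pairs <- unique(pairs)
  pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
}

#' Construct an areal adjacency graph
#'
#' Builds an \code{\linkS4class{AreaGraph}} from a list of adjacent area
#' pairs. Pairs are canonicalized to (min, max) order, duplicates collapsed,
#' and the edge list sorted lexicographically so edge indices are
#' deterministic.
#'
#' @param edgePairs two-column matrix (or coercible) of 1-based area index
#'   pairs; each row one adjacency.
#' @param n number of areal units.
#' @return an \code{\linkS4class{AreaGraph}}.
#' @examples
#' g <- areaGraph(rbind(c(1, 2), c(2, 3)), n = 3)
#' edgeCount(g)   # 2
#' degrees(g)     # 1 2 1
#' @export
areaGraph <- function(edgePairs, n) {
  n <- as.integer(n)
  new("AreaGraph", n = n, edges = .canonEdges(edgePairs, n))
}

#' Rook-adjacency lattice graph
#'
#' Regular \code{nrow} x \code{ncol} lattice with rook (shared-border)
#' adjacency, the default simulation geometry. Areas are numbered row-major.
#'
#' @param nrow,ncol lattice dimensions.
#' @return an \code{\linkS4class{AreaGraph}}.
#' @seealso \code{\link{latticeCoords}}
#' @examples
#' edgeCount(latticeGraph(2, 2))  # 4
#' @export
latticeGraph <- function(nrow, ncol = nrow) {
  nrow <- as.integer(nrow); ncol <- as.integer(ncol)
  idx <- function(i, j) (i - 1L) * ncol + j
  horiz <- if (ncol > 1L)
    cbind(rep(seq_len(nrow), each = ncol - 1L),
          rep(seq_len(ncol - 1L), nrow))
  else matrix(integer(0), ncol = 2L)
  pairs <- rbind(
    if (nrow(horiz)) cbind(idx(horiz[, 1L], horiz[, 2L]),
                           idx(horiz[, 1L], horiz[, 2L] + 1L)),
    if (nrow > 1L) {
      vert <- cbind(rep(seq_len(nrow - 1L), each = ncol),
                    rep(seq_len(ncol), nrow - 1L))
      cbind(idx(vert[, 1L], vert[, 2L]), idx(vert[, 1L] + 1L, vert[, 2L]))
    })
  areaGraph(pairs, nrow * ncol)
}

#' Unit-square centroid coordinates of a lattice graph
#'
#' @param nrow,ncol lattice dimensions (must match the graph they are used
#'   with).
#' @return an \code{(nrow*ncol) x 2} matrix of centroid coordinates.
#' @export
latticeCoords <- function(nrow, ncol = nrow) {
  cbind(x = rep(seq_len(ncol), nrow), y = rep(seq_len(nrow), each = ncol))
}

#' Read an areal adjacency structure from file
#'
#' Accepts either a plain-text edge list (two whitespace-separated 1-based
#' integer columns, one edge per line, compatible with common spatial-weights
#' exports) or a CSV 0/1 symmetric adjacency matrix (detected by the presence
#' of commas).
#'
#' @param path file path.
#' @param n number of areas; required for edge lists (for a matrix it is
#'   taken from the dimension and checked if given).
#' @return an \code{\linkS4class{AreaGraph}}.
#' @export
readEdgeList <- function(path, n = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first, fixed = TRUE)) {
    A <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(A) <- NULL
    if (nrow(A) != ncol(A) || !isSymmetric(unname(A)))
      stop("adjacency matrix must be square and symmetric", call. = FALSE)
    if (!all(A %in% c(0, 1)) || any(diag(A) != 0))
      stop("adjacency matrix must be 0/1 with an empty diagonal",
           call. = FALSE)
    if (!is.null(n) && as.integer(n) != nrow(A))
      stop("'n' does not match the adjacency matrix dimension", call. = FALSE)
    idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
    return(areaGraph(idx, nrow(A)))
  }
  tab <- utils::read.table(path, header = FALSE,
                           colClasses = c("integer", "integer"))
  if (is.null(n))
    stop("'n' is required when reading an edge list", call. = FALSE)
  areaGraph(as.matrix(tab), n)
}

#' @describeIn AreaGraph-accessors number of areal units.
#' @export
setMethod("nAreas", "AreaGraph", function(x) x@n)

#' AreaGraph accessors
#'
#' @param x an \code{\linkS4class{AreaGraph}} (or, for some accessors, an
#'   \code{\linkS4class{EdgeState}} / \code{\linkS4class{CandidatePath}},
#'   which delegate to their graph).
#' @name AreaGraph-accessors
NULL

#' @describeIn AreaGraph-accessors canonical two-column edge matrix.
#' @export
setMethod("edges", "AreaGraph", function(x) x@edges)

#' @describeIn AreaGraph-accessors number of edges \eqn{N_E}.
#' @export
setMethod("edgeCount", "AreaGraph", function(x) nrow(x@edges))

#' @describeIn AreaGraph-accessors per-area number of adjacent areas.
#' @export
setMethod("degrees", "AreaGraph", function(x)
  tabulate(c(x@edges[, 1L], x@edges[, 2L]), nbins = x@n))

setMethod("show", "AreaGraph", function(object) {
  cat("AreaGraph with", object@n, "areas and", nrow(object@edges),
      "edges\n")
})

#' Construct an edge-removal state
#'
#' @param graph an \code{\linkS4class{AreaGraph}}.
#' @param removed removed edges: either a sorted-able integer vector of edge
#'   indices (rows of \code{edges(graph)}) or a two-column matrix of area
#'   pairs, each of which must be an edge of the graph.
#' @return an \code{\linkS4class{EdgeState}}.
#' @examples
#' g <- areaGraph(rbind(c(1, 2), c(2, 3)), n = 3)
#' s <- edgeState(g, removed = rbind(c(1, 2)))
#' wStar(s)  # 1 1 0
#' @export
edgeState <- function(graph, removed = integer(0)) {
  if (is.matrix(removed) || is.data.frame(removed)) {
    rm <- .canonEdges(removed, graph@n)
    key <- paste(graph@edges[, 1L], graph@edges[, 2L])
    idx <- match(paste(rm[, 1L], rm[, 2L]), key)
    if (anyNA(idx))
      stop("removed pair is not an edge of the graph", call. = FALSE)
    removed <- idx
  }
  removed <- sort(unique(as.integer(removed)))
  if (length(removed) &&
      (min(removed) < 1L || max(removed) > nrow(graph@edges)))
    stop("removed edge index out of range", call. = FALSE)
  new("EdgeState", graph = graph, removed = removed)
}

#' EdgeState accessors
#'
#' @param x an \code{\linkS4class{EdgeState}}.
#' @name EdgeState-accessors
NULL

#' @describeIn EdgeState-accessors retained edges (two-column matrix).
#' @export
setMethod("retainedEdges", "EdgeState", function(x) {
  e <- x@graph@edges
  if (length(x@removed)) e[-x@removed, , drop = FALSE] else e
})

#' @describeIn EdgeState-accessors removed edges (two-column matrix).
#' @export
setMethod("removedEdges", "EdgeState", function(x)
  x@graph@edges[x@removed, , drop = FALSE])

#' @describeIn EdgeState-accessors global-link indicators: 1 exactly for
#'   areas with at least one removed edge.
#' @export
setMethod("wStar", "EdgeState", function(x) {
  w <- integer(x@graph@n)
  if (length(x@removed)) {
    rm <- x@graph@edges[x@removed, , drop = FALSE]
    w[unique(c(rm[, 1L], rm[, 2L]))] <- 1L
  }
  w
})

#' @describeIn EdgeState-accessors position on the candidate path: the
#'   number of removed edges.
#' @export
setMethod("stateIndex", "EdgeState", function(x) length(x@removed))

#' @describeIn EdgeState-accessors per-area number of retained edges.
#' @export
setMethod("degrees", "EdgeState", function(x) {
  e <- retainedEdges(x)
  tabulate(c(e[, 1L], e[, 2L]), nbins = x@graph@n)
})

setMethod("show", "EdgeState", function(object) {
  cat("EdgeState:", length(object@removed), "of",
      nrow(object@graph@edges), "edges removed (",
      sum(wStar(object)), "areas linked to the global node )\n")
})

#' Precision-matrix hyperparameters
#'
#' @param epsilon diagonal-dominance constant (default 1e-4, the recommended
#'   value; 1e-3 is also in common use and results are insensitive to the
#'   choice).
#' @param tau2 conditional-variance scale (default 1; during model fitting
#'   tau2 is a parameter and this slot is only a starting value).
#' @return a \code{\linkS4class{PrecisionSpec}}.
#' @export
precisionSpec <- function(epsilon = 1e-4, tau2 = 1) {
  new("PrecisionSpec", epsilon = as.numeric(epsilon), tau2 = as.numeric(tau2))
}

#' Assemble the extended LCAR precision matrix
#'
#' Returns the unscaled \eqn{(n+1) \times (n+1)} precision
#' \eqn{Q(\tilde W) + \epsilon I}, where
#' \eqn{Q(\tilde W) = \mathrm{diag}(\tilde W 1) - \tilde W} and
#' \eqn{\tilde W} is the extended neighborhood matrix of the state (retained
#' edges between areas, plus links from the global node, stored last, to each
#' area with at least one removed edge). The variance scale \eqn{\tau^2}
#' divides this matrix downstream. The result is symmetric and diagonally
#' dominant with smallest eigenvalue at least \eqn{\epsilon}, hence positive
#' definite.
#'
#' @param state an \code{\linkS4class{EdgeState}}.
#' @param spec a \code{\linkS4class{PrecisionSpec}} (only \code{epsilon}
#'   is used).
#' @return a sparse symmetric \code{\link[Matrix]{dsCMatrix-class}} matrix.
#' @export
assemblePrecision <- function(state, spec = precisionSpec()) {
  stopifnot(is(state, "EdgeState"), is(spec, "PrecisionSpec"))
  n <- state@graph@n
  ret <- retainedEdges(state)
  ws <- wStar(state)
  star <- which(ws == 1L)
  ii <- c(ret[, 1L], star)
  jj <- c(ret[, 2L], rep(n + 1L, length(star)))
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = rep(1, length(ii)),
                            dims = c(n + 1L, n + 1L), symmetric = TRUE)
  Q <- Matrix::Diagonal(n + 1L, Matrix::rowSums(W) + spec@epsilon) - W
  methods::as(methods::as(Q, "symmetricMatrix"), "CsparseMatrix")
}

#' Gaussian full conditional of one random effect
#'
#' The LCAR prior's full conditional distribution of a single random effect
#' given all others. For area \eqn{k}:
#' mean \eqn{(\sum_{i \sim k \,\mathrm{retained}} \phi_i + w_k^* \phi^*) /
#' (d_k + w_k^* + \epsilon)} and variance
#' \eqn{\tau^2 / (d_k + w_k^* + \epsilon)}, where \eqn{d_k} is the number of
#' retained edges at \eqn{k}. For the global node: mean
#' \eqn{\sum_k w_k^* \phi_k / (\sum_k w_k^* + \epsilon)} and variance
#' \eqn{\tau^2 / (\sum_k w_k^* + \epsilon)}. Identical to the conditional of
#' the joint Gaussian with precision
#' \eqn{(Q(\tilde W) + \epsilon I)/\tau^2}.
#'
#' @param state an \code{\linkS4class{EdgeState}}.
#' @param spec a \code{\linkS4class{PrecisionSpec}}.
#' @param phi length-n vector of area random effects.
#' @param phiStar scalar global random effect.
#' @param k area index in 1..n, or \code{"global"}.
#' @return list with elements \code{mean} and \code{variance}.
#' @export
fullConditional <- function(state, spec, phi, phiStar, k) {
  stopifnot(is(state, "EdgeState"), is(spec, "PrecisionSpec"))
  n <- state@graph@n
  stopifnot(length(phi) == n, length(phiStar) == 1L)
  ws <- wStar(state)
  if (identical(k, "global")) {
    s <- sum(ws)
    prec <- s + spec@epsilon
    return(list(mean = sum(ws * phi) / prec,
                variance = spec@tau2 / prec))
  }
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= n)
  ret <- retainedEdges(state)
  nb <- c(ret[ret[, 1L] == k, 2L], ret[ret[, 2L] == k, 1L])
  prec <- length(nb) + ws[k] + spec@epsilon
  list(mean = (sum(phi[nb]) + ws[k] * phiStar) / prec,
       variance = spec@tau2 / prec)
}

#' Partial autocorrelation between two area random effects
#'
#' \eqn{-Q_{kj} / \sqrt{Q_{kk} Q_{jj}}} on the assembled extended precision;
#' zero whenever (k, j) is not a retained edge, so removing an edge makes the
#' two effects conditionally independent.
#'
#' @inheritParams fullConditional
#' @param k,j distinct area indices.
#' @return a number in [-1, 1].
#' @export
partialCorrelation <- function(state, spec, k, j) {
  stopifnot(k != j)
  Q <- assemblePrecision(state, spec)
  -Q[k, j] / sqrt(Q[k, k] * Q[j, j])
}
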