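#' @include graph.R
NULL

#' Construct historical count data for prior elicitation
#'
#' @param Yhist r x n matrix of historical observed counts (one row per
#'   prior period); a vector is treated as a single period.
#' @param Ehist r x n matrix of matching positive expected counts.
#' @param X design matrix shared with the study period (leading intercept
#'   column of ones).
#' @return a \code{\linkS4class{PriorCounts}}.
#' @export
priorCounts <- function(Yhist, Ehist, X) {
  if (is.vector(Yhist)) Yhist <- matrix(Yhist, nrow = 1L)
  if (is.vector(Ehist)) Ehist <- matrix(Ehist, nrow = 1L)
  X <- as.matrix(X)
  storage.mode(Yhist) <- "integer"
  storage.mode(Ehist) <- "double"
  storage.mode(X) <- "double"
  new("PriorCounts", Yhist = Yhist, Ehist = Ehist, X = X)
}

## connected component labels (1-based) by breadth-first search
.components <- function(graph) {
  n <- graph@n
  e <- graph@edges
  nbr <- vector("list", n)
  for (r in seq_len(nrow(e))) {
    nbr[[e[r, 1L]]] <- c(nbr[[e[r, 1L]]], e[r, 2L])
    nbr[[e[r, 2L]]] <- c(nbr[[e[r, 2L]]], e[r, 1L])
  }
  comp <- integer(n)
  g <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      g <- g + 1L
      queue <- s
      comp[s] <- g
      while (length(queue)) {
        v <- queue[[1L]]; queue <- queue[-1L]
        for (w in nbr[[v]]) if (comp[w] == 0L) { comp[w] <- g; queue <- c(queue, w) }
      }
    }
  }
  comp
}

#' Pooled log-SIR residuals for prior elicitation
#'
#' Pools the historical periods into one empirical log standardized
#' incidence ratio per area, \eqn{\bar z_k = \frac{1}{r}\sum_t
#' \ln\{(Y_k^{(t)} + 0.5) / E_k^{(t)}\}}, removes the covariate trend by an
#' ordinary least-squares fit on \code{X} (the maximum-likelihood estimator
#' under the Gaussian approximation), and appends the plug-in global effect
#' (the mean residual) as element \eqn{n+1}. The +0.5 continuity correction
#' guards zero counts and can be disabled.
#'
#' @param prior a \code{\linkS4class{PriorCounts}}.
#' @param halfCorrection add 0.5 to counts before taking logs (default TRUE).
#' @return a \code{\linkS4class{ResidualVector}}.
#' @export
pooledResiduals <- function(prior, halfCorrection = TRUE) {
  stopifnot(is(prior, "PriorCounts"))
  shift <- if (halfCorrection) 0.5 else 0
  lsir <- log((prior@Yhist + shift) / prior@Ehist)
  if (any(!is.finite(lsir)))
    stop("non-finite log-SIR; zero counts need the +0.5 correction",
         call. = FALSE)
  zbar <- colMeans(lsir)
  fit <- stats::lm.fit(prior@X, zbar)
  z <- as.numeric(fit$residuals)
  new("ResidualVector", z = z, zExt = c(z, mean(z)),
      betaHat = as.numeric(fit$coefficients))
}

#' Approximate Gaussian log-likelihood of an edge-removal state
#'
#' The elicitation objective: with the extended residual vector
#' \eqn{\tilde z} treated as a draw from
#' \eqn{N(0, \tau^2 (Q(\tilde W) + \epsilon I)^{-1})} and \eqn{\tau^2}
#' profiled out at \eqn{\hat\tau^2 = \tilde z^\top (Q + \epsilon I)\tilde z /
#' (n+1)}, returns
#' \deqn{\tfrac12 \log|Q + \epsilon I| - \tfrac{n+1}{2}\log\hat\tau^2 -
#'   \tilde z^\top (Q+\epsilon I) \tilde z / (2\hat\tau^2),}
#' with additive constants dropped. A floor of \code{tau2Floor} on
#' \eqn{\hat\tau^2} guards degenerate all-zero residuals.
#'
#' @param zExt length-(n+1) extended residual vector, or a
#'   \code{\linkS4class{ResidualVector}}.
#' @param state an \code{\linkS4class{EdgeState}}.
#' @param spec a \code{\linkS4class{PrecisionSpec}} (only \code{epsilon}
#'   is used; \eqn{\tau^2} is profiled).
#' @param tau2Floor lower bound for the profiled variance (default 1e-12).
#' @return scalar log-likelihood (up to a constant).
#' @export
gaussianLogLik <- function(zExt, state, spec = precisionSpec(),
                           tau2Floor = 1e-12) {
  if (is(zExt, "ResidualVector")) zExt <- zExt@zExt
  n <- state@graph@n
  stopifnot(length(zExt) == n + 1L)
  Q <- as.matrix(assemblePrecision(state, spec))
  R <- chol(Q)
  logdet <- 2 * sum(log(diag(R)))
  quad <- sum((R %*% zExt)^2)
  m <- n + 1L
  t2 <- max(quad / m, tau2Floor)
  0.5 * logdet - 0.5 * m * log(t2) - quad / (2 * t2)
}

#' Elicit the candidate edge-removal path from historical data
#'
#' Greedy construction of the ordered sequence of neighborhood matrices over
#' which the model's discrete-uniform prior is placed. Starting from the
#' full graph, each step evaluates the approximate Gaussian log-likelihood
#' (\code{\link{gaussianLogLik}}) of every state reachable by removing one
#' additional edge and moves to the maximizer, until all edges are removed.
#' Ties are broken by canonical (sorted) edge order. Log-determinants of all
#' \eqn{N_E + 1} states are cached for reuse by the MCMC path-index update;
#' each is computed from a full Cholesky factorization of the accepted state
#' (candidate screening uses rank-\eqn{\le 3} determinant updates, which do
#' not affect the cached values).
#'
#' Only prior-period data enter this computation; study-period counts are
#' never used here.
#'
#' @param graph an \code{\linkS4class{AreaGraph}}; a warning is issued if it
#'   is disconnected.
#' @param prior a \code{\linkS4class{PriorCounts}}, or a pre-computed
#'   \code{\linkS4class{ResidualVector}}.
#' @param spec a \code{\linkS4class{PrecisionSpec}}.
#' @param method \code{"downdate"} (default; Cholesky determinant updates in
#'   compiled code) or \code{"dense"} (reference implementation that refits
#'   every candidate from scratch in R; identical result, used for
#'   verification).
#' @param tau2Floor floor for the profiled variance.
#' @return a \code{\linkS4class{CandidatePath}}.
#' @export
elicitPath <- function(graph, prior, spec = precisionSpec(),
                       method = c("downdate", "dense"),
                       tau2Floor = 1e-12) {
  method <- match.arg(method)
  stopifnot(is(graph, "AreaGraph"))
  resid <- if (is(prior, "ResidualVector")) prior else pooledResiduals(prior)
  zext <- resid@zExt
  if (length(zext) != graph@n + 1L)
    stop("residual vector does not match the graph dimension", call. = FALSE)
  ne <- edgeCount(graph)
  if (ne == 0L) {
    warning("graph has no edges; returning the degenerate length-1 path")
    s <- edgeState(graph)
    ld <- 2 * sum(log(diag(chol(as.matrix(assemblePrecision(s, spec))))))
    return(new("CandidatePath", graph = graph, removalOrder = integer(0),
               logdets = ld, epsilon = spec@epsilon,
               loglik = gaussianLogLik(zext, s, spec, tau2Floor)))
  }
  if (max(.components(graph)) > 1L)
    warning("graph is disconnected; elicitation proceeds per the full graph")

  if (method == "downdate") {
    res <- cpp_elicit_path(graph@edges - 1L, graph@n, zext, spec@epsilon,
                           tau2Floor)
    return(new("CandidatePath", graph = graph,
               removalOrder = as.integer(res$removalOrder),
               logdets = as.numeric(res$logdets),
               epsilon = spec@epsilon,
               loglik = as.numeric(res$loglik)))
  }

  ## dense reference: full refit of every candidate
  removed <- integer(0)
  order_out <- integer(0)
  logdets <- numeric(ne + 1L)
  logliks <- numeric(ne + 1L)
  stateLd <- function(rm) {
    Q <- as.matrix(assemblePrecision(edgeState(graph, rm), spec))
    2 * sum(log(diag(chol(Q))))
  }
  for (j in 0:(ne - 1L)) {
    logdets[j + 1L] <- stateLd(removed)
    logliks[j + 1L] <- gaussianLogLik(zext, edgeState(graph, removed), spec,
                                      tau2Floor)
    cand <- setdiff(seq_len(ne), removed)
    ll <- vapply(cand, function(e)
      gaussianLogLik(zext, edgeState(graph, c(removed, e)), spec,
                     tau2Floor), numeric(1))
    best <- cand[which.max(ll)]   # which.max takes the first (canonical) tie
    removed <- sort(c(removed, best))
    order_out <- c(order_out, best)
  }
  logdets[ne + 1L] <- stateLd(seq_len(ne))
  logliks[ne + 1L] <- gaussianLogLik(zext, edgeState(graph, seq_len(ne)),
                                     spec, tau2Floor)
  new("CandidatePath", graph = graph, removalOrder = order_out,
      logdets = logdets, epsilon = spec@epsilon, loglik = logliks)
}

#' CandidatePath accessors
#'
#' @param x a \code{\linkS4class{CandidatePath}}.
#' @param j state index in 0..\eqn{N_E} (number of removed edges).
#' @name CandidatePath-accessors
NULL

#' @describeIn CandidatePath-accessors the \code{\linkS4class{EdgeState}} at
#'   position \code{j} on the path (the first \code{j} removals applied).
#' @export
setMethod("pathState", "CandidatePath", function(x, j) {
  j <- as.integer(j)
  stopifnot(j >= 0L, j <= length(x@removalOrder))
  edgeState(x@graph, x@removalOrder[seq_len(j)])
})

#' @describeIn CandidatePath-accessors number of states, \eqn{N_E + 1}.
#' @export
setMethod("pathLength", "CandidatePath", function(x)
  length(x@removalOrder) + 1L)

#' @describeIn CandidatePath-accessors cached log-determinants, one per state.
#' @export
setMethod("pathLogDets", "CandidatePath", function(x) x@logdets)

#' @describeIn CandidatePath-accessors edge indices in removal order.
#' @export
setMethod("removalOrder", "CandidatePath", function(x) x@removalOrder)

setMethod("show", "CandidatePath", function(object) {
  cat("CandidatePath over", object@graph@n, "areas:",
      length(object@removalOrder) + 1L, "states (epsilon =",
      object@epsilon, ")\n")
})
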