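#' @include localCAR-package.R
NULL

#' Areal adjacency graph
#'
#' An \code{AreaGraph} holds the fixed support of the neighborhood matrix
#' \eqn{W}: the number of areal units \eqn{n} and the canonical edge list of
#' unordered adjacent pairs. Edges are stored as a two-column integer matrix
#' with \code{edge[, 1] < edge[, 2]}, sorted lexicographically, so that edge
#' indices are deterministic and an \code{\linkS4class{EdgeState}} or
#' \code{\linkS4class{CandidatePath}} can refer to edges by row index.
#'
#' @slot n number of areal units.
#' @slot edges integer matrix with two columns (1-based area indices,
#'   first < second), one row per undirected edge, lexicographically sorted.
#'
#' @seealso \code{\link{areaGraph}}, \code{\link{latticeGraph}},
#'   \code{\link{readEdgeList}}
#' @export
setClass("AreaGraph",
         representation(n = "integer", edges = "matrix"))

setValidity("AreaGraph", function(object) {
  msg <- character()
  n <- object@n
  e <- object@edges
  if (length(n) != 1L || is.na(n) || n < 1L)
    msg <- c(msg, "'n' must be a single positive integer")
  if (!is.integer(e) || ncol(e) != 2L)
    msg <- c(msg, "'edges' must be a two-column integer matrix")
  else if (nrow(e) > 0L) {
    if (any(e < 1L) || any(e > n))
      msg <- c(msg, "edge indices must lie in [1, n]")
    if (any(e[, 1L] >= e[, 2L]))
      msg <- c(msg, "edges must satisfy edge[,1] < edge[,2] (no self-loops)")
    o <- order(e[, 1L], e[, 2L])
    if (!identical(o, seq_len(nrow(e))))
      msg <- c(msg, "edges must be lexicographically sorted")
    if (anyDuplicated(paste(e[, 1L], e[, 2L])))
      msg <- c(msg, "duplicate edges are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' Edge-removal state of the neighborhood matrix
#'
#' An \code{EdgeState} records which edges of an \code{\linkS4class{AreaGraph}}
#' are currently removed from the neighborhood matrix. From the removed set it
#' derives the global-link indicator vector \eqn{w_k^*} (one exactly for the
#' areas with at least one removed edge) and hence the extended
#' \eqn{(n+1)\times(n+1)} neighborhood matrix in which a global node is
#' connected to every such area.
#'
#' @slot graph the underlying \code{\linkS4class{AreaGraph}}.
#' @slot removed integer vector of removed edge indices (rows of
#'   \code{edges(graph)}), sorted, possibly empty.
#'
#' @seealso \code{\link{edgeState}}, \code{\link{wStar}},
#'   \code{\link{assemblePrecision}}
#' @export
setClass("EdgeState",
         representation(graph = "AreaGraph", removed = "integer"))

setValidity("EdgeState", function(object) {
  msg <- character()
  ne <- nrow(object@graph@edges)
  r <- object@removed
  if (length(r)) {
    if (any(is.na(r)) || any(r < 1L) || any(r > ne))
      msg <- c(msg, "'removed' must index rows of the graph's edge list")
    if (anyDuplicated(r))
      msg <- c(msg, "'removed' must not contain duplicates")
    if (is.unsorted(r))
      msg <- c(msg, "'removed' must be sorted")
  }
  if (length(msg)) msg else TRUE
})

#' Precision-matrix hyperparameters
#'
#' Bundles the diagonal-dominance constant \eqn{\epsilon} and the conditional
#' variance scale \eqn{\tau^2} of the localized CAR prior. The unscaled
#' precision is \eqn{Q(\tilde W) + \epsilon I}; \eqn{\tau^2} divides it in the
#' Gaussian prior, so the conditional variance of an area's random effect is
#' \eqn{\tau^2} over its (extended) degree plus \eqn{\epsilon}.
#'
#' @slot epsilon small positive constant added to the diagonal; default 1e-4.
#' @slot tau2 positive variance scale; default 1.
#'
#' @seealso \code{\link{precisionSpec}}
#' @export
setClass("PrecisionSpec",
         representation(epsilon = "numeric", tau2 = "numeric"))

setValidity("PrecisionSpec", function(object) {
  msg <- character()
  if (length(object@epsilon) != 1L || !is.finite(object@epsilon) ||
      object@epsilon <= 0)
    msg <- c(msg, "'epsilon' must be a single positive number")
  if (length(object@tau2) != 1L || !is.finite(object@tau2) ||
      object@tau2 <= 0)
    msg <- c(msg, "'tau2' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Candidate path of neighborhood matrices
#'
#' The ordered sequence of edge-removal states from the full graph (state 0,
#' all edges retained, the intrinsic CAR support) to the empty graph (state
#' \eqn{N_E}, all removed, independent random effects shrunk to the global
#' effect). Consecutive states differ by exactly one removed edge; the order
#' is elicited from historical data by \code{\link{elicitPath}}. The path
#' stores the removal order, the cached log-determinants
#' \eqn{\log|Q(\tilde W^{(j)}) + \epsilon I|} needed by the MCMC path-index
#' update, and the greedy objective trace.
#'
#' @slot graph the underlying \code{\linkS4class{AreaGraph}}.
#' @slot removalOrder integer vector of length \eqn{N_E}; edge indices in the
#'   order they are removed along the path.
#' @slot logdets numeric vector of length \eqn{N_E + 1}; log-determinant of
#'   the extended precision for each state.
#' @slot epsilon the diagonal constant the log-determinants were computed with.
#' @slot loglik numeric vector of length \eqn{N_E + 1}; the approximate
#'   Gaussian log-likelihood of each state at elicitation time (NA when the
#'   path was constructed without data).
#'
#' @seealso \code{\link{elicitPath}}, \code{\link{pathState}},
#'   \code{\link{writePath}}
#' @export
setClass("CandidatePath",
         representation(graph = "AreaGraph", removalOrder = "integer",
                        logdets = "numeric", epsilon = "numeric",
                        loglik = "numeric"))

setValidity("CandidatePath", function(object) {
  msg <- character()
  ne <- nrow(object@graph@edges)
  ro <- object@removalOrder
  if (length(ro) != ne)
    msg <- c(msg, "'removalOrder' must contain every edge exactly once")
  else if (ne > 0L && !identical(sort(ro), seq_len(ne)))
    msg <- c(msg, "'removalOrder' must be a permutation of the edge indices")
  if (length(object@logdets) != ne + 1L)
    msg <- c(msg, "'logdets' must have length N_E + 1")
  if (length(object@loglik) != ne + 1L)
    msg <- c(msg, "'loglik' must have length N_E + 1")
  if (length(object@epsilon) != 1L || object@epsilon <= 0)
    msg <- c(msg, "'epsilon' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Study-period areal count data
#'
#' Observed counts \code{Y}, expected counts \code{E} (offsets from external
#' standardization) and the design matrix \code{X} (leading column of ones)
#' for one study period over \eqn{n} areal units.
#'
#' @slot Y integer vector of observed counts, length \eqn{n}.
#' @slot E numeric vector of positive expected counts, length \eqn{n}.
#' @slot X numeric design matrix, \eqn{n \times (p+1)}, full column rank,
#'   first column all ones.
#'
#' @seealso \code{\link{countData}}, \code{\link{readArealCSV}},
#'   \code{\link{sir}}
#' @export
setClass("CountData",
         representation(Y = "integer", E = "numeric", X = "matrix"))

setValidity("CountData", function(object) {
  msg <- character()
  n <- length(object@Y)
  if (any(is.na(object@Y)) || any(object@Y < 0L))
    msg <- c(msg, "'Y' must be nonnegative integer counts")
  if (length(object@E) != n || any(!is.finite(object@E)) ||
      any(object@E <= 0))
    msg <- c(msg, "'E' must be positive and of the same length as 'Y'")
  X <- object@X
  if (!is.numeric(X) || nrow(X) != n)
    msg <- c(msg, "'X' must be a numeric matrix with one row per area")
  else {
    if (any(X[, 1L] != 1))
      msg <- c(msg, "the first column of 'X' must be an intercept of ones")
    if (qr(X)$rank < ncol(X))
      msg <- c(msg, "'X' must have full column rank")
  }
  if (length(msg)) msg else TRUE
})

#' Historical (prior-period) count data
#'
#' Observed and expected counts for \eqn{r} time periods preceding the study
#' period, with the covariate design shared with the study data. Used only
#' for prior elicitation of the candidate edge-removal path; study-period
#' counts never enter that computation.
#'
#' @slot Yhist integer matrix, \eqn{r \times n}, historical observed counts.
#' @slot Ehist numeric matrix, \eqn{r \times n}, historical expected counts
#'   (strictly positive).
#' @slot X numeric design matrix shared with the study period.
#'
#' @seealso \code{\link{priorCounts}}, \code{\link{pooledResiduals}},
#'   \code{\link{elicitPath}}
#' @export
setClass("PriorCounts",
         representation(Yhist = "matrix", Ehist = "matrix", X = "matrix"))

setValidity("PriorCounts", function(object) {
  msg <- character()
  Yh <- object@Yhist; Eh <- object@Ehist
  if (!is.numeric(Yh) || any(is.na(Yh)) || any(Yh < 0) ||
      any(Yh != round(Yh)))
    msg <- c(msg, "'Yhist' must contain nonnegative integer counts")
  if (!identical(dim(Yh), dim(Eh)))
    msg <- c(msg, "'Yhist' and 'Ehist' must have identical dimensions")
  else if (any(!is.finite(Eh)) || any(Eh <= 0))
    msg <- c(msg, "'Ehist' must be strictly positive")
  if (nrow(object@X) != ncol(Yh))
    msg <- c(msg, "'X' must have one row per area (column of Yhist)")
  if (length(msg)) msg else TRUE
})

#' Pooled log-SIR residual vector
#'
#' The approximate Gaussian data vector used for prior elicitation: per-area
#' residuals of the pooled empirical log standardized-incidence-ratio after
#' removing the least-squares covariate fit, extended by the plug-in estimate
#' of the global random effect.
#'
#' @slot z numeric length-\eqn{n} residual vector.
#' @slot zExt numeric length-\eqn{(n+1)} vector; \code{z} followed by the
#'   plug-in global effect (the mean residual).
#' @slot betaHat least-squares covariate coefficients used to detrend.
#'
#' @seealso \code{\link{pooledResiduals}}, \code{\link{gaussianLogLik}}
#' @export
setClass("ResidualVector",
         representation(z = "numeric", zExt = "numeric", betaHat = "numeric"))

setValidity("ResidualVector", function(object) {
  msg <- character()
  if (length(object@zExt) != length(object@z) + 1L)
    msg <- c(msg, "'zExt' must be 'z' plus one global element")
  if (any(!is.finite(object@z)) || any(!is.finite(object@zExt)))
    msg <- c(msg, "residuals must be finite")
  if (length(msg)) msg else TRUE
})

#' MCMC sampler configuration
#'
#' @slot nSample retained iterations per chain (after burn-in).
#' @slot nBurn burn-in iterations per chain.
#' @slot nChains number of chains.
#' @slot qWindow half-width of the discrete uniform proposal window for the
#'   path index (the mixing tuning parameter).
#' @slot stepBeta,stepPhi initial random-walk standard deviations for the
#'   regression coefficients and the random effects; adapted during burn-in
#'   toward 40--50\% acceptance and then frozen.
#' @slot betaPriorVar prior variance of each regression coefficient
#'   (zero-mean Gaussian); default 1000^2.
#' @slot tau2Shape,tau2Rate inverse-gamma prior for variance parameters;
#'   default IG(1, 0.01).
#' @slot seed integer seed; chain \eqn{c} uses \code{seed + c - 1}.
#'
#' @seealso \code{\link{mcmcConfig}}, \code{\link{lcarFit}},
#'   \code{\link{bymFit}}
#' @export
setClass("McmcConfig",
         representation(nSample = "integer", nBurn = "integer",
                        nChains = "integer", qWindow = "integer",
                        stepBeta = "numeric", stepPhi = "numeric",
                        betaPriorVar = "numeric", tau2Shape = "numeric",
                        tau2Rate = "numeric", seed = "integer"))

setValidity("McmcConfig", function(object) {
  msg <- character()
  if (object@nSample < 1L) msg <- c(msg, "'nSample' must be positive")
  if (object@nBurn < 0L) msg <- c(msg, "'nBurn' must be nonnegative")
  if (object@nChains < 1L) msg <- c(msg, "'nChains' must be positive")
  if (object@qWindow < 1L) msg <- c(msg, "'qWindow' must be >= 1")
  if (object@betaPriorVar <= 0 || object@tau2Shape <= 0 ||
      object@tau2Rate <= 0)
    msg <- c(msg, "prior hyperparameters must be positive")
  if (object@stepBeta <= 0 || object@stepPhi <= 0)
    msg <- c(msg, "step sizes must be positive")
  if (length(msg)) msg else TRUE
})

#' Posterior samples from a spatial count model fit
#'
#' Pooled post-burn-in draws from all chains, with a chain label per draw.
#' LCAR fits populate \code{phiStar} and \code{pathIndex}; BYM fits populate
#' \code{theta}/\code{sigma2} (and use \code{phi} for the spatially
#' structured component); IAR fits leave both empty.
#'
#' @slot model one of "lcar", "bym", "iar".
#' @slot beta draws x (p+1) matrix of regression coefficients.
#' @slot phi draws x n matrix of (structured) spatial random effects.
#' @slot phiStar numeric draws of the global random effect (LCAR; else empty).
#' @slot tau2 numeric draws of the spatial variance.
#' @slot pathIndex integer draws of the edge-removal path index (LCAR).
#' @slot theta draws x n matrix of unstructured effects (BYM; else 0-col).
#' @slot sigma2 numeric draws of the unstructured variance (BYM).
#' @slot chain integer chain label per draw.
#' @slot acceptance named list of per-chain acceptance rates.
#' @slot config the \code{\linkS4class{McmcConfig}} used.
#'
#' @seealso \code{\link{lcarFit}}, \code{\link{bymFit}}, \code{\link{dic}},
#'   \code{\link{riskSummaries}}, \code{\link{edgePosteriorSummary}}
#' @export
setClass("PosteriorSamples",
         representation(model = "character", beta = "matrix", phi = "matrix",
                        phiStar = "numeric", tau2 = "numeric",
                        pathIndex = "integer", theta = "matrix",
                        sigma2 = "numeric", chain = "integer",
                        acceptance = "list", config = "McmcConfig"))

setValidity("PosteriorSamples", function(object) {
  msg <- character()
  nd <- nrow(object@beta)
  if (!object@model %in% c("lcar", "bym", "iar"))
    msg <- c(msg, "'model' must be one of lcar/bym/iar")
  if (nrow(object@phi) != nd || length(object@chain) != nd ||
      length(object@tau2) != nd)
    msg <- c(msg, "draw counts of beta/phi/tau2/chain must agree")
  if (length(object@tau2) && any(object@tau2 <= 0))
    msg <- c(msg, "'tau2' draws must be positive")
  if (length(object@phiStar) && length(object@phiStar) != nd)
    msg <- c(msg, "'phiStar' must be empty or one draw per row")
  if (length(object@pathIndex) && length(object@pathIndex) != nd)
    msg <- c(msg, "'pathIndex' must be empty or one draw per row")
  if (length(msg)) msg else TRUE
})

#' Simulation scenario
#'
#' One cell of the simulation-study design: a piecewise-constant localized
#' mean with levels \{-1, 0, 1\} scaled by \code{M}, Matern(\eqn{\nu = 2.5})
#' covariate and residual surfaces, expected counts drawn uniformly from
#' \code{eRange}, and \code{rPrior} historical years whose residual surface
#' is the study surface plus independent Uniform[-0.1, 0.1] noise.
#'
#' @slot M step-change magnitude multiplying the \{-1,0,1\} template.
#' @slot eRange length-2 range of expected counts.
#' @slot beta true covariate effect (default 0.1).
#' @slot maternNu Matern smoothness (default 2.5).
#' @slot rangeShort,rangeLong correlation ranges of the two covariate
#'   processes; \code{rangeLong} is also the residual-process range.
#'   \code{NA} means "set from the region diameter at generation time"
#'   (1/10 and 1/3 of it, respectively).
#' @slot sigma2Resid residual-process variance (default 0.25^2).
#' @slot sigma2Cov variance of the covariate's component processes before
#'   standardization (default 1; 0 gives a constant zero covariate).
#' @slot rPrior number of prior years (default 3).
#' @slot priorNoise half-width of the uniform prior-year perturbation
#'   (default 0.1).
#'
#' @seealso \code{\link{scenario}}, \code{\link{scenarioGrid}},
#'   \code{\link{genDataset}}
#' @export
setClass("Scenario",
         representation(M = "numeric", eRange = "numeric", beta = "numeric",
                        maternNu = "numeric", rangeShort = "numeric",
                        rangeLong = "numeric", sigma2Resid = "numeric",
                        sigma2Cov = "numeric", rPrior = "integer",
                        priorNoise = "numeric"))

setValidity("Scenario", function(object) {
  msg <- character()
  if (object@M < 0) msg <- c(msg, "'M' must be nonnegative")
  if (length(object@eRange) != 2L || any(object@eRange <= 0) ||
      object@eRange[1L] > object@eRange[2L])
    msg <- c(msg, "'eRange' must be a positive increasing pair")
  if (object@sigma2Resid < 0) msg <- c(msg, "'sigma2Resid' must be >= 0")
  if (object@rPrior < 1L) msg <- c(msg, "'rPrior' must be >= 1")
  if (object@priorNoise < 0) msg <- c(msg, "'priorNoise' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Simulated dataset (study + prior periods + truth)
#'
#' @slot study the study-period \code{\linkS4class{CountData}}.
#' @slot prior the historical \code{\linkS4class{PriorCounts}}.
#' @slot truth list with elements \code{beta}, \code{phiTrue},
#'   \code{covariate}, \code{template}, \code{E} and \code{uPrior}
#'   (the r x n uniform perturbations of the prior-year residual surfaces).
#'
#' @seealso \code{\link{genDataset}}
#' @export
setClass("SimulatedDataset",
         representation(study = "CountData", prior = "PriorCounts",
                        truth = "list"))
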