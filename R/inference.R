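#' @include elicitation.R
NULL

#' Construct study-period count data
#'
#' @param Y nonnegative integer observed counts.
#' @param E positive expected counts (standardization offsets).
#' @param X covariate matrix (without intercept) or full design matrix whose
#'   first column is already ones; an intercept column is prepended when
#'   absent. \code{NULL} gives an intercept-only design.
#' @return a \code{\linkS4class{CountData}}.
#' @export
countData <- function(Y, E, X = NULL) {
  n <- length(Y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  X <- as.matrix(X)
  if (ncol(X) == 0L || any(X[, 1L] != 1))
    X <- cbind(1, X)
  storage.mode(X) <- "double"
  colnames(X) <- c("(Intercept)",
                   if (ncol(X) > 1L) {
                     nm <- colnames(X)[-1L]
                     if (is.null(nm) || any(!nzchar(nm)))
                       paste0("x", seq_len(ncol(X) - 1L)) else nm
                   })
  if (any(is.na(Y)) || any(Y != round(Y)))
    stop("'Y' must be integer counts", call. = FALSE)
  new("CountData", Y = as.integer(Y), E = as.numeric(E), X = X)
}

setMethod("show", "CountData", function(object) {
  cat("CountData:", length(object@Y), "areas,",
      ncol(object@X) - 1L, "covariate(s); total Y =", sum(object@Y), "\n")
})

#' @describeIn AreaGraph-accessors number of areas of a CountData object.
#' @export
setMethod("nAreas", "CountData", function(x) length(x@Y))

#' MCMC configuration
#'
#' @param nSample retained iterations per chain.
#' @param nBurn burn-in iterations per chain.
#' @param nChains number of chains (the application default in the field is
#'   3 chains of 50,000 + 50,000; tests and examples use far smaller runs).
#' @param qWindow half-width of the path-index proposal window.
#' @param stepBeta,stepPhi initial random-walk standard deviations (adapted
#'   during burn-in toward 40--50\% acceptance, then frozen).
#' @param betaPriorVar Gaussian prior variance for each coefficient.
#' @param tau2Shape,tau2Rate inverse-gamma prior for variances, IG(1, 0.01)
#'   by default.
#' @param seed base seed; chain \code{c} runs under \code{seed + c - 1}.
#' @return an \code{\linkS4class{McmcConfig}}.
#' @export
mcmcConfig <- function(nSample = 2000L, nBurn = 2000L, nChains = 1L,
                       qWindow = 10L, stepBeta = 0.05, stepPhi = 0.2,
                       betaPriorVar = 1000^2, tau2Shape = 1,
                       tau2Rate = 0.01, seed = 1L) {
  new("McmcConfig", nSample = as.integer(nSample), nBurn = as.integer(nBurn),
      nChains = as.integer(nChains), qWindow = as.integer(qWindow),
      stepBeta = as.numeric(stepBeta), stepPhi = as.numeric(stepPhi),
      betaPriorVar = as.numeric(betaPriorVar),
      tau2Shape = as.numeric(tau2Shape), tau2Rate = as.numeric(tau2Rate),
      seed = as.integer(seed))
}

.removalRank <- function(path) {
  ne <- length(path@removalOrder)
  rank <- integer(ne)
  rank[path@removalOrder] <- seq_len(ne)
  rank
}

.bindChains <- function(chains, model, cfg, hasTheta = FALSE) {
  nd <- sum(vapply(chains, function(ch) nrow(ch$beta), integer(1)))
  beta <- do.call(rbind, lapply(chains, `[[`, "beta"))
  phi <- do.call(rbind, lapply(chains, `[[`, "phi"))
  chain <- rep(seq_along(chains),
               vapply(chains, function(ch) nrow(ch$beta), integer(1)))
  new("PosteriorSamples",
      model = model, beta = beta, phi = phi,
      phiStar = if (!is.null(chains[[1L]]$phiStar))
        unlist(lapply(chains, `[[`, "phiStar")) else numeric(0),
      tau2 = unlist(lapply(chains, `[[`, "tau2")),
      pathIndex = if (!is.null(chains[[1L]]$pathIndex))
        as.integer(unlist(lapply(chains, `[[`, "pathIndex"))) else integer(0),
      theta = if (hasTheta) do.call(rbind, lapply(chains, `[[`, "theta"))
        else matrix(0, nd, 0L),
      sigma2 = if (hasTheta) unlist(lapply(chains, `[[`, "sigma2"))
        else numeric(0),
      chain = as.integer(chain),
      acceptance = lapply(chains, function(ch)
        ch[intersect(c("accBeta", "accPhi", "accPath", "accTheta"),
                     names(ch))]),
      config = cfg)
}

#' Fit the localized CAR hierarchical model by MCMC
#'
#' Metropolis-within-Gibbs sampling for the full hierarchical model:
#' \eqn{Y_k \sim \mathrm{Poisson}(E_k e^{x_k^\top\beta + \phi_k})} with the
#' localized CAR prior
#' \eqn{\tilde\phi \sim N(0, \tau^2 (Q(\tilde W^{(j)}) + \epsilon I)^{-1})},
#' a discrete uniform prior on the path index \eqn{j}, a diffuse Gaussian
#' prior on \eqn{\beta} and an inverse-gamma prior on \eqn{\tau^2}.
#' Coefficients and area effects use adaptive single-site random walks, the
#' global effect and \eqn{\tau^2} are Gibbs steps, and the path index uses a
#' windowed discrete proposal with Hastings correction at the boundaries
#' (cached log-determinants make this cheap).
#'
#' The candidate path must be elicited from data disjoint in time from
#' \code{data} (historical periods); that separation is the model's guard
#' against using the study data twice.
#'
#' @param data a \code{\linkS4class{CountData}}.
#' @param path a \code{\linkS4class{CandidatePath}} from
#'   \code{\link{elicitPath}}.
#' @param spec a \code{\linkS4class{PrecisionSpec}}; defaults to the
#'   epsilon the path was built with.
#' @param config an \code{\linkS4class{McmcConfig}}.
#' @param pathInit starting path index (default: the middle state).
#' @return a \code{\linkS4class{PosteriorSamples}}.
#' @export
lcarFit <- function(data, path, spec = NULL, config = mcmcConfig(),
                    pathInit = NULL) {
  stopifnot(is(data, "CountData"), is(path, "CandidatePath"),
            is(config, "McmcConfig"))
  if (nAreas(data) != path@graph@n)
    stop("data and path disagree on the number of areas", call. = FALSE)
  if (is.null(spec)) spec <- precisionSpec(epsilon = path@epsilon)
  if (abs(spec@epsilon - path@epsilon) > 1e-12)
    warning("epsilon differs from the value the path logdets were cached ",
            "with; using the path's value")
  ne <- length(path@removalOrder)
  jinit <- if (is.null(pathInit)) ne %/% 2L else as.integer(pathInit)
  rank <- .removalRank(path)
  chains <- lapply(seq_len(config@nChains), function(ch) {
    set.seed(config@seed + ch - 1L)
    cpp_lcar_mcmc(data@Y, data@E, data@X, path@graph@edges - 1L, rank,
                  path@logdets, path@epsilon, config@qWindow,
                  config@nBurn, config@nSample, config@betaPriorVar,
                  config@tau2Shape, config@tau2Rate, config@stepBeta,
                  config@stepPhi, jinit)
  })
  out <- .bindChains(chains, "lcar", config)
  if (any(!is.finite(out@beta)) || any(!is.finite(out@phi)))
    stop("non-finite draws produced; check the inputs", call. = FALSE)
  colnames(out@beta) <- colnames(data@X)
  out
}

#' Fit the BYM convolution model by MCMC
#'
#' Baseline model with linear predictor
#' \eqn{x_k^\top\beta + \psi_k + \theta_k}: \eqn{\psi} follows an intrinsic
#' CAR prior (sum-to-zero constrained per connected component) and
#' \eqn{\theta} is iid Gaussian. Same MCMC skeleton and priors as
#' \code{\link{lcarFit}}.
#'
#' @param data a \code{\linkS4class{CountData}}.
#' @param graph the \code{\linkS4class{AreaGraph}}.
#' @param config an \code{\linkS4class{McmcConfig}}.
#' @return a \code{\linkS4class{PosteriorSamples}} with \code{phi} holding
#'   the structured component and \code{theta} the unstructured one.
#' @export
bymFit <- function(data, graph, config = mcmcConfig()) {
  .carBaseline(data, graph, config, includeTheta = TRUE, model = "bym")
}

#' Fit the intrinsic CAR (IAR) model by MCMC
#'
#' \code{\link{bymFit}} without the unstructured component: linear predictor
#' \eqn{x_k^\top\beta + \psi_k} with an intrinsic CAR prior on \eqn{\psi}.
#'
#' @inheritParams bymFit
#' @return a \code{\linkS4class{PosteriorSamples}}.
#' @export
iarFit <- function(data, graph, config = mcmcConfig()) {
  .carBaseline(data, graph, config, includeTheta = FALSE, model = "iar")
}

.carBaseline <- function(data, graph, config, includeTheta, model) {
  stopifnot(is(data, "CountData"), is(graph, "AreaGraph"),
            is(config, "McmcConfig"))
  if (nAreas(data) != graph@n)
    stop("data and graph disagree on the number of areas", call. = FALSE)
  comp <- .components(graph)
  chains <- lapply(seq_len(config@nChains), function(ch) {
    set.seed(config@seed + ch - 1L)
    cpp_bym_mcmc(data@Y, data@E, data@X, graph@edges - 1L, comp,
                 includeTheta, config@nBurn, config@nSample,
                 config@betaPriorVar, config@tau2Shape, config@tau2Rate,
                 config@stepBeta, config@stepPhi)
  })
  out <- .bindChains(chains, model, config, hasTheta = includeTheta)
  colnames(out@beta) <- colnames(data@X)
  out
}

#' One Metropolis-Hastings update of the path index
#'
#' Proposes a new index uniformly from
#' \eqn{\{\max(0, j-q), \ldots, \min(N_E, j+q)\} \setminus \{j\}} and
#' accepts with the Gaussian prior density ratio of the current extended
#' random-effect vector under the two states (cached log-determinants,
#' sparse quadratic forms) times the Hastings correction for the unequal
#' window sizes near the path boundaries. This is the same compiled kernel
#' the sampler loop uses, exposed for direct study of the update.
#'
#' @param j current index in 0..\eqn{N_E}.
#' @param path a \code{\linkS4class{CandidatePath}}.
#' @param phi length-n area random effects.
#' @param phiStar scalar global effect.
#' @param tau2 current variance.
#' @param qWindow window half-width.
#' @return the new index (possibly \code{j}).
#' @export
updatePathIndex <- function(j, path, phi, phiStar, tau2, qWindow = 10L) {
  ne <- length(path@removalOrder)
  stopifnot(j >= 0L, j <= ne)
  if (ne == 0L) return(0L)
  cpp_update_path_index(as.integer(j), path@graph@edges - 1L,
                        .removalRank(path), path@logdets, path@graph@n,
                        path@epsilon, as.numeric(phi),
                        as.numeric(phiStar), as.numeric(tau2),
                        as.integer(qWindow))
}

## draws x n matrix of linear predictors x'beta + phi (+ theta)
.linpred <- function(samples, data) {
  lp <- samples@beta %*% t(data@X) + samples@phi
  if (ncol(samples@theta)) lp <- lp + samples@theta
  lp
}

#' Posterior relative-risk and fitted-risk summaries
#'
#' For each covariate, the posterior median and 95\% credible interval of
#' \eqn{\exp(\beta_i s_i)} — the relative risk for an increase of
#' \code{sdScale[i]} (by default one standard deviation of the covariate).
#' Also returns per-area summaries of the fitted risk
#' \eqn{R_k = \exp(x_k^\top\beta + \phi_k)}.
#'
#' @param samples a \code{\linkS4class{PosteriorSamples}}.
#' @param data the \code{\linkS4class{CountData}} the model was fitted to.
#' @param sdScale per-covariate increase at which to report the risk;
#'   defaults to the sample standard deviation of each covariate column.
#' @return list with \code{rr} (data.frame: covariate, median, lower, upper)
#'   and \code{fitted} (data.frame: area, median, lower, upper of
#'   \eqn{R_k}).
#' @export
riskSummaries <- function(samples, data, sdScale = NULL) {
  stopifnot(is(samples, "PosteriorSamples"), is(data, "CountData"))
  p <- ncol(data@X) - 1L
  rr <- NULL
  if (p > 0L) {
    if (is.null(sdScale))
      sdScale <- apply(data@X[, -1L, drop = FALSE], 2L, stats::sd)
    stopifnot(length(sdScale) == p)
    qs <- vapply(seq_len(p), function(i) {
      draws <- exp(samples@beta[, i + 1L] * sdScale[i])
      stats::quantile(draws, c(0.5, 0.025, 0.975), names = FALSE)
    }, numeric(3))
    rr <- data.frame(covariate = colnames(data@X)[-1L],
                     scale = sdScale,
                     rr = qs[1L, ], lower = qs[2L, ], upper = qs[3L, ],
                     row.names = NULL)
  }
  risk <- exp(.linpred(samples, data))
  fq <- apply(risk, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975),
              names = FALSE)
  list(rr = rr,
       fitted = data.frame(area = seq_len(nAreas(data)),
                           median = fq[1L, ], lower = fq[2L, ],
                           upper = fq[3L, ]))
}

setMethod("show", "PosteriorSamples", function(object) {
  cat("PosteriorSamples (", object@model, "): ", nrow(object@beta),
      " draws from ", object@config@nChains, " chain(s), ",
      ncol(object@phi), " areas\n", sep = "")
  bm <- colMeans(object@beta)
  cat("  beta posterior means:", paste(signif(bm, 4), collapse = " "), "\n")
  if (length(object@pathIndex))
    cat("  path index: median", stats::median(object@pathIndex), "of",
        "range", paste(range(object@pathIndex), collapse = "-"), "\n")
  ## combined level beta0 + mean(phi): the identifiable intercept quantity
  lvl <- object@beta[, 1L] + rowMeans(object@phi)
  cat("  combined level (beta0 + mean phi):", signif(mean(lvl), 4), "\n")
})
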