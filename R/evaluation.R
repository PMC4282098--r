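#' @include inference.R
NULL

#' RMSE of replicate estimates with a bootstrap interval
#'
#' Root mean square error \eqn{\sqrt{\mathrm{mean}((\hat\beta - \beta)^2)}}
#' of per-replicate point estimates around the truth, with a percentile
#' bootstrap interval over replicate resampling.
#'
#' @param estimates per-replicate point estimates.
#' @param truth true parameter value (scalar).
#' @param nBoot bootstrap resamples (default 1000).
#' @return list with \code{rmse}, \code{lower}, \code{upper}.
#' @export
rmseWithBootstrap <- function(estimates, truth, nBoot = 1000L) {
  stopifnot(length(estimates) >= 2L, length(truth) == 1L)
  sq <- (estimates - truth)^2
  bs <- vapply(seq_len(nBoot), function(b)
    sqrt(mean(sample(sq, replace = TRUE))), numeric(1))
  ci <- stats::quantile(bs, c(0.025, 0.975), names = FALSE)
  list(rmse = sqrt(mean(sq)), lower = ci[1L], upper = ci[2L])
}

#' Coverage and mean width of replicate credible intervals
#'
#' @param lower,upper per-replicate 95\% interval endpoints.
#' @param truth true parameter value.
#' @return list with \code{coverage} (percent of intervals containing the
#'   truth) and \code{width} (mean upper - lower).
#' @export
coverageWidth <- function(lower, upper, truth) {
  stopifnot(length(lower) == length(upper), all(upper >= lower))
  list(coverage = 100 * mean(lower <= truth & truth <= upper),
       width = mean(upper - lower))
}

#' Deviance information criterion of a Poisson model fit
#'
#' \eqn{\mathrm{DIC} = \bar D + p_D} with
#' \eqn{p_D = \bar D - D(\bar\eta)}: the posterior mean deviance minus the
#' deviance at the posterior mean linear predictor (the original plug-in
#' form). The deviance is \eqn{-2} times the Poisson log-likelihood.
#'
#' @param samples a \code{\linkS4class{PosteriorSamples}}.
#' @param data the \code{\linkS4class{CountData}} the model was fitted to.
#' @return list with \code{dic}, \code{pD} (effective parameters) and
#'   \code{dbar} (posterior mean deviance).
#' @export
dic <- function(samples, data) {
  stopifnot(is(samples, "PosteriorSamples"), is(data, "CountData"))
  lp <- .linpred(samples, data)
  dev <- function(eta)
    -2 * sum(stats::dpois(data@Y, data@E * exp(eta), log = TRUE))
  devs <- apply(lp, 1L, dev)
  dbar <- mean(devs)
  dhat <- dev(colMeans(lp))
  list(dic = dbar + (dbar - dhat), pD = dbar - dhat, dbar = dbar)
}

#' Moran's I permutation test for areal autocorrelation
#'
#' Moran's I with row-unnormalized binary adjacency weights,
#' \deqn{I = \frac{n}{S_0} \frac{\sum_{k \sim j} (x_k - \bar x)(x_j - \bar
#'   x)}{\sum_k (x_k - \bar x)^2},}
#' with a one-sided (positive autocorrelation) permutation p-value
#' \eqn{(1 + \#\{I_{perm} \ge I_{obs}\}) / (n_{perm} + 1)}.
#'
#' @param x length-n vector (typically model residuals).
#' @param graph an \code{\linkS4class{AreaGraph}}.
#' @param nPerm number of random permutations (default 10000).
#' @return list with \code{I} and \code{p}.
#' @export
moranPermutation <- function(x, graph, nPerm = 10000L) {
  stopifnot(is(graph, "AreaGraph"), length(x) == graph@n)
  if (stats::var(x) == 0)
    stop("Moran's I is undefined for constant input", call. = FALSE)
  n <- graph@n
  e <- graph@edges
  s0 <- 2 * nrow(e)
  stat <- function(v) {
    z <- v - mean(v)
    ## each undirected edge contributes twice to the double sum
    (n / s0) * 2 * sum(z[e[, 1L]] * z[e[, 2L]]) / sum(z^2)
  }
  obs <- stat(x)
  perm <- vapply(seq_len(nPerm), function(b) stat(sample(x)), numeric(1))
  list(I = obs, p = (1 + sum(perm >= obs)) / (nPerm + 1))
}

#' Standardized incidence ratio
#'
#' The elementwise ratio of observed to expected counts, the standard
#' exploratory estimate of area-level disease risk.
#'
#' @param data a \code{\linkS4class{CountData}}.
#' @return length-n numeric vector \code{Y/E}.
#' @export
sir <- function(data) {
  stopifnot(is(data, "CountData"))
  as.numeric(data@Y) / data@E
}

#' Quasi-Poisson overdispersion of the covariate-only model
#'
#' Dispersion estimate of the Poisson log-linear model with offset
#' \eqn{\log E} and the covariates only (no random effects): the sum of
#' squared Pearson residuals divided by the residual degrees of freedom.
#' Values well above 1 indicate extra-Poisson variation that random effects
#' should absorb.
#'
#' @param data a \code{\linkS4class{CountData}}.
#' @return scalar dispersion estimate.
#' @export
overdispersion <- function(data) {
  stopifnot(is(data, "CountData"))
  n <- nAreas(data)
  p1 <- ncol(data@X)
  if (n <= p1)
    stop("no residual degrees of freedom", call. = FALSE)
  fit <- stats::glm(data@Y ~ data@X - 1 + offset(log(data@E)),
                    family = stats::quasipoisson())
  sum(stats::residuals(fit, type = "pearson")^2) / (n - p1)
}

#' Posterior summary of the number of removed edges
#'
#' Pooled and per-chain distributions of the path index (the number of
#' edges removed from the neighborhood matrix), its posterior mode and the
#' central 95\% interval.
#'
#' @param samples a \code{\linkS4class{PosteriorSamples}} from an LCAR fit.
#' @return list with \code{density} (data.frame: removed, proportion),
#'   \code{perChain} (list of such data.frames), \code{mode},
#'   \code{lower}, \code{upper}.
#' @export
edgePosteriorSummary <- function(samples) {
  stopifnot(is(samples, "PosteriorSamples"))
  if (!length(samples@pathIndex))
    stop("no path-index draws; not an LCAR fit", call. = FALSE)
  tab <- function(ix) {
    t <- table(ix)
    data.frame(removed = as.integer(names(t)),
               proportion = as.numeric(t) / length(ix))
  }
  pooled <- tab(samples@pathIndex)
  ci <- stats::quantile(samples@pathIndex, c(0.025, 0.975), names = FALSE,
                        type = 1L)
  list(density = pooled,
       perChain = lapply(split(samples@pathIndex, samples@chain), tab),
       mode = pooled$removed[which.max(pooled$proportion)],
       lower = ci[1L], upper = ci[2L])
}

#' Split-chain potential scale reduction factor
#'
#' Gelman-Rubin R-hat computed on chains split in half, for a single scalar
#' parameter's draws.
#'
#' @param x draws (pooled over chains, in chain order).
#' @param chain integer chain label per draw.
#' @return scalar R-hat.
#' @export
gelmanRhat <- function(x, chain) {
  halves <- unlist(lapply(split(x, chain), function(v) {
    h <- length(v) %/% 2L
    list(v[seq_len(h)], v[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves)
  nn <- min(lengths(halves))
  halves <- lapply(halves, function(v) v[seq_len(nn)])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  B <- nn * stats::var(means)
  W <- mean(vars)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}
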