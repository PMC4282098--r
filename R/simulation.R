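#' @include inference.R
NULL

#' Define a simulation scenario
#'
#' @param M step-change magnitude multiplying the \{-1, 0, 1\} template
#'   (study values 0.5, 1, 1.5).
#' @param eRange length-2 interval for the expected counts; study values
#'   c(10, 25), c(50, 100), c(150, 200).
#' @param beta true covariate effect (0.1 in the study design).
#' @param maternNu Matern smoothness, 2.5.
#' @param rangeShort,rangeLong correlation ranges of the covariate's two
#'   component processes; \code{rangeLong} also drives the residual surface
#'   (the confounded direction). \code{NA} (default) sets them at generation
#'   time to 1/10 and 1/3 of the region diameter.
#' @param sigma2Resid residual-process variance (default 0.25^2).
#' @param sigma2Cov variance of the covariate's component processes before
#'   standardization (default 1; 0 gives a constant zero covariate).
#' @param rPrior number of historical years generated (default 3).
#' @param priorNoise half-width of the uniform perturbation added to the
#'   residual surface for each prior year (default 0.1).
#' @return a \code{\linkS4class{Scenario}}.
#' @export
scenario <- function(M = 1, eRange = c(50, 100), beta = 0.1,
                     maternNu = 2.5, rangeShort = NA_real_,
                     rangeLong = NA_real_, sigma2Resid = 0.25^2,
                     sigma2Cov = 1, rPrior = 3L, priorNoise = 0.1) {
  new("Scenario", M = as.numeric(M), eRange = as.numeric(eRange),
      beta = as.numeric(beta), maternNu = as.numeric(maternNu),
      rangeShort = as.numeric(rangeShort), rangeLong = as.numeric(rangeLong),
      sigma2Resid = as.numeric(sigma2Resid), sigma2Cov = as.numeric(sigma2Cov),
      rPrior = as.integer(rPrior), priorNoise = as.numeric(priorNoise))
}

setMethod("show", "Scenario", function(object) {
  cat("Scenario: M =", object@M, ", E in [",
      object@eRange[1L], ",", object@eRange[2L], "], beta =",
      object@beta, ",", object@rPrior, "prior year(s)\n")
})

#' The nine-scenario simulation grid
#'
#' Pairwise combinations of the step-change magnitude
#' \eqn{M \in \{0.5, 1, 1.5\}} and the expected-count range
#' \eqn{E_k \in [10,25], [50,100], [150,200]}, sharing all other defaults
#' (in particular \eqn{\beta = 0.1}).
#'
#' @param ... overrides passed to every \code{\link{scenario}} call.
#' @return a named list of 9 \code{\linkS4class{Scenario}} objects.
#' @export
scenarioGrid <- function(...) {
  Ms <- c(0.5, 1, 1.5)
  Es <- list(c(10, 25), c(50, 100), c(150, 200))
  out <- list()
  for (e in Es) for (m in Ms) {
    nm <- sprintf("M%g_E%g-%g", m, e[1L], e[2L])
    out[[nm]] <- scenario(M = m, eRange = e, ...)
  }
  out
}

#' Matern covariance matrix
#'
#' Matern covariance over point coordinates at smoothness
#' \eqn{\nu \in \{0.5, 1.5, 2.5\}} (closed forms). At \eqn{\nu = 2.5}:
#' \deqn{\sigma^2 (1 + \sqrt5 d/\rho + 5 d^2 / (3\rho^2))
#'   \exp(-\sqrt5 d/\rho).}
#'
#' @param coords n x 2 matrix of (distinct) centroid coordinates.
#' @param range correlation range \eqn{\rho > 0}.
#' @param nu smoothness (default 2.5).
#' @param sigma2 process variance (default 1).
#' @return symmetric positive semi-definite n x n matrix.
#' @export
maternCov <- function(coords, range, nu = 2.5, sigma2 = 1) {
  if (!is.numeric(range) || range <= 0)
    stop("'range' must be positive", call. = FALSE)
  coords <- as.matrix(coords)
  d <- as.matrix(stats::dist(coords))
  if (nu == 2.5) {
    a <- sqrt(5) * d / range
    C <- (1 + a + a^2 / 3) * exp(-a)
  } else if (nu == 1.5) {
    a <- sqrt(3) * d / range
    C <- (1 + a) * exp(-a)
  } else if (nu == 0.5) {
    C <- exp(-d / range)
  } else {
    stop("'nu' must be one of 0.5, 1.5, 2.5", call. = FALSE)
  }
  sigma2 * C
}

## one zero-mean GP draw given a covariance matrix (chol with jitter)
.gpDraw <- function(Sigma) {
  n <- nrow(Sigma)
  R <- chol(Sigma + diag(1e-10, n))
  as.numeric(t(R) %*% stats::rnorm(n))
}

.regionRanges <- function(scn, coords) {
  diam <- sqrt(sum((apply(coords, 2L, max) - apply(coords, 2L, min))^2))
  list(short = if (is.na(scn@rangeShort)) diam / 10 else scn@rangeShort,
       long = if (is.na(scn@rangeLong)) diam / 3 else scn@rangeLong)
}

#' Generate the spatially smooth covariate
#'
#' The pollution-like covariate: the average of two zero-mean Gaussian
#' process draws with Matern(\eqn{\nu = 2.5}) correlation, one at the short
#' range and one at the long range — the latter shared with the residual
#' surface, which makes the covariate partially confounded with it. The
#' result is standardized to zero mean and unit sample variance per draw.
#'
#' @param scn a \code{\linkS4class{Scenario}}.
#' @param coords n x 2 centroid coordinates.
#' @return length-n standardized covariate vector.
#' @export
genCovariate <- function(scn, coords) {
  if (scn@sigma2Cov == 0) return(rep(0, nrow(as.matrix(coords))))
  rg <- .regionRanges(scn, coords)
  x <- (.gpDraw(maternCov(coords, rg$short, scn@maternNu, scn@sigma2Cov)) +
        .gpDraw(maternCov(coords, rg$long, scn@maternNu, scn@sigma2Cov))) / 2
  as.numeric(scale(x))
}

#' Piecewise-constant template with three contiguous blocks
#'
#' Default localized-mean template: three contiguous blocks of roughly equal
#' size grown by breadth-first search from three mutually distant seed
#' areas, labelled -1, 0, 1. Deterministic given graph and coordinates.
#'
#' @param graph an \code{\linkS4class{AreaGraph}}.
#' @param coords n x 2 centroid coordinates.
#' @return integer vector of labels in \{-1, 0, 1\}.
#' @export
makeTemplate <- function(graph, coords) {
  n <- graph@n
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == n)
  e <- graph@edges
  nbr <- vector("list", n)
  for (r in seq_len(nrow(e))) {
    nbr[[e[r, 1L]]] <- c(nbr[[e[r, 1L]]], e[r, 2L])
    nbr[[e[r, 2L]]] <- c(nbr[[e[r, 2L]]], e[r, 1L])
  }
  d2 <- function(a, b) sum((coords[a, ] - coords[b, ])^2)
  s1 <- which.min(coords[, 1L] + coords[, 2L])
  s2 <- which.max(vapply(seq_len(n), d2, numeric(1), a = s1))
  s3 <- which.max(vapply(seq_len(n), function(k)
    min(d2(k, s1), d2(k, s2)), numeric(1)))
  seeds <- c(s1, s2, s3)
  block <- integer(n)
  block[seeds] <- 1:3
  frontier <- list(seeds[1L], seeds[2L], seeds[3L])
  repeat {
    grew <- FALSE
    for (b in 1:3) {
      newf <- integer(0)
      for (v in frontier[[b]]) {
        for (w in nbr[[v]]) if (block[w] == 0L) {
          block[w] <- b
          newf <- c(newf, w)
        }
      }
      frontier[[b]] <- newf
      if (length(newf)) grew <- TRUE
    }
    if (!grew) break
  }
  block[block == 0L] <- 2L  # isolated areas default to the middle level
  c(-1L, 0L, 1L)[block]
}

#' Generate one simulated dataset (study + prior periods)
#'
#' Draws the residual surface
#' \eqn{\phi \sim N(M \cdot \mathrm{template},\,
#' \mathrm{Matern}(\rho_{long}, \sigma^2_{resid}))}, a fresh standardized
#' covariate from \code{\link{genCovariate}}, expected counts
#' \eqn{E_k \sim U(eRange)}, study counts
#' \eqn{Y_k \sim \mathrm{Poisson}(E_k e^{x_k\beta + \phi_k})}, and
#' \code{rPrior} historical years
#' \eqn{Y_k^{(t)} \sim \mathrm{Poisson}(E_k e^{x_k\beta + \phi_k +
#' u_k^{(t)}})} with iid \eqn{u_k^{(t)} \sim U(-0.1, 0.1)} — the historical
#' residual surface mimics the study surface up to small perturbations.
#' Expected counts are shared between the study and prior periods (expected
#' counts change slowly between adjacent years).
#'
#' @param scn a \code{\linkS4class{Scenario}}.
#' @param graph an \code{\linkS4class{AreaGraph}}.
#' @param coords n x 2 centroid coordinates.
#' @param template optional per-area labels in \{-1, 0, 1\}; default
#'   \code{\link{makeTemplate}}.
#' @return a \code{\linkS4class{SimulatedDataset}}.
#' @export
genDataset <- function(scn, graph, coords, template = NULL) {
  stopifnot(is(scn, "Scenario"), is(graph, "AreaGraph"))
  n <- graph@n
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == n)
  if (is.null(template)) template <- makeTemplate(graph, coords)
  stopifnot(length(template) == n, all(template %in% c(-1, 0, 1)))

  rg <- .regionRanges(scn, coords)
  phi <- scn@M * template +
    if (scn@sigma2Resid > 0)
      .gpDraw(maternCov(coords, rg$long, scn@maternNu, scn@sigma2Resid))
    else rep(0, n)
  x <- genCovariate(scn, coords)
  E <- stats::runif(n, scn@eRange[1L], scn@eRange[2L])
  eta <- x * scn@beta + phi
  Y <- stats::rpois(n, E * exp(eta))
  u <- matrix(stats::runif(scn@rPrior * n, -scn@priorNoise, scn@priorNoise),
              nrow = scn@rPrior)
  Yh <- matrix(stats::rpois(scn@rPrior * n,
                            rep(E, each = scn@rPrior) *
                              exp(rep(eta, each = scn@rPrior) + as.numeric(u))),
               nrow = scn@rPrior)
  ## a degenerate (constant) covariate cannot enter the design matrix
  study <- countData(Y, E, if (stats::sd(x) > 0) matrix(x, ncol = 1L))
  new("SimulatedDataset",
      study = study,
      prior = priorCounts(Yh, matrix(rep(E, each = scn@rPrior),
                                     nrow = scn@rPrior), study@X),
      truth = list(beta = scn@beta, phiTrue = phi, covariate = x,
                   template = template, E = E, uPrior = u))
}
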