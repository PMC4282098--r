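test_that("RMSE and its bootstrap interval follow the definitions", {
  set.seed(71)
  expect_equal(rmseWithBootstrap(c(0.0, 0.2), 0.1, nBoot = 200)$rmse, 0.1)

  r0 <- rmseWithBootstrap(rep(0.3, 5), 0.3, nBoot = 100)
  expect_equal(r0$rmse, 0)
  expect_equal(c(r0$lower, r0$upper), c(0, 0))

  est <- rnorm(40, 0.1, 0.05)
  r <- rmseWithBootstrap(est, 0.1, nBoot = 500)
  expect_lte(r$lower, r$rmse)
  expect_gte(r$upper, r$rmse)
})

test_that("coverage and width are exact fractions of the replicates", {
  expect_equal(coverageWidth(c(-10, -10), c(10, 10), 0.1)$coverage, 100)
  expect_equal(coverageWidth(c(1, 1), c(2, 2), 0.1)$coverage, 0)
  cw <- coverageWidth(c(0, 1), c(1, 2), 0.5)
  expect_equal(cw$coverage, 50)
  expect_equal(cw$width, 1)
  expect_error(coverageWidth(c(0, 2), c(1, 1), 0.5), "upper >= lower")
})

test_that("DIC reduces to the plug-in deviance for a point-mass posterior
           and ignores constant covariates", {
  n <- 12L
  set.seed(72)
  dat <- countData(rpois(n, 30), rep(30, n))
  mk <- function(beta, phi, nd = 40L) new("PosteriorSamples",
    model = "iar", beta = matrix(beta, nd, length(beta), byrow = TRUE),
    phi = matrix(phi, nd, n, byrow = TRUE), phiStar = numeric(0),
    tau2 = rep(1, nd), pathIndex = integer(0), theta = matrix(0, nd, 0L),
    sigma2 = numeric(0), chain = rep(1L, nd), acceptance = list(),
    config = mcmcConfig())

  s <- mk(0.05, rep(0, n))
  d <- dic(s, dat)
  expect_equal(d$pD, 0)
  expect_equal(d$dic, -2 * sum(dpois(dat@Y, dat@E * exp(0.05), log = TRUE)))

  # same linear predictor through an extra zero-coefficient covariate
  dat2 <- countData(dat@Y, dat@E, matrix(rnorm(n), ncol = 1))
  s2 <- mk(c(0.05, 0), rep(0, n))
  expect_equal(dic(s2, dat2)$dic, d$dic)
})

test_that("Moran's I equals -1 on the 2x2 checkerboard and matches ape", {
  g <- latticeGraph(2, 2)
  x <- c(1, -1, -1, 1)
  set.seed(73)
  m <- moranPermutation(x, g, nPerm = 200)
  expect_equal(m$I, -1)

  # cross-check against ape on a degree-regular graph (ape row-normalizes
  # its weights; on a regular graph the two statistics coincide)
  set.seed(74)
  cyc <- areaGraph(cbind(1:16, c(2:16, 1)), n = 16)
  y <- rnorm(16)
  W <- matrix(0, 16, 16)
  e <- edges(cyc)
  for (r in seq_len(nrow(e)))
    W[e[r, 1L], e[r, 2L]] <- W[e[r, 2L], e[r, 1L]] <- 1
  m2 <- moranPermutation(y, cyc, nPerm = 100)
  expect_equal(m2$I, ape::Moran.I(y, W)$observed, tolerance = 1e-10)

  expect_error(moranPermutation(rep(1, 4), g), "constant")
})

test_that("the Moran permutation test is calibrated under the null and
           powered against smooth surfaces", {
  g <- latticeGraph(7, 7)
  set.seed(75)
  ps <- replicate(200, moranPermutation(rnorm(49), g, nPerm = 120)$p)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)

  coords <- latticeCoords(7, 7)
  set.seed(76)
  smoothp <- replicate(20, {
    x <- as.numeric(chol(maternCov(coords, 3) + diag(1e-8, 49)) %*%
                      rnorm(49))
    moranPermutation(x, g, nPerm = 200)$p
  })
  expect_lt(median(smoothp), 0.05)
})

test_that("the SIR is the elementwise observed/expected ratio", {
  d1 <- countData(c(10L, 40L, 0L), c(10, 20, 5))
  expect_equal(sir(d1), c(1, 2, 0))
})

test_that("overdispersion is near one for Poisson data and grows with
           added noise", {
  set.seed(77)
  n <- 200L
  x <- rnorm(n)
  E <- runif(n, 50, 100)
  disp <- replicate(20, {
    overdispersion(countData(rpois(n, E * exp(0.1 * x)), E,
                             matrix(x, ncol = 1)))
  })
  expect_lt(abs(mean(disp) - 1), 0.15)

  # multiplicative lognormal noise inflates the dispersion monotonically
  d1 <- overdispersion(countData(rpois(n, E * exp(0.1 * x + rnorm(n, 0, 0.2))),
                                 E, matrix(x, ncol = 1)))
  d2 <- overdispersion(countData(rpois(n, E * exp(0.1 * x + rnorm(n, 0, 0.5))),
                                 E, matrix(x, ncol = 1)))
  expect_gt(d1, 1.5)
  expect_gt(d2, d1)

  expect_error(overdispersion(countData(c(1L, 2L), c(1, 2),
                                        matrix(rnorm(2), ncol = 1))),
               "degrees of freedom")
})

test_that("edge posterior summaries report mode and central interval", {
  mk <- function(ix) new("PosteriorSamples", model = "lcar",
    beta = matrix(0, length(ix), 1L), phi = matrix(0, length(ix), 2L),
    phiStar = rep(0, length(ix)), tau2 = rep(1, length(ix)),
    pathIndex = as.integer(ix), theta = matrix(0, length(ix), 0L),
    sigma2 = numeric(0), chain = rep(1L, length(ix)),
    acceptance = list(), config = mcmcConfig())

  s <- mk(rep(231L, 50))
  ep <- edgePosteriorSummary(s)
  expect_equal(ep$mode, 231L)
  expect_equal(c(ep$lower, ep$upper), c(231, 231))

  s2 <- mk(rep(0:10, each = 100))
  ep2 <- edgePosteriorSummary(s2)
  expect_equal(c(ep2$lower, ep2$upper), c(0, 10))
})
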