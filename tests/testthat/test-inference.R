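# A tiny fitted problem reused by several blocks
.tinyFit <- function() {
  g <- latticeGraph(4, 4)
  set.seed(100)
  sim <- genDataset(scenario(M = 0.5, eRange = c(50, 100)), g,
                    latticeCoords(4, 4))
  p <- elicitPath(g, sim@prior)
  list(g = g, sim = sim, path = p)
}

test_that("variance Gibbs draws follow the inverse-gamma full conditional", {
  set.seed(51)
  quad <- 3.7; m <- 17L; shape <- 1; rate <- 0.01
  draws <- vapply(1:10000, function(i)
    localCAR:::cpp_draw_variance(quad, m, shape, rate), numeric(1))
  # X ~ IG(a, b)  <=>  1/X ~ Gamma(a, rate = b)
  ks <- suppressWarnings(
    ks.test(1 / draws, pgamma, shape = shape + m / 2, rate = rate + quad / 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("the path-index chain reproduces the exact two-state posterior", {
  g <- areaGraph(rbind(c(1, 2)), n = 2)
  pr <- priorCounts(c(12L, 30L), c(20, 20), matrix(1, 2, 1))
  p <- elicitPath(g, pr)
  phi <- c(0.4, -0.6); ps <- 0.1; tau2 <- 0.3
  masses <- exactPathMasses(p, phi, ps, tau2)

  set.seed(52)
  nit <- 20000L
  j <- 0L
  visits <- integer(2)
  for (it in seq_len(nit)) {
    j <- updatePathIndex(j, p, phi, ps, tau2, qWindow = 1L)
    visits[j + 1L] <- visits[j + 1L] + 1L
  }
  prop <- visits / nit
  # iid-equivalent 4-sigma band (chain correlation makes this conservative
  # only up to a factor; the band below allows for it)
  se <- sqrt(masses[1] * (1 - masses[1]) / nit)
  expect_lt(abs(prop[1] - masses[1]), max(6 * se, 0.02))
})

test_that("null data give a near-zero intercept with shrunken effects", {
  g <- latticeGraph(4, 4)
  n <- nAreas(g)
  E <- rep(100, n)
  dat <- countData(rep(100L, n), E)      # Y == E, intercept only
  pr <- priorCounts(rep(100L, n), E, dat@X)
  p <- elicitPath(g, pr)
  fit <- lcarFit(dat, p, config = mcmcConfig(nSample = 2000, nBurn = 2000,
                                             seed = 53))
  # the level splits weakly between beta0 and phi (the epsilon-proper prior
  # is nearly flat in the constant direction); the identifiable quantity is
  # their combination
  level <- fit@beta[, 1] + rowMeans(fit@phi)
  expect_lt(abs(mean(level)), 0.05)
  expect_lt(mean(apply(fit@phi - rowMeans(fit@phi), 2, sd)), 0.2)
  expect_true(all(fit@tau2 > 0))
  expect_true(all(fit@pathIndex >= 0 & fit@pathIndex <= edgeCount(g)))
})

test_that("the LCAR sampler recovers the generating covariate effect and
           mixes across chains", {
  g <- latticeGraph(12, 12)
  set.seed(54)
  sim <- genDataset(scenario(M = 1, eRange = c(50, 100)), g,
                    latticeCoords(12, 12))
  p <- elicitPath(g, sim@prior)
  fit <- lcarFit(sim@study, p,
                 config = mcmcConfig(nSample = 10000, nBurn = 10000,
                                     nChains = 3, seed = 55))
  est <- mean(fit@beta[, 2]); sdv <- sd(fit@beta[, 2])
  expect_lt(abs(est - 0.1), 3 * sdv)
  expect_lt(gelmanRhat(fit@beta[, 2], fit@chain), 1.05)
  expect_equal(nrow(fit@beta), 3L * 10000L)
})

test_that("the BYM sampler recovers the effect on globally smooth data and
           handles disconnected graphs", {
  g <- latticeGraph(8, 8)
  set.seed(56)
  # globally smooth residual surface: no template steps
  sim <- genDataset(scenario(M = 0, eRange = c(100, 150)), g,
                    latticeCoords(8, 8))
  fit <- bymFit(sim@study, g, mcmcConfig(nSample = 2000, nBurn = 2000,
                                         seed = 57))
  est <- mean(fit@beta[, 2]); sdv <- sd(fit@beta[, 2])
  expect_lt(abs(est - 0.1), 4 * sdv)
  expect_equal(ncol(fit@theta), nAreas(g))

  # two disconnected components: per-component centering keeps psi bounded
  g2 <- areaGraph(rbind(c(1, 2), c(2, 3), c(4, 5), c(5, 6)), n = 6)
  dat <- countData(rpois(6, 50), rep(50, 6))
  fit2 <- bymFit(dat, g2, mcmcConfig(nSample = 500, nBurn = 500, seed = 58))
  means <- colMeans(fit2@phi)
  expect_lt(abs(mean(means[1:3])), 0.05)
  expect_lt(abs(mean(means[4:6])), 0.05)
})

test_that("risk summaries transform coefficient draws deterministically", {
  tiny <- .tinyFit()
  dat <- tiny$sim@study
  nd <- 50L; n <- nAreas(dat)
  mk <- function(bdraws) new("PosteriorSamples", model = "iar",
    beta = bdraws, phi = matrix(0, nd, n), phiStar = numeric(0),
    tau2 = rep(1, nd), pathIndex = integer(0),
    theta = matrix(0, nd, 0L), sigma2 = numeric(0),
    chain = rep(1L, nd), acceptance = list(), config = mcmcConfig())

  s0 <- mk(cbind(rep(0, nd), rep(0, nd)))
  rs0 <- riskSummaries(s0, dat)
  expect_equal(rs0$rr$rr, 1)
  expect_equal(rs0$rr$lower, 1)
  expect_equal(rs0$rr$upper, 1)

  sdx <- sd(dat@X[, 2])
  s1 <- mk(cbind(rep(0, nd), rep(log(1.04) / sdx, nd)))
  expect_equal(riskSummaries(s1, dat)$rr$rr, 1.04)
})

test_that("an IAR fit is a BYM fit without the unstructured component", {
  tiny <- .tinyFit()
  fit <- iarFit(tiny$sim@study, tiny$g,
                mcmcConfig(nSample = 300, nBurn = 300, seed = 59))
  expect_equal(fit@model, "iar")
  expect_equal(ncol(fit@theta), 0L)
  expect_equal(length(fit@sigma2), 0L)
})

test_that("dimension mismatches and bad configs are rejected", {
  tiny <- .tinyFit()
  small <- countData(rpois(4, 10), rep(10, 4))
  expect_error(lcarFit(small, tiny$path), "disagree")
  expect_error(mcmcConfig(nSample = 0), "positive")
  expect_error(mcmcConfig(qWindow = 0), ">= 1")
})
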