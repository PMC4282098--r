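test_that("pooled residuals vanish for null data and pool identical years", {
  n <- 6L
  X <- matrix(1, n, 1L)
  E <- rep(20, n)
  pr <- priorCounts(E, E, X)  # Y == E exactly
  r0 <- pooledResiduals(pr, halfCorrection = FALSE)
  expect_equal(r0@z, rep(0, n))
  expect_equal(r0@zExt[n + 1L], 0)

  # two identical years equal one
  pr2 <- priorCounts(rbind(E, E), rbind(E, E), X)
  expect_equal(pooledResiduals(pr2, halfCorrection = FALSE)@z, r0@z)

  # OLS residuals have zero mean, so the appended global term is zero
  set.seed(5)
  Y <- rpois(n, E)
  r1 <- pooledResiduals(priorCounts(Y, E, X))
  expect_equal(r1@zExt[n + 1L], mean(r1@z))
  expect_equal(mean(r1@z), 0)
})

test_that("detrending recovers the covariate effect from large-count data", {
  # any single draw carries chance covariate/surface correlation of order
  # sd(phi) * cor(x, phi), so unbiasedness is checked on the average
  set.seed(21)
  g <- latticeGraph(15, 15)
  coords <- latticeCoords(15, 15)
  scn <- scenario(beta = 0.1, eRange = c(2000, 3000), M = 0.5)
  bhat <- replicate(25, {
    sim <- genDataset(scn, g, coords)
    pooledResiduals(sim@prior)@betaHat[2L]
  })
  expect_lt(abs(mean(bhat) - 0.1), 0.05)
})

test_that("the approximate Gaussian log-likelihood matches a dense
           multivariate-normal oracle up to the dropped constant", {
  set.seed(31)
  for (rep in 1:10) {
    g <- randomGraph(5)
    s <- randomState(g)
    spec <- precisionSpec(epsilon = 1e-3)
    m <- nAreas(g) + 1L
    z <- rnorm(m)
    got <- gaussianLogLik(z, s, spec)
    Q <- denseExtendedPrecision(s, spec@epsilon)
    quad <- as.numeric(z %*% Q %*% z)
    t2 <- quad / m
    dens <- -m / 2 * log(2 * pi) - 0.5 * determinant(t2 * solve(Q))$modulus -
      quad / (2 * t2)
    expect_equal(got, as.numeric(dens) + m / 2 * log(2 * pi),
                 tolerance = 1e-8)
  }
})

test_that("profiling: scaling the residuals by c shifts the objective by
           -(n+1) log c", {
  set.seed(32)
  g <- randomGraph(6)
  s <- randomState(g)
  z <- rnorm(nAreas(g) + 1L)
  for (cc in c(0.5, 2, 10)) {
    expect_equal(gaussianLogLik(cc * z, s, precisionSpec()),
                 gaussianLogLik(z, s, precisionSpec()) -
                   (nAreas(g) + 1L) * log(cc),
                 tolerance = 1e-8)
  }
})

test_that("a single-edge graph yields the two-state path", {
  g <- areaGraph(rbind(c(1, 2)), n = 2)
  pr <- priorCounts(c(5L, 9L), c(6, 6), matrix(1, 2, 1))
  p <- elicitPath(g, pr)
  expect_equal(pathLength(p), 2L)
  expect_equal(stateIndex(pathState(p, 0L)), 0L)
  expect_equal(stateIndex(pathState(p, 1L)), 1L)
})

test_that("greedy elicitation removes the step-change edge of a triangle
           first and matches exhaustive search", {
  g <- areaGraph(rbind(c(1, 2), c(1, 3), c(2, 3)), n = 3)
  spec <- precisionSpec()
  # step change between area 3 and areas 1-2
  z <- c(-0.6, -0.55, 0.9)
  zext <- c(z - mean(z), 0)
  rv <- new("ResidualVector", z = z - mean(z), zExt = zext,
            betaHat = mean(z))
  p <- elicitPath(g, rv, spec)
  expect_equal(pathLength(p), 4L)
  # exhaustive check of the first choice: best single removal by the dense
  # objective
  ll1 <- vapply(1:3, function(e)
    gaussianLogLik(zext, edgeState(g, e), spec), numeric(1))
  expect_equal(removalOrder(p)[1L], which.max(ll1))
  # the first removed edge crosses the step (it touches area 3)
  expect_true(3 %in% edges(g)[removalOrder(p)[1L], ])
  # greedy continuation matches exhaustive search at each depth
  rem <- removalOrder(p)[1L]
  for (d in 2:3) {
    cand <- setdiff(1:3, rem)
    ll <- vapply(cand, function(e)
      gaussianLogLik(zext, edgeState(g, sort(c(rem, e))), spec), numeric(1))
    expect_equal(removalOrder(p)[d], cand[which.max(ll)])
    rem <- c(rem, removalOrder(p)[d])
  }
})

test_that("the fast downdating path equals the dense reference
           implementation", {
  set.seed(41)
  for (g in list(randomGraph(5), latticeGraph(3, 3))) {
    n <- nAreas(g)
    pr <- priorCounts(rpois(n, 50), runif(n, 40, 60), matrix(1, n, 1L))
    pf <- elicitPath(g, pr, method = "downdate")
    pd <- elicitPath(g, pr, method = "dense")
    expect_identical(removalOrder(pf), removalOrder(pd))
    expect_equal(pathLogDets(pf), pathLogDets(pd), tolerance = 1e-8)
    expect_equal(pf@loglik, pd@loglik, tolerance = 1e-8)
  }
})

test_that("cached log-determinants match from-scratch factorizations", {
  set.seed(43)
  g <- latticeGraph(4, 4)
  n <- nAreas(g)
  pr <- priorCounts(rpois(n, 80), runif(n, 60, 90), matrix(1, n, 1L))
  p <- elicitPath(g, pr)
  expect_equal(pathLength(p), edgeCount(g) + 1L)
  for (j in c(0L, 1L, 7L, edgeCount(g))) {
    Q <- denseExtendedPrecision(pathState(p, j), p@epsilon)
    expect_equal(pathLogDets(p)[j + 1L],
                 as.numeric(determinant(Q)$modulus), tolerance = 1e-8)
  }
})

test_that("an edgeless graph elicits the degenerate one-state path with a
           warning", {
  g <- areaGraph(matrix(integer(0), ncol = 2), n = 3)
  pr <- priorCounts(c(4L, 5L, 6L), rep(5, 3), matrix(1, 3, 1))
  expect_warning(p <- elicitPath(g, pr), "no edges")
  expect_equal(pathLength(p), 1L)
})
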