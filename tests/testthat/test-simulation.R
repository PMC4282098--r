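test_that("the Matern(2.5) covariance matches the general Bessel form", {
  set.seed(61)
  coords <- matrix(runif(8), 4, 2)
  rho <- 0.7; s2 <- 1.9; nu <- 2.5
  C <- maternCov(coords, range = rho, sigma2 = s2)
  # independent oracle: Matern in its Bessel-function form at general nu
  d <- as.matrix(dist(coords))
  a <- sqrt(2 * nu) * d / rho
  Co <- s2 * 2^(1 - nu) / gamma(nu) * a^nu * besselK(a, nu)
  diag(Co) <- s2
  expect_equal(C, Co, tolerance = 1e-10, ignore_attr = TRUE)

  expect_equal(diag(C), rep(s2, 4), ignore_attr = TRUE)  # d = 0
  far <- maternCov(rbind(c(0, 0), c(1e4, 0)), range = 1)
  expect_lt(far[1, 2], 1e-12)                            # d -> infinity
  expect_error(maternCov(coords, range = 0), "positive")
})

test_that("the generated covariate is standardized and spatially smooth", {
  g <- latticeGraph(10, 10)
  coords <- latticeCoords(10, 10)
  scn <- scenario()
  set.seed(62)
  x <- genCovariate(scn, coords)
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(var(x), 1, tolerance = 1e-12)
  # zero process variance gives the constant zero covariate
  expect_equal(genCovariate(scenario(sigma2Cov = 0), coords), rep(0, 100))
  # smoothness: average over draws, neighbors correlate strongly
  set.seed(63)
  e <- edges(g)
  cors <- replicate(50, {
    x <- genCovariate(scn, coords)
    cor(x[e[, 1L]], x[e[, 2L]])
  })
  expect_gt(mean(cors), 0.5)
})

test_that("the default template forms three contiguous blocks of the three
           levels", {
  g <- latticeGraph(9, 9)
  tpl <- makeTemplate(g, latticeCoords(9, 9))
  expect_setequal(unique(tpl), c(-1L, 0L, 1L))
  expect_true(all(table(tpl) >= 9))  # roughly equal blocks on 81 areas
  # contiguity: each label class induces a connected subgraph
  e <- edges(g)
  for (lab in c(-1L, 0L, 1L)) {
    idx <- which(tpl == lab)
    sub <- e[tpl[e[, 1L]] == lab & tpl[e[, 2L]] == lab, , drop = FALSE]
    relabel <- match(sub, idx)
    gg <- areaGraph(matrix(relabel, ncol = 2), n = length(idx))
    expect_equal(max(localCAR:::.components(gg)), 1L)
  }
})

test_that("generated datasets honor the scenario contract", {
  g <- latticeGraph(8, 8)
  coords <- latticeCoords(8, 8)
  scn <- scenario(M = 1, eRange = c(50, 100))

  set.seed(64)
  sim <- genDataset(scn, g, coords)
  n <- nAreas(g)
  expect_equal(length(sim@study@Y), n)
  expect_true(all(sim@study@E >= 50 & sim@study@E <= 100))
  expect_equal(nrow(sim@prior@Yhist), 3L)
  # prior-year residual surfaces sit within the noise band of the truth
  expect_true(all(abs(sim@truth$uPrior) <= 0.1))
  # prior years share the study-period expected counts
  expect_equal(sim@prior@Ehist[1L, ], sim@truth$E)

  # fixed seed reproduces bit-identically; new seed gives fresh surfaces
  set.seed(64); sim2 <- genDataset(scn, g, coords)
  expect_identical(sim@study@Y, sim2@study@Y)
  expect_identical(sim@truth$phiTrue, sim2@truth$phiTrue)
  set.seed(65); sim3 <- genDataset(scn, g, coords)
  expect_false(identical(sim@truth$phiTrue, sim3@truth$phiTrue))
  expect_false(identical(sim@truth$covariate, sim3@truth$covariate))
})

test_that("degenerate scenarios reduce to pure Poisson noise", {
  g <- latticeGraph(6, 6)
  set.seed(66)
  scn <- scenario(M = 0, sigma2Resid = 0, beta = 0, eRange = c(200, 200))
  sim <- genDataset(scn, g, latticeCoords(6, 6))
  expect_equal(sim@truth$phiTrue, rep(0, 36))
  # Y ~ Poisson(200): mean within 5 sigma
  expect_lt(abs(mean(sim@study@Y) - 200), 5 * sqrt(200 / 36))
})

test_that("the expected-count midpoint is recovered across replicates", {
  set.seed(67)
  g <- latticeGraph(4, 4); coords <- latticeCoords(4, 4)
  scn <- scenario(M = 0.5, eRange = c(10, 25))
  Es <- replicate(200, mean(genDataset(scn, g, coords)@truth$E))
  expect_lt(abs(mean(Es) - 17.5), 0.5)
})

test_that("the scenario grid spans the nine study cells", {
  grid <- scenarioGrid()
  expect_length(grid, 9L)
  Ms <- vapply(grid, function(s) s@M, numeric(1))
  expect_equal(sort(unique(Ms)), c(0.5, 1, 1.5))
  has <- any(vapply(grid, function(s)
    s@M == 1 && identical(s@eRange, c(50, 100)), logical(1)))
  expect_true(has)
  expect_true(all(vapply(grid, function(s) s@beta == 0.1, logical(1))))
  expect_true(all(vapply(grid, function(s) s@maternNu == 2.5, logical(1))))
})
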