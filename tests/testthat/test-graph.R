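test_that("graph construction canonicalizes edges and counts degrees", {
  g <- areaGraph(rbind(c(1, 2), c(3, 2)), n = 3)
  expect_equal(edgeCount(g), 2L)
  expect_equal(degrees(g), c(1L, 2L, 1L))
  expect_equal(edges(g), cbind(c(1L, 2L), c(2L, 3L)), ignore_attr = TRUE)

  # duplicates (in either orientation) collapse
  g2 <- areaGraph(rbind(c(1, 2), c(2, 1), c(1, 2)), n = 2)
  expect_equal(edgeCount(g2), 1L)

  expect_equal(edgeCount(latticeGraph(2, 2)), 4L)
  expect_equal(edgeCount(latticeGraph(12, 12)), 264L)

  expect_error(areaGraph(rbind(c(1, 4)), n = 3), "out of range")
  expect_error(areaGraph(rbind(c(2, 2)), n = 3), "self-loop")
})

test_that("edge states derive the global-link indicators of their removals", {
  g <- areaGraph(rbind(c(1, 2), c(2, 3), c(3, 4)), n = 4)

  s0 <- edgeState(g)
  expect_equal(wStar(s0), rep(0L, 4))
  expect_equal(stateIndex(s0), 0L)

  s1 <- edgeState(g, removed = rbind(c(2, 3)))
  expect_equal(wStar(s1), c(0L, 1L, 1L, 0L))
  expect_equal(stateIndex(s1), 1L)
  expect_equal(degrees(s1), c(1L, 1L, 1L, 1L))

  sAll <- edgeState(g, seq_len(edgeCount(g)))
  expect_equal(wStar(sAll), rep(1L, 4))
  expect_equal(nrow(retainedEdges(sAll)), 0L)

  expect_error(edgeState(g, removed = rbind(c(1, 3))), "not an edge")
})

test_that("assembled precision matches the hand-derived two-area matrices", {
  g <- areaGraph(rbind(c(1, 2)), n = 2)
  eps <- 0.01
  spec <- precisionSpec(epsilon = eps)

  Qr <- as.matrix(assemblePrecision(edgeState(g), spec))
  expect_equal(Qr,
               matrix(c(1 + eps, -1, 0, -1, 1 + eps, 0, 0, 0, eps), 3, 3),
               ignore_attr = TRUE)

  Qd <- as.matrix(assemblePrecision(edgeState(g, 1L), spec))
  expect_equal(Qd,
               matrix(c(1 + eps, 0, -1, 0, 1 + eps, -1, -1, -1, 2 + eps),
                      3, 3),
               ignore_attr = TRUE)
})

test_that("assembled precision is SPD and matches the dense definition", {
  set.seed(42)
  for (rep in 1:10) {
    g <- randomGraph(sample(3:8, 1))
    s <- randomState(g)
    spec <- precisionSpec(epsilon = 1e-4)
    Q <- as.matrix(assemblePrecision(s, spec))
    expect_equal(Q, denseExtendedPrecision(s, 1e-4), ignore_attr = TRUE)
    expect_true(isSymmetric(Q))
    ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), 1e-4 - 1e-12)
  }
})

test_that("removing one edge perturbs only the incident rows and columns", {
  set.seed(7)
  g <- randomGraph(6)
  spec <- precisionSpec()
  s0 <- edgeState(g)
  e1 <- edges(g)[1L, ]
  s1 <- edgeState(g, 1L)
  D <- as.matrix(assemblePrecision(s1, spec)) -
    as.matrix(assemblePrecision(s0, spec))
  touched <- sort(unique(which(D != 0, arr.ind = TRUE)[, 1L]))
  expect_true(all(touched %in% c(e1, nAreas(g) + 1L)))
})

test_that("full conditionals agree with dense GMRF conditionals", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    g <- randomGraph(n)
    s <- randomState(g)
    spec <- precisionSpec(epsilon = 1e-4, tau2 = runif(1, 0.2, 3))
    Q <- denseExtendedPrecision(s, spec@epsilon)
    phi <- rnorm(n); ps <- rnorm(1)
    x <- c(phi, ps)
    for (k in seq_len(n)) {
      got <- fullConditional(s, spec, phi, ps, k)
      want <- gmrfConditionalOracle(Q, spec@tau2, x, k)
      expect_equal(got$mean, want$mean, tolerance = 1e-10)
      expect_equal(got$variance, want$variance, tolerance = 1e-10)
    }
    got <- fullConditional(s, spec, phi, ps, "global")
    want <- gmrfConditionalOracle(Q, spec@tau2, x, n + 1L)
    expect_equal(got$mean, want$mean, tolerance = 1e-10)
    expect_equal(got$variance, want$variance, tolerance = 1e-10)
  }
})

test_that("partial correlation is zero off-graph and 1/(d+eps) for
           symmetric-degree neighbors", {
  # areas 1 and 2 adjacent, each with exactly 3 retained edges
  g <- areaGraph(rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 5), c(2, 6)), n = 6)
  spec <- precisionSpec(epsilon = 1e-4)
  s <- edgeState(g)
  expect_equal(partialCorrelation(s, spec, 1, 2), 1 / (3 + 1e-4))
  expect_equal(partialCorrelation(s, spec, 3, 4), 0)   # not adjacent
  # removing the edge zeroes the partial correlation
  s2 <- edgeState(g, removed = rbind(c(1, 2)))
  expect_equal(partialCorrelation(s2, spec, 1, 2), 0)
})

test_that("with nothing removed the area block is the IAR precision and the
           global node is isolated", {
  set.seed(3)
  g <- randomGraph(7)
  n <- nAreas(g)
  eps <- 1e-4
  Q <- as.matrix(assemblePrecision(edgeState(g), precisionSpec(eps)))
  # IAR block: diag(W1) - W + eps I
  W <- matrix(0, n, n)
  e <- edges(g)
  for (r in seq_len(nrow(e)))
    W[e[r, 1L], e[r, 2L]] <- W[e[r, 2L], e[r, 1L]] <- 1
  expect_equal(Q[1:n, 1:n], diag(rowSums(W)) - W + diag(eps, n),
               ignore_attr = TRUE)
  expect_equal(Q[n + 1L, ], c(rep(0, n), eps), ignore_attr = TRUE)
})

test_that("edge-list and adjacency-matrix files round-trip through the
           reader", {
  g <- latticeGraph(3, 3)
  f <- tempfile(fileext = ".txt")
  writeLines(paste(edges(g)[, 1L], edges(g)[, 2L]), f)
  g2 <- readEdgeList(f, n = 9)
  expect_equal(edges(g2), edges(g))

  # adjacency CSV
  A <- matrix(0L, 9, 9)
  for (r in seq_len(edgeCount(g)))
    A[edges(g)[r, 1L], edges(g)[r, 2L]] <-
      A[edges(g)[r, 2L], edges(g)[r, 1L]] <- 1L
  fc <- tempfile(fileext = ".csv")
  write.table(A, fc, sep = ",", row.names = FALSE, col.names = FALSE)
  g3 <- readEdgeList(fc)
  expect_equal(edges(g3), edges(g))
})
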