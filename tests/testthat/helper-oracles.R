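# Independent dense-matrix oracles used across the suite. These build the
# extended neighborhood matrix directly from its definition and use base
# dense linear algebra only, so they share no code path with the package's
# sparse/compiled implementations.

# random connected-ish graph on n nodes: spanning tree plus random extras
randomGraph <- function(n, extra = n %/% 2) {
  pairs <- cbind(2:n, vapply(2:n, function(k) sample.int(k - 1L, 1L),
                             integer(1)))
  if (extra > 0) {
    all <- t(combn(n, 2))
    more <- all[sample.int(nrow(all), min(extra, nrow(all))), , drop = FALSE]
    pairs <- rbind(pairs, more)
  }
  areaGraph(pairs, n)
}

# dense (n+1) x (n+1) extended precision built from first principles
denseExtendedPrecision <- function(state, epsilon) {
  g <- state@graph
  n <- nAreas(g)
  Wt <- matrix(0, n + 1L, n + 1L)
  ret <- retainedEdges(state)
  for (r in seq_len(nrow(ret)))
    Wt[ret[r, 1L], ret[r, 2L]] <- Wt[ret[r, 2L], ret[r, 1L]] <- 1
  rem <- removedEdges(state)
  for (r in seq_len(nrow(rem))) {
    Wt[rem[r, 1L], n + 1L] <- Wt[n + 1L, rem[r, 1L]] <- 1
    Wt[rem[r, 2L], n + 1L] <- Wt[n + 1L, rem[r, 2L]] <- 1
  }
  diag(rowSums(Wt)) - Wt + diag(epsilon, n + 1L)
}

# conditional mean/variance of component k of N(0, tau2 * Q^{-1}) given the
# rest, from the precision-row identity
gmrfConditionalOracle <- function(Q, tau2, x, k) {
  prec <- Q[k, k]
  list(mean = -sum(Q[k, -k] * x[-k]) / prec, variance = tau2 / prec)
}

# random removal state of a graph
randomState <- function(g, prob = 0.5) {
  ne <- edgeCount(g)
  edgeState(g, which(runif(ne) < prob))
}

# exact normalized posterior masses of the path index given fixed effects:
# pi_j propto exp(0.5 logdet_j - quad_j / (2 tau2)) over j = 0..NE
exactPathMasses <- function(path, phi, phiStar, tau2) {
  ne <- length(removalOrder(path))
  lp <- vapply(0:ne, function(j) {
    Q <- denseExtendedPrecision(pathState(path, j), path@epsilon)
    zt <- c(phi, phiStar)
    0.5 * path@logdets[j + 1L] - as.numeric(zt %*% Q %*% zt) / (2 * tau2)
  }, numeric(1))
  w <- exp(lp - max(lp))
  w / sum(w)
}
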