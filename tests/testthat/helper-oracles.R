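# Independent oracles used to validate the package's own algorithms.
# These are deliberately written against the definitions, not against the
# package's internal code paths.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Site likelihood by exhaustive summation over all internal-node state
# assignments (20^Nnode terms); feasible for trees with <= 3 internal nodes.
bruteForceLoglik <- function(phy, column, model, r) {
  nTip <- length(phy$tip.label)
  nNode <- phy$Nnode
  states <- match(toupper(column[phy$tip.label]), AA20)
  Pm <- lapply(seq_len(nrow(phy$edge)), function(e)
    transitionMatrix(model, r * phy$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(1:20), nNode)))
  freqs <- stationaryFrequencies(model)
  root <- nTip + 1L
  prob <- freqs[grid[, root - nTip]]
  for (e in seq_len(nrow(phy$edge))) {
    pa <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    paS <- grid[, pa - nTip]
    chS <- if (ch <= nTip) rep(states[ch], nrow(grid)) else grid[, ch - nTip]
    prob <- prob * Pm[[e]][cbind(paS, chS)]
  }
  log(sum(prob))
}

# ML rate by a dense uniform grid over the optimisation interval.
denseGridRate <- function(column, phylogeny, model, nGrid = 10000) {
  grid <- seq(1e-6, 20, length.out = nGrid)
  ll <- siteLogLikelihood(column, phylogeny, model, grid)
  grid[which.max(ll)]
}

# Conover-Iman all-pairs test, coded independently from the published
# formulation: pooled midranks, S^2 as the variance of the ranks, t
# statistics referred to N - k degrees of freedom, Bonferroni over pairs.
conoverOracle <- function(groups) {
  k <- length(groups)
  pooled <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_len(k), vapply(groups, length, integer(1))))
  r <- rank(pooled)
  N <- length(pooled)
  H <- unname(stats::kruskal.test(pooled, g)$statistic)
  S2 <- stats::var(r)                    # equals (sum r^2 - N(N+1)^2/4)/(N-1)
  Rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  prs <- t(utils::combn(k, 2))
  res <- apply(prs, 1, function(ij) {
    i <- ij[1]; j <- ij[2]
    tt <- (Rbar[i] - Rbar[j]) /
      sqrt(S2 * ((N - 1 - H) / (N - k)) * (1 / n[i] + 1 / n[j]))
    2 * stats::pt(-abs(tt), N - k)
  })
  pmin(1, res * nrow(prs))
}

# Hypergeometric upper tail by direct log-binomial summation.
hyperTail <- function(k, K, N, n) {
  xs <- k:min(K, n)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}
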