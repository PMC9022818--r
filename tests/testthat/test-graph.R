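test_that("binarization rules apply thresholds as specified", {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.6
  m[1, 3] <- m[3, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- -0.7
  edges <- function(net) sum(adjacency(net)) / 2
  expect_equal(edges(binarizeFC(m, 0.5, "absolute")), 1)
  expect_equal(edges(binarizeFC(m, 0.5, "absolute", useAbs = TRUE)), 2)
  cost1 <- binarizeFC(m, 1 / 3, "cost")
  expect_equal(edges(cost1), 1)
  expect_equal(adjacency(cost1)[1, 2], 1)
  ## proportional: threshold relative to max off-diagonal
  expect_equal(edges(binarizeFC(m, 0.5, "proportional")), 1)
  ## with useAbs the max is 0.7; only that edge beats 0.9 * 0.7
  prop <- binarizeFC(m, 0.9, "proportional", useAbs = TRUE)
  expect_equal(edges(prop), 1)
  expect_equal(adjacency(prop)[2, 3], 1)
  ## missing coefficients are never kept, even at threshold -1
  m[1, 2] <- m[2, 1] <- NA
  lo <- binarizeFC(m, -1, "absolute")
  expect_equal(edges(lo), 2)            # 0.2 and -0.7 both exceed -1
  expect_equal(adjacency(lo)[1, 2], 0)  # the missing pair stays absent
  expect_warning(binarizeFC(m, 1, "cost"), "capped")
})

test_that("shortest paths agree with Floyd-Warshall relaxation", {
  expect_equal(unname(shortestPathLengths(fixtureK4())),
               matrix(1, 4, 4) - diag(4))
  p3 <- matrix(0, 3, 3); p3[1, 2] <- p3[2, 3] <- 1; p3 <- p3 + t(p3)
  expect_equal(shortestPathLengths(p3)[1, 3], 2)
  set.seed(41)
  for (i in 1:3) {
    a <- randomGraph(50, sample(40:120, 1))
    expect_equal(shortestPathLengths(a), oracleDistances(a))
  }
})

test_that("efficiency and path length match closed forms", {
  star <- fixtureStar()
  p3 <- matrix(0, 3, 3); p3[1, 2] <- p3[2, 3] <- 1; p3 <- p3 + t(p3)
  expect_equal(globalEfficiency(fixtureK4()), 1)
  expect_equal(globalEfficiency(p3), 5 / 6)
  expect_equal(globalEfficiency(star), 0.75)
  expect_equal(networkLocalEfficiency(fixtureK4()), 1)
  expect_equal(networkLocalEfficiency(star), 0)
  tri <- matrix(0, 3, 3); tri[upper.tri(tri)] <- 1; tri <- tri + t(tri)
  expect_equal(networkLocalEfficiency(tri), 1)
  expect_equal(characteristicPathLength(fixtureK4()), 1)
  expect_equal(characteristicPathLength(star), 1.5)
  ## two disjoint edges: reachable ordered pairs only
  de <- matrix(0, 4, 4); de[1, 2] <- de[3, 4] <- 1; de <- de + t(de)
  expect_equal(characteristicPathLength(de), 1)
  expect_error(characteristicPathLength(matrix(0, 3, 3)), "no reachable")
})

test_that("clustering and transitivity count triangles correctly", {
  tri <- matrix(0, 3, 3); tri[upper.tri(tri)] <- 1; tri <- tri + t(tri)
  cl <- clusteringCoefficients(tri)
  expect_equal(cl$nodal, rep(1, 3))
  expect_equal(cl$network, 1)
  expect_equal(clusteringCoefficients(fixtureStar())$network, 0)
  expect_equal(transitivityCoefficient(fixtureK4()), 1)
  expect_warning(t0 <- transitivityCoefficient(matrix(0, 3, 3)), "triple")
  expect_equal(t0, 0)
  ## triangle plus a pendant edge: 3 triangles-in-triples / 5 triples
  p <- matrix(0, 4, 4); p[1, 2] <- p[2, 3] <- p[1, 3] <- p[3, 4] <- 1
  p <- p + t(p)
  expect_equal(transitivityCoefficient(p), 0.6)
  expect_equal(suppressWarnings(transitivityCoefficient(fixtureStar())), 0)
})

test_that("mean nodal clustering equals the network coefficient", {
  set.seed(42)
  for (i in 1:5) {
    a <- randomGraph(sample(5:20, 1))
    cl <- clusteringCoefficients(a)
    expect_equal(mean(cl$nodal), cl$network, tolerance = 1e-14)
  }
})

test_that("assortativity is the endpoint-degree correlation", {
  expect_equal(assortativityCoefficient(fixtureStar()), -1)
  ring <- fixtureRing(8, 2)
  expect_true(is.nan(assortativityCoefficient(ring)))   # all degrees equal
  set.seed(43)
  a <- randomGraph(40, 100)
  expect_equal(assortativityCoefficient(a), oracleAssortativity(a),
               tolerance = 1e-12)
})

test_that("nodal metrics match star and triangle closed forms", {
  nm <- nodalMetrics(fixtureStar())
  expect_equal(nm$nodalEfficiency, c(1, 2 / 3, 2 / 3, 2 / 3))
  expect_equal(nm$betweenness, c(1, 0, 0, 0))
  expect_equal(nm$degree, c(3, 1, 1, 1))
  tri <- matrix(0, 3, 3); tri[upper.tri(tri)] <- 1; tri <- tri + t(tri)
  nmt <- nodalMetrics(tri)
  expect_equal(nmt$clustering, rep(1, 3))
  expect_equal(nmt$betweenness, rep(0, 3))
})

test_that("betweenness equals exhaustive path enumeration", {
  set.seed(44)
  for (i in 1:5) {
    a <- randomGraph(sample(5:8, 1))
    expect_equal(nodalMetrics(a)$betweenness, oracleBetweenness(a),
                 tolerance = 1e-12)
  }
})

test_that("graph metrics cross-check against igraph on larger graphs", {
  skip_if_not_installed("igraph")
  set.seed(45)
  a <- randomGraph(40, 140)
  ig <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  n <- nrow(a)
  expect_equal(unname(shortestPathLengths(a)),
               unname(igraph::distances(ig)))
  expect_equal(transitivityCoefficient(a),
               igraph::transitivity(ig, type = "global"), tolerance = 1e-12)
  expect_equal(assortativityCoefficient(a),
               igraph::assortativity_degree(ig), tolerance = 1e-12)
  expect_equal(nodalMetrics(a)$betweenness * (n - 1) * (n - 2) / 2,
               unname(igraph::betweenness(ig)), tolerance = 1e-9)
  expect_equal(clusteringCoefficients(a)$nodal,
               ifelse(is.nan(igraph::transitivity(ig, type = "local")), 0,
                      igraph::transitivity(ig, type = "local")),
               tolerance = 1e-12)
})

test_that("modularity finds planted structure and respects bounds", {
  two <- fixtureTwoTriangles()
  res <- modularityCoefficient(two)          # exact for n = 6
  expect_equal(res$Q, 0.5)
  expect_equal(length(unique(res$membership)), 2)
  expect_equal(modularityCoefficient(fixtureK4())$Q, 0)
  g <- modularityCoefficient(two, method = "greedy")
  expect_equal(g$Q, 0.5)                     # greedy recovers it here
  expect_error(modularityCoefficient(matrix(0, 3, 3)), "empty")
  set.seed(46)
  for (i in 1:5) {
    a <- randomGraph(sample(5:7, 1))
    if (sum(a) == 0) next
    ex <- modularityCoefficient(a, method = "exact")$Q
    expect_equal(ex, oracleModularity(a), tolerance = 1e-12)
    gr <- modularityCoefficient(a, method = "greedy")$Q
    expect_gte(gr, 0)
    expect_lte(gr, ex + 1e-12)
  }
})

test_that("random ensembles preserve (n, m) and are seed-deterministic", {
  ensK4 <- randomEnsemble(fixtureK4(), size = 5, seed = 9)
  expect_equal(ensK4$Crand, 1)   # m = 6 on 4 nodes forces K4
  expect_equal(ensK4$Lrand, 1)
  e1 <- randomEnsemble(fixtureRing(12, 4), size = 10, seed = 3)
  e2 <- randomEnsemble(fixtureRing(12, 4), size = 10, seed = 3)
  expect_identical(e1$C, e2$C)
  expect_identical(e1$L, e2$L)
  e3 <- randomEnsemble(fixtureRing(12, 4), size = 10, seed = 4)
  expect_false(identical(e1$C, e3$C))
  ## G(n, m) mean clustering approaches the density 2m/(n(n-1))
  big <- randomEnsemble(matrix(0, 100, 100) + randomGraph(100, 300),
                        size = 20, seed = 1)
  dens <- 2 * 300 / (100 * 99)
  se <- sd(big$C) / sqrt(20)
  expect_lt(abs(big$Crand - dens), 3 * se + 1e-3)
  ## rewiring preserves the degree sequence
  a <- randomGraph(20, 50)
  er <- randomEnsemble(a, size = 3, seed = 2, method = "rewire")
  expect_equal(er$n, 20); expect_equal(er$m, 50)
})

test_that("ensemble RNG state does not leak into the session", {
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(randomEnsemble(fixtureRing(10, 4), size = 3,
                                          seed = 77)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("normalized metrics form the gamma/lambda/sigma ratios", {
  ring <- fixtureRing(20, 4)
  ens <- randomEnsemble(ring, size = 20, seed = 1)
  nm <- normalizedMetrics(ring, ens)
  expect_equal(nm$S, nm$Cnorm / nm$Lnorm, tolerance = 1e-14)
  expect_gt(nm$S, 1)          # lattice: high clustering, longer paths
  expect_gt(nm$Cnorm, nm$Lnorm)
  ## degenerate ensemble (too sparse for any triangle) errors out
  sparse <- matrix(0, 30, 30); sparse[1, 2] <- sparse[2, 1] <- 1
  ens0 <- randomEnsemble(sparse, size = 3, seed = 1)
  expect_error(normalizedMetrics(sparse, ens0), "degenerate")
})

test_that("density is monotone in the absolute threshold", {
  set.seed(47)
  m <- cor(matrix(rnorm(40 * 8), 40, 8))
  prev <- Inf
  for (th in seq(0, 0.9, by = 0.1)) {
    deg <- averageDegree(binarizeFC(m, th, "absolute"))
    expect_lte(deg, prev + 1e-12)
    prev <- deg
  }
})

test_that("metric trajectories cover the sweep and stay flat for static
           input", {
  set.seed(48)
  x <- matrix(rnorm(40 * 5), 40, 5)
  ts <- roiTimeSeries(rbind(x, x, x), tr = 1)
  fc <- slidingWindowFC(ts, windowSize = 40, stepSize = 40)  # 3 identical
  tab <- metricsOverSeries(fc, thresholds = seq(0.5, 0.85, by = 0.01),
                           metrics = c("Eglob", "C"))
  expect_equal(length(unique(tab$threshold)), 36)
  byMetric <- split(tab$value, list(tab$metric, tab$threshold))
  for (v in byMetric) expect_equal(var(v), 0)
  ## long format is complete
  expect_equal(nrow(tab), 3 * 36 * 2)
})

test_that("nodal trajectories are keyed by window, threshold and node", {
  set.seed(49)
  ts <- roiTimeSeries(matrix(rnorm(30 * 4), 30, 4), tr = 1)
  fc <- slidingWindowFC(ts, windowSize = 20, stepSize = 5)
  res <- metricsOverSeries(fc, thresholds = c(0.2, 0.5), nodal = TRUE)
  expect_named(res, c("global", "nodal"))
  expect_equal(sort(unique(res$nodal$node)), paste0("roi", 1:4))
  expect_equal(nrow(res$nodal), nWindows(fc) * 2 * 4 * 5)
})
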