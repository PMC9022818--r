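## Independent brute-force oracles for the graph metrics, deliberately
## written with different algorithms than the package (triple loops,
## explicit path enumeration, recursive partition search), plus small
## fixture builders.

randomGraph <- function(n, m = NULL) {
  pairs <- which(upper.tri(matrix(0, n, n)))
  if (is.null(m))
    m <- sample(seq_len(length(pairs)), 1)
  a <- matrix(0, n, n)
  a[sample(pairs, m)] <- 1
  a + t(a)
}

fixtureK4 <- function() {
  a <- matrix(1, 4, 4); diag(a) <- 0; a
}

fixtureStar <- function(n = 4) {
  a <- matrix(0, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1
  a
}

fixtureRing <- function(n = 20, k = 4) {
  a <- matrix(0, n, n)
  for (i in seq_len(n)) for (d in seq_len(k / 2)) {
    j <- ((i - 1 + d) %% n) + 1
    a[i, j] <- a[j, i] <- 1
  }
  a
}

fixtureTwoTriangles <- function() {
  a <- matrix(0, 6, 6)
  a[1, 2] <- a[2, 3] <- a[1, 3] <- 1
  a[4, 5] <- a[5, 6] <- a[4, 6] <- 1
  a + t(a)
}

## Floyd-Warshall relaxation
oracleDistances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a > 0] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j])
          d[i, j] <- d[i, k] + d[k, j]
  d
}

oracleGlobalEfficiency <- function(a) {
  n <- nrow(a)
  d <- oracleDistances(a)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && is.finite(d[i, j])) s <- s + 1 / d[i, j]
  s / (n * (n - 1))
}

oracleLocalEfficiency <- function(a) {
  n <- nrow(a)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracleGlobalEfficiency(a[nb, nb, drop = FALSE])
  }, numeric(1)))
}

oracleClustering <- function(a) {
  n <- nrow(a)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (x in nb) for (y in nb)
      if (x < y && a[x, y] > 0) links <- links + 1
    ci[i] <- 2 * links / (k * (k - 1))
  }
  list(nodal = ci, network = mean(ci))
}

oraclePathLength <- function(a) {
  d <- oracleDistances(a)
  diag(d) <- Inf
  mean(d[is.finite(d)])
}

oracleTransitivity <- function(a) {
  n <- nrow(a)
  triangles <- 0; triples <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i == j || j == k || i == k) next
    if (a[i, j] > 0 && a[j, k] > 0) {
      triples <- triples + 1
      if (a[i, k] > 0) triangles <- triangles + 1
    }
  }
  if (triples == 0) 0 else triangles / triples
}

oracleAssortativity <- function(a) {
  deg <- rowSums(a)
  xs <- c(); ys <- c()
  n <- nrow(a)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (a[i, j] > 0) { xs <- c(xs, deg[i]); ys <- c(ys, deg[j]) }
  if (!length(xs) || sd(xs) == 0 || sd(ys) == 0) return(NaN)
  cor(xs, ys)
}

## explicit enumeration of every shortest path
oracleShortestPaths <- function(a, j, k, d) {
  if (!is.finite(d[j, k])) return(list())
  if (j == k) return(list(j))
  out <- list()
  for (v in which(a[j, ] > 0)) {
    if (d[v, k] == d[j, k] - 1) {
      for (p in oracleShortestPaths(a, v, k, d))
        out[[length(out) + 1]] <- c(j, p)
    }
  }
  out
}

oracleBetweenness <- function(a) {
  n <- nrow(a)
  d <- oracleDistances(a)
  bc <- numeric(n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j == k || !is.finite(d[j, k])) next
    paths <- oracleShortestPaths(a, j, k, d)
    P <- length(paths)
    if (P == 0) next
    for (i in seq_len(n)) {
      if (i == j || i == k) next
      through <- sum(vapply(paths, function(p) i %in% p[-c(1, length(p))],
                            logical(1)))
      bc[i] <- bc[i] + through / P
    }
  }
  bc / ((n - 1) * (n - 2))
}

## Q of a labelled partition, straight from the definition
oracleQ <- function(a, memb) {
  m <- sum(a) / 2
  deg <- rowSums(a)
  n <- nrow(a)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (memb[i] == memb[j])
      q <- q + a[i, j] - deg[i] * deg[j] / (2 * m)
  q / (2 * m)
}

## exhaustive maximum modularity by recursive first-fit assignment
oracleModularity <- function(a) {
  n <- nrow(a)
  best <- -Inf
  assign <- function(memb, nextLabel) {
    i <- length(memb) + 1
    if (i > n) {
      q <- oracleQ(a, memb)
      if (q > best) best <<- q
      return(invisible())
    }
    for (lab in seq_len(nextLabel))
      assign(c(memb, lab), max(nextLabel, lab + 1))
  }
  assign(integer(0), 1)
  best
}
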