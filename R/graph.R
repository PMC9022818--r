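## Binary-network construction from FC matrices and the global/nodal
## topological properties, with random-network normalization.
##
## All metrics operate on undirected, unweighted simple graphs. Distances
## are shortest-path edge counts; unreachable pairs contribute 0 to
## efficiencies and are excluded from the characteristic-path-length
## average (documented choice: the average is over reachable ordered
## pairs, which matters at sparse thresholds).

#' Binarize a correlation matrix
#'
#' Three thresholding rules. `"absolute"`: an edge exists when the
#' coefficient exceeds the threshold (strict). `"proportional"`: the
#' effective threshold is `threshold` times the maximum off-diagonal
#' coefficient of the matrix. `"cost"`: the top
#' `round(threshold * n(n-1)/2)` off-diagonal values are kept (wiring
#' cost = kept edges / possible edges); ties are broken by descending
#' value, then by ascending node-pair order. With `useAbs = TRUE` the
#' absolute value of each coefficient is taken before any rule, so strong
#' negative correlations also produce edges. Missing coefficients are
#' never kept.
#'
#' @param mat symmetric correlation matrix (diagonal ignored).
#' @param threshold threshold value: in `[-1, 1]` for `"absolute"`, in
#'   `[0, 1]` for `"proportional"` and `"cost"`.
#' @param method `"absolute"` (default), `"proportional"` or `"cost"`.
#' @param useAbs take `abs()` of coefficients before thresholding?
#' @return A [BinaryNetwork-class] object.
#' @export
binarizeFC <- function(mat, threshold,
                       method = c("absolute", "proportional", "cost"),
                       useAbs = FALSE) {
  method <- match.arg(method)
  adj <- .binarizeAdj(mat, threshold, method, useAbs)
  binaryNetwork(adj, nodeLabels = rownames(as.matrix(mat)))
}

## binarization core on plain matrices (no S4 validation); shared by
## binarizeFC and the per-window sweep
.binarizeAdj <- function(mat, threshold, method, useAbs) {
  a <- as.matrix(mat)
  n <- nrow(a)
  if (useAbs) a <- abs(a)
  diag(a) <- NA
  up <- which(upper.tri(a))
  vals <- a[up]
  keep <- switch(method,
    absolute = {
      if (threshold < -1 || threshold > 1)
        stop("absolute threshold must lie in [-1, 1]")
      !is.na(vals) & vals > threshold
    },
    proportional = {
      if (threshold < 0 || threshold > 1)
        stop("proportional threshold must lie in [0, 1]")
      mx <- suppressWarnings(max(vals, na.rm = TRUE))
      !is.na(vals) & vals > threshold * mx
    },
    cost = {
      if (threshold < 0 || threshold > 1)
        stop("cost must lie in [0, 1]")
      k <- round(threshold * n * (n - 1) / 2)
      finite <- which(!is.na(vals))
      if (k > length(finite)) {
        warning("cost asks for ", k, " edges but only ", length(finite),
                " finite coefficients; capped")
        k <- length(finite)
      }
      ord <- finite[order(-vals[finite], finite)]
      sel <- logical(length(vals))
      sel[ord[seq_len(k)]] <- TRUE
      sel
    })
  adj <- matrix(0, n, n, dimnames = dimnames(a))
  adj[up[keep]] <- 1
  adj + t(adj)
}

#' All-pairs shortest path lengths
#'
#' Breadth-first expansion from every node by boolean matrix products;
#' distances are edge counts, `Inf` marks unreachable pairs.
#'
#' @param g a [BinaryNetwork-class] or adjacency matrix.
#' @return n x n numeric matrix of shortest-path edge counts with zero
#'   diagonal.
#' @export
shortestPathLengths <- function(g) {
  a <- .adj(g) > 0
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a] <- 1
  reach <- a | diag(TRUE, n)
  k <- 1L
  repeat {
    newReach <- (reach %*% a > 0) | reach
    fresh <- newReach & !reach
    if (!any(fresh) || k >= n) break
    k <- k + 1L
    d[fresh] <- k
    reach <- newReach
  }
  d
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest path length;
#' unreachable pairs contribute 0.
#'
#' @param g a [BinaryNetwork-class] or adjacency matrix.
#' @return Value in `[0, 1]`.
#' @export
globalEfficiency <- function(g) {
  a <- .adj(g)
  n <- nrow(a)
  if (n < 2)
    stop("global efficiency undefined for fewer than 2 nodes")
  d <- shortestPathLengths(g)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

## efficiency of the subgraph induced by node i's neighbors; 0 when < 2
.neighborSubgraphEfficiency <- function(a, i) {
  nb <- which(a[i, ] > 0)
  if (length(nb) < 2) return(0)
  globalEfficiency(a[nb, nb, drop = FALSE])
}

#' Network local efficiency
#'
#' Mean over nodes of the global efficiency of each node's
#' neighbor-induced subgraph (nodes with fewer than 2 neighbors
#' contribute 0).
#'
#' @inheritParams globalEfficiency
#' @return Value in `[0, 1]`.
#' @export
networkLocalEfficiency <- function(g) {
  a <- .adj(g)
  mean(vapply(seq_len(nrow(a)), function(i)
    .neighborSubgraphEfficiency(a, i), numeric(1)))
}

#' Clustering coefficients
#'
#' Nodal clustering `C(i)` is the fraction of a node's neighbor pairs that
#' are themselves connected (for binary graphs the generalized cube-root
#' triple product reduces to triangle counting); `C(i) = 0` for degree
#' below 2. The network coefficient is the mean over all nodes.
#'
#' @inheritParams globalEfficiency
#' @return List with `nodal` (per-node values) and `network` (their mean).
#' @export
clusteringCoefficients <- function(g) {
  a <- .adj(g)
  k <- rowSums(a)
  tri <- diag(a %*% a %*% a)    # 2 x triangles through each node
  ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  list(nodal = ci, network = mean(ci))
}

#' Characteristic path length
#'
#' Mean shortest-path edge count over reachable ordered node pairs.
#'
#' @inheritParams globalEfficiency
#' @return Value `>= 1` for any graph with at least one edge.
#' @export
characteristicPathLength <- function(g) {
  d <- shortestPathLengths(g)
  diag(d) <- Inf          # exclude self pairs
  dd <- d[is.finite(d)]
  if (!length(dd))
    stop("no reachable node pair: path length undefined")
  mean(dd)
}

#' Average degree
#' @inheritParams globalEfficiency
#' @return `2m/n`.
#' @export
averageDegree <- function(g) {
  a <- .adj(g)
  mean(rowSums(a))
}

#' Transitivity
#'
#' Three times the number of triangles divided by the number of connected
#' triples (0 with a warning when the graph has no connected triple).
#'
#' @inheritParams globalEfficiency
#' @return Value in `[0, 1]`.
#' @export
transitivityCoefficient <- function(g) {
  a <- .adj(g)
  k <- rowSums(a)
  triples <- sum(k * (k - 1)) / 2
  if (triples == 0) {
    warning("no connected triple: transitivity defined as 0")
    return(0)
  }
  triangles <- sum(diag(a %*% a %*% a)) / 6
  3 * triangles / triples
}

#' Degree assortativity
#'
#' Pearson correlation of endpoint degrees over both orientations of every
#' edge. Returns `NaN` (flag, not an error) when endpoint degrees have
#' zero variance (e.g. a regular graph).
#'
#' @inheritParams globalEfficiency
#' @return Correlation in `[-1, 1]`, or `NaN`.
#' @export
assortativityCoefficient <- function(g) {
  a <- .adj(g)
  deg <- rowSums(a)
  e <- which(a > 0, arr.ind = TRUE)   # both orientations
  if (!nrow(e)) return(NaN)
  x <- deg[e[, 1]]; y <- deg[e[, 2]]
  if (sd(x) == 0 || sd(y) == 0) return(NaN)
  cor(x, y)
}

## Newman modularity of a partition, from the modularity matrix
.partitionQ <- function(a, membership, m) {
  deg <- rowSums(a)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    q <- q + sum(a[idx, idx]) / (2 * m) - (sum(deg[idx]) / (2 * m))^2
  }
  q
}

## next restricted-growth string (canonical set partition) in lexicographic
## order, or NULL after the last one
.nextRGS <- function(rgs) {
  n <- length(rgs)
  if (n == 1L) return(NULL)
  pre <- cummax(rgs)
  for (i in n:2) {
    if (rgs[i] <= pre[i - 1L]) {
      rgs[i] <- rgs[i] + 1L
      if (i < n) rgs[(i + 1L):n] <- 1L
      return(rgs)
    }
  }
  NULL
}

#' Modularity
#'
#' Newman modularity Q of an undirected binary graph. `method = "exact"`
#' maximizes Q over all node partitions (feasible for small n; used
#' automatically for `n <= 8`); `method = "greedy"` is deterministic
#' agglomerative merging (best merge first, ties broken by ascending
#' community-pair order), returning the best partition seen along the
#' merge path. The returned Q is never below the single-module partition
#' (Q = 0).
#'
#' @inheritParams globalEfficiency
#' @param method `"auto"` (default), `"exact"` or `"greedy"`.
#' @return List with `Q` and `membership` (integer community labels).
#' @export
modularityCoefficient <- function(g, method = c("auto", "exact", "greedy")) {
  method <- match.arg(method)
  a <- .adj(g)
  n <- nrow(a)
  m <- sum(a) / 2
  if (m < 1)
    stop("modularity undefined for an empty graph")
  if (method == "auto")
    method <- if (n <= 8) "exact" else "greedy"
  if (method == "exact") {
    best <- list(Q = -Inf, membership = rep(1L, n))
    rgs <- rep(1L, n)
    repeat {
      q <- .partitionQ(a, rgs, m)
      if (q > best$Q)
        best <- list(Q = q, membership = rgs)
      rgs <- .nextRGS(rgs)
      if (is.null(rgs)) break
    }
    return(best)
  }
  ## greedy agglomeration on community pairs
  memb <- seq_len(n)
  bestQ <- .partitionQ(a, memb, m)
  bestMemb <- memb
  curQ <- bestQ
  deg <- rowSums(a)
  ## community-level edge and degree fractions
  comms <- as.list(seq_len(n))
  repeat {
    ids <- sort(unique(memb))
    if (length(ids) == 1L) break
    bestGain <- -Inf; bestPair <- NULL
    for (ii in seq_along(ids)) {
      for (jj in seq_along(ids)) {
        if (jj <= ii) next
        i <- ids[ii]; j <- ids[jj]
        vi <- memb == i; vj <- memb == j
        eij <- sum(a[vi, vj]) / (2 * m)
        ai <- sum(deg[vi]) / (2 * m); aj <- sum(deg[vj]) / (2 * m)
        gain <- 2 * (eij - ai * aj)
        if (gain > bestGain + 1e-15) {
          bestGain <- gain; bestPair <- c(i, j)
        }
      }
    }
    memb[memb == bestPair[2]] <- bestPair[1]
    curQ <- curQ + bestGain
    if (curQ > bestQ + 1e-15) {
      bestQ <- curQ; bestMemb <- memb
    }
  }
  list(Q = max(bestQ, 0), membership = as.integer(factor(bestMemb)))
}

#' Nodal metrics
#'
#' Per-node topological properties: degree, clustering, nodal (global)
#' efficiency, nodal local efficiency, and betweenness centrality.
#' Nodal efficiency of node i is the mean inverse distance from i to every
#' other node (unreachable contribute 0). Betweenness is the normalized
#' sum over ordered pairs `j != k` (both different from i) of the fraction
#' of shortest j-k paths passing through i, with normalization
#' `1/((n-1)(n-2))`.
#'
#' @inheritParams globalEfficiency
#' @return A data.frame with one row per node and columns `node`,
#'   `degree`, `clustering`, `nodalEfficiency`, `localEfficiency`,
#'   `betweenness`.
#' @export
nodalMetrics <- function(g) {
  a <- .adj(g)
  n <- nrow(a)
  labs <- rownames(a)
  if (is.null(labs)) labs <- paste0("n", seq_len(n))
  d <- shortestPathLengths(a)
  inv <- 1 / d; diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  eNodal <- rowSums(inv) / (n - 1)
  eLocal <- vapply(seq_len(n), function(i)
    .neighborSubgraphEfficiency(a, i), numeric(1))
  cl <- clusteringCoefficients(a)$nodal
  btw <- .betweenness(a)
  data.frame(node = labs, degree = rowSums(a), clustering = cl,
             nodalEfficiency = eNodal, localEfficiency = eLocal,
             betweenness = btw, row.names = NULL)
}

## Brandes' accumulation for unweighted graphs -> normalized betweenness
.betweenness <- function(a) {
  n <- nrow(a)
  bc <- numeric(n)
  if (n < 3) return(bc)
  nbrs <- lapply(seq_len(n), function(i) which(a[i, ] > 0))
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order <- c(order, v)
      for (w in nbrs[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  ## accumulation over all sources counts each ordered pair once
  bc / ((n - 1) * (n - 2))
}

#' Uniform random reference ensemble
#'
#' Draws `size` uniform random simple graphs with exactly the same number
#' of nodes and edges as the reference network, and records their
#' clustering coefficients and characteristic path lengths. Deterministic
#' for a fixed seed. `method = "rewire"` instead applies degree-preserving
#' edge rewiring to the reference network.
#'
#' @param g reference [BinaryNetwork-class] or adjacency matrix.
#' @param size ensemble size (default 20).
#' @param seed RNG seed (default 1).
#' @param method `"gnm"` (uniform fixed n, m; default) or `"rewire"`.
#' @param rewiresPerEdge rewiring attempts per edge (`"rewire"` only).
#' @return List with `C` and `L` (per-member values), their means `Crand`
#'   and `Lrand`, and the parameters.
#' @export
randomEnsemble <- function(g, size = 20L, seed = 1L,
                           method = c("gnm", "rewire"),
                           rewiresPerEdge = 10) {
  method <- match.arg(method)
  a <- .adj(g)
  n <- nrow(a)
  m <- sum(a) / 2
  if (m < 1) stop("reference network has no edges")
  pairs <- which(upper.tri(matrix(0, n, n)))
  Cs <- numeric(size); Ls <- numeric(size)
  .withSeed(seed, {
    for (b in seq_len(size)) {
      adj <- matrix(0, n, n)
      if (method == "gnm") {
        sel <- sample(pairs, m)
        adj[sel] <- 1
        adj <- adj + t(adj)
      } else {
        adj <- .rewire(a, round(rewiresPerEdge * m))
      }
      Cs[b] <- clusteringCoefficients(adj)$network
      Ls[b] <- characteristicPathLength(adj)
    }
  })
  list(C = Cs, L = Ls, Crand = mean(Cs), Lrand = mean(Ls),
       size = size, seed = seed, n = n, m = m, method = method)
}

## degree-preserving double-edge swaps
.rewire <- function(a, attempts) {
  el <- which(a > 0 & upper.tri(a), arr.ind = TRUE)
  for (t in seq_len(attempts)) {
    if (nrow(el) < 2) break
    pick <- sample.int(nrow(el), 2)
    e1 <- el[pick[1], ]; e2 <- el[pick[2], ]
    x1 <- e1[1]; y1 <- e1[2]; x2 <- e2[1]; y2 <- e2[2]
    if (length(unique(c(x1, y1, x2, y2))) < 4) next
    if (a[x1, y2] == 0 && a[x2, y1] == 0) {
      a[x1, y1] <- a[y1, x1] <- 0
      a[x2, y2] <- a[y2, x2] <- 0
      a[x1, y2] <- a[y2, x1] <- 1
      a[x2, y1] <- a[y1, x2] <- 1
      el[pick[1], ] <- sort(c(x1, y2))
      el[pick[2], ] <- sort(c(x2, y1))
    }
  }
  a
}

#' Random-network-normalized metrics
#'
#' Normalized clustering (gamma), normalized path length (lambda) and the
#' small-world coefficient sigma = gamma/lambda, relative to an ensemble
#' of random networks with the same number of nodes and edges.
#'
#' @param g a [BinaryNetwork-class] or adjacency matrix.
#' @param ensemble result of [randomEnsemble()] for this network; built
#'   with defaults when omitted.
#' @return List with `Cnorm`, `Lnorm`, `S`.
#' @export
normalizedMetrics <- function(g, ensemble = NULL) {
  if (is.null(ensemble))
    ensemble <- randomEnsemble(g)
  if (ensemble$Crand <= 0 || ensemble$Lrand <= 0)
    stop("degenerate ensemble: zero mean clustering or path length")
  Cn <- clusteringCoefficients(g)$network / ensemble$Crand
  Ln <- characteristicPathLength(g) / ensemble$Lrand
  list(Cnorm = Cn, Lnorm = Ln, S = Cn / Ln)
}

#' Global metrics of one binary network
#'
#' @inheritParams normalizedMetrics
#' @param normalized also compute gamma/lambda/sigma against a random
#'   ensemble?
#' @param ensembleSize,seed ensemble parameters when `normalized = TRUE`.
#' @param modularity also compute modularity Q (exact for `n <= 8`,
#'   greedy otherwise)?
#' @return Named list of global properties.
#' @export
globalMetrics <- function(g, normalized = FALSE, ensembleSize = 20L,
                          seed = 1L, modularity = FALSE) {
  a <- .adj(g)
  cl <- clusteringCoefficients(a)
  hasEdge <- sum(a) > 0
  out <- list(
    Eglob = globalEfficiency(a),
    Eloc = networkLocalEfficiency(a),
    C = cl$network,
    degree = averageDegree(a),
    L = if (hasEdge) characteristicPathLength(a) else NA_real_,
    transitivity = if (hasEdge) suppressWarnings(transitivityCoefficient(a))
                   else NA_real_,
    assortativity = assortativityCoefficient(a))
  if (modularity)
    out$Q <- if (hasEdge) modularityCoefficient(a)$Q else NA_real_
  if (normalized && hasEdge) {
    ens <- randomEnsemble(a, size = ensembleSize, seed = seed)
    nm <- normalizedMetrics(a, ens)
    out$Cnorm <- nm$Cnorm; out$Lnorm <- nm$Lnorm; out$S <- nm$S
  }
  out
}

## compute only the requested global metrics on a plain adjacency matrix,
## sharing the distance matrix between Eglob and L
.selectedGlobalMetrics <- function(a, metrics, ensembleSize = 20L,
                                   seed = 1L) {
  n <- nrow(a)
  hasEdge <- sum(a) > 0
  d <- NULL
  if (any(c("Eglob", "L", "Lnorm", "S") %in% metrics))
    d <- shortestPathLengths(a)
  cl <- if (any(c("C", "Cnorm", "S") %in% metrics))
    clusteringCoefficients(a) else NULL
  Lval <- function() {
    dd <- d; diag(dd) <- Inf
    dd <- dd[is.finite(dd)]
    if (length(dd)) mean(dd) else NA_real_
  }
  ens <- NULL
  if (any(c("Cnorm", "Lnorm", "S") %in% metrics) && hasEdge)
    ens <- randomEnsemble(a, size = ensembleSize, seed = seed)
  vapply(metrics, function(mt) {
    switch(mt,
      Eglob = { inv <- 1 / d; diag(inv) <- 0
                sum(inv[is.finite(inv)]) / (n * (n - 1)) },
      Eloc = networkLocalEfficiency(a),
      C = cl$network,
      degree = mean(rowSums(a)),
      L = if (hasEdge) Lval() else NA_real_,
      transitivity = if (hasEdge)
        suppressWarnings(transitivityCoefficient(a)) else NA_real_,
      assortativity = assortativityCoefficient(a),
      Q = if (hasEdge) modularityCoefficient(a, method = "greedy")$Q
          else NA_real_,
      Cnorm = if (is.null(ens)) NA_real_ else cl$network / ens$Crand,
      Lnorm = if (is.null(ens)) NA_real_ else Lval() / ens$Lrand,
      S = if (is.null(ens)) NA_real_
          else (cl$network / ens$Crand) / (Lval() / ens$Lrand))
  }, numeric(1))
}

#' Metric trajectories over a windowed FC series
#'
#' Binarizes every windowed matrix at every threshold of a sweep and
#' computes the selected global (and optionally nodal) properties,
#' returning long-format tables addressed by `(window, threshold)`.
#'
#' @param fc an [FCSeries-class] object.
#' @param thresholds numeric vector of thresholds (e.g.
#'   `seq(0.5, 0.85, by = 0.01)`).
#' @param method binarization rule, see [binarizeFC()].
#' @param useAbs take absolute correlation before thresholding?
#' @param metrics global metrics to compute, a subset of `"Eglob"`,
#'   `"Eloc"`, `"C"`, `"degree"`, `"L"`, `"transitivity"`,
#'   `"assortativity"`, `"Q"`, `"Cnorm"`, `"Lnorm"`, `"S"`. The normalized
#'   metrics trigger a seeded random ensemble per (window, threshold).
#' @param nodal also return nodal metrics per (window, threshold)?
#' @param ensembleSize,seed ensemble parameters for normalized metrics.
#' @return A data.frame `(window, threshold, metric, value)`; when
#'   `nodal = TRUE`, a list with elements `global` and `nodal` (the latter
#'   additionally keyed by `node`).
#' @export
metricsOverSeries <- function(fc, thresholds = seq(0.5, 0.85, by = 0.01),
                              method = "absolute", useAbs = FALSE,
                              metrics = c("Eglob", "Eloc", "C", "degree", "L"),
                              nodal = FALSE, ensembleSize = 20L, seed = 1L) {
  known <- c("Eglob", "Eloc", "C", "degree", "L", "transitivity",
             "assortativity", "Q", "Cnorm", "Lnorm", "S")
  if (!all(metrics %in% known))
    stop("unknown metric(s): ",
         paste(setdiff(metrics, known), collapse = ", "))
  needNorm <- any(c("Cnorm", "Lnorm", "S") %in% metrics)
  needQ <- "Q" %in% metrics
  W <- nWindows(fc)
  nTh <- length(thresholds)
  nrows <- if (nodal) vector("list", W * nTh) else NULL
  vals <- array(NA_real_, c(length(metrics), nTh, W))
  k <- 0L
  for (w in seq_len(W)) {
    mw <- fc@matrices[, , w]
    for (ti in seq_len(nTh)) {
      k <- k + 1L
      adj <- .binarizeAdj(mw, thresholds[ti], method = method,
                          useAbs = useAbs)
      vals[, ti, w] <- .selectedGlobalMetrics(adj, metrics,
                                              ensembleSize = ensembleSize,
                                              seed = seed)
      if (nodal) {
        nm <- nodalMetrics(adj)
        nrows[[k]] <- cbind(window = w, threshold = thresholds[ti],
                            utils::stack(nm[-1]), node = nm$node)
      }
    }
  }
  globalDf <- data.frame(
    window = rep(seq_len(W), each = length(metrics) * nTh),
    threshold = rep(rep(thresholds, each = length(metrics)), W),
    metric = rep(metrics, nTh * W),
    value = as.numeric(vals))
  if (!nodal) return(globalDf)
  nd <- do.call(rbind, nrows)
  names(nd)[names(nd) == "ind"] <- "metric"
  names(nd)[names(nd) == "values"] <- "value"
  list(global = globalDf, nodal = nd[, c("window", "threshold", "node",
                                         "metric", "value")])
}
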