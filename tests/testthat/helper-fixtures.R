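## shared fixture builders and independent oracles

## incidence matrix from an edge list given as a two-column data frame
toyIncidence <- function(edges, dimension = "toy", namespace = "gene") {
  toIncidence(associationTable(edges, dimension, namespace))
}

## distance matrix from an explicit value matrix and ids
mkDist <- function(values, ids = NULL, metric = NA_character_) {
  if (is.null(ids)) ids <- sprintf("d%02d", seq_len(nrow(values)))
  dimnames(values) <- list(ids, ids)
  diseaseDistanceMatrix(values, metric = metric)
}

## distance matrix of 1-D points (absolute differences, scaled into [0, 1])
pointDist <- function(x, ids = NULL) {
  v <- abs(outer(x, x, `-`))
  mkDist(v / max(v), ids)
}

## random feature set over a universe of given size
randomSet <- function(universe, minSize = 1L) {
  n <- sample(minSize:length(universe), 1L)
  sample(universe, n)
}

## brute-force Dunn index: explicit double loops, no vectorized shortcuts
bruteDunn <- function(v, labels) {
  n <- nrow(v)
  sep <- Inf
  diam <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (labels[i] == labels[j]) diam <- max(diam, v[i, j])
      else sep <- min(sep, v[i, j])
    }
  }
  sep / diam
}

## independent Ipsen-Mikhailov oracle: own eigendecomposition, Lorentzian
## density with closed-form normalization, fixed 20,001-point trapezoid
trapezoidIM <- function(W1, W2, gamma, npts = 20001L) {
  freqs <- function(W) {
    L <- diag(rowSums(W)) - W
    ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
    sqrt(pmax(ev[-1], 0))
  }
  om1 <- freqs(W1); om2 <- freqs(W2)
  dens <- function(om) {
    K <- 1 / sum(pi / 2 + atan(om / gamma))
    function(w) K * gamma *
      vapply(w, function(wi) sum(1 / ((wi - om)^2 + gamma^2)), numeric(1))
  }
  r1 <- dens(om1); r2 <- dens(om2)
  upper <- max(om1, om2, 0) + 10 * gamma
  w <- seq(0, upper, length.out = npts)
  y <- (r1(w) - r2(w))^2
  sqrt(sum((y[-1] + y[-length(y)]) / 2) * (w[2] - w[1]))
}

## exhaustive hypergeometric enumeration for a 2x2 table with margins fixed
enumFisher <- function(a, b, c, d, sided) {
  K <- a + b; n1 <- a + c; N <- a + b + c + d
  lo <- max(0, n1 - (N - K)); hi <- min(K, n1)
  xs <- lo:hi
  pr <- choose(K, xs) * choose(N - K, n1 - xs) / choose(N, n1)
  if (sided == "greater") sum(pr[xs >= a])
  else {
    pObs <- choose(K, a) * choose(N - K, n1 - a) / choose(N, n1)
    sum(pr[pr <= pObs * (1 + 1e-7)])
  }
}

## run the full recovery chain on one synthetic dataset; returns labels and
## matching truth (restricted to the intersected disease set)
recoveryChain <- function(config, kMax = 30L) {
  sim <- generateAssociations(config)
  incs <- intersectDiseases(lapply(sim$tables, toIncidence))
  g <- calibrateGamma(nDiseases(incs[[1]]))
  cons <- dimensionConsensus(lapply(incs, metricConsensus, gamma = g),
                             gamma = g)
  tree <- hclustWard2(cons)
  scan <- dunnScan(cons, tree, kMax = kMax)
  k <- attr(scan, "selected_k")
  labels <- cutK(tree, k)
  list(labels = labels, truth = sim$truth$cluster_of[names(labels)],
       k = k, consensus = cons, scan = scan)
}
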