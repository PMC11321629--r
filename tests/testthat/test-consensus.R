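## tiny helper: constant off-diagonal 2x2 distance matrix
constDist <- function(x, ids = c("a", "b")) {
  mkDist(matrix(c(0, x, x, 0), 2, 2), ids)
}

test_that("merge schedules follow the family distances", {
  fam2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2, dimnames = list(c("A", "B"),
                                                          c("A", "B")))
  s2 <- buildSchedule(fam2)
  expect_equal(nrow(s2$merge), 1L)

  ## IM(A,B) << IM(.,C): the first merge must be (A,B)
  fam3 <- matrix(c(0, 0.1, 2, 0.1, 0, 2.1, 2, 2.1, 0), 3, 3,
                 dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  s3 <- buildSchedule(fam3)
  expect_equal(sort(s3$merge[1, ]), c(-2, -1))  # leaves A and B

  perm <- c("C", "A", "B")
  s3p <- buildSchedule(fam3[perm, perm])
  expect_setequal(s3p$labels[-s3p$merge[1, ]], c("A", "B"))
})

test_that("stepwise averaging reproduces hand arithmetic and idempotence", {
  fam <- list(A = constDist(0.2), B = constDist(0.4), C = constDist(0.8))
  sched <- buildSchedule(matrix(c(0, 0.1, 1, 0.1, 0, 1, 1, 1, 0), 3, 3,
                                dimnames = list(names(fam), names(fam))))
  cons <- hierarchicalAverage(fam, sched)
  expect_equal(as.matrix(cons)["a", "b"], ((0.2 + 0.4) / 2 + 0.8) / 2)
  expect_equal(sort(leafWeights(cons)[c("A", "B", "C")]),
               sort(c(A = 0.25, B = 0.25, C = 0.5)))

  same <- list(A = constDist(0.3), B = constDist(0.3), C = constDist(0.3))
  consSame <- hierarchicalAverage(same, sched)
  expect_equal(as.matrix(consSame), as.matrix(same$A))
})

test_that("a balanced schedule over four equal-weight inputs is the plain mean", {
  set.seed(3)
  ids <- c("a", "b", "c")
  mats <- lapply(1:4, function(i) {
    v <- matrix(runif(9, 0, 0.5), 3, 3); v <- (v + t(v)) / 2; diag(v) <- 0
    mkDist(v, ids)
  })
  names(mats) <- c("A", "B", "C", "D")
  ## family distance forcing merges (A,B) then (C,D) then the two pairs
  fam <- matrix(1, 4, 4, dimnames = list(names(mats), names(mats)))
  fam[1, 2] <- fam[2, 1] <- 0.1
  fam[3, 4] <- fam[4, 3] <- 0.1
  diag(fam) <- 0
  cons <- hierarchicalAverage(mats, buildSchedule(fam))
  expect_equal(unname(leafWeights(cons)[names(mats)]), rep(0.25, 4))
  plainMean <- Reduce(`+`, lapply(mats, as.matrix)) / 4
  expect_equal(as.matrix(cons), plainMean, tolerance = 1e-12)
})

test_that("consensus entries are exact convex combinations of the inputs", {
  set.seed(12)
  ids <- sprintf("d%02d", 1:6)
  mats <- lapply(1:5, function(i) {
    v <- matrix(runif(36, 0, 1), 6, 6); v <- (v + t(v)) / 2; diag(v) <- 0
    mkDist(pmin(v, 1), ids)
  })
  names(mats) <- LETTERS[1:5]
  cons <- dimensionConsensus(mats, gamma = 0.45)
  w <- leafWeights(cons)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  rebuilt <- Reduce(`+`, lapply(names(mats), function(l)
    w[[l]] * as.matrix(mats[[l]])))
  expect_equal(as.matrix(cons), rebuilt, tolerance = 1e-12)
  ## envelope: within the elementwise [min, max] of the inputs
  lo <- Reduce(pmin, lapply(mats, as.matrix))
  hi <- Reduce(pmax, lapply(mats, as.matrix))
  expect_true(all(as.matrix(cons) >= lo - 1e-12))
  expect_true(all(as.matrix(cons) <= hi + 1e-12))
  ## the output is itself a valid distance matrix
  expect_true(validObject(cons))
})

test_that("dimension consensus of identical inputs returns the input; an outlier merges last", {
  sim <- generateAssociations(syntheticConfig(nDiseases = 20, coverage = 1,
                                              seed = 6))
  d <- metricConsensus(toIncidence(sim$tables$genes), gamma = 0.45)
  base <- diseaseDistanceMatrix(as.matrix(d))
  same <- list(A = base, B = base, C = base, D = base, E = base, F = base)
  cons <- dimensionConsensus(same, gamma = 0.45)
  expect_equal(as.matrix(cons), as.matrix(base), tolerance = 1e-12)

  ## five near-copies plus one genuinely different matrix: the outlier is the
  ## last leaf to join the schedule (and so carries weight 1/2)
  set.seed(4)
  jitterOf <- function(m) {
    v <- as.matrix(m)
    e <- matrix(runif(length(v), -0.01, 0.01), nrow(v))
    e <- (e + t(e)) / 2; diag(e) <- 0
    v <- v + e; v[v < 0] <- 0; v[v > 1] <- 1
    mkDist(v, diseaseIds(m))
  }
  other <- generateAssociations(syntheticConfig(nDiseases = 20, nClusters = 4,
                                                coverage = 1, seed = 77))
  vo <- as.matrix(metricConsensus(toIncidence(other$tables$symptoms),
                                  gamma = 0.45))
  dimnames(vo) <- list(diseaseIds(base), diseaseIds(base))
  famMats <- list(r1 = jitterOf(base), r2 = jitterOf(base), r3 = jitterOf(base),
                  r4 = jitterOf(base), r5 = jitterOf(base),
                  outlier = diseaseDistanceMatrix(vo))
  cons2 <- dimensionConsensus(famMats, gamma = 0.45)
  expect_equal(unname(leafWeights(cons2)["outlier"]), 0.5)
})

test_that("metric consensus within-cluster distances never exceed the worst metric", {
  ## convexity implies the consensus within-cluster mean is bounded by the
  ## worst single metric's within-cluster mean; checked on generated data
  for (s in 1:5) {
    sim <- generateAssociations(syntheticConfig(nDiseases = 30, coverage = 1,
                                                seed = s))
    inc <- toIncidence(sim$tables$genes)
    cl <- sim$truth$cluster_of[diseaseIds(inc)]
    within <- outer(cl, cl, `==`); diag(within) <- FALSE
    cons <- metricConsensus(inc, gamma = 0.45)
    consMean <- mean(as.matrix(cons)[within])
    metricMeans <- vapply(metricMatrices(inc), function(m)
      mean(as.matrix(m)[within]), numeric(1))
    expect_lte(consMean, max(metricMeans) + 1e-12)
  }
})
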