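test_that("single-table exact p-values match hand enumeration and fisher.test", {
  ## cluster of 5 out of 20 diseases, feature in 4 inside and 1 outside:
  ## p = [C(5,4) C(15,1) + C(5,5)] / C(20,5) = 76/15504
  expect_equal(fisherExactP(4, 1, 1, 14), 76 / 15504)
  ## feature present in every disease -> degenerate margin, p = 1
  expect_equal(fisherExactP(5, 15, 0, 0), 1)
  expect_equal(fisherExactP(0, 0, 5, 15), 1)

  ## independent library route on a handful of tables
  for (tab in list(c(4, 1, 1, 14), c(6, 1, 2, 8), c(2, 5, 3, 2))) {
    m <- matrix(tab, 2, 2, byrow = TRUE)
    expect_equal(fisherExactP(tab[1], tab[2], tab[3], tab[4], "greater"),
                 stats::fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-12)
    expect_equal(fisherExactP(tab[1], tab[2], tab[3], tab[4], "two.sided"),
                 stats::fisher.test(m)$p.value, tolerance = 1e-12)
  }
})

test_that("exact p-values equal exhaustive enumeration on small tables", {
  for (N in c(6, 9, 12)) {
    for (n1 in 1:(N - 1)) {
      for (K in 0:N) {
        lo <- max(0, n1 - (N - K)); hi <- min(K, n1)
        for (a in lo:hi) {
          b <- K - a; cc <- n1 - a; dd <- N - K - cc
          expect_equal(fisherExactP(a, b, cc, dd, "greater"),
                       enumFisher(a, b, cc, dd, "greater"),
                       tolerance = 1e-12)
          expect_equal(fisherExactP(a, b, cc, dd, "two.sided"),
                       enumFisher(a, b, cc, dd, "two.sided"),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("one-vs-all enrichment builds correct tables and adjusts p-values", {
  set.seed(20)
  ## 20 diseases, cluster 1 = 5 of them; feature fX in 4 inside, 1 outside
  ids <- sprintf("d%02d", 1:20)
  edges <- data.frame(
    d = c(ids[1:4], ids[6], ids),
    f = c(rep("fX", 5), paste0("bg", 1:20)))
  inc <- toyIncidence(edges)
  labels <- setNames(c(rep(1L, 5), rep(2L, 15)), ids)
  rec <- fisherOneVsAll(inc, labels, 1L)
  rx <- rec[rec$feature_id == "fX", ]
  expect_equal(rx[, c("a", "b", "c", "d")],
               data.frame(a = 4, b = 1, c = 1, d = 14), ignore_attr = TRUE)
  expect_equal(rx$p_nominal, 76 / 15504)
  expect_equal(rx$p_adjusted,
               min(1, rx$p_nominal * 2 * nFeatures(inc)))
  expect_true(rx$haldane == FALSE)
  expect_equal(sum(rec$a + rec$b + rec$c + rec$d == 20), nrow(rec))
})

test_that("Bonferroni adjustment follows the clusters-by-features multiplier", {
  expect_equal(bonferroniAdjust(1e-6, 71, 21020), 1)          # 1.49 capped
  expect_false(bonferroniAdjust(1e-6, 71, 21020) < 0.05)
  expect_equal(bonferroniAdjust(1e-10, 71, 21020), 1e-10 * 71 * 21020)
  expect_true(bonferroniAdjust(1e-10, 71, 21020) < 0.05)
  expect_equal(bonferroniAdjust(0, 71, 21020), 0)
  ## order preservation
  p <- sort(runif(20, 0, 1e-4))
  expect_false(is.unsorted(bonferroniAdjust(p, 71, 21020)))
})

test_that("pairwise and group contrasts behave like their tails", {
  ids <- sprintf("d%02d", 1:17)
  A <- ids[1:8]; B <- ids[9:17]
  edges <- data.frame(d = c(A[1:6], B[1]), f = rep("fY", 7))
  edges <- rbind(edges, data.frame(d = ids, f = paste0("bg", seq_along(ids))))
  inc <- toyIncidence(edges)
  rec <- fisherPairwise(inc, A, B)
  ry <- rec[rec$feature_id == "fY", ]
  expect_equal(ry[, c("a", "b", "c", "d")],
               data.frame(a = 6, b = 1, c = 2, d = 8), ignore_attr = TRUE)
  expect_equal(ry$p_nominal, enumFisher(6, 1, 2, 8, "greater"))

  ## identical association rates -> no enrichment signal
  edges2 <- data.frame(d = c(ids[1:4], ids[9:12]), f = rep("fZ", 8))
  inc2 <- toyIncidence(rbind(edges2,
                             data.frame(d = ids, f = paste0("bg", 1:17))))
  recA <- fisherPairwise(inc2, ids[1:8], ids[9:16])
  expect_gte(recA[recA$feature_id == "fZ", "p_nominal"], 0.5)

  ## swapping the groups complements the tail: p_A + p_B >= 1
  pA <- fisherPairwise(inc, A, B)
  pB <- fisherPairwise(inc, B, A)
  shared <- intersect(pA$feature_id, pB$feature_id)
  expect_true(all(pA$p_nominal[match(shared, pA$feature_id)] +
                  pB$p_nominal[match(shared, pB$feature_id)] >= 1 - 1e-12))

  ## two-sided group contrast: symmetric table gives p = 1, and the
  ## two-sided p never undercuts the one-sided p
  g2 <- fisherGroupVsGroup(inc, A, B)
  g1 <- fisherPairwise(inc, A, B)
  m <- match(g2$feature_id, g1$feature_id)
  expect_true(all(g2$p_nominal >= g1$p_nominal[m] - 1e-12))
  recSym <- fisherGroupVsGroup(inc2, ids[1:8], ids[9:16])
  expect_equal(recSym[recSym$feature_id == "fZ", "p_nominal"], 1)
})

test_that("feature frequencies count linked diseases with deterministic ties", {
  tab <- associationTable(
    data.frame(d = c("d1", "d2", "d1"), f = c("g1", "g1", "g2")),
    "genes", "gene")
  ff <- featureFrequency(tab)
  expect_equal(ff$feature_id, c("g1", "g2"))
  expect_equal(ff$n_diseases_linked, c(2L, 1L))
  expect_equal(ff$rank, 1:2)
  expect_equal(nrow(featureFrequency(tab, topN = 100)), 2L)

  tie <- associationTable(
    data.frame(d = c("d1", "d1", "d2", "d2"), f = c("gB", "gA", "gB", "gA")),
    "genes", "gene")
  expect_equal(featureFrequency(tie)$feature_id, c("gA", "gB"))
})

test_that("Spearman reports match a direct rank computation, ties included", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 4, 9, 16, 25)
  expect_equal(spearmanReport(x, y)$rho, 1)
  expect_equal(spearmanReport(x, rev(y))$rho, -1)

  set.seed(2)
  xt <- sample(c(1, 2, 2, 3, 5, 5, 5, 8), 40, replace = TRUE)
  yt <- sample(c(0, 1, 1, 4, 6), 40, replace = TRUE)
  direct <- stats::cor(rank(xt, ties.method = "average"),
                       rank(yt, ties.method = "average"))
  expect_equal(spearmanReport(xt, yt)$rho, direct, tolerance = 1e-12)

  names(xt) <- names(yt) <- sprintf("e%02d", 1:40)
  expect_equal(spearmanReport(xt, yt[sample(names(yt))])$rho, direct,
               tolerance = 1e-12)
})
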