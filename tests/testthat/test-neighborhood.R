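test_that("top-k neighborhoods rank by distance with lexicographic ties", {
  v <- matrix(c(0, .1, .4, .2,
                .1, 0, .3, .5,
                .4, .3, 0, .6,
                .2, .5, .6, 0), 4, 4, byrow = TRUE)
  d <- mkDist(v, c("q", "a", "b", "c"))
  top <- topKNeighbors(d, "q", k = 3)
  expect_equal(top$disease_id, c("a", "c", "b"))
  expect_equal(top$distance, c(.1, .2, .4))
  expect_false("q" %in% top$disease_id)

  full <- topKNeighbors(d, "q", k = 3)       # k = n - 1: the full ranking
  expect_equal(nrow(full), 3L)
  expect_false(is.unsorted(full$distance))

  ## tie at the cutoff is flagged and broken lexicographically
  vt <- matrix(0.5, 4, 4); diag(vt) <- 0
  dt <- mkDist(vt, c("q", "z", "m", "a"))
  t1 <- topKNeighbors(dt, "q", k = 2)
  expect_equal(t1$disease_id, c("a", "m"))
  expect_true(all(t1$tied_at_cutoff))
  expect_error(topKNeighbors(d, "nope"), "unknown")

  ## agreement with a full sort oracle on random matrices
  set.seed(41)
  for (rep in 1:5) {
    n <- 12
    m <- matrix(runif(n * n), n, n); m <- (m + t(m)) / 2; diag(m) <- 0
    dm <- mkDist(m)
    q <- diseaseIds(dm)[1]
    row <- as.matrix(dm)[q, -1]
    oracle <- names(sort(row))[1:5]
    got <- topKNeighbors(dm, q, k = 5)$disease_id
    expect_equal(got[order(row[got])], got)   # sorted by distance
    expect_setequal(got, oracle)
  }
})

test_that("shared exclusive features follow set arithmetic", {
  inc <- toyIncidence(data.frame(
    d = c("d1", "d1", "d1", "d2", "d2", "d3"),
    f = c("f1", "f2", "f3", "f2", "f3", "f3")))
  expect_equal(sharedExclusiveFeatures(inc, c("d1", "d2"), "d3"), "f2")
  expect_equal(sharedExclusiveFeatures(inc, c("d1", "d2")), c("f2", "f3"))
  disj <- toyIncidence(data.frame(d = c("a", "b"), f = c("x", "y")))
  expect_length(sharedExclusiveFeatures(disj, c("a", "b")), 0)
  expect_error(sharedExclusiveFeatures(inc, c("d1", "zz")), "unknown")

  ## inclusion-exclusion style identity on random incidences:
  ## shared(pair) = shared(pair, excl) U (shared(pair) n features(excl))
  set.seed(6)
  for (rep in 1:10) {
    edges <- unique(data.frame(
      d = sample(sprintf("d%d", 1:8), 60, replace = TRUE),
      f = sample(sprintf("f%02d", 1:15), 60, replace = TRUE)))
    incR <- toyIncidence(edges)
    ids <- diseaseIds(incR)
    if (length(ids) < 4) next
    pair <- ids[1:2]; excl <- ids[3]
    m <- as.matrix(incR)
    plain <- sharedExclusiveFeatures(incR, pair)
    kept <- sharedExclusiveFeatures(incR, pair, excl)
    exclFeats <- colnames(m)[m[excl, ] > 0]
    expect_setequal(plain, union(kept, intersect(plain, exclFeats)))
    expect_length(intersect(kept, exclFeats), 0)
  }
})

test_that("feature rarity counts carriers over the dimension universe", {
  inc <- toyIncidence(data.frame(
    d = c("d1", "d2", "d3"), f = c("fR", "fR", "fR")))
  expect_equal(featureRarity(inc, "fR"), 3L)
  expect_equal(featureRarity(inc, "fR", excludePair = c("d1", "d2")), 1L)
  pairOnly <- toyIncidence(data.frame(d = c("d1", "d2"), f = c("fU", "fU")))
  expect_equal(featureRarity(pairOnly, "fU", excludePair = c("d1", "d2")), 0L)
  expect_error(featureRarity(inc, "nope"), "unknown")
})

test_that("ICD-10 level similarity is symmetric and depth-monotone", {
  expect_equal(icd10Similarity("E11.3", "E11.3"), 1)
  expect_equal(icd10Similarity("E11.3", "E11.5"), 2 / 3)
  expect_equal(icd10Similarity("E11.3", "E45.1"), 1 / 3)
  expect_equal(icd10Similarity("A00", "Z99"), 0)
  expect_equal(icd10Similarity("E11.3", "E11.5"),
               icd10Similarity("E11.5", "E11.3"))
  ## deeper shared prefix never lowers the similarity
  s <- c(icd10Similarity("E11.3", "F11.3"),
         icd10Similarity("E11.3", "E45.3"),
         icd10Similarity("E11.3", "E11.9"),
         icd10Similarity("E11.3", "E11.3"))
  expect_false(is.unsorted(s))
  expect_error(icd10Similarity("11E", "E11"), "malformed")
  expect_error(icd10Similarity("E1", "E11"), "malformed")
})

test_that("ICD comparison restricts matrices and joins the IM family", {
  sim <- generateAssociations(syntheticConfig(nDiseases = 24, coverage = 1,
                                              seed = 19))
  incs <- lapply(sim$tables[c("genes", "symptoms")], toIncidence)
  cons <- lapply(incs, metricConsensus, gamma = 0.45)
  ids <- diseaseIds(cons$genes)
  mapped <- ids[1:15]
  cl <- sim$truth$cluster_of[mapped]
  mapping <- setNames(c("C18", "E11", "G30")[cl], mapped)
  fam <- icdCompare(cons, mapping, gamma = 0.45)
  expect_identical(attr(fam, "diseases"), sort(mapped))
  expect_equal(rownames(fam), c("genes", "symptoms", "icd10"))
  expect_true(all(diag(fam) == 0) && all(fam >= 0))

  ## all-identical codes: degenerate all-zero ICD matrix, clearly distinct
  ## from any non-degenerate dimension matrix
  same <- setNames(rep("E11", length(mapped)), mapped)
  fam0 <- icdCompare(cons, same, gamma = 0.45)
  expect_gt(fam0["icd10", "genes"], 0)
  icdM <- icdDistanceMatrix(same, mapped)
  expect_true(all(as.matrix(icdM) == 0))

  ## spectral invariance: relabelling diseases (shuffled mapping) yields an
  ## isomorphic code graph, hence the identical IM distance -- structural,
  ## not label-wise, comparison
  set.seed(10)
  shuffled <- setNames(sample(mapping), names(mapping))
  famS <- icdCompare(cons, shuffled, gamma = 0.45)
  expect_equal(famS["icd10", "genes"], fam["icd10", "genes"], tolerance = 1e-9)

  expect_error(icdCompare(cons, mapping[1:2]), "fewer than 3")
})
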