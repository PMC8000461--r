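make_two_branch_store <- function(dir, cross_ani = 70.75,
                                  within = c(99.3, 99.5, 99.2, 99.6)) {
  # two branches diverging at the 75%-threshold position (B): the founders'
  # single recorded computation links every cross-branch pair
  store <- createStore(config = quiet_config())
  ids <- c("f1", "f2", "m1a", "m1b", "m2a", "m2b")
  for (id in ids) registerGenome(store, tiny_fasta(id, dir), genomeId = id)
  sn <- "lin20"
  recordLIN(store, "f1", sn, rep(0L, 20))
  recordLIN(store, "f2", sn, assignLIN(linOf(store, "f1"), cross_ani, sn,
                                       store))
  recordANI(store, "f2", "f1", cross_ani)
  recordLIN(store, "m1a", sn, assignLIN(linOf(store, "f1"), within[1], sn,
                                        store))
  recordANI(store, "m1a", "f1", within[1])
  recordLIN(store, "m1b", sn, assignLIN(linOf(store, "m1a"), within[2], sn,
                                        store))
  recordANI(store, "m1b", "m1a", within[2])
  recordLIN(store, "m2a", sn, assignLIN(linOf(store, "f2"), within[3], sn,
                                        store))
  recordANI(store, "m2a", "f2", within[3])
  recordLIN(store, "m2b", sn, assignLIN(linOf(store, "f2"), within[4], sn,
                                        store))
  recordANI(store, "m2b", "f2", within[4])
  store
}

test_that("directly recorded ANI values pass through unchanged", {
  dir <- withr::local_tempdir()
  store <- make_two_branch_store(dir)
  expect_equal(inferPairwise(store, "f2", "f1"), 70.75)
  expect_equal(inferPairwise(store, "f1", "f2"), 70.75)
  expect_equal(inferPairwise(store, "m1a", "f1", detail = TRUE),
               list(value = 99.3, rule = "direct"))
})

test_that("cross-branch pairs inherit the founders' single computation", {
  dir <- withr::local_tempdir()
  store <- make_two_branch_store(dir)
  branch1 <- c("f1", "m1a", "m1b"); branch2 <- c("f2", "m2a", "m2b")
  for (x in branch1) for (y in branch2)
    expect_equal(inferPairwise(store, x, y), 70.75)
  # and the full matrix shows the merging phenomenon: one distinct value
  # across all nine cross pairs
  m <- similarityValues(fullMatrix(store))
  expect_equal(unique(as.vector(m[branch1, branch2])), 70.75)
})

test_that("three-branch stores fall back to the later founder's record", {
  dir <- withr::local_tempdir()
  store <- createStore(config = quiet_config())
  for (id in c("g0", "g1", "g1m", "g2"))
    registerGenome(store, tiny_fasta(id, dir), genomeId = id)
  sn <- "lin20"
  recordLIN(store, "g0", sn, rep(0L, 20))
  # branch 1 and branch 2 both diverge from g0 at position B, so the
  # founder of branch 2's subject (g0) carries branch 0's number there
  recordLIN(store, "g1", sn, assignLIN(linOf(store, "g0"), 72.0, sn,
                                       store))
  recordANI(store, "g1", "g0", 72.0)
  recordLIN(store, "g1m", sn, assignLIN(linOf(store, "g1"), 99.4, sn,
                                        store))
  recordANI(store, "g1m", "g1", 99.4)
  recordLIN(store, "g2", sn, assignLIN(linOf(store, "g0"), 73.5, sn,
                                       store))
  recordANI(store, "g2", "g0", 73.5)
  # no computation spans branches 1 and 2; the later founder's (g2's)
  # record is propagated and stays inside the same threshold bracket
  res <- inferPairwise(store, "g1m", "g2", detail = TRUE)
  expect_equal(res$rule, "propagated")
  expect_equal(res$value, 73.5)
  expect_true(res$value >= 70 && res$value < 75)
})

test_that("novel first-position splits fall back to the shared threshold", {
  dir <- withr::local_tempdir()
  store <- createStore(config = quiet_config())
  for (id in c("a", "b")) registerGenome(store, tiny_fasta(id, dir),
                                         genomeId = id)
  recordLIN(store, "a", "lin20", rep(0L, 20))
  recordLIN(store, "b", "lin20", assignLIN(NULL, 0, "lin20", store))
  res <- inferPairwise(store, "a", "b", detail = TRUE)
  expect_equal(res$rule, "threshold")
  expect_equal(res$value, 0) # nothing shared: only known to be < 70%
})

test_that("fullMatrix fills n(n-1)/2 entries from n-1 records", {
  dir <- withr::local_tempdir()
  store <- make_two_branch_store(dir)
  m <- fullMatrix(store)
  v <- similarityValues(m)
  expect_equal(dim(v), c(6L, 6L))
  expect_equal(nrow(aniRecords(store)), 5L)
  expect_true(all(v[upper.tri(v)] > 0))
  expect_equal(v, t(v))
  expect_equal(unname(diag(v)), rep(100, 6))
  # single genome: trivial 1x1 matrix
  solo_dir <- withr::local_tempdir()
  solo <- createStore(config = quiet_config())
  registerGenome(solo, tiny_fasta("only", solo_dir), genomeId = "only")
  recordLIN(solo, "only", "lin20", rep(0L, 20))
  expect_equal(similarityValues(fullMatrix(solo)),
               matrix(100, 1, 1, dimnames = list("only", "only")))
})

test_that("inferred values respect the divergence-position bracket", {
  sch <- builtinScheme("lin20")
  thr <- thresholds(sch)
  for (seed in 1:4) {
    truth <- random_ani_matrix(12, lo = 65, hi = 100, seed = seed)
    store <- replay_store(truth, scheme = sch,
                          dir = withr::local_tempdir())
    ids <- rownames(truth)
    for (i in 1:11) for (j in (i + 1):12) {
      res <- inferPairwise(store, ids[i], ids[j], detail = TRUE)
      if (res$rule == "direct") next
      lx <- linOf(store, ids[i]); ly <- linOf(store, ids[j])
      p <- which(lx != ly)[1]
      if (is.na(p)) next
      lower <- if (p > 1) thr[p - 1] else 0
      expect_gte(res$value, lower)
      expect_lt(res$value, thr[p])
    }
  }
})

test_that("fullMatrix commutes with relabelling by insertion order", {
  truth <- 100 * makeClade(twoGroupClade(nPerGroup = 3,
                                         genomeLength = 1000,
                                         seed = 81))$expected
  m1 <- fullMatrix(replay_store(truth, dir = withr::local_tempdir()))
  perm <- c(4, 1, 6, 2, 5, 3)
  m2 <- fullMatrix(replay_store(truth, perm,
                                dir = withr::local_tempdir()))
  ids <- matrixLabels(m1)
  v1 <- similarityValues(m1)[ids, ids]
  v2 <- similarityValues(m2)[ids, ids]
  # digits differ across orders, but every pair stays in the same
  # divergence bracket as its true ANI
  sch <- builtinScheme("lin20")
  expect_equal(sharedDepth(sch, v1[upper.tri(v1)]),
               sharedDepth(sch, truth[ids, ids][upper.tri(v1)]))
  expect_equal(sharedDepth(sch, v2[upper.tri(v2)]),
               sharedDepth(sch, truth[ids, ids][upper.tri(v2)]))
})

test_that("complete linkage matches a naive agglomerative oracle", {
  # trivial: all-identical matrix collapses at height zero
  ids <- paste0("g", 1:4)
  same <- similarityMatrix(matrix(100, 4, 4, dimnames = list(ids, ids)))
  hc_same <- completeLinkage(same)
  expect_equal(hc_same$height, rep(0, 3))
  # two planted groups: first split at 100 - 80 = 20
  v <- matrix(80, 4, 4, dimnames = list(ids, ids))
  v[1:2, 1:2] <- 99; v[3:4, 3:4] <- 99; diag(v) <- 100
  hc <- completeLinkage(similarityMatrix(v))
  expect_equal(max(hc$height), 20)
  expect_equal(sort(unname(stats::cutree(hc, h = 5))), c(1, 1, 2, 2))
  # random matrices: merge heights equal the O(n^3) oracle's
  for (seed in 1:5) {
    truth <- random_ani_matrix(6, lo = 70, hi = 99, seed = 100 + seed)
    sm <- similarityMatrix(truth)
    hc <- completeLinkage(sm)
    expect_equal(sort(hc$height),
                 naive_complete_heights(100 - truth),
                 tolerance = 1e-12)
  }
})

test_that("mantelTest matches closed-form Pearson and the permutation oracle", {
  ids <- paste0("g", 1:4)
  m1 <- similarityMatrix(random_ani_matrix(4, seed = 11))
  expect_equal(mantelTest(m1, m1, permutations = 99, seed = 1)$r, 1.0)
  m2 <- similarityMatrix(random_ani_matrix(4, seed = 12))
  res <- mantelTest(m1, m2, permutations = 99, seed = 2)
  v1 <- similarityValues(m1)[upper.tri(similarityValues(m1))]
  v2 <- similarityValues(m2)[upper.tri(similarityValues(m2))]
  expect_equal(res$r, cor(v1, v2))
  # exhaustive permutation oracle on a 5x5 pair
  a <- random_ani_matrix(5, seed = 13)
  b <- random_ani_matrix(5, seed = 14)
  ut <- upper.tri(a)
  r_obs <- cor(a[ut], b[ut])
  r_perm <- vapply(all_permutations(5), function(p)
    cor(a[ut], b[p, p][ut]), numeric(1))
  p_exact <- mean(r_perm >= r_obs)
  res5 <- mantelTest(similarityMatrix(a), similarityMatrix(b),
                     permutations = 9999, seed = 3)
  expect_lt(abs(res5$p - p_exact), 0.05)
  # seeded reproducibility
  res5b <- mantelTest(similarityMatrix(a), similarityMatrix(b),
                      permutations = 9999, seed = 3)
  expect_identical(res5, res5b)
})

test_that("mantelTest guards labels and degenerate inputs", {
  a <- random_ani_matrix(4, seed = 21)
  b <- random_ani_matrix(4, seed = 22)
  rownames(b) <- colnames(b) <- paste0("x", 1:4)
  expect_error(mantelTest(similarityMatrix(a), similarityMatrix(b)),
               "labels")
  const <- matrix(90, 4, 4, dimnames = dimnames(a)); diag(const) <- 100
  expect_warning(res <- mantelTest(similarityMatrix(const),
                                   similarityMatrix(a), 99),
                 "undefined")
  expect_true(is.na(res$r) && is.na(res$p))
})

test_that("mantel r agrees with an independent implementation", {
  a <- random_ani_matrix(8, seed = 31)
  b <- random_ani_matrix(8, seed = 32)
  ours <- mantelTest(similarityMatrix(a), similarityMatrix(b),
                     permutations = 99, seed = 1)
  ref <- vegan::mantel(as.dist(100 - a), as.dist(100 - b),
                       permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("matrix and dendrogram round-trip through their export formats", {
  dir <- withr::local_tempdir()
  m <- similarityMatrix(random_ani_matrix(5, seed = 41))
  p <- file.path(dir, "m.tsv")
  exportMatrix(m, p)
  back <- readMatrix(p)
  expect_equal(similarityValues(back), similarityValues(m),
               tolerance = 1e-9)
  expect_equal(matrixLabels(back), matrixLabels(m))
  nwk <- file.path(dir, "hc.nwk")
  exportDendrogram(completeLinkage(m), nwk)
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, matrixLabels(m))
})
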