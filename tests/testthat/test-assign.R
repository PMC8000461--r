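test_that("Jaccard brackets switch exactly at the calibration cutoffs", {
  eps <- 1e-12
  expect_equal(jaccardBracket(0.30), "same_f_group")
  expect_equal(jaccardBracket(0.10), "shared_a")
  expect_equal(jaccardBracket(0.001), "novel")
  # upper boundary: J = 0.2475 itself is still shared_a
  expect_equal(jaccardBracket(0.2475), "shared_a")
  expect_equal(jaccardBracket(0.2475 + eps), "same_f_group")
  # lower boundary: J = 0.0025 itself is already novel
  expect_equal(jaccardBracket(0.0025), "novel")
  expect_equal(jaccardBracket(0.0025 + eps), "shared_a")
})

test_that("classifyQuery brackets discrete sketch overlaps correctly", {
  # sketches sharing m of 2000 bottom hashes have J = m/2000 exactly
  base <- 1:2000
  rep_sig <- synthetic_sig(base, "rep")
  probe <- function(m)
    synthetic_sig(c(base[seq_len(m)], 10000L + seq_len(2000 - m)), "q")
  cfg <- quiet_config()
  # 495/2000 = 0.2475 stays shared_a; 496/2000 crosses into the F-group
  out495 <- classifyQuery(probe(495), list(rep = rep_sig), cfg)
  expect_equal(searchBracket(out495), "shared_a")
  expect_equal(bestJaccard(out495), 0.2475)
  out496 <- classifyQuery(probe(496), list(rep = rep_sig), cfg)
  expect_equal(searchBracket(out496), "same_f_group")
  # 5/2000 = 0.0025 is novel; 6/2000 is not
  expect_equal(searchBracket(classifyQuery(probe(5), list(rep = rep_sig),
                                           cfg)), "novel")
  expect_equal(searchBracket(classifyQuery(probe(6), list(rep = rep_sig),
                                           cfg)), "shared_a")
  # empty store: novel with no subject
  out0 <- classifyQuery(probe(100), list(), cfg)
  expect_equal(searchBracket(out0), "novel")
  expect_length(bestSubject(out0), 0L)
  # maximum wins; ties go to the earliest representative
  far <- synthetic_sig(50000L + 1:2000, "far")
  out <- classifyQuery(probe(600), list(far = far, rep = rep_sig), cfg)
  expect_equal(bestSubject(out), "rep")
  out_tie <- classifyQuery(probe(600),
                           list(first = rep_sig, second = rep_sig), cfg)
  expect_equal(bestSubject(out_tie), "first")
})

test_that("mostSimilarInGroup ranks members like the exact oracle", {
  g <- randomGenome(20000, seed = 61)
  members <- list(m01 = evolveGenome(g, 0.01, seed = 62)$child,
                  m05 = evolveGenome(g, 0.05, seed = 63)$child,
                  m10 = evolveGenome(g, 0.10, seed = 64)$child)
  qsig <- computeSignature(g, "q")
  msigs <- lapply(names(members), function(id)
    computeSignature(members[[id]], id))
  names(msigs) <- names(members)
  expect_equal(mostSimilarInGroup(qsig, msigs), "m01")
  # oracle agreement: exact Jaccard ranks members identically
  exact <- vapply(members, exact_jaccard, numeric(1), a = g, k = 21)
  expect_equal(names(which.max(exact)), "m01")
  # single member wins regardless; identical member dominates
  expect_equal(mostSimilarInGroup(qsig, msigs["m10"]), "m10")
  msigs$self <- computeSignature(g, "self")
  expect_equal(mostSimilarInGroup(qsig, msigs), "self")
})

test_that("assignLIN reproduces the worked 95.4575% example", {
  dir <- withr::local_tempdir()
  store <- createStore(config = quiet_config())
  registerGenome(store, tiny_fasta("subj", dir), genomeId = "subj")
  subj_lin <- c(3L, 0L, 1L, 0L, 2L, 1L, 4L, 0L, 0L, 0L, 1L, 0L, 0L, 0L,
                0L, 0L, 0L, 0L, 0L, 0L)
  recordLIN(store, "subj", "lin20", subj_lin)
  lin <- assignLIN(subj_lin, 95.4575, "lin20", store)
  # positions A-F copied, a fresh number at G, zeros H-T
  expect_equal(lin[1:6], subj_lin[1:6])
  expect_false(lin[7] == subj_lin[7])
  expect_equal(lin[7], 0L) # smallest number unused under that prefix
  expect_equal(lin[8:20], rep(0L, 13))
  # novel genome: fresh number at A, zeros after
  novel <- assignLIN(NULL, 0, "lin20", store)
  expect_equal(novel, c(0L, rep(0L, 19))) # 0 unused at A (subj holds 3)
  # ANI at or above the top threshold copies the subject LIN wholesale
  expect_equal(assignLIN(subj_lin, 100, "lin20", store), subj_lin)
})

test_that("the first genome of a store gets the all-zero LIN", {
  dir <- withr::local_tempdir()
  store <- createStore(schemes = list(builtinScheme("lin300")),
                       config = quiet_config())
  g <- randomGenome(15000, seed = 71)
  p <- file.path(dir, "first.fasta")
  writeLines(c(">first", g), p)
  res <- addGenome(store, p)
  expect_equal(res$bracket, "first_genome")
  expect_equal(linOf(store, "first", "lin20"), rep(0L, 20))
  expect_equal(linOf(store, "first", "lin300"), rep(0L, 300))
  expect_equal(nrow(aniRecords(store)), 0L)
  expect_equal(representatives(store), "first")
})

test_that("adding a duplicate genome copies the full LIN at ANI 100", {
  dir <- withr::local_tempdir()
  store <- createStore(config = quiet_config())
  g <- randomGenome(15000, seed = 72)
  p1 <- file.path(dir, "orig.fasta"); writeLines(c(">orig", g), p1)
  p2 <- file.path(dir, "copy.fasta"); writeLines(c(">copy", g), p2)
  addGenome(store, p1)
  res <- addGenome(store, p2)
  expect_equal(res$bracket, "same_f_group")
  expect_equal(res$subject, "orig")
  expect_equal(res$ani, 100)
  # duplicate LIN by design: uniqueness lives at the genome id
  expect_identical(linOf(store, "copy"), linOf(store, "orig"))
  expect_equal(nrow(aniRecords(store)), 1L)
})

test_that("a close pair shares the prefix bracketing its true divergence", {
  dir <- withr::local_tempdir()
  store <- createStore(config = quiet_config())
  g <- randomGenome(20000, seed = 73)
  child <- evolveGenome(g, 0.02, seed = 74)$child
  p1 <- file.path(dir, "parent.fasta"); writeLines(c(">parent", g), p1)
  p2 <- file.path(dir, "child.fasta"); writeLines(c(">child", child), p2)
  addGenome(store, p1)
  res <- addGenome(store, p2)
  expect_lt(abs(res$ani - 98.0), 0.5)
  lp <- linOf(store, "parent"); lc <- linOf(store, "child")
  d <- sharedDepth(storeScheme(store), res$ani)
  expect_equal(lp[seq_len(d)], lc[seq_len(d)])
  expect_false(lp[d + 1L] == lc[d + 1L])
})

test_that("an unrelated genome is novel with a fresh first position", {
  dir <- withr::local_tempdir()
  store <- createStore(config = quiet_config())
  p1 <- file.path(dir, "a.fasta")
  writeLines(c(">a", randomGenome(15000, seed = 75)), p1)
  p2 <- file.path(dir, "b.fasta")
  writeLines(c(">b", randomGenome(15000, seed = 76)), p2)
  addGenome(store, p1)
  res <- addGenome(store, p2)
  expect_equal(res$bracket, "novel")
  expect_equal(linOf(store, "b"), c(1L, rep(0L, 19)))
  # novel genomes trigger no precise ANI computation
  expect_equal(nrow(aniRecords(store)), 0L)
  expect_equal(representatives(store), c("a", "b"))
})

test_that("each added genome triggers at most one precise ANI computation", {
  dir <- withr::local_tempdir()
  store <- createStore(config = quiet_config())
  paths <- writeClade(makeClade(twoGroupClade(nPerGroup = 3,
                                              genomeLength = 15000,
                                              seed = 77)),
                      file.path(dir, "clade"))
  for (p in paths) addGenome(store, p)
  a <- aniRecords(store)
  expect_equal(nrow(a), length(paths) - 1L)
  expect_false(any(duplicated(a$query_id)))
  # the first genome never appears as a query
  expect_false(genomeIds(store)[1] %in% a$query_id)
  # prefix coherence on directly computed pairs
  sch <- storeScheme(store)
  for (i in seq_len(nrow(a))) {
    lq <- linOf(store, a$query_id[i]); ls <- linOf(store, a$subject_id[i])
    agree <- cumprod(lq == ls)
    expect_equal(sum(agree), sharedDepth(sch, a$ani[i]))
  }
})

test_that("insertion order shifts digits but not divergence brackets", {
  # replay the assignment logic over a known ultrametric ANI matrix
  truth <- 100 * makeClade(twoGroupClade(nPerGroup = 3,
                                         genomeLength = 1000,
                                         seed = 78))$expected
  n <- nrow(truth)
  sch <- builtinScheme("lin20")
  first_diff <- function(store) {
    ids <- sort(rownames(truth))
    out <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      lx <- linOf(store, ids[i], "lin20")
      ly <- linOf(store, ids[j], "lin20")
      p <- which(lx != ly)
      out[i, j] <- if (length(p)) p[1] else 21L
    }
    out
  }
  dir <- withr::local_tempdir()
  ref <- first_diff(replay_store(truth, seq_len(n), sch, dir))
  set.seed(79)
  for (rep in 1:5) {
    perm <- sample.int(n)
    got <- first_diff(replay_store(truth, perm, sch,
                                   withr::local_tempdir()))
    expect_identical(got, ref)
  }
})
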