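test_that("alignment score is the L2 norm of identity-segment lengths", {
  expect_identical(scoreAlignment(100), 100)
  expect_identical(scoreAlignment(c(30, 40)), 50)
  expect_equal(scoreAlignment(c(60, 60)), sqrt(7200), tolerance = 1e-12)
  expect_lt(scoreAlignment(c(60, 60)), scoreAlignment(120))
  expect_identical(scoreAlignment(integer(0)), 0)
})

test_that("the score grows with added segments and shrinks under splits", {
  set.seed(401)
  for (i in 1:50) {
    segs <- sample.int(200, sample.int(6, 1), replace = TRUE)
    expect_gt(scoreAlignment(c(segs, sample.int(200, 1))),
              scoreAlignment(segs))
    l <- segs[1]
    if (l >= 2) {
      a <- sample.int(l - 1, 1)
      expect_lt(scoreAlignment(c(a, l - a, segs[-1])), scoreAlignment(segs))
    }
  }
})

test_that("a lone seed with no close neighbor is removed by the noise filter", {
  subj <- randomDna(10000, seed = 402)
  db <- oneSeqDb(subj)
  q <- randomDna(2000)
  substr(q, 500, 555) <- substr(subj, 1001, 1056)  # one grid-aligned window
  p1 <- runPass1(q, db)
  expect_identical(nrow(p1$runs), 0L)
})

test_that("two same-diagonal seeds 500 bp apart survive and merge into a run", {
  subj <- randomDna(10000, seed = 403)
  db <- oneSeqDb(subj)
  q <- randomDna(2000)
  substr(q, 501, 556) <- substr(subj, 1001, 1056)
  substr(q, 1001, 1056) <- substr(subj, 1501, 1556)  # same diagonal, 500 apart
  p1 <- runPass1(q, db)
  expect_gte(nrow(p1$runs), 1L)
  expect_true(any(p1$runs$qstart <= 500 & p1$runs$qend >= 1056))
})

test_that("a query identical to a subject yields one full-coverage run", {
  subj <- randomDna(5000, seed = 404)
  db <- oneSeqDb(subj)
  p1 <- runPass1(subj, db)
  expect_identical(nrow(p1$runs), 1L)
  expect_identical(p1$runs$qstart, 0L)
  expect_identical(p1$runs$qend, 5000L)
  expect_identical(p1$stats$nUngapped, 1L)
  expect_identical(p1$stats$maxLen, 5000)
})

test_that("taxa in the top three of any pass-1 metric are retained", {
  one <- data.frame(taxid = 7L, nUngapped = 3L, maxLen = 100,
                    sumLen = 200, sumSqLen = 2e4)
  expect_identical(selectTaxa(one), 7L)
  # taxid 10 ranks 4th on three metrics but 2nd on maxLen
  st <- data.frame(taxid = 1:10,
                   nUngapped = c(10:2, 1L), maxLen = c(100, 90, 80, 11:16, 95),
                   sumLen = c(1000, 900, 800, 110:115, 70),
                   sumSqLen = c(1e6, 9e5, 8e5, seq(1e4, 6e4, 1e4), 7e4))
  expect_true(10L %in% selectTaxa(st))
  # cardinality bound: at most 3 x 4 taxa can be selected
  big <- data.frame(taxid = 1:20,
                    nUngapped = sample(1:20), maxLen = sample(1:20),
                    sumLen = sample(1:20), sumSqLen = sample(1:20))
  expect_lte(length(selectTaxa(big)), 12L)
})

test_that("a single SNP splits a pass-2 hit into two flanking segments", {
  subj <- randomDna(2000, seed = 405)
  db <- oneSeqDb(subj)
  q <- subj
  substr(q, 1000, 1000) <-
    c(A = "C", C = "A", G = "T", T = "G")[substr(subj, 1000, 1000)]
  hits <- alignContig(q, db)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$qstart, 0L)
  expect_identical(hits$qend, 2000L)
  segs <- hits$segments[[1]]
  expect_identical(length(segs), 2L)
  expect_identical(sort(segs), c(999L, 1000L))
})

test_that("a small insertion produces a gapped hit spanning the indel", {
  subj <- randomDna(2000, seed = 406)
  db <- oneSeqDb(subj)
  q <- paste0(substr(subj, 1, 1000),
              chartr("ACGT", "CATG", substr(subj, 1001, 1003)),
              substr(subj, 1001, 2000))
  hits <- alignContig(q, db)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$qstart, 0L)
  expect_identical(hits$qend, 2003L)
  expect_gte(length(hits$segments[[1]]), 2L)
  expect_gte(sum(hits$segments[[1]]), 1995L)
})

test_that("pass 2 with no selected taxa returns no hits", {
  subj <- randomDna(2000, seed = 407)
  db <- oneSeqDb(subj)
  p1 <- runPass1(subj, db)
  h <- runPass2(subj, db, integer(0), p1$runs)
  expect_identical(nrow(h), 0L)
})

test_that("each database sequence replayed as a query is nearly self-covered", {
  w <- tinyWorld()
  for (i in seq_along(w$db@sequences)) {
    s <- as.character(w$db@sequences[[i]])
    hits <- alignContig(s, w$db)
    own <- hits[hits$ordinal == i, , drop = FALSE]
    cov <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(own$qstart + 1L, own$qend))))
    expect_gte(cov / nchar(s), 0.99)
  }
})

test_that("screening a query and its reverse complement is symmetric", {
  w <- snWorld()
  q <- deriveStrain(substr(as.character(w$refs$sequences[[1]]), 1, 50000),
                    seed = 408)
  h1 <- alignContig(q, w$db)
  h2 <- alignContig(revComp(q), w$db)
  covBp <- function(h, tax) {
    h <- h[h$taxid == tax, , drop = FALSE]
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(h$qstart + 1L, h$qend))))
  }
  expect_setequal(unique(h1$taxid), unique(h2$taxid))
  for (tax in unique(h1$taxid)) {
    c1 <- covBp(h1, tax); c2 <- covBp(h2, tax)
    expect_lt(abs(c1 - c2) / max(c1, c2), 0.02)
  }
})

test_that("identity segments agree with a dynamic-programming oracle", {
  # pairwiseAlignment is the independent oracle: total exactly-matching bp
  # along its optimal path should be close to the matches our heuristic
  # extension recovers on small diverged pairs
  set.seed(409)
  agree <- logical(20)
  for (i in seq_len(20)) {
    subj <- randomDna(1500)
    db <- oneSeqDb(subj)
    q <- mutateSequence(subj, subRate = 0.015, indelRate = 0.001)
    hits <- alignContig(q, db)
    ours <- sum(unlist(hits$segments))
    pa <- Biostrings::pairwiseAlignment(q, subj, type = "global")
    oracle <- Biostrings::nmatch(pa)
    agree[i] <- abs(ours - oracle) / oracle <= 0.10
  }
  expect_gte(mean(agree), 0.95)
})
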