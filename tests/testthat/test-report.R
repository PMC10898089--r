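mkRecords <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(seqId = r$seqId, seqLen = r$seqLen, division = r$division %||%
                 "prok:a-proteobacteria", category = "contaminant",
               whole = r$whole %||% FALSE, start = r$start, end = r$end,
               score = r$score %||% 500, covFrac = r$covFrac %||% 1,
               action = r$action, kingdom = r$kingdom %||% "Bacteria",
               topSpecies = r$topSpecies %||% "spX",
               stringsAsFactors = FALSE)))
}

test_that("the action report round-trips and is sorted and stable", {
  path <- tempfile(fileext = ".tsv")
  writeActionReport(NULL, path)
  expect_identical(readLines(path),
                   "seq_id\tstart_pos\tend_pos\tseq_len\taction\tdiv\tagg_cont_cov\ttop_tax_name")
  rec <- mkRecords(
    list(seqId = "s2", seqLen = 5000, start = 1, end = 5000, whole = TRUE,
         action = "EXCLUDE"),
    list(seqId = "s1", seqLen = 9000, start = 2000, end = 3000,
         action = "FIX"))
  writeActionReport(rec, path)
  back <- readActionReport(path)
  expect_identical(back$seqId, c("s1", "s2"))
  expect_identical(back$start, c(2000L, 1L))
  expect_identical(back$end, c(3000L, 5000L))
  expect_identical(back$action, c("FIX", "EXCLUDE"))
  # whole-sequence convention: 1..length
  expect_identical(back$start[2], 1L)
  expect_identical(back$end[2], back$seqLen[2])
  # FIX range excludes both termini
  expect_gt(back$start[1], 1L)
  expect_lt(back$end[1], back$seqLen[1])
  # rewriting is byte-identical
  p2 <- tempfile()
  writeActionReport(rec, p2)
  expect_identical(readBin(path, "raw", 1e5), readBin(p2, "raw", 1e5))
})

test_that("cleaning removes exactly what the corrective actions specify", {
  set.seed(601)
  fa <- Biostrings::DNAStringSet(c(a = randomDna(3000), b = randomDna(4000),
                                   c = randomDna(5000)))
  rec <- mkRecords(
    list(seqId = "a", seqLen = 3000, start = 1, end = 3000, whole = TRUE,
         action = "EXCLUDE"),
    list(seqId = "b", seqLen = 4000, start = 1, end = 500, action = "TRIM"),
    list(seqId = "c", seqLen = 5000, start = 2001, end = 2500,
         action = "FIX"))
  out <- applyActions(fa, rec)
  expect_false("a" %in% names(out$cleaned))
  expect_true("a" %in% names(out$binned))
  expect_identical(as.character(out$cleaned[["b"]]),
                   substring(as.character(fa[["b"]]), 501))
  # FIX splits and renames the parts
  expect_setequal(setdiff(names(out$cleaned), "b"), c("c.1", "c.2"))
  expect_identical(nchar(as.character(out$cleaned[["c.1"]])), 2000L)
  # conservation: cleaned length == input length - removed spans
  expect_identical(sum(Biostrings::width(out$cleaned)),
                   sum(Biostrings::width(fa)) - 3000L - 500L - 500L)
})

test_that("non-corrective actions and empty reports leave the FASTA alone", {
  fa <- Biostrings::DNAStringSet(c(a = randomDna(2000, seed = 602),
                                   b = randomDna(999)))
  out <- applyActions(fa, mkRecords(
    list(seqId = "a", seqLen = 2000, start = 1, end = 2000, whole = TRUE,
         action = "REVIEW"),
    list(seqId = "a", seqLen = 2000, start = 10, end = 500,
         action = "REVIEW_RARE"),
    list(seqId = "b", seqLen = 999, start = 1, end = 100, action = "INFO")))
  expect_identical(as.character(out$cleaned), as.character(fa))
  expect_identical(length(out$binned), 0L)
  # empty report is the identity
  empty <- applyActions(fa, emptyRecords())
  expect_identical(as.character(empty$cleaned), as.character(fa))
  # the recommended 1-kbp minimum drops short clean sequences
  dropped <- applyActions(fa, emptyRecords(), minSeqLen = 1000)
  expect_identical(names(dropped$cleaned), "a")
})

test_that("randomized non-corrective reports never alter sequences", {
  set.seed(603)
  fa <- Biostrings::DNAStringSet(setNames(
    vapply(1:5, function(i) randomDna(sample(500:2000, 1)), ""),
    paste0("q", 1:5)))
  for (i in 1:10) {
    n <- sample(1:6, 1)
    ids <- sample(names(fa), n, replace = TRUE)
    lens <- Biostrings::width(fa)[match(ids, names(fa))]
    st <- vapply(lens, function(l) sample.int(l, 1), 0L)
    en <- pmin(st + sample(50:400, n, replace = TRUE), lens)
    rec <- data.frame(seqId = ids, seqLen = lens, start = st, end = en,
                      action = sample(c("INFO", "REVIEW", "REVIEW_RARE"), n,
                                      replace = TRUE),
                      division = "dX", covFrac = 1, topSpecies = "x",
                      stringsAsFactors = FALSE)
    out <- applyActions(fa, rec)
    expect_identical(as.character(out$cleaned), as.character(fa))
  }
})

test_that("a report range outside its sequence is a hard error", {
  fa <- Biostrings::DNAStringSet(c(a = randomDna(100, seed = 604)))
  bad <- mkRecords(list(seqId = "a", seqLen = 100, start = 50, end = 200,
                        action = "TRIM"))
  expect_error(applyActions(fa, bad), "corrupt report")
  missing <- mkRecords(list(seqId = "zz", seqLen = 100, start = 1, end = 10,
                            action = "FIX"))
  expect_error(applyActions(fa, missing), "absent from the FASTA")
})
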