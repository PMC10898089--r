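test_that("scaffolds split at N runs of 10 or more, never below", {
  c2 <- splitOnNRuns(paste0("ACGT", strrep("N", 10), "ACGT"), "s")
  expect_identical(nrow(c2), 2L)
  expect_identical(c2$start, c(0L, 14L))
  expect_identical(c2$sequence, c("ACGT", "ACGT"))
  c1 <- splitOnNRuns(paste0("ACGT", strrep("N", 9), "ACGT"), "s")
  expect_identical(nrow(c1), 1L)
  expect_identical(nrow(splitOnNRuns(strrep("N", 50), "s")), 0L)
})

test_that("contigs and their offsets reconstruct the scaffold exactly", {
  set.seed(301)
  for (i in 1:10) {
    pieces <- replicate(4, randomDna(sample(30:200, 1)))
    gaps <- replicate(3, strrep("N", sample(c(3, 10, 25), 1)))
    scaffold <- paste0(pieces[1], gaps[1], pieces[2], gaps[2],
                       pieces[3], gaps[3], pieces[4])
    ct <- splitOnNRuns(scaffold, "s")
    rebuilt <- strsplit(strrep("N", nchar(scaffold)), "")[[1]]
    for (j in seq_len(nrow(ct))) {
      at <- ct$start[j] + seq_len(ct$length[j])
      rebuilt[at] <- strsplit(ct$sequence[j], "")[[1]]
    }
    # positions outside contigs must be N in the input; short N runs stay
    # inside contigs
    expect_identical(paste(rebuilt, collapse = ""), scaffold)
  }
})

test_that("chunking follows the 100-kbp / 100-bp-overlap convention", {
  expect_identical(nrow(chunkContig(strrep("A", 100000))), 1L)
  ch <- chunkContig(strrep("A", 250100))
  expect_identical(ch$start, c(0L, 99900L, 199800L))
  ch2 <- chunkContig(strrep("A", 100001))
  expect_identical(nrow(ch2), 2L)
  expect_identical(ch2$length[2], 101L)
})

test_that("chunks with overlaps removed concatenate back to the contig", {
  s <- randomDna(250100, seed = 302)
  ch <- chunkContig(s)
  parts <- c(ch$sequence[1],
             vapply(seq_len(nrow(ch))[-1], function(i)
               substring(ch$sequence[i], 101), ""))
  expect_identical(paste(parts, collapse = ""), s)
})

test_that("window entropies match a brute-force hexamer histogram", {
  s <- randomDna(1049, seed = 303)  # 1000 windows of 50 bp
  ent <- hexamerEntropy(s)
  oracle <- vapply(seq_len(nchar(s) - 49), function(p) {
    win <- substring(s, p, p + 49)
    hx <- substring(win, 1:45, 6:50)
    pr <- table(hx) / 45
    -sum(pr * log2(pr))
  }, 0)
  expect_equal(ent, oracle, tolerance = 1e-12)
})

test_that("low-complexity masking toggles at the entropy threshold", {
  # homopolymer: entropy 0, fully masked
  hp <- maskLowComplexity(strrep("A", 200))
  expect_identical(sum(IRanges::width(hp)), 200L)
  # a window whose 45 hexamers are all distinct: entropy log2(45) ~ 5.49
  s <- randomDna(50, seed = 304)
  while (length(unique(substring(s, 1:45, 6:50))) < 45) s <- randomDna(50)
  expect_equal(hexamerEntropy(s), log2(45), tolerance = 1e-12)
  expect_identical(length(maskLowComplexity(s)), 0L)
  # (AC)n dinucleotide repeat: two hexamer types, entropy ~ 1 bit < 4.5
  ac <- strrep("AC", 50)
  eAC <- hexamerEntropy(substring(ac, 1, 50))[1]
  expect_equal(eAC, -(23 / 45) * log2(23 / 45) - (22 / 45) * log2(22 / 45),
               tolerance = 1e-12)
  expect_gt(sum(IRanges::width(maskLowComplexity(ac))), 0L)
  # masking is deterministic / idempotent on the same input
  expect_identical(maskLowComplexity(ac), maskLowComplexity(ac))
})

test_that("planted repeat families are flagged, single-copy flanks are not", {
  spec <- simSpec(divisions = data.frame(
    division = "fung:ascomycetes", kingdom = "Fungi", genomeLength = 1e6,
    stringsAsFactors = FALSE), repeatCopies = 25L)
  refs <- generateReferenceSet(spec, seed = 305)
  g <- as.character(refs$sequences[[1]])
  tp <- detectTransposonHmers(g)
  expect_gt(length(tp$keys), 0)
  masked <- sum(IRanges::width(tp$intervals[[1]]))
  # roughly the repeat content (25 x 800 bp), never a large genome fraction
  expect_gt(masked, 5000)
  expect_lt(masked, 100000)
})

test_that("sequences below the N80 scope contribute nothing to repeat stats", {
  g <- randomDna(400e3, seed = 306)
  phage <- randomDna(3000)
  short <- rep(phage, 30)                       # many identical short pieces
  seqs <- c(g, short)
  tp <- detectTransposonHmers(seqs)
  # scope = min(100 kbp, N80) is dominated by the long scaffold, so the
  # phage copies are excluded from the statistics and nothing is flagged
  expect_identical(length(tp$keys), 0L)
  expect_true(all(lengths(tp$intervals) == 0L))
})
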