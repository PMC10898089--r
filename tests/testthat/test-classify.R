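# helpers to build classifier inputs directly

mkSeqStats <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(seqId = r$seqId %||% "s1", seqLen = r$seqLen %||% 10000,
               division = r$division, kingdom = r$kingdom %||% "Bacteria",
               covBp = r$covBp, score = r$score,
               lcConsBp = r$lcConsBp %||% 0,
               transposonBp = r$transposonBp %||% 0,
               sourceOverlapBp = r$sourceOverlapBp %||% 0,
               stringsAsFactors = FALSE)))
}


mkSummary <- function(id = "s1", len = 10000, divisions, ranges,
                      lcConsBp = NULL, transposonBp = NULL, nHits = NULL) {
  list(id = id, length = len,
       nHits = nHits %||% nrow(divisions),
       divisions = divisions, ranges = ranges,
       lcConsBp = lcConsBp %||% setNames(rep(0, nrow(divisions)),
                                         divisions$division),
       transposonBp = transposonBp %||% setNames(rep(0, nrow(divisions)),
                                                 divisions$division))
}

ctx <- function(declaredKingdom = "Bacteria",
                declaredDivision = "prok:a-proteobacteria",
                primarySet = declaredDivision, aggCoverage = 1,
                genomeLength = 1e6)
  list(declaredKingdom = declaredKingdom, declaredDivision = declaredDivision,
       primarySet = primarySet, aggCoverage = aggCoverage,
       genomeLength = genomeLength)

test_that("aggregate statistics apply the score and coverage boundaries", {
  base <- list(division = "dX", covBp = 9000, score = 150)
  agg <- aggregateDivisions(mkSeqStats(base))
  expect_identical(nrow(agg), 1L)                     # score 150 included
  base$score <- 149
  expect_identical(nrow(aggregateDivisions(mkSeqStats(base))), 0L)
  base$score <- 500; base$covBp <- 8000               # exactly 80%: excluded
  expect_identical(nrow(aggregateDivisions(mkSeqStats(base))), 0L)
  base$covBp <- 8050                                  # 80.5%: included
  expect_identical(nrow(aggregateDivisions(mkSeqStats(base))), 1L)
  expect_identical(nrow(aggregateDivisions(NULL)), 0L)
})

test_that("divisions are flagged only when all four criteria hold", {
  agg <- data.frame(division = "dX", kingdom = "Bacteria",
                    totalBp = 13000, nonRepBp = 12000, lcConsFrac = 0.10,
                    transposonFrac = 0, sourceOverlapFrac = 0.05, nSeqs = 2L)
  expect_identical(flagContaminantDivisions(agg), "dX")
  a <- agg; a$nonRepBp <- 9000                        # (c) fails
  expect_identical(length(flagContaminantDivisions(a)), 0L)
  a <- agg; a$sourceOverlapFrac <- 0.80               # (d) fails
  expect_identical(length(flagContaminantDivisions(a)), 0L)
  a <- agg; a$lcConsFrac <- 0.80                      # (a) fails
  expect_identical(length(flagContaminantDivisions(a)), 0L)
  a <- agg; a$transposonFrac <- 0.80                  # (b) fails
  expect_identical(length(flagContaminantDivisions(a)), 0L)
  expect_identical(length(flagContaminantDivisions(agg, primarySet = "dX")), 0L)
})

test_that("the coverage cutoff follows max(0.2, 0.6 * (1 - fraction))", {
  expect_identical(coverageCutoff(1.0), 0.2)
  expect_identical(coverageCutoff(0.0), 0.6)
  expect_equal(coverageCutoff(2 / 3), 0.2, tolerance = 1e-12)
  expect_equal(coverageCutoff(0.5), 0.3, tolerance = 1e-12)
})

test_that("per-sequence calls obey the flagged/unflagged score boundaries", {
  # same-kingdom division, so only the score rule applies
  dv <- data.frame(division = "dX", kingdom = "Bacteria", covBp = 9500,
                   score = 51, stringsAsFactors = FALSE)
  sm <- mkSummary(divisions = dv,
                  ranges = list(dX = IRanges::IRanges(1, 9500)))
  cc <- ctx()
  call51 <- callSequence(sm, flagged = "dX", context = cc)
  expect_identical(call51$category, "contaminant")
  expect_true(call51$whole)
  sm$divisions$score <- 50
  expect_identical(nrow(callSequence(sm, "dX", cc)), 0L)
  # an inter-kingdom contaminant with >= 80% coverage is called even at
  # score 50
  smI <- sm
  smI$divisions$kingdom <- "Archaea"
  expect_identical(nrow(callSequence(smI, "dX", cc)), 1L)
  # unflagged: needs score > 100 and repeat/conserved content < 50%
  sm$divisions$score <- 101
  call101 <- callSequence(sm, character(0), cc)
  expect_identical(call101$category, "contaminant")
  sm$lcConsBp <- c(dX = 5000)                         # 52% repeats
  expect_identical(nrow(callSequence(sm, character(0), cc)), 0L)
  sm$lcConsBp <- c(dX = 3500)                         # 37%: called again
  expect_identical(nrow(callSequence(sm, character(0), cc)), 1L)
})

test_that("zero alignments yield an inconclusive assignment", {
  sm <- mkSummary(divisions = data.frame(division = character(0),
                                         kingdom = character(0),
                                         covBp = numeric(0),
                                         score = numeric(0)),
                  ranges = list(), nHits = 0L)
  call <- callSequence(sm, character(0), ctx())
  expect_identical(call$category, "inconclusive")
})

test_that("the coverage cutoff gates calls in poorly covered genomes", {
  dv <- data.frame(division = "dX", kingdom = "Archaea", covBp = 3000,
                   score = 400, stringsAsFactors = FALSE)
  sm <- mkSummary(divisions = dv,
                  ranges = list(dX = IRanges::IRanges(1, 3000)))
  # region coverage 30% passes the 0.2 floor but fails the 0.54 cutoff at
  # aggregate coverage 0.1
  expect_identical(nrow(callSequence(sm, "dX", ctx(aggCoverage = 1))), 1L)
  expect_identical(nrow(callSequence(sm, "dX", ctx(aggCoverage = 0.1))), 0L)
})

mkCall <- function(seqId = "s1", division = "dX", kingdom = "Archaea",
                   whole = FALSE, start = 2000, end = 13000, seqLen = 1e5,
                   score = 500, covFrac = 1) {
  data.frame(seqId = seqId, seqLen = seqLen, division = division,
             kingdom = kingdom, category = "contaminant", whole = whole,
             start = if (whole) 1 else start, end = if (whole) seqLen else end,
             score = score, covFrac = covFrac, stringsAsFactors = FALSE)
}

test_that("whole-sequence contaminants are excluded; chimeras trim or fix", {
  cc <- ctx(declaredKingdom = "Fungi", declaredDivision = "fung:ascomycetes")
  expect_identical(assignActions(mkCall(whole = TRUE), cc)$action, "EXCLUDE")
  # internal inter-kingdom span
  expect_identical(assignActions(mkCall(start = 2000, end = 13000), cc)$action,
                   "FIX")
  # terminal spans (within 100 bp of an end)
  expect_identical(assignActions(mkCall(start = 50, end = 13000), cc)$action,
                   "TRIM")
  expect_identical(assignActions(mkCall(start = 95000, end = 99990), cc)$action,
                   "TRIM")
})

test_that("intra-kingdom chimeras are reported only from 10 kbp", {
  cc <- ctx(declaredKingdom = "Archaea", declaredDivision = "arch:euryarchaeota")
  nine <- mkCall(start = 2001, end = 11000)    # 9 kbp, same kingdom
  expect_identical(nrow(assignActions(nine, cc)), 0L)
  eleven <- mkCall(start = 2001, end = 13000)  # 11 kbp
  expect_identical(assignActions(eleven, cc)$action, "REVIEW")
  ten <- mkCall(start = 2001, end = 12000)     # exactly 10 kbp: reported
  expect_identical(assignActions(ten, cc)$action, "REVIEW")
})

test_that("small prokaryote-in-prokaryote contamination is REVIEW_RARE", {
  cc <- ctx(declaredKingdom = "Bacteria", genomeLength = 1e6)
  # a whole 5-kbp archaeal sequence in a bacterial genome: 0.5% of 1 Mbp
  small <- mkCall(whole = TRUE, seqLen = 5000)
  expect_identical(assignActions(small, cc)$action, "REVIEW_RARE")
  # 5% of the genome: cleaned normally
  big <- mkCall(whole = TRUE, seqLen = 50001)
  expect_identical(assignActions(big, cc)$action, "EXCLUDE")
  # eukaryote contamination in a prokaryote is not downgraded
  euk <- mkCall(whole = TRUE, seqLen = 5000, kingdom = "Fungi",
                division = "fung:ascomycetes")
  expect_identical(assignActions(euk, cc)$action, "EXCLUDE")
})

test_that("known lateral-transfer source chimeras are informational", {
  cc <- ctx(declaredKingdom = "Metazoa", declaredDivision = "anml:insects")
  lgt <- mkCall(division = "prok:endosymbionts", kingdom = "Bacteria",
                start = 2000, end = 4000)
  expect_identical(assignActions(lgt, cc)$action, "INFO")
})

test_that("virus calls follow the host-kingdom rules", {
  vdiv <- "virs:eukaryotic-virus"
  # eukaryote host: whole-virus sequences cleaned, chimeric spans ignored
  cc <- ctx(declaredKingdom = "Metazoa", declaredDivision = "anml:primates")
  expect_identical(
    assignActions(mkCall(whole = TRUE, division = vdiv, kingdom = "Viruses"),
                  cc)$action, "EXCLUDE")
  expect_identical(
    nrow(assignActions(mkCall(division = vdiv, kingdom = "Viruses"), cc)), 0L)
  # prokaryote host: all viral elements ignored
  ccP <- ctx(declaredKingdom = "Bacteria")
  expect_identical(
    nrow(assignActions(mkCall(whole = TRUE, division = "virs:prokaryotic-virus",
                              kingdom = "Viruses"), ccP)), 0L)
  # virus host: only cross-superkingdom viral contaminants are reported
  ccV <- ctx(declaredKingdom = "Viruses",
             declaredDivision = "virs:prokaryotic-virus")
  expect_identical(
    assignActions(mkCall(whole = TRUE, division = vdiv, kingdom = "Viruses"),
                  ccV)$action, "EXCLUDE")
  expect_identical(
    nrow(assignActions(mkCall(whole = TRUE,
                              division = "virs:prokaryotic-virus",
                              kingdom = "Viruses"), ccV)), 0L)
  # ...and non-viral contaminants in virus genomes are reported
  expect_identical(
    assignActions(mkCall(whole = TRUE, division = "prok:firmicutes",
                         kingdom = "Bacteria", seqLen = 5e4), ccV)$action,
    "EXCLUDE")
})

test_that("the inferred primary set follows overlap concordance", {
  ir <- function(a, b) IRanges::IRanges(a, b)
  divK <- c(dA = "Bacteria", dB = "Bacteria", dC = "Bacteria")
  db <- tinyWorld()$db
  tracks <- list(
    dA = list(s1 = ir(1, 100000)),
    dB = list(s1 = ir(1, 90000)),     # 90% overlap with dA
    dC = list(s1 = ir(95001, 105000)) # 50% overlap
  )
  # declared dA, high aggregate coverage: dB joins the primary set, dC not
  ps <- inferPrimarySet(tracks, "dA", divK, aggCoverage = 1, db = db)
  expect_setequal(ps$primary, c("dA", "dB"))
  expect_false(ps$wrongTaxid)
  # declared division absent but well represented elsewhere: wrong-taxid path
  w <- snWorld()
  decl <- gxMetadata(w$db)$division[3]  # anml:primates, present in this db
  tracks2 <- list(`prok:a-proteobacteria` = list(s1 = ir(1, 100000)))
  divK2 <- c(`prok:a-proteobacteria` = "Bacteria",
             setNames("Metazoa", decl))
  ps2 <- inferPrimarySet(tracks2, decl, divK2, aggCoverage = 1, db = w$db)
  expect_true(ps2$wrongTaxid)
  expect_identical(ps2$primary, decl)
})
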