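# end-to-end behavior of runScreen() on the shared synthetic world

test_that("a clean genome screened with its own taxid is untouched", {
  w <- snWorld()
  q <- generateQuerySet(w$refs, "fragments", hostTaxid = w$hostTaxid,
                        fragmentSize = 10000, seed = 701)
  scr <- runScreen(q$sequences, w$hostTaxid, w$db, verbose = FALSE)
  expect_identical(nrow(gxRecords(scr)), 0L)
  expect_identical(as.character(gxCleaned(scr)), as.character(q$sequences))
  ev <- evaluateSnSp(scr, q$truth)
  expect_identical(ev$sp, 100)
})

test_that("screening with a wrong well-represented taxid warns and reports", {
  w <- snWorld()
  q <- generateQuerySet(w$refs, "fragments", hostTaxid = w$hostTaxid,
                        fragmentSize = 10000, seed = 702)
  expect_warning(
    scr <- runScreen(q$sequences, w$mockHostTaxid, w$db, verbose = FALSE),
    "check the declared taxid")
  expect_true(gxContext(scr)$wrongTaxid)
  expect_gt(nrow(gxRecords(scr)), 0L)
})

test_that("a 5% contaminated mixture is cleaned, the host untouched", {
  w <- snWorld()
  q <- generateQuerySet(w$refs, "mixture", hostTaxid = w$hostTaxid,
                        contamTaxid = w$contamTaxid, seed = 703)
  scr <- runScreen(q$sequences, w$hostTaxid, w$db, verbose = FALSE)
  ev <- evaluateSnSp(scr, q$truth)
  expect_gte(ev$sn, 95)
  expect_identical(ev$sp, 100)
  # host fragments survive cleaning; contaminant fragments are binned
  hostIds <- q$truth$id[q$truth$sourceTaxid == w$hostTaxid]
  expect_true(all(hostIds %in% names(gxCleaned(scr))))
})

test_that("chimeras with a 10-N separator split into separate contigs", {
  w <- snWorld()
  q <- generateQuerySet(w$refs, "chimera", hostTaxid = w$hostTaxid,
                        contamTaxid = w$contamTaxid, separator = TRUE,
                        seed = 704)
  s <- as.character(q$sequences[[1]])
  ct <- splitOnNRuns(s, "chim")
  expect_identical(nrow(ct), 2L)
  expect_identical(ct$length[2], 1000L)
  # the terminal 1-kbp same-kingdom span is below the 10-kbp chimera limit,
  # so it must not trigger a corrective action
  scr <- runScreen(q$sequences, w$hostTaxid, w$db, verbose = FALSE)
  expect_false(any(gxRecords(scr)$action %in% c("EXCLUDE", "TRIM", "FIX")))
})

test_that("identical inputs and seeds produce byte-identical reports", {
  w <- snWorld()
  q <- generateQuerySet(w$refs, "mixture", hostTaxid = w$hostTaxid,
                        contamTaxid = w$contamTaxid, seed = 705)
  d1 <- file.path(tempdir(), "rerun1"); d2 <- file.path(tempdir(), "rerun2")
  runScreen(q$sequences, w$hostTaxid, w$db, outDir = d1, verbose = FALSE)
  runScreen(q$sequences, w$hostTaxid, w$db, outDir = d2, verbose = FALSE)
  for (f in c("report.tsv", "cleaned.fna", "contaminants.fna")) {
    a <- readBin(file.path(d1, f), "raw", file.size(file.path(d1, f)))
    b <- readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    expect_identical(a, b)
  }
})

test_that("an undeclared taxid fails before any alignment work", {
  w <- snWorld()
  expect_error(runScreen(Biostrings::DNAStringSet(c(q = randomDna(200))),
                         999999L, w$db), "not present")
})

test_that("replicate seeds reproduce simulations to the last digit", {
  w <- snWorld()
  q1 <- generateQuerySet(w$refs, "mixture", hostTaxid = w$hostTaxid,
                         contamTaxid = w$contamTaxid, seed = 706)
  q2 <- generateQuerySet(w$refs, "mixture", hostTaxid = w$hostTaxid,
                         contamTaxid = w$contamTaxid, seed = 706)
  expect_identical(as.character(q1$sequences), as.character(q2$sequences))
  expect_identical(q1$truth, q2$truth)
  q3 <- generateQuerySet(w$refs, "mixture", hostTaxid = w$hostTaxid,
                         contamTaxid = w$contamTaxid, seed = 707)
  expect_false(identical(as.character(q1$sequences),
                         as.character(q3$sequences)))
})

test_that("divergence-free strains reproduce their reference", {
  w <- tinyWorld()
  g <- as.character(w$refs$sequences[[1]])
  expect_identical(deriveStrain(g, divergence = 0, indelRate = 0), g)
  s <- deriveStrain(g, divergence = 0.01, indelRate = 0, seed = 708)
  ident <- mean(strsplit(s, "")[[1]] == strsplit(g, "")[[1]])
  expect_gt(ident, 0.985)
  expect_lt(ident, 0.995)
})
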