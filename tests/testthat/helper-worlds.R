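# Shared synthetic worlds, built once per test run (cached in an environment).
# Sizes are kept small so the whole suite stays fast on one CPU; the methods
# vignette records the problem sizes.

.worldCache <- new.env(parent = emptyenv())

.cached <- function(key, build) {
  if (!exists(key, .worldCache)) assign(key, build(), .worldCache)
  get(key, .worldCache)
}

# two bacterial divisions, one species each, 60-kbp genomes
tinyWorld <- function() .cached("tiny", function() {
  spec <- simSpec(divisions = data.frame(
    division = c("prok:a-proteobacteria", "prok:enterobacteria"),
    kingdom = "Bacteria", genomeLength = 60e3, stringsAsFactors = FALSE))
  refs <- generateReferenceSet(spec, seed = 42)
  list(spec = spec, refs = refs,
       db = buildGxDatabase(refs$sequences, refs$taxonomy, refs$taxids))
})

# the sensitivity/specificity world: a 400-kbp bacterial host species, a
# second bacterial division, and a metazoan division usable as a
# cross-kingdom mock host
snWorld <- function() .cached("sn", function() {
  spec <- simSpec()
  spec$divisions <- spec$divisions[c(1, 2, 5), ]  # a-proteo, entero, primates
  spec$divisions$genomeLength <- c(400e3, 150e3, 150e3)
  refs <- generateReferenceSet(spec, seed = 42)
  db <- buildGxDatabase(refs$sequences, refs$taxonomy, refs$taxids)
  list(spec = spec, refs = refs, db = db,
       hostTaxid = refs$taxonomy$taxid[1],
       contamTaxid = refs$taxonomy$taxid[2],
       mockHostTaxid = refs$taxonomy$taxid[3])
})

# a single-subject database built from one explicit sequence (for targeted
# aligner fixtures)
oneSeqDb <- function(seq, division = "prok:a-proteobacteria",
                     kingdom = "Bacteria", taxid = 900L, id = "subj1") {
  tax <- data.frame(taxid = taxid, species = paste0("sp", taxid),
                    division = division, kingdom = kingdom,
                    stringsAsFactors = FALSE)
  buildGxDatabase(Biostrings::DNAStringSet(setNames(seq, id)), tax, taxid)
}

randomDna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force packing oracle: drop wobble positions (i %% 3 == 2, 0-based),
# encode A,G -> 0 and C,T -> 1, big-endian into a double
packOracle <- function(window) {
  b <- strsplit(window, "")[[1]]
  keep <- b[(seq_along(b) - 1L) %% 3L != 2L]
  bits <- as.numeric(keep %in% c("C", "T"))
  sum(bits * 2^rev(seq_along(bits) - 1L))
}

revComp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

`%||%` <- function(a, b) if (is.null(a)) b else a

emptyRecords <- function()
  data.frame(seqId = character(0), seqLen = integer(0), start = integer(0),
             end = integer(0), action = character(0), division = character(0),
             covFrac = numeric(0), topSpecies = character(0),
             stringsAsFactors = FALSE)
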