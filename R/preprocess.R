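#' Split a scaffold into contigs on runs of Ns
#'
#' Contaminants are often assembled as whole contigs inside larger scaffolds,
#' so screening operates on contigs: scaffolds are split at every maximal run
#' of `minRun` or more Ns (assembly gap convention). Shorter N runs are
#' retained and pseudorandom-filled downstream.
#'
#' @param seq Scaffold sequence (character or `DNAString`).
#' @param id Scaffold identifier (used in contig ids).
#' @param minRun Minimum N-run length that splits, in bp (default 10).
#' @return data.frame with one row per contig: `scaffoldId`, `contigIndex`,
#'   `start` (0-based offset in the scaffold), `length`, `sequence`. An
#'   all-N scaffold yields zero rows; offsets reconstruct the scaffold layout.
#' @examples
#' splitOnNRuns(paste0("ACGT", strrep("N", 10), "ACGT"), "s1")[, 1:4]
#' @export
splitOnNRuns <- function(seq, id = "scaffold", minRun = 10L) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  gaps <- gregexpr(sprintf("N{%d,}", minRun), seq)[[1]]
  if (gaps[1] == -1L) {
    starts <- 1L; ends <- n
  } else {
    gs <- as.integer(gaps)
    ge <- gs + attr(gaps, "match.length") - 1L
    starts <- c(1L, ge + 1L)
    ends <- c(gs - 1L, n)
  }
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts))
    return(data.frame(scaffoldId = character(0), contigIndex = integer(0),
                      start = integer(0), length = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  data.frame(
    scaffoldId = id, contigIndex = seq_along(starts),
    start = starts - 1L, length = ends - starts + 1L,
    sequence = substring(seq, starts, ends),
    stringsAsFactors = FALSE)
}

#' Chunk a contig for alignment
#'
#' To cap working memory, contigs are aligned in 100-kbp chunks overlapping
#' by 100 bp; chunk hits are later recombined as if the contig had been
#' aligned whole. Chunk starts advance by `chunkSize - overlap` and a contig
#' no longer than `chunkSize` yields a single chunk.
#'
#' @param seq Contig sequence (character or `DNAString`).
#' @param chunkSize Chunk length in bp (default 100,000).
#' @param overlap Overlap between consecutive chunks in bp (default 100).
#' @return data.frame with `start` (0-based), `length`, `sequence`.
#' @examples
#' chunkContig(strrep("A", 250100))[, c("start", "length")]
#' @export
chunkContig <- function(seq, chunkSize = 100000L, overlap = 100L) {
  seq <- as.character(seq)
  n <- nchar(seq)
  starts <- integer(0)
  s <- 0L
  repeat {
    starts <- c(starts, s)
    e <- min(s + chunkSize, n)
    if (e >= n) break
    s <- s + chunkSize - overlap
  }
  ends <- pmin(starts + chunkSize, n)
  data.frame(start = starts, length = ends - starts,
             sequence = substring(seq, starts + 1L, ends),
             stringsAsFactors = FALSE)
}

#' Fill ambiguous bases with reproducible pseudorandom bases
#'
#' Non-ACGT positions (IUPAC ambiguity codes, hardmasked Ns below the
#' scaffold-split threshold) are replaced with pseudorandom A/C/G/T drawn
#' from a generator seeded by the sequence id and position, so the same
#' input always fills identically. Filled positions are flagged and never
#' count toward 100%-identity segments during alignment scoring.
#'
#' @param seq Sequence (character or `DNAString`).
#' @param id Sequence identifier used in the fill seed.
#' @return list with `seq` (filled, uppercase) and `fill` (integer vector of
#'   1-based filled positions).
#' @export
fillAmbiguousBases <- function(seq, id = "seq") {
  res <- cpp_fill_ambiguous(id, as.character(seq))
  list(seq = res$seq, fill = as.integer(res$fill))
}

#' Hexamer Shannon entropy in sliding windows
#'
#' @param seq Sequence of A/C/G/T bases.
#' @param window Window size in bp (default 50; a 50-bp window holds 45
#'   overlapping hexamers).
#' @return Numeric vector of per-window entropies in bits (step 1 bp).
#'   Sequences shorter than the window yield a single entropy for the full
#'   sequence when it holds at least one hexamer, otherwise an empty vector.
#' @seealso [maskLowComplexity()]
#' @export
hexamerEntropy <- function(seq, window = 50L) {
  cpp_entropy_windows(toupper(as.character(seq)), as.integer(window))
}

#' Mask low-complexity regions
#'
#' Slides a 50-bp window over the sequence and flags windows whose hexamer
#' Shannon entropy falls below the threshold (4.5 bits); flagged windows are
#' merged into maximal intervals. A uniform distribution over the 45 window
#' hexamers has entropy log2(45) ~ 5.49 bits, so typical sequence is left
#' unmasked while homopolymers and short tandem repeats fall far below the
#' threshold.
#'
#' @param seq Sequence of A/C/G/T bases.
#' @param window Window size in bp.
#' @param threshold Entropy threshold in bits (default 4.5).
#' @return An [IRanges::IRanges] of masked intervals (1-based, inclusive).
#' @examples
#' maskLowComplexity(strrep("AC", 100))   # fully masked
#' @export
maskLowComplexity <- function(seq, window = 50L, threshold = 4.5) {
  seq <- toupper(as.character(seq))
  ent <- cpp_entropy_windows(seq, as.integer(window))
  if (!length(ent)) return(IRanges())
  w <- min(window, nchar(seq))
  below <- which(ent < threshold)
  if (!length(below)) return(IRanges())
  reduce(IRanges(start = below, width = w))
}

#' Assembly Nxx length
#'
#' Length L such that sequences of length >= L contain at least `frac` of the
#' total assembly bases (N50 for `frac = 0.5`, N80 for `frac = 0.8`).
#'
#' @param lengths Sequence lengths in bp.
#' @param frac Cumulative fraction (default 0.8).
#' @return The Nxx length in bp (0 for an empty set).
#' @export
assemblyN80 <- function(lengths, frac = 0.8) {
  if (!length(lengths)) return(0)
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= frac * sum(s))[1L]]
}

#' Detect transposon-like repeats as overrepresented h-mers
#'
#' Eukaryote genomes carry high-copy transposable elements that would
#' otherwise generate cross-division alignment noise. h-mer counts are
#' computed over the query's own genomic sequences, restricted to sequences
#' whose source scaffold is at least `min(100 kbp, scaffold N80)` long (so a
#' genome made of many short similar sequences -- egregious contamination
#' rather than a repeat family -- contributes nothing); h-mers whose
#' genome-wide count exceeds the overrepresentation cutoff are flagged and
#' the query positions they cover become transposon intervals. Transposon
#' masking is not used for prokaryote or virus queries.
#'
#' @param seqs Character vector or `DNAStringSet` of (filled) contig
#'   sequences for the whole query genome.
#' @param scaffoldLengths Lengths of the assembly scaffolds before splitting
#'   on Ns (used for the N80 scope rule); defaults to the contig lengths.
#' @param contigScaffold Integer index mapping each contig to its scaffold.
#' @param stride h-mer sampling stride in bp for the statistic. The default
#'   of 1 counts every window, so repeat copies are counted regardless of
#'   their phase relative to a sampling grid.
#' @param k h-mer window size.
#' @param scopeLimit Absolute scope cap in bp (default 100,000).
#' @param cutoffFloor,cutoffMult The overrepresentation cutoff is
#'   `max(cutoffFloor, cutoffMult * expected count under uniform sampling)`;
#'   at desk scale the floor (default 10) governs.
#' @return list with `keys` (flagged h-mer key values), `cutoff`, and
#'   `intervals` (list of [IRanges::IRanges] of transposon intervals, one per
#'   contig).
#' @export
detectTransposonHmers <- function(seqs, scaffoldLengths = NULL,
                                  contigScaffold = NULL,
                                  stride = 1L, k = 56L,
                                  scopeLimit = 100000L,
                                  cutoffFloor = 10, cutoffMult = 5) {
  seqs <- as.character(seqs)
  nc <- nchar(seqs)
  if (is.null(scaffoldLengths)) scaffoldLengths <- nc
  if (is.null(contigScaffold)) contigScaffold <- seq_along(seqs)
  scope <- min(scopeLimit, assemblyN80(scaffoldLengths))
  eligible <- scaffoldLengths[contigScaffold] >= scope

  hm <- lapply(seqs, extractHmers, stride = stride, k = k)
  pooled <- unlist(lapply(hm[eligible], `[[`, "key"), use.names = FALSE)
  empty <- list(keys = numeric(0), cutoff = Inf,
                intervals = replicate(length(seqs), IRanges(), simplify = FALSE))
  if (is.null(pooled) || !length(pooled)) return(empty)
  cutoff <- max(cutoffFloor, cutoffMult * length(pooled) / 2^cpp_hmer_key(strrep("A", k))$bits)
  srt <- sort(pooled)
  r <- rle(srt)
  flagged <- r$values[r$lengths > cutoff]
  intervals <- lapply(hm, function(h) {
    if (!nrow(h) || !length(flagged)) return(IRanges())
    hit <- h$pos[!is.na(match(h$key, flagged))]
    if (!length(hit)) return(IRanges())
    reduce(IRanges(hit + 1L, width = k))
  })
  list(keys = flagged, cutoff = cutoff, intervals = intervals)
}
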