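#' Aligner tuning parameters
#'
#' @param ... Name-value overrides of the defaults below.
#' @return A list of parameters:
#' \describe{
#'   \item{queryStride}{query h-mer sampling stride in pass 1 (1 bp: every
#'     position is looked up).}
#'   \item{diagWindow,antidiagWindow}{seed noise filter: a seed survives only
#'     if another seed lies within 1 kbp on the diagonal AND 10 kbp on the
#'     antidiagonal.}
#'   \item{mergeGap}{same-diagonal surviving seeds within this distance are
#'     merged into one ungapped run (1 kbp).}
#'   \item{k2}{pass-2 query-index window size (30 bp -> 20-bit keys).}
#'   \item{neighborhood}{subject neighborhood half-width around pass-1 loci;
#'     the effective width is `min(neighborhood, 2 * query length)`.}
#'   \item{xDrop}{ungapped extension X-drop (match +1, mismatch -3).}
#'   \item{gapSearch}{indels are sought within this many bp of the alignment
#'     end during gapped extension (25).}
#'   \item{minSegment}{a gapped extension step must yield an exact segment of
#'     at least this many bp to continue (8).}
#'   \item{minMatches}{minimum total identity bp for a pass-2 hit to be kept.}
#'   \item{topTaxa}{taxa in the top `topTaxa` of any pass-1 metric go to
#'     pass 2 (3).}
#'   \item{chunkSize,chunkOverlap}{contig chunking for alignment.}
#'   \item{maxBucket,maxBucket2}{repetitive-key guards: database buckets /
#'     query-index buckets larger than this are skipped during seeding.}
#'   \item{maxSeeds}{hard cap on collected pass-1 seeds per chunk.}
#' }
#' @export
gxAlignParams <- function(...) {
  p <- list(
    queryStride = 1L,
    diagWindow = 1000L, antidiagWindow = 10000L, mergeGap = 1000L,
    k2 = 30L, neighborhood = 100000L,
    xDrop = 30L, gapSearch = 25L, minSegment = 8L, minMatches = 40L,
    topTaxa = 3L, chunkSize = 100000L, chunkOverlap = 100L,
    maxBucket = 1000L, maxBucket2 = 200L, maxSeeds = 5e6)
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown alignment parameter(s): ", paste(bad, collapse = ", "))
  for (n in names(ov)) p[[n]] <- ov[[n]]
  p
}

#' Alignment score of a set of identity segments
#'
#' The score of an alignment is the square root of the sum of squares of the
#' lengths of its maximal 100%-identity segments. Clustered mismatches
#' therefore cost less than the same number of mismatches spread across the
#' alignment: two 60-bp segments score ~84.9 while one unbroken 120-bp
#' segment scores 120.
#'
#' @param segments Integer vector of 100%-identity segment lengths in bp.
#' @return The score (0 for an empty segment list).
#' @examples
#' scoreAlignment(c(30, 40))  # 50
#' @export
scoreAlignment <- function(segments) {
  if (!length(segments)) return(0)
  sqrt(sum(as.numeric(segments)^2))
}

# positions (1-based) covered by an IRanges, as an integer vector
.rangePositions <- function(ir, maxLen = NULL) {
  if (is.null(ir) || length(ir) == 0L) return(integer(0))
  ir <- reduce(ir)
  p <- unlist(lapply(seq_along(ir), function(i)
    seq.int(start(ir)[i], end(ir)[i])), use.names = FALSE)
  if (!is.null(maxLen)) p <- p[p >= 1L & p <= maxLen]
  as.integer(p)
}

.subjectKeep <- function(db, excludeTaxa) {
  if (is.null(excludeTaxa)) rep(TRUE, nrow(db@metadata))
  else !(db@metadata$taxid %in% as.integer(excludeTaxa))
}

#' Pass 1: seed collection, noise filtering and ungapped runs
#'
#' Every query h-mer is looked up in the database; the resulting seeds
#' (query position, subject, subject position, relative orientation) pass a
#' noise filter requiring a close neighbor within 1 kbp on the diagonal and
#' 10 kbp on the antidiagonal. Surviving same-diagonal seeds within 1 kbp
#' are merged into ungapped runs, runs are X-drop extended on their diagonal,
#' and per taxon only the best-scoring alignments among those overlapping on
#' query coordinates are kept.
#'
#' @param chunk Query chunk sequence (character or `DNAString`, ACGT only).
#' @param db A [GxDatabase-class].
#' @param skip Optional [IRanges::IRanges] (1-based) of query intervals
#'   excluded from seeding (low-complexity + transposon masks).
#' @param fill Optional integer vector of 1-based pseudorandom-filled query
#'   positions (never count as identity).
#' @param excludeTaxa Taxids whose subjects are ignored (simulates screening
#'   a species absent from the database).
#' @param params [gxAlignParams()].
#' @return list with `runs` (data.frame: ordinal, taxid, strand, qstart/qend
#'   and sstart/send 0-based half-open, len, score, nseg, plus a `segments`
#'   list column of identity-segment lengths) and `stats` (per-taxon pass-1
#'   metrics: nUngapped, maxLen, sumLen, sumSqLen).
#' @export
runPass1 <- function(chunk, db, skip = NULL, fill = NULL,
                     excludeTaxa = NULL, params = gxAlignParams()) {
  chunk <- toupper(as.character(chunk))
  skipPos <- .rangePositions(skip, nchar(chunk))
  res <- cpp_pass1(chunk,
                   skipPos, as.integer(fill %||% integer(0)),
                   db@nodeKey, db@nodeOrdinal, db@nodePos,
                   as.character(db@sequences), db@fill,
                   db@metadata$taxid, .subjectKeep(db, excludeTaxa),
                   db@k, params$queryStride,
                   params$diagWindow, params$antidiagWindow, params$mergeGap,
                   params$xDrop, params$maxBucket, params$maxSeeds)
  runs <- res$runs
  runs$segments <- res$segments
  list(runs = runs, stats = pass1Stats(runs))
}

# per-taxon aggregate metrics over pass-1 runs
pass1Stats <- function(runs) {
  if (!nrow(runs))
    return(data.frame(taxid = integer(0), nUngapped = integer(0),
                      maxLen = numeric(0), sumLen = numeric(0),
                      sumSqLen = numeric(0)))
  sp <- split(as.numeric(runs$len), runs$taxid)
  data.frame(
    taxid = as.integer(names(sp)),
    nUngapped = vapply(sp, length, 0L),
    maxLen = vapply(sp, max, 0),
    sumLen = vapply(sp, sum, 0),
    sumSqLen = vapply(sp, function(l) sum(l^2), 0),
    row.names = NULL)
}

#' Select taxa for the second alignment pass
#'
#' Taxa placed in the top `topN` (default 3) of any of the four pass-1
#' metrics -- number of ungapped alignments, maximum alignment length,
#' summed alignment length, summed squared alignment length -- are retained.
#' Ties break deterministically by (metric value, taxid).
#'
#' @param stats Per-taxon metrics from [runPass1()] (rows may be pooled over
#'   chunks before selection).
#' @param topN Rank cutoff per metric.
#' @return Integer vector of selected taxids (at most `4 * topN`).
#' @export
selectTaxa <- function(stats, topN = 3L) {
  if (!nrow(stats)) return(integer(0))
  pick <- function(v) stats$taxid[order(-v, stats$taxid)][seq_len(min(topN, nrow(stats)))]
  sort(unique(c(pick(stats$nUngapped), pick(stats$maxLen),
                pick(stats$sumLen), pick(stats$sumSqLen))))
}

#' Pass 2: refined seed-and-extend alignment for selected taxa
#'
#' The query chunk is indexed on the fly with smaller h-mers (30-bp windows,
#' 20-bit keys); subject neighborhoods around the pass-1 loci (width
#' `min(100 kbp, 2 x query length)`) of each selected taxon are scanned
#' against the query index. Seeds are extended ungapped and then gapped:
#' repeatedly the indel near the alignment end yielding the highest-identity
#' continuation seed is taken, while the continuation still produces a
#' significant ungapped segment.
#'
#' @inheritParams runPass1
#' @param selectedTaxa Taxids retained by [selectTaxa()].
#' @param pass1Runs `runs` data.frame from [runPass1()] for this chunk
#'   (supplies the subject loci around which neighborhoods are built).
#' @return data.frame of hits: ordinal, taxid, strand, qstart/qend,
#'   sstart/send (0-based half-open, forward subject coordinates), matches,
#'   score, nseg and a `segments` list column.
#' @export
runPass2 <- function(chunk, db, selectedTaxa, pass1Runs,
                     skip = NULL, fill = NULL, params = gxAlignParams()) {
  chunk <- toupper(as.character(chunk))
  selOrd <- db@metadata$ordinal[db@metadata$taxid %in% selectedTaxa]
  keep <- pass1Runs$ordinal %in% selOrd
  res <- cpp_pass2(chunk,
                   .rangePositions(skip, nchar(chunk)),
                   as.integer(fill %||% integer(0)),
                   as.character(db@sequences), db@fill, db@metadata$taxid,
                   as.integer(selOrd),
                   as.integer(pass1Runs$ordinal[keep]),
                   as.integer(pass1Runs$sstart[keep]),
                   as.integer(pass1Runs$send[keep]),
                   params$k2, params$neighborhood, params$xDrop,
                   params$gapSearch, params$minSegment, params$minMatches,
                   params$maxBucket2)
  hits <- res$hits
  hits$segments <- res$segments
  hits
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Align a whole contig against the database
#'
#' Runs the full two-pass alignment on a contig: the contig is cut into
#' 100-kbp chunks with 100-bp overlaps, pass 1 runs per chunk, the per-taxon
#' metrics are pooled to select taxa, pass 2 runs per chunk, and chunk hits
#' are merged back to contig coordinates as if the contig had been aligned
#' whole (overlap duplicates collapsed, abutting same-diagonal hits merged).
#'
#' @inheritParams runPass1
#' @param masks Optional list with `lowComplexity` and `transposon`
#'   [IRanges::IRanges] in contig coordinates (excluded from seeding, still
#'   available to extension).
#' @return data.frame of hits in contig coordinates (see [runPass2()]).
#' @export
alignContig <- function(contig, db, masks = NULL, fill = NULL,
                        excludeTaxa = NULL, params = gxAlignParams()) {
  contig <- toupper(as.character(contig))
  n <- nchar(contig)
  if (n < db@k) return(.emptyHits())
  chunks <- chunkContig(contig, params$chunkSize, params$chunkOverlap)
  skipIR <- NULL
  if (!is.null(masks)) {
    both <- c(masks$lowComplexity %||% IRanges(), masks$transposon %||% IRanges())
    if (length(both)) skipIR <- reduce(both)
  }
  fill <- as.integer(fill %||% integer(0))

  p1 <- vector("list", nrow(chunks))
  for (i in seq_len(nrow(chunks))) {
    cs <- chunks$start[i]; ce <- cs + chunks$length[i]
    sk <- .shiftRanges(skipIR, cs, ce)
    fl <- fill[fill > cs & fill <= ce] - cs
    p1[[i]] <- runPass1(chunks$sequence[i], db, skip = sk, fill = fl,
                        excludeTaxa = excludeTaxa, params = params)
  }
  allRuns <- do.call(rbind, lapply(seq_along(p1), function(i) {
    r <- p1[[i]]$runs
    if (nrow(r)) { r$qstart <- r$qstart + chunks$start[i]
                   r$qend <- r$qend + chunks$start[i] }
    r
  }))
  if (is.null(allRuns) || !nrow(allRuns)) return(.emptyHits())
  sel <- selectTaxa(pass1Stats(allRuns), params$topTaxa)

  hits <- vector("list", nrow(chunks))
  for (i in seq_len(nrow(chunks))) {
    cs <- chunks$start[i]; ce <- cs + chunks$length[i]
    sk <- .shiftRanges(skipIR, cs, ce)
    fl <- fill[fill > cs & fill <= ce] - cs
    h <- runPass2(chunks$sequence[i], db, sel, p1[[i]]$runs,
                  skip = sk, fill = fl, params = params)
    if (nrow(h)) { h$qstart <- h$qstart + cs; h$qend <- h$qend + cs }
    hits[[i]] <- h
  }
  .mergeChunkHits(do.call(rbind, hits))
}

.emptyHits <- function() {
  h <- data.frame(ordinal = integer(0), taxid = integer(0), strand = integer(0),
                  qstart = integer(0), qend = integer(0),
                  sstart = integer(0), send = integer(0),
                  matches = numeric(0), score = numeric(0), nseg = integer(0))
  h$segments <- list()
  h
}

# clip ranges to (cs, ce] (0-based chunk bounds) and shift to chunk coords
.shiftRanges <- function(ir, cs, ce) {
  if (is.null(ir) || !length(ir)) return(NULL)
  ir <- ir[start(ir) <= ce & end(ir) > cs]  # drop ranges outside the chunk
  if (!length(ir)) return(NULL)
  ir <- IRanges(pmax(start(ir), cs + 1L), pmin(end(ir), ce))
  IRanges::shift(ir, -cs)
}

# collapse duplicate hits from chunk overlaps; merge abutting same-diagonal
# hits; drop hits nearly contained in a better hit of the same subject/strand
.mergeChunkHits <- function(hits) {
  if (is.null(hits) || !nrow(hits)) return(.emptyHits())
  hits <- hits[!duplicated(hits[, c("ordinal", "strand", "qstart", "qend",
                                    "sstart", "send")]), , drop = FALSE]
  hits$diag <- hits$qstart - ifelse(hits$strand == 1L, hits$sstart, -hits$send)
  out <- list()
  for (key in unique(paste(hits$ordinal, hits$strand))) {
    h <- hits[paste(hits$ordinal, hits$strand) == key, , drop = FALSE]
    h <- h[order(h$qstart, -h$score), , drop = FALSE]
    merged <- list()
    for (r in seq_len(nrow(h))) {
      row <- h[r, , drop = FALSE]
      if (length(merged)) {
        last <- merged[[length(merged)]]
        sameDiag <- abs(row$diag - last$diag) <= 25L
        if (sameDiag && row$qstart <= last$qend + 100L && row$qend > last$qend) {
          last$qend <- row$qend
          last$sstart <- min(last$sstart, row$sstart)
          last$send <- max(last$send, row$send)
          last$segments[[1L]] <- c(last$segments[[1L]], row$segments[[1L]])
          last$matches <- last$matches + row$matches
          last$score <- scoreAlignment(last$segments[[1L]])
          last$nseg <- length(last$segments[[1L]])
          merged[[length(merged)]] <- last
          next
        }
        if (row$qend <= last$qend) next  # contained in the previous hit
      }
      merged[[length(merged) + 1L]] <- row
    }
    out <- c(out, merged)
  }
  res <- do.call(rbind, out)
  res$diag <- NULL
  res[order(res$qstart, res$taxid, res$ordinal), , drop = FALSE]
}
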