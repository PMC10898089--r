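#' @title GxScreen: the result of screening one assembly
#'
#' @description Holds the finalized action records, per-sequence reports,
#' the screening context (declared lineage, aggregate coverage, inferred
#' primary set), the cleaned sequences and the binned contaminants.
#'
#' @slot records Action records (see [writeActionReport()] for the layout).
#' @slot calls All contaminant calls before action filtering.
#' @slot sequenceReports Per-sequence summaries (species/division evidence).
#' @slot inconclusive Ids of sequences with zero database alignments.
#' @slot context Screening context list.
#' @slot cleaned,binned `DNAStringSet`: input minus removed material, and
#'   the removed material.
#' @export
setClass("GxScreen", representation(
  records = "data.frame",
  calls = "data.frame",
  sequenceReports = "list",
  inconclusive = "character",
  context = "list",
  cleaned = "DNAStringSet",
  binned = "DNAStringSet"
))

setMethod("show", "GxScreen", function(object) {
  ctx <- object@context
  cat(sprintf("GxScreen: %d sequence(s) screened against %d-division database\n",
              length(object@sequenceReports),
              length(ctx$divisionKingdoms)))
  cat(sprintf("  declared: taxid %s (%s, %s); aggregate coverage %.1f%%\n",
              ctx$declaredTaxid, ctx$declaredDivision, ctx$declaredKingdom,
              100 * ctx$aggCoverage))
  if (isTRUE(ctx$wrongTaxid))
    cat("  WARNING: ", ctx$primaryMessage, "\n", sep = "")
  if (nrow(object@records)) {
    tab <- table(object@records$action)
    cat("  actions: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  } else cat("  actions: none (no contamination reported)\n")
  cat(sprintf("  inconclusive: %d; cleaned: %d sequence(s), binned: %d\n",
              length(object@inconclusive), length(object@cleaned),
              length(object@binned)))
  invisible(object)
})

#' Accessors for GxScreen results
#'
#' @param x A [GxScreen-class] object.
#' @return `gxRecords()` the action-record data.frame; `gxCleaned()` /
#'   `gxBinned()` the cleaned and binned `DNAStringSet`s; `gxContext()` the
#'   screening context.
#' @export
gxRecords <- function(x) x@records

#' @rdname gxRecords
#' @export
gxCleaned <- function(x) x@cleaned

#' @rdname gxRecords
#' @export
gxBinned <- function(x) x@binned

#' @rdname gxRecords
#' @export
gxContext <- function(x) x@context

.reportColumns <- c("seq_id", "start_pos", "end_pos", "seq_len", "action",
                    "div", "agg_cont_cov", "top_tax_name")

#' Write / read an action report
#'
#' The report is a tab-separated table with one row per recommended action:
#' `seq_id`, `start_pos`/`end_pos` (1-based inclusive; a whole-sequence call
#' spans 1..length), `seq_len`, `action` (EXCLUDE/TRIM/FIX/INFO/REVIEW/
#' REVIEW_RARE), `div` (contaminant division), `agg_cont_cov` (percent
#' coverage of the called range by contaminant-division alignments) and
#' `top_tax_name` (best-scoring contaminant species). Rows are sorted by
#' `seq_id` then `start_pos`; reruns are byte-identical.
#'
#' @param records data.frame of action records (from [runScreen()] /
#'   [assignActions()]).
#' @param path Output file.
#' @return `writeActionReport()` the path, invisibly; `readActionReport()`
#'   the records data.frame.
#' @export
writeActionReport <- function(records, path) {
  df <- data.frame(
    seq_id = records$seqId %||% character(0),
    start_pos = as.integer(records$start %||% integer(0)),
    end_pos = as.integer(records$end %||% integer(0)),
    seq_len = as.integer(records$seqLen %||% integer(0)),
    action = records$action %||% character(0),
    div = records$division %||% character(0),
    agg_cont_cov = round(100 * (records$covFrac %||% numeric(0)), 1),
    top_tax_name = records$topSpecies %||% character(0),
    stringsAsFactors = FALSE)
  df <- df[order(df$seq_id, df$start_pos, df$div), , drop = FALSE]
  con <- file(path, "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  writeLines(paste(.reportColumns, collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  invisible(path)
}

#' @rdname writeActionReport
#' @export
readActionReport <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(identical(names(df), .reportColumns))
  data.frame(seqId = as.character(df$seq_id), start = df$start_pos,
             end = df$end_pos, seqLen = df$seq_len, action = df$action,
             division = df$div, covFrac = df$agg_cont_cov / 100,
             topSpecies = df$top_tax_name, stringsAsFactors = FALSE)
}

#' Apply cleaning actions to a FASTA
#'
#' Only the corrective actions modify the assembly: EXCLUDE removes whole
#' sequences, TRIM removes terminal ranges, FIX removes internal ranges and
#' splits the remainder (parts are renamed with `.1`, `.2`, ... suffixes);
#' INFO, REVIEW and REVIEW_RARE never modify sequences. Removed material is
#' collected in a contaminant bin. An optional minimum-length drop is
#' applied last (a 1-kbp threshold is recommended for eukaryote genomes).
#'
#' @param fasta `DNAStringSet` or FASTA path.
#' @param records Action records (data.frame or report path).
#' @param minSeqLen Drop cleaned sequences shorter than this (0 = keep all).
#' @return list with `cleaned` and `binned` `DNAStringSet`s.
#' @export
applyActions <- function(fasta, records, minSeqLen = 0L) {
  if (is.character(fasta)) fasta <- readDNAStringSet(fasta)
  names(fasta) <- sub("\\s.*$", "", names(fasta))
  if (is.character(records)) records <- readActionReport(records)
  corrective <- records[records$action %in% c("EXCLUDE", "TRIM", "FIX"), ,
                        drop = FALSE]
  if (nrow(corrective)) {
    miss <- setdiff(corrective$seqId, names(fasta))
    if (length(miss))
      stop("action report references sequence(s) absent from the FASTA: ",
           paste(miss, collapse = ", "))
    lens <- setNames(width(fasta), names(fasta))[corrective$seqId]
    if (any(corrective$start < 1 | corrective$end > lens |
            corrective$start > corrective$end))
      stop("action report contains range(s) outside their sequence: corrupt report")
  }
  cleaned <- list(); binned <- list()
  for (id in names(fasta)) {
    s <- fasta[[id]]
    acts <- corrective[corrective$seqId == id, , drop = FALSE]
    if (!nrow(acts)) { cleaned[[id]] <- s; next }
    if (any(acts$action == "EXCLUDE")) { binned[[id]] <- s; next }
    rem <- reduce(IRanges(acts$start, acts$end))
    keepR <- IRanges::setdiff(IRanges(1L, length(s)), rem)
    for (j in seq_along(rem))
      binned[[sprintf("%s:%d-%d", id, start(rem)[j], end(rem)[j])]] <-
        Biostrings::subseq(s, start(rem)[j], end(rem)[j])
    if (length(keepR) == 1L) {
      cleaned[[id]] <- Biostrings::subseq(s, start(keepR), end(keepR))
    } else if (length(keepR) > 1L) {
      for (j in seq_along(keepR))
        cleaned[[sprintf("%s.%d", id, j)]] <-
          Biostrings::subseq(s, start(keepR)[j], end(keepR)[j])
    }
  }
  toSet <- function(x) if (length(x)) DNAStringSet(x) else DNAStringSet()
  cleaned <- toSet(cleaned)
  if (minSeqLen > 0L) cleaned <- cleaned[width(cleaned) >= minSeqLen]
  list(cleaned = cleaned, binned = toSet(binned))
}

# ---- the end-to-end screen --------------------------------------------------

#' Screen an assembly for contamination
#'
#' Runs the full pipeline on a query assembly: scaffolds are split into
#' contigs on runs of 10+ Ns, ambiguous bases are pseudorandom-filled,
#' low-complexity (and, for eukaryotes, transposon-like) regions are masked
#' for seeding, contigs are aligned against the database in two passes,
#' per-sequence hits are summarized under the reporting limits, the
#' classifier produces contamination calls and actions, and a cleaned FASTA
#' plus action report are assembled.
#'
#' @param query `DNAStringSet` or FASTA path of the assembly to screen.
#' @param taxid Declared taxid of the assembly (must resolve in the
#'   database's taxonomy; checked before alignment).
#' @param db A [GxDatabase-class].
#' @param config [gxConfig()] classifier thresholds.
#' @param params [gxAlignParams()] aligner parameters.
#' @param repeatMask Mask transposon-like repeats (default: on for eukaryote
#'   queries; never used for prokaryote or virus queries).
#' @param excludeTaxa Taxids excluded from alignment (set to the query's own
#'   species taxids to simulate screening a novel species).
#' @param minSeqLen Minimum cleaned-sequence length (dropped after cleaning).
#' @param outDir If non-NULL, write `report.tsv`, `cleaned.fna`,
#'   `contaminants.fna` and `summary.json` there.
#' @param verbose Log per-stage counts.
#' @return A [GxScreen-class] object.
#' @export
runScreen <- function(query, taxid, db, config = gxConfig(),
                      params = gxAlignParams(), repeatMask = NULL,
                      excludeTaxa = NULL, minSeqLen = 0L, outDir = NULL,
                      verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(query)) query <- readDNAStringSet(query)
  names(query) <- sub("\\s.*$", "", names(query))
  if (is.null(names(query)) || anyDuplicated(names(query)))
    stop("query sequences must carry unique ids")
  declared <- resolveLineage(taxid, db@taxonomy)
  if (is.null(repeatMask)) repeatMask <- .isEuk(declared$kingdom)
  if (!.isEuk(declared$kingdom)) repeatMask <- FALSE
  say("screen: %d sequence(s), %.2f Mbp; declared %s / %s / %s",
      length(query), sum(as.numeric(width(query))) / 1e6,
      declared$species, declared$division, declared$kingdom)

  # 1. split scaffolds into contigs, fill ambiguous bases
  contigs <- do.call(rbind, lapply(seq_along(query), function(i)
    splitOnNRuns(as.character(query[[i]]), names(query)[i])))
  if (is.null(contigs) || !nrow(contigs))
    stop("no non-N sequence in the query")
  fills <- vector("list", nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    f <- fillAmbiguousBases(contigs$sequence[i],
                            paste0(contigs$scaffoldId[i], ":", contigs$start[i]))
    contigs$sequence[i] <- f$seq
    fills[[i]] <- f$fill
  }
  say("preprocess: %d contig(s) from %d scaffold(s)", nrow(contigs),
      length(query))

  # 2. masking
  scafLens <- setNames(width(query), names(query))
  lcMask <- lapply(contigs$sequence, maskLowComplexity)
  if (repeatMask) {
    tp <- detectTransposonHmers(
      contigs$sequence,
      scaffoldLengths = as.numeric(scafLens),
      contigScaffold = match(contigs$scaffoldId, names(query)))
    tpMask <- tp$intervals
    say("mask: %d transposon h-mer(s) flagged; %d low-complexity interval(s)",
        length(tp$keys), sum(lengths(lcMask)))
  } else {
    tpMask <- replicate(nrow(contigs), IRanges(), simplify = FALSE)
    say("mask: transposon masking off; %d low-complexity interval(s)",
        sum(lengths(lcMask)))
  }

  # 3. alignment, lifted to scaffold coordinates
  md <- gxMetadata(db)
  hitsBySeq <- setNames(vector("list", length(query)), names(query))
  masksBySeq <- setNames(vector("list", length(query)), names(query))
  for (i in seq_len(nrow(contigs))) {
    h <- alignContig(contigs$sequence[i], db,
                     masks = list(lowComplexity = lcMask[[i]],
                                  transposon = tpMask[[i]]),
                     fill = fills[[i]], excludeTaxa = excludeTaxa,
                     params = params)
    off <- contigs$start[i]
    sid <- contigs$scaffoldId[i]
    if (nrow(h)) {
      h$qstart <- h$qstart + off; h$qend <- h$qend + off
      hitsBySeq[[sid]] <- if (is.null(hitsBySeq[[sid]])) h else
        rbind(hitsBySeq[[sid]], h)
    }
    m0 <- masksBySeq[[sid]] %||% list(lowComplexity = IRanges(),
                                      transposon = IRanges())
    m0$lowComplexity <- c(m0$lowComplexity, IRanges::shift(lcMask[[i]], off))
    m0$transposon <- c(m0$transposon, IRanges::shift(tpMask[[i]], off))
    masksBySeq[[sid]] <- m0
  }
  nhit <- sum(vapply(hitsBySeq, function(h) if (is.null(h)) 0L else nrow(h), 0L))
  say("align: %d hit(s) across %d sequence(s)", nhit,
      sum(vapply(hitsBySeq, function(h) !is.null(h) && nrow(h) > 0, NA)))

  # 4. per-sequence summaries
  divK <- .divisionKingdoms(db@taxonomy)
  summaries <- vector("list", length(query))
  names(summaries) <- names(query)
  for (sid in names(query)) {
    h <- hitsBySeq[[sid]]
    len <- as.numeric(scafLens[[sid]])
    if (!is.null(h) && nrow(h)) {
      mi <- match(h$taxid, md$taxid)
      h$species <- md$species[mi]; h$division <- md$division[mi]
      h$kingdom <- md$kingdom[mi]
    }
    rep1 <- summarizeSequenceHits(h, len)
    cons <- conservedIntervals(h, len, declared$kingdom)
    m <- masksBySeq[[sid]] %||% list(lowComplexity = IRanges(),
                                     transposon = IRanges())
    lcCons <- reduce(c(m$lowComplexity, cons))
    tpIR <- reduce(m$transposon)
    ranges <- list(); lcConsBp <- numeric(0); transposonBp <- numeric(0)
    if (!is.null(h) && nrow(h)) {
      for (d in unique(h$division)) {
        r <- reduce(.hitRanges(h[h$division == d, , drop = FALSE]))
        ranges[[d]] <- r
        lcConsBp[[d]] <- sum(as.numeric(width(IRanges::intersect(r, lcCons))))
        transposonBp[[d]] <- sum(as.numeric(width(IRanges::intersect(r, tpIR))))
      }
    }
    summaries[[sid]] <- list(
      id = sid, length = len, nHits = rep1$nHits, hits = h,
      species = rep1$species, divisions = rep1$divisions,
      ranges = ranges, conserved = cons,
      lcConsBp = lcConsBp, transposonBp = transposonBp)
  }

  # 5. genome context: aggregate coverage over the top-4 species per sequence
  totalLen <- sum(as.numeric(scafLens))
  top4Bp <- sum(vapply(summaries, function(s) {
    if (!nrow(s$species)) return(0)
    sum(as.numeric(width(reduce(do.call(c, unname(
      lapply(head(s$species$taxid, 4L), function(t)
        reduce(.hitRanges(s$hits[s$hits$taxid == t, , drop = FALSE])))))))))
  }, 0))
  aggCov <- min(1, top4Bp / totalLen)

  # 6. inferred primary divisions and per-division aggregates
  divTracks <- list()
  for (sid in names(summaries))
    for (d in names(summaries[[sid]]$ranges))
      divTracks[[d]][[sid]] <- summaries[[sid]]$ranges[[d]]
  primary <- inferPrimarySet(divTracks, declared$division, divK, aggCov, db,
                             config)
  if (isTRUE(primary$wrongTaxid)) warning(primary$message)
  say("classify: aggregate coverage %.1f%%; primary set {%s}%s",
      100 * aggCov, paste(primary$primary, collapse = ", "),
      if (isTRUE(primary$wrongTaxid)) " [declared-taxid mismatch]" else "")

  seqStats <- do.call(rbind, lapply(summaries, function(s) {
    if (!length(s$ranges)) return(NULL)
    prim <- s$ranges[intersect(names(s$ranges), primary$primary)]
    primR <- if (length(prim)) reduce(do.call(c, unname(prim))) else IRanges()
    do.call(rbind, lapply(seq_len(nrow(s$divisions)), function(i) {
      d <- s$divisions$division[i]
      data.frame(seqId = s$id, seqLen = s$length, division = d,
                 kingdom = s$divisions$kingdom[i],
                 covBp = s$divisions$covBp[i], score = s$divisions$score[i],
                 lcConsBp = s$lcConsBp[[d]], transposonBp = s$transposonBp[[d]],
                 sourceOverlapBp = sum(as.numeric(width(
                   IRanges::intersect(s$ranges[[d]], primR)))),
                 stringsAsFactors = FALSE)
    }))
  }))
  aggregates <- aggregateDivisions(seqStats, config)
  flagged <- flagContaminantDivisions(aggregates, primary$primary, config)
  say("classify: %d division(s) flagged as contamination sources%s",
      length(flagged),
      if (length(flagged)) paste0(" (", paste(flagged, collapse = ", "), ")")
      else "")

  # 7. per-sequence calls and actions
  context <- list(
    declaredTaxid = declared$taxid, declaredDivision = declared$division,
    declaredKingdom = declared$kingdom, primarySet = primary$primary,
    topDivision = primary$topDivision, wrongTaxid = primary$wrongTaxid,
    primaryMessage = primary$message, aggCoverage = aggCov,
    genomeLength = totalLen, divisionKingdoms = divK,
    aggregates = aggregates, flagged = flagged)
  calls <- do.call(rbind, lapply(summaries, callSequence,
                                 flagged = flagged, context = context,
                                 config = config))
  inconclusive <- unique(calls$seqId[calls$category == "inconclusive"])
  records <- assignActions(calls, context, config)
  # annotate the top contaminant species per (sequence, division)
  records$topSpecies <- vapply(seq_len(nrow(records)), function(i) {
    sp <- summaries[[records$seqId[i]]]$species
    cand <- sp$species[sp$division == records$division[i]]
    if (length(cand)) cand[1L] else NA_character_
  }, "")
  say("report: %d action record(s); %d inconclusive sequence(s)",
      nrow(records), length(inconclusive))

  cleaned <- applyActions(query, records, minSeqLen = minSeqLen)
  res <- new("GxScreen", records = records,
             calls = calls[calls$category == "contaminant", , drop = FALSE],
             sequenceReports = summaries, inconclusive = inconclusive,
             context = context, cleaned = cleaned$cleaned,
             binned = cleaned$binned)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeActionReport(records, file.path(outDir, "report.tsv"))
    writeXStringSet(res@cleaned, file.path(outDir, "cleaned.fna"))
    writeXStringSet(res@binned, file.path(outDir, "contaminants.fna"))
    jsonlite::write_json(
      list(declared = declared, aggregateCoverage = aggCov,
           primarySet = primary$primary, flagged = flagged,
           nRecords = nrow(records), inconclusive = inconclusive),
      file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}
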