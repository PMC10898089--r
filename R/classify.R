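#' Classifier configuration
#'
#' All contamination-calling thresholds, each defaulting to its standard
#' value. Override any of them by name, e.g. `gxConfig(chimeraMinSpan = 5000)`.
#'
#' @param ... Name-value overrides.
#' @return A list of thresholds:
#' \describe{
#'   \item{minAggScore}{alignments scoring below 150 are filtered out of the
#'     per-division aggregate statistics.}
#'   \item{minAggCoverage}{only alignments covering more than 80% of their
#'     sequence are retained for the aggregates (strict).}
#'   \item{flagMaskFrac}{criteria (a)/(b): a high-confidence contaminant
#'     division must have less than 75% of its aligned regions identified as
#'     low-complexity/conserved, and less than 75% as transposon-like.}
#'   \item{flagMinNonRepBp}{criterion (c): more than 10 kbp of aligned
#'     regions must be non-repetitive.}
#'   \item{flagSourceOverlapFrac}{criterion (d): less than 75% of aligned
#'     regions may overlap alignments to the declared source division.}
#'   \item{seqScoreFlagged}{sequences are called contaminants of a flagged
#'     division when the alignment score exceeds 50.}
#'   \item{interKingdomCoverage}{...or, for inter-kingdom contaminants, when
#'     alignment coverage is at least 80%.}
#'   \item{seqScoreUnflagged,unflaggedRepeatFrac}{calls against unflagged
#'     divisions require score above 100 and repeat/conserved content below
#'     50%.}
#'   \item{coverageFloor,coverageSlope}{minimum coverage cutoff for calls:
#'     `max(0.2, 0.6 * (1 - genome aggregate coverage fraction))`.}
#'   \item{chimeraMinSpan}{intra-kingdom chimeras below 10 kbp are ignored;
#'     longer ones are reported as REVIEW.}
#'   \item{prokInProkFrac}{prokaryote-in-prokaryote contamination totaling at
#'     most 1% of the genome is reported as REVIEW_RARE, not cleaned.}
#'   \item{trimTerminalDist}{a chimeric span reaching within 100 bp of a
#'     sequence end is terminal (TRIM); otherwise internal (FIX).}
#'   \item{primaryConcordanceMax,primaryConcordanceMin}{dynamic concordance
#'     for the inferred-primary set: threshold
#'     `min + (max - min) * aggregate coverage` (lower for poorly
#'     represented species).}
#'   \item{wellRepresentedMinSeqs,wellRepresentedMinBp}{a division counts as
#'     well represented in the database with at least this many sequences
#'     and total bp (desk-scale defaults).}
#'   \item{lgtDivisions}{divisions whose chimeras are known lateral-transfer
#'     sources (endosymbionts); reported as INFO, never cleaned.}
#'   \item{minPrimaryBp}{below this much primary-division coverage a
#'     contaminated sequence is treated as wholly contaminant rather than
#'     chimeric.}
#'   \item{junctionFuzz}{maximum per-side widening of a called chimeric
#'     span toward the contaminant-alignment boundary, absorbing the
#'     few-bp ambiguity of local alignment ends at junctions.}
#'   \item{callMergeGap,minCallSpan}{contaminant ranges closer than
#'     `callMergeGap` are merged; ranges below `minCallSpan` are dropped.}
#' }
#' @export
gxConfig <- function(...) {
  cfg <- list(
    minAggScore = 150, minAggCoverage = 0.80,
    flagMaskFrac = 0.75, flagMinNonRepBp = 10000,
    flagSourceOverlapFrac = 0.75,
    seqScoreFlagged = 50, interKingdomCoverage = 0.80,
    seqScoreUnflagged = 100, unflaggedRepeatFrac = 0.50,
    coverageFloor = 0.2, coverageSlope = 0.6,
    chimeraMinSpan = 10000, prokInProkFrac = 0.01,
    trimTerminalDist = 100,
    primaryConcordanceMax = 0.75, primaryConcordanceMin = 0.5,
    wellRepresentedMinSeqs = 1, wellRepresentedMinBp = 5e4,
    lgtDivisions = c("prok:endosymbionts"),
    minPrimaryBp = 100, callMergeGap = 1000, minCallSpan = 50,
    junctionFuzz = 25)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config option(s): ", paste(bad, collapse = ", "))
  for (n in names(ov)) cfg[[n]] <- ov[[n]]
  cfg
}

#' Minimum coverage cutoff for contaminant calls
#'
#' Genomes with few close taxonomic neighbors in the database (low aggregate
#' coverage) get a higher coverage bar, restricting calls to the highest
#' confidence ones: the cutoff is
#' `max(0.2, 0.6 * (1 - aggregate coverage fraction))`.
#'
#' @param fraction Genome aggregate coverage fraction in `[0, 1]` (total
#'   length aligned to the top four hits over total genome size).
#' @param config [gxConfig()].
#' @return The minimum coverage threshold.
#' @examples
#' coverageCutoff(1.0)  # the 0.2 floor
#' coverageCutoff(0.0)  # 0.6
#' @export
coverageCutoff <- function(fraction, config = gxConfig()) {
  stopifnot(fraction >= 0, fraction <= 1)
  max(config$coverageFloor, config$coverageSlope * (1 - fraction))
}

#' Aggregate per-division statistics over a screened genome
#'
#' Accumulates division evidence from high-confidence alignments only:
#' rows with score at least `minAggScore` (150; a score of 149 is excluded,
#' 150 included) and sequence coverage strictly above `minAggCoverage` (80%).
#'
#' @param seqStats data.frame with one row per (sequence, division):
#'   `seqId`, `seqLen`, `division`, `kingdom`, `covBp`, `score`, `lcConsBp`
#'   (aligned bp overlapping low-complexity or conserved intervals),
#'   `transposonBp`, `sourceOverlapBp` (aligned bp overlapping the declared
#'   source division's alignments).
#' @param config [gxConfig()].
#' @return data.frame per division: `totalBp` (aligned), `nonRepBp`,
#'   `lcConsFrac`, `transposonFrac`, `sourceOverlapFrac`, `nSeqs`.
#' @export
aggregateDivisions <- function(seqStats, config = gxConfig()) {
  empty <- data.frame(division = character(0), kingdom = character(0),
                      totalBp = numeric(0), nonRepBp = numeric(0),
                      lcConsFrac = numeric(0), transposonFrac = numeric(0),
                      sourceOverlapFrac = numeric(0), nSeqs = integer(0))
  if (is.null(seqStats) || !nrow(seqStats)) return(empty)
  keep <- seqStats$score >= config$minAggScore &
    seqStats$covBp / seqStats$seqLen > config$minAggCoverage
  seqStats <- seqStats[keep, , drop = FALSE]
  if (!nrow(seqStats)) return(empty)
  sp <- split(seq_len(nrow(seqStats)), seqStats$division)
  out <- do.call(rbind, lapply(sp, function(ix) {
    tot <- sum(seqStats$covBp[ix])
    lc <- sum(seqStats$lcConsBp[ix])
    tr <- sum(seqStats$transposonBp[ix])
    so <- sum(seqStats$sourceOverlapBp[ix])
    data.frame(division = seqStats$division[ix[1L]],
               kingdom = seqStats$kingdom[ix[1L]],
               totalBp = tot, nonRepBp = max(0, tot - lc - tr),
               lcConsFrac = lc / tot, transposonFrac = tr / tot,
               sourceOverlapFrac = so / tot, nSeqs = length(ix),
               stringsAsFactors = FALSE)
  }))
  row.names(out) <- NULL
  out
}

#' Flag high-confidence contaminant divisions
#'
#' A division is flagged as a genome-level contamination source only when
#' all four criteria hold: (a) less than 75% of its aligned regions are
#' low-complexity or highly conserved, (b) less than 75% are transposon-like
#' repeats, (c) more than 10 kbp of aligned regions are non-repetitive, and
#' (d) less than 75% of aligned regions overlap alignments to the declared
#' source division.
#'
#' @param aggregates From [aggregateDivisions()].
#' @param primarySet Divisions treated as the source organism (never
#'   flagged).
#' @param config [gxConfig()].
#' @return Character vector of flagged divisions.
#' @export
flagContaminantDivisions <- function(aggregates, primarySet = character(0),
                                     config = gxConfig()) {
  if (is.null(aggregates) || !nrow(aggregates)) return(character(0))
  ok <- !(aggregates$division %in% primarySet) &
    aggregates$lcConsFrac < config$flagMaskFrac &
    aggregates$transposonFrac < config$flagMaskFrac &
    aggregates$nonRepBp > config$flagMinNonRepBp &
    aggregates$sourceOverlapFrac < config$flagSourceOverlapFrac
  sort(aggregates$division[ok])
}

# does this division look well represented in the database?
.wellRepresented <- function(division, db, config) {
  md <- gxMetadata(db)
  i <- md$division == division
  sum(i) >= config$wellRepresentedMinSeqs &&
    sum(as.numeric(md$length[i])) >= config$wellRepresentedMinBp
}

#' Infer the set of primary divisions
#'
#' Sequences of one organism may top-score against several divisions of the
#' same kingdom (database granularity, shared ancestry). For every division,
#' the degree to which its alignments overlap those of the top-coverage
#' division is computed; same-kingdom divisions above a dynamic concordance
#' threshold (lower for poorly represented species) join the inferred
#' primary set and are treated as belonging to the declared source organism.
#' If the declared division is well represented in the database yet absent
#' from the inferred set (wrong taxid, gross contamination), the inferred
#' divisions are instead reported as contaminants and a warning is attached.
#'
#' @param divTracks Named list: division -> named list of per-sequence
#'   reduced [IRanges::IRanges] of aligned query intervals.
#' @param declaredDivision Division of the declared taxid.
#' @param divisionKingdoms Named character vector division -> kingdom.
#' @param aggCoverage Genome aggregate coverage fraction.
#' @param db [GxDatabase-class] (for the well-represented check).
#' @param config [gxConfig()].
#' @return list with `primary` (character vector), `topDivision`,
#'   `wrongTaxid` (logical) and `message` (NA or warning text).
#' @export
inferPrimarySet <- function(divTracks, declaredDivision, divisionKingdoms,
                            aggCoverage, db, config = gxConfig()) {
  if (!length(divTracks))
    return(list(primary = declaredDivision, topDivision = NA_character_,
                wrongTaxid = FALSE, message = NA_character_))
  covBp <- vapply(divTracks, function(tr)
    sum(vapply(tr, function(ir) sum(as.numeric(width(ir))), 0)), 0)
  top <- names(covBp)[order(-covBp, names(covBp))][1L]
  thr <- config$primaryConcordanceMin +
    (config$primaryConcordanceMax - config$primaryConcordanceMin) *
    max(0, min(1, aggCoverage))
  overlapFrac <- vapply(names(divTracks), function(d) {
    if (d == top) return(1)
    num <- 0
    for (s in names(divTracks[[d]])) {
      o <- divTracks[[top]][[s]]
      if (is.null(o)) next
      num <- num + sum(as.numeric(width(IRanges::intersect(divTracks[[d]][[s]], o))))
    }
    if (covBp[[d]] > 0) num / covBp[[d]] else 0
  }, 0)
  sameK <- divisionKingdoms[names(divTracks)] == divisionKingdoms[[top]]
  inferred <- names(divTracks)[sameK & overlapFrac >= thr]

  if (declaredDivision %in% inferred)
    return(list(primary = sort(unique(c(inferred, declaredDivision))),
                topDivision = top, wrongTaxid = FALSE,
                message = NA_character_))
  if (.wellRepresented(declaredDivision, db, config)) {
    return(list(primary = declaredDivision, topDivision = top,
                wrongTaxid = TRUE,
                message = paste0(
                  "declared division '", declaredDivision, "' is well ",
                  "represented in the database but the assembly aligns ",
                  "predominantly to '", top, "'; check the declared taxid -- ",
                  "inferred divisions are reported as contaminants")))
  }
  list(primary = sort(unique(c(inferred, declaredDivision))),
       topDivision = top, wrongTaxid = FALSE, message = NA_character_)
}

#' Call one sequence from its per-division evidence
#'
#' Applies the per-sequence calling rules: flagged divisions need score
#' above 50 (or at least 80% coverage for inter-kingdom contaminants);
#' unflagged divisions need score above 100 and repeat/conserved content
#' below 50%; every call must also clear the genome-level coverage cutoff
#' ([coverageCutoff()]) over the called region. A sequence with zero
#' alignments is inconclusive. When both primary-division and
#' contaminant-division alignments partition the sequence, chimeric
#' contaminant ranges are produced instead of a whole-sequence call.
#'
#' @param summary Per-sequence summary: list with `id`, `length`, `nHits`,
#'   `divisions` (data.frame: division, kingdom, covBp, score), `ranges`
#'   (named list division -> reduced [IRanges::IRanges]), `lcConsBp`,
#'   `transposonBp` (named numeric per division).
#' @param flagged Flagged divisions from [flagContaminantDivisions()].
#' @param context list with `declaredKingdom`, `primarySet`, `aggCoverage`.
#' @param config [gxConfig()].
#' @return data.frame of calls: `seqId`, `seqLen`, `division`, `kingdom`,
#'   `category` ("contaminant" or "inconclusive"), `whole`, `start`, `end`
#'   (1-based inclusive), `score`, `covFrac`.
#' @export
callSequence <- function(summary, flagged, context, config = gxConfig()) {
  empty <- data.frame(seqId = character(0), seqLen = numeric(0),
                      division = character(0), kingdom = character(0),
                      category = character(0), whole = logical(0),
                      start = numeric(0), end = numeric(0),
                      score = numeric(0), covFrac = numeric(0),
                      stringsAsFactors = FALSE)
  len <- summary$length
  if (summary$nHits == 0L)
    return(data.frame(seqId = summary$id, seqLen = len, division = NA_character_,
                      kingdom = NA_character_, category = "inconclusive",
                      whole = FALSE, start = NA_real_, end = NA_real_,
                      score = 0, covFrac = 0, stringsAsFactors = FALSE))
  prim <- summary$ranges[intersect(names(summary$ranges), context$primarySet)]
  primaryRanges <- if (length(prim)) reduce(do.call(c, unname(prim))) else IRanges()
  primaryCov <- sum(width(primaryRanges))
  cutoff <- coverageCutoff(context$aggCoverage, config)

  rows <- list()
  dv <- summary$divisions
  for (i in seq_len(nrow(dv))) {
    d <- dv$division[i]
    if (d %in% context$primarySet) next
    rawR <- summary$ranges[[d]]
    if (is.null(rawR) || !length(rawR)) next
    covBp <- dv$covBp[i]; score <- dv$score[i]
    interK <- dv$kingdom[i] != context$declaredKingdom
    if (primaryCov < config$minPrimaryBp) {
      contamR <- IRanges(1L, len); whole <- TRUE
    } else {
      # the host and contaminant alignments partition the sequence: the
      # contaminant spans are the holes in primary-division coverage that
      # carry contaminant-division alignments. Local alignment ends are
      # ambiguous by a few bases at a chimeric junction (either alignment
      # may claim chance-matching bases across it), so each hole is widened
      # to the overlapping contaminant-alignment boundaries, by at most
      # junctionFuzz bases per side.
      holes <- IRanges::setdiff(IRanges(1L, len), primaryRanges)
      holes <- holes[IRanges::overlapsAny(holes, rawR)]
      if (!length(holes)) next
      fz <- config$junctionFuzz
      r <- do.call(c, lapply(seq_along(holes), function(j) {
        h <- holes[j]
        ov <- rawR[IRanges::overlapsAny(rawR, h)]
        extL <- min(fz, max(0L, start(h) - min(start(ov))))
        extR <- min(fz, max(0L, max(end(ov)) - end(h)))
        IRanges(max(1L, start(h) - extL), min(len, end(h) + extR))
      }))
      r <- reduce(r, min.gapwidth = config$callMergeGap)
      r <- r[width(r) >= config$minCallSpan]
      if (!length(r)) next
      contamR <- r; whole <- FALSE
    }
    regionLen <- sum(as.numeric(width(contamR)))
    regionCov <- sum(as.numeric(width(IRanges::intersect(rawR, contamR)))) / regionLen
    seqCov <- covBp / len
    getBp <- function(x) if (!is.null(x) && d %in% names(x)) x[[d]] else 0
    repFrac <- getBp(summary$lcConsBp) + getBp(summary$transposonBp)
    repFrac <- if (covBp > 0) repFrac / covBp else 0
    eligible <- if (d %in% flagged) {
      score > config$seqScoreFlagged ||
        (interK && seqCov >= config$interKingdomCoverage)
    } else {
      score > config$seqScoreUnflagged && repFrac < config$unflaggedRepeatFrac
    }
    if (!eligible || regionCov < cutoff) next
    rows[[length(rows) + 1L]] <- data.frame(
      seqId = summary$id, seqLen = len, division = d, kingdom = dv$kingdom[i],
      category = "contaminant", whole = whole,
      start = as.numeric(start(contamR)), end = as.numeric(end(contamR)),
      score = score, covFrac = regionCov, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Assign cleaning actions to contamination calls
#'
#' Maps calls to the six actions: whole-sequence contaminants are EXCLUDE;
#' inter-kingdom chimeric spans are TRIM (terminal) or FIX (internal);
#' chimeras from configured known lateral-gene-transfer source divisions are
#' INFO; intra-kingdom chimeras of at least 10 kbp are REVIEW (smaller ones
#' are not reported); prokaryote-in-prokaryote contamination totaling at
#' most 1% of the genome is downgraded to REVIEW_RARE (not auto-cleaned).
#' Virus rules: in eukaryote queries only wholly-viral sequences are cleaned
#' and chimeric viral spans are ignored; in prokaryote queries all viral
#' elements are ignored; virus queries report cross-superkingdom viral and
#' all non-viral contaminants.
#'
#' @param calls data.frame from [callSequence()] (contaminant rows).
#' @param context list with `declaredKingdom`, `declaredDivision`,
#'   `genomeLength`.
#' @param config [gxConfig()].
#' @return `calls` with an `action` column, unreported rows removed.
#' @export
assignActions <- function(calls, context, config = gxConfig()) {
  calls <- calls[calls$category == "contaminant", , drop = FALSE]
  if (!nrow(calls)) { calls$action <- character(0); return(calls) }
  hostK <- context$declaredKingdom
  keep <- rep(TRUE, nrow(calls))
  action <- character(nrow(calls))

  # chimeric span total per (sequence, division), for the 10-kbp rule
  spanKey <- paste(calls$seqId, calls$division)
  spanTot <- tapply(ifelse(calls$whole, 0, calls$end - calls$start + 1),
                    spanKey, sum)

  for (i in seq_len(nrow(calls))) {
    k <- calls$kingdom[i]
    whole <- calls$whole[i]
    viral <- k == "Viruses"
    if (viral) {
      if (.isEuk(hostK)) {
        if (!whole) { keep[i] <- FALSE; next }           # chimeric viral span
      } else if (.isProk(hostK)) {
        keep[i] <- FALSE; next                           # all viral ignored
      } else if (hostK == "Viruses") {
        sk <- .virusSuperkingdom(calls$division[i])
        hk <- .virusSuperkingdom(context$declaredDivision)
        if (!(sk %in% c("prok", "euk") && hk %in% c("prok", "euk") && sk != hk)) {
          keep[i] <- FALSE; next                         # same-superkingdom virus
        }
      }
    }
    if (whole) { action[i] <- "EXCLUDE"; next }
    # chimeric span
    if (calls$division[i] %in% config$lgtDivisions) { action[i] <- "INFO"; next }
    if (k == hostK) {
      if (spanTot[[paste(calls$seqId[i], calls$division[i])]] >=
          config$chimeraMinSpan) action[i] <- "REVIEW"
      else keep[i] <- FALSE
      next
    }
    terminal <- calls$start[i] <= config$trimTerminalDist ||
      calls$end[i] > calls$seqLen[i] - config$trimTerminalDist
    action[i] <- if (terminal) "TRIM" else "FIX"
  }
  calls <- calls[keep, , drop = FALSE]
  calls$action <- action[keep]

  # prokaryote-in-prokaryote <= 1% of the genome: report only, do not clean
  if (.isProk(hostK) && nrow(calls)) {
    pp <- .isProk(calls$kingdom) & calls$action %in% c("EXCLUDE", "TRIM", "FIX")
    if (any(pp)) {
      tot <- sum(ifelse(calls$whole[pp], calls$seqLen[pp],
                        calls$end[pp] - calls$start[pp] + 1))
      if (tot <= config$prokInProkFrac * context$genomeLength)
        calls$action[pp] <- "REVIEW_RARE"
    }
  }
  calls[order(calls$seqId, calls$start, calls$division), , drop = FALSE]
}
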