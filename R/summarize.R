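# hits for one input sequence are expected as the data.frame produced by
# alignContig() (lifted to input-sequence coordinates) with lineage columns
# species/division/kingdom joined from the database metadata

.hitRanges <- function(hits) IRanges(hits$qstart + 1L, hits$qend)

#' Summarize the hits of one query sequence
#'
#' Aggregates alignments per species (coverage length = length of the union
#' of query intervals; score = L2-combined identity-segment score over the
#' species' hits), ranks species by score, and truncates reporting to at
#' most `maxSpecies` species overall and `maxPerDivision` per division --
#' keeping more than one species per division helps distinguish valid
#' contaminants from false positives arising from contamination in the
#' database. Per-division aggregates are retained for all divisions; the
#' caps govern species reporting only.
#'
#' @param hits data.frame of hits for one sequence with columns `taxid`,
#'   `species`, `division`, `kingdom`, `qstart`, `qend` (0-based half-open)
#'   and `segments` (list of identity-segment lengths).
#' @param seqLength Sequence length in bp.
#' @param maxSpecies,maxPerDivision Reporting caps (4 and 2).
#' @return list with `species` (ranked, capped data.frame: taxid, species,
#'   division, kingdom, covBp, score), `divisions` (per-division aggregates
#'   over all hits: covBp, score), and `nHits`.
#' @export
summarizeSequenceHits <- function(hits, seqLength, maxSpecies = 4L,
                                  maxPerDivision = 2L) {
  if (is.null(hits) || !nrow(hits)) {
    return(list(
      species = data.frame(taxid = integer(0), species = character(0),
                           division = character(0), kingdom = character(0),
                           covBp = numeric(0), score = numeric(0)),
      divisions = data.frame(division = character(0), kingdom = character(0),
                             covBp = numeric(0), score = numeric(0)),
      nHits = 0L))
  }
  bySp <- split(seq_len(nrow(hits)), hits$taxid)
  sp <- do.call(rbind, lapply(bySp, function(ix) {
    cov <- sum(width(reduce(.hitRanges(hits[ix, , drop = FALSE]))))
    data.frame(taxid = hits$taxid[ix[1L]], species = hits$species[ix[1L]],
               division = hits$division[ix[1L]], kingdom = hits$kingdom[ix[1L]],
               covBp = min(cov, seqLength),
               score = scoreAlignment(unlist(hits$segments[ix])),
               stringsAsFactors = FALSE)
  }))
  sp <- sp[order(-sp$score, sp$taxid), , drop = FALSE]
  row.names(sp) <- NULL

  byDiv <- split(seq_len(nrow(hits)), hits$division)
  dv <- do.call(rbind, lapply(byDiv, function(ix) {
    cov <- sum(width(reduce(.hitRanges(hits[ix, , drop = FALSE]))))
    data.frame(division = hits$division[ix[1L]], kingdom = hits$kingdom[ix[1L]],
               covBp = min(cov, seqLength),
               score = scoreAlignment(unlist(hits$segments[ix])),
               stringsAsFactors = FALSE)
  }))
  row.names(dv) <- NULL

  # reporting caps: <= maxPerDivision species per division, <= maxSpecies total
  keep <- logical(nrow(sp))
  divCount <- integer(0)
  total <- 0L
  for (i in seq_len(nrow(sp))) {
    d <- sp$division[i]
    c0 <- if (d %in% names(divCount)) divCount[[d]] else 0L
    if (total < maxSpecies && c0 < maxPerDivision) {
      keep[i] <- TRUE
      divCount[[d]] <- c0 + 1L
      total <- total + 1L
    }
  }
  list(species = sp[keep, , drop = FALSE], divisions = dv, nHits = nrow(hits))
}

#' Highly conserved intervals
#'
#' Base positions of a eukaryote query covered by alignments from at least
#' `minDivisions` (five) distinct taxonomic divisions are flagged as highly
#' conserved; such regions (ultraconserved elements, rRNA and the like)
#' align across much of the tree of life and must not drive contamination
#' calls. Conserved intervals are calculated only for eukaryote queries; for
#' prokaryote and virus queries the result is always empty.
#'
#' @param hits data.frame of hits for one sequence (needs `division`,
#'   `qstart`, `qend`).
#' @param seqLength Sequence length in bp.
#' @param queryKingdom Declared kingdom of the query.
#' @param minDivisions Division-count threshold (5).
#' @return [IRanges::IRanges] of conserved intervals (1-based inclusive).
#' @export
conservedIntervals <- function(hits, seqLength, queryKingdom,
                               minDivisions = 5L) {
  if (!.isEuk(queryKingdom) || is.null(hits) || !nrow(hits)) return(IRanges())
  byDiv <- split(seq_len(nrow(hits)), hits$division)
  if (length(byDiv) < minDivisions) return(IRanges())
  covs <- lapply(byDiv, function(ix)
    coverage(reduce(.hitRanges(hits[ix, , drop = FALSE])), width = seqLength))
  tot <- Reduce(`+`, covs)  # each term is 0/1 after reduce()
  slice(tot, lower = minDivisions, rangesOnly = TRUE)
}
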