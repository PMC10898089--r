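# Synthetic worlds: mock taxonomies, reference genomes, diverged strains,
# contaminated mixtures and chimeras, plus the sensitivity/specificity
# bookkeeping used to evaluate the screen without any downloads.

#' Default division layout for synthetic worlds
#'
#' Ten divisions spanning seven kingdoms: three bacterial and one archaeal
#' division (150-kbp genomes), five eukaryote divisions (200-kbp genomes)
#' and a prokaryotic-virus division (20 kbp). Enough divisions exist for
#' conserved-interval logic (five distinct divisions) to be exercisable.
#'
#' @return data.frame with `division`, `kingdom`, `genomeLength`.
#' @export
gxSimDivisions <- function() {
  data.frame(
    division = c("prok:a-proteobacteria", "prok:enterobacteria",
                 "prok:firmicutes", "arch:euryarchaeota",
                 "anml:primates", "anml:insects", "fung:ascomycetes",
                 "plnt:monocots", "prst:kinetoplastids",
                 "virs:prokaryotic-virus"),
    kingdom = c("Bacteria", "Bacteria", "Bacteria", "Archaea",
                "Metazoa", "Metazoa", "Fungi", "Viridiplantae",
                "other-Eukaryota", "Viruses"),
    genomeLength = c(150e3, 150e3, 150e3, 150e3,
                     200e3, 200e3, 200e3, 200e3, 200e3, 20e3),
    stringsAsFactors = FALSE)
}

#' Simulation specification
#'
#' Parameters of the synthetic world: division layout and genome sizes,
#' divergence rates (substitution-dominated, transition:transversion 2:1 so
#' the h-mer transition tolerance is exercised), planted shared "conserved"
#' segments across divisions (exercising conserved-interval logic), planted
#' repeat families in eukaryote genomes (exercising transposon masking),
#' fragment sizes, the 5%-by-length contamination design with 1-kbp
#' fragments, the 100-kbp-host + 1-kbp-contaminant chimera design, and five
#' replicate seeds.
#'
#' @param ... Name-value overrides of the defaults.
#' @return A list of simulation parameters.
#' @export
simSpec <- function(...) {
  spec <- list(
    divisions = gxSimDivisions(),
    speciesPerDivision = 1L,
    gc = 0.42,
    speciesDivergence = 0.05, speciesIndelRate = 0.002,
    strainDivergence = 0.01, strainIndelRate = 0.001,
    tstv = 2, maxIndel = 5L,
    conservedLength = 2000L, conservedDivergence = 0.03,
    repeatLength = 800L, repeatCopies = 25L, repeatDivergence = 0.02,
    fragmentSizes = c(1000L, 10000L, 100000L),
    contamFraction = 0.05, contamFragmentSize = 1000L,
    chimeraHostSize = 100000L, chimeraContamSize = 1000L,
    chimeraSeparator = TRUE,
    replicates = 5L)
  ov <- list(...)
  bad <- setdiff(names(ov), names(spec))
  if (length(bad)) stop("unknown simulation parameter(s): ", paste(bad, collapse = ", "))
  for (n in names(ov)) spec[[n]] <- ov[[n]]
  spec
}

.randSeq <- function(n, gc = 0.42) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Mutate a sequence with substitutions and indels
#'
#' Substitutions are transition-biased (`tstv`-to-1 transitions over all
#' transversions combined); indels of 1..`maxIndel` bp occur at `indelRate`
#' per base, half insertions and half deletions. Uses the current RNG
#' stream; seed upstream for reproducibility.
#'
#' @param seq Character sequence.
#' @param subRate Per-base substitution probability.
#' @param indelRate Per-base indel event probability.
#' @param tstv Transition:transversion ratio.
#' @param maxIndel Maximum indel size in bp.
#' @return The mutated sequence.
#' @export
mutateSequence <- function(seq, subRate, indelRate = 0, tstv = 2,
                           maxIndel = 5L) {
  v <- strsplit(toupper(seq), "")[[1L]]
  n <- length(v)
  if (subRate > 0 && n > 0) {
    nsub <- rbinom(1L, n, subRate)
    if (nsub > 0) {
      pos <- sample.int(n, nsub)
      isTi <- runif(nsub) < tstv / (tstv + 1)
      tiMap <- c(A = "G", G = "A", C = "T", T = "C")
      tv1 <- c(A = "C", G = "C", C = "A", T = "A")
      tv2 <- c(A = "T", G = "T", C = "G", T = "G")
      new <- ifelse(isTi, tiMap[v[pos]],
                    ifelse(runif(nsub) < 0.5, tv1[v[pos]], tv2[v[pos]]))
      v[pos] <- new
    }
  }
  out <- paste(v, collapse = "")
  if (indelRate > 0 && n > 0) {
    nind <- rbinom(1L, n, indelRate)
    if (nind > 0) {
      # single left-to-right pass: copy between events, skip deletions,
      # splice insertions
      pos <- sort(sample.int(n, nind))
      lens <- sample.int(maxIndel, nind, replace = TRUE)
      isDel <- runif(nind) < 0.5
      parts <- character(2L * nind + 1L)
      prev <- 1L; k <- 0L
      for (i in seq_len(nind)) {
        p <- pos[i]
        if (p < prev) next
        k <- k + 1L
        parts[k] <- substring(out, prev, p - 1L)
        if (isDel[i]) {
          prev <- p + lens[i]
        } else {
          k <- k + 1L
          parts[k] <- paste(sample(c("A", "C", "G", "T"), lens[i],
                                   replace = TRUE), collapse = "")
          prev <- p
        }
      }
      k <- k + 1L
      parts[k] <- if (prev <= n) substring(out, prev, n) else ""
      out <- paste(parts[seq_len(k)], collapse = "")
    }
  }
  out
}

#' Derive a strain from a reference genome
#'
#' Applies strain-level divergence (default 1% substitutions, 0.1% indels)
#' under a fixed seed; divergence 0 reproduces the input.
#'
#' @param seq Reference sequence (character or `DNAString`).
#' @param divergence Substitution rate.
#' @param indelRate Indel event rate.
#' @param tstv Transition:transversion ratio.
#' @param seed RNG seed.
#' @return The strain sequence (character).
#' @export
deriveStrain <- function(seq, divergence = 0.01, indelRate = 0.001,
                         tstv = 2, seed = 1L) {
  if (divergence == 0 && indelRate == 0) return(toupper(as.character(seq)))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  mutateSequence(as.character(seq), divergence, indelRate, tstv)
}

#' Generate a synthetic reference set
#'
#' Builds one random ancestral genome per division, plants a shared
#' conserved segment (mutated per species at low divergence) into every
#' genome and a division-specific repeat family into eukaryote genomes,
#' then derives the requested number of species per division at the
#' species-level divergence. Deterministic under the seed.
#'
#' @param spec [simSpec()].
#' @param seed RNG seed.
#' @return list with `sequences` (`DNAStringSet`, one genome per species,
#'   named `ref_<taxid>`), `taxids` (named integer vector parallel to the
#'   sequences), `taxonomy` (taxonomy data.frame), `spec`, `seed`.
#' @export
generateReferenceSet <- function(spec = simSpec(), seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  dv <- spec$divisions
  conserved <- .randSeq(spec$conservedLength, spec$gc)
  seqs <- character(0); taxids <- integer(0)
  taxRows <- list()
  nextTaxid <- 1001L
  for (i in seq_len(nrow(dv))) {
    len <- dv$genomeLength[i]
    anc <- .randSeq(len, spec$gc)
    if (.isEuk(dv$kingdom[i]) && spec$repeatCopies > 0) {
      elt <- .randSeq(spec$repeatLength, spec$gc)
      starts <- sample.int(len - spec$repeatLength, spec$repeatCopies)
      for (s in starts) {
        copy <- mutateSequence(elt, spec$repeatDivergence, 0, spec$tstv)
        substr(anc, s, s + nchar(copy) - 1L) <- copy
      }
    }
    for (j in seq_len(spec$speciesPerDivision)) {
      g <- mutateSequence(anc, spec$speciesDivergence, spec$speciesIndelRate,
                          spec$tstv, spec$maxIndel)
      cp <- mutateSequence(conserved, spec$conservedDivergence, 0, spec$tstv)
      at <- sample.int(nchar(g) - nchar(cp), 1L)
      substr(g, at, at + nchar(cp) - 1L) <- cp
      tid <- nextTaxid; nextTaxid <- nextTaxid + 1L
      nm <- paste0("ref_", tid)
      seqs[nm] <- g
      taxids[nm] <- tid
      taxRows[[length(taxRows) + 1L]] <- data.frame(
        taxid = tid,
        species = sprintf("%s synthetica %d", sub("^.*:", "", dv$division[i]), j),
        division = dv$division[i], kingdom = dv$kingdom[i],
        stringsAsFactors = FALSE)
    }
  }
  list(sequences = DNAStringSet(seqs), taxids = taxids,
       taxonomy = do.call(rbind, taxRows), spec = spec, seed = seed)
}

#' Generate a labeled query set
#'
#' Emits screened inputs with truth labels, in three modes mirroring the
#' evaluation designs: `fragments` splits a strain of one species into
#' equal-size pieces; `mixture` combines 100-kbp host fragments with 1-kbp
#' contaminant fragments at the stated fraction by length; `chimera` fuses
#' each host fragment with a single contaminant span (with or without a
#' 10-N separator).
#'
#' @param refs Reference set from [generateReferenceSet()].
#' @param mode One of `"fragments"`, `"mixture"`, `"chimera"`.
#' @param hostTaxid Species supplying the (host) sequence.
#' @param contamTaxid Species supplying contaminant material (mixture and
#'   chimera modes).
#' @param fragmentSize Fragment size for `fragments` mode.
#' @param contamSize Contaminant span size(s); recycled over host fragments
#'   in `chimera` mode.
#' @param contamFraction Contamination fraction by length (`mixture` mode).
#' @param separator Insert a 10-N separator between host and contaminant
#'   (`chimera` mode)?
#' @param insertAt `"end"` (appended) or `"middle"` (internal span) for
#'   `chimera` mode.
#' @param strainDivergence,strainIndelRate Divergence applied to derive the
#'   query strain from its reference genome.
#' @param seed RNG seed (recorded in the output).
#' @return list with `sequences` (`DNAStringSet`) and `truth` (data.frame:
#'   `id`, `sourceTaxid`, `division`, `kingdom`, and for chimeras
#'   `contamTaxid`, `contamDivision`, `contamKingdom`, `contamStart`,
#'   `contamEnd` 1-based inclusive).
#' @export
generateQuerySet <- function(refs, mode = c("fragments", "mixture", "chimera"),
                             hostTaxid, contamTaxid = NULL,
                             fragmentSize = 10000L,
                             contamSize = NULL, contamFraction = NULL,
                             separator = NULL, insertAt = c("end", "middle"),
                             strainDivergence = NULL, strainIndelRate = NULL,
                             seed = 1L) {
  mode <- match.arg(mode)
  insertAt <- match.arg(insertAt)
  spec <- refs$spec
  contamSize <- contamSize %||% spec$chimeraContamSize
  contamFraction <- contamFraction %||% spec$contamFraction
  separator <- separator %||% spec$chimeraSeparator
  strainDivergence <- strainDivergence %||% spec$strainDivergence
  strainIndelRate <- strainIndelRate %||% spec$strainIndelRate

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  lin <- function(tid) {
    i <- match(tid, refs$taxonomy$taxid)
    if (is.na(i)) stop("taxid ", tid, " not in the reference set")
    refs$taxonomy[i, ]
  }
  genomeOf <- function(tid)
    as.character(refs$sequences[[match(tid, refs$taxids)]])
  strainOf <- function(tid)
    mutateSequence(genomeOf(tid), strainDivergence, strainIndelRate, spec$tstv)
  fragment <- function(seq, size, prefix) {
    n <- nchar(seq)
    nf <- n %/% size
    if (nf == 0L) stop("sequence shorter than the fragment size")
    starts <- (seq_len(nf) - 1L) * size + 1L
    setNames(substring(seq, starts, starts + size - 1L),
             sprintf("%s_%05d", prefix, seq_len(nf)))
  }

  hostLin <- lin(hostTaxid)
  if (mode == "fragments") {
    fr <- fragment(strainOf(hostTaxid), fragmentSize, paste0("t", hostTaxid))
    truth <- data.frame(id = names(fr), sourceTaxid = hostTaxid,
                        division = hostLin$division, kingdom = hostLin$kingdom,
                        stringsAsFactors = FALSE)
    return(list(sequences = DNAStringSet(fr), truth = truth, seed = seed))
  }

  stopifnot(!is.null(contamTaxid))
  contamLin <- lin(contamTaxid)
  host <- fragment(strainOf(hostTaxid), spec$chimeraHostSize,
                   paste0("t", hostTaxid))
  contamAll <- fragment(strainOf(contamTaxid), spec$contamFragmentSize,
                        paste0("t", contamTaxid))

  if (mode == "mixture") {
    want <- ceiling(contamFraction * sum(nchar(host)) / spec$contamFragmentSize)
    pick <- sample(names(contamAll), min(want, length(contamAll)))
    fr <- c(host, contamAll[pick])
    truth <- data.frame(
      id = names(fr),
      sourceTaxid = c(rep(hostTaxid, length(host)), rep(contamTaxid, length(pick))),
      division = c(rep(hostLin$division, length(host)),
                   rep(contamLin$division, length(pick))),
      kingdom = c(rep(hostLin$kingdom, length(host)),
                  rep(contamLin$kingdom, length(pick))),
      stringsAsFactors = FALSE)
    return(list(sequences = DNAStringSet(fr), truth = truth, seed = seed))
  }

  # chimera: one contaminant span per host fragment
  sizes <- rep_len(as.integer(contamSize), length(host))
  contamSrc <- strainOf(contamTaxid)
  sep <- if (separator) strrep("N", 10L) else ""
  seqs <- character(length(host)); truth <- vector("list", length(host))
  for (i in seq_along(host)) {
    cs <- sample.int(nchar(contamSrc) - sizes[i], 1L)
    span <- substring(contamSrc, cs, cs + sizes[i] - 1L)
    h <- host[[i]]
    if (insertAt == "end") {
      seqs[i] <- paste0(h, sep, span)
      a <- nchar(h) + nchar(sep) + 1L
    } else {
      mid <- nchar(h) %/% 2L
      seqs[i] <- paste0(substring(h, 1L, mid), sep, span, sep,
                        substring(h, mid + 1L))
      a <- mid + nchar(sep) + 1L
    }
    truth[[i]] <- data.frame(
      id = sprintf("chim_%05d", i), sourceTaxid = hostTaxid,
      division = hostLin$division, kingdom = hostLin$kingdom,
      contamTaxid = contamTaxid, contamDivision = contamLin$division,
      contamKingdom = contamLin$kingdom,
      contamStart = a, contamEnd = a + sizes[i] - 1L,
      stringsAsFactors = FALSE)
  }
  names(seqs) <- sprintf("chim_%05d", seq_along(seqs))
  list(sequences = DNAStringSet(seqs), truth = do.call(rbind, truth),
       seed = seed)
}

#' Sensitivity and specificity of a screen against truth labels
#'
#' Sensitivity is the percentage of truth-contaminant sequences assigned a
#' corrective action (EXCLUDE, TRIM, FIX) whose reported division matches
#' the taxonomic division of the source genome; sequences assigned as
#' prokaryote virus count as true positives for prokaryote sources.
#' Specificity is the percentage of truth-clean sequences assigned no
#' corrective or review action (EXCLUDE, TRIM, FIX, REVIEW). Sequence-level
#' specificity bounds: the upper bound is
#' `100 * (1 - sameKingdomCallBp / (totalBp - crossKingdomCallBp))` and the
#' lower bound `100 * (1 - allCallBp / totalBp)`.
#'
#' A truth row whose `division` equals the screen's declared division counts
#' as clean (host); all other rows count as contaminant. Chimera truth rows
#' (non-NA `contamStart`) count as contaminant and score a true positive
#' when a corrective action overlaps the true contaminant range with the
#' matching division.
#'
#' @param screen A [GxScreen-class] (or its action-record data.frame plus a
#'   `context` argument).
#' @param truth Truth table from [generateQuerySet()].
#' @param context Screening context (defaulted from `screen`).
#' @return list with `sn`, `sp`, `spUpper`, `spLower`, `nContaminant`,
#'   `nClean`, `confusion` (action x truth-role table).
#' @export
evaluateSnSp <- function(screen, truth, context = NULL) {
  if (is(screen, "GxScreen")) {
    records <- gxRecords(screen)
    context <- gxContext(screen)
  } else records <- screen
  if (is.null(context)) stop("a screening context is required")
  bad <- setdiff(records$seqId, truth$id)
  if (length(bad))
    stop("screen reports sequence(s) absent from the truth table: ",
         paste(head(bad, 5L), collapse = ", "))
  divK <- context$divisionKingdoms
  corrective <- c("EXCLUDE", "TRIM", "FIX")

  isChimera <- !is.null(truth$contamStart) && any(!is.na(truth$contamStart))
  contamDiv <- if (isChimera) truth$contamDivision else truth$division
  contamKing <- if (isChimera) truth$contamKingdom else truth$kingdom
  role <- ifelse(
    if (isChimera) !is.na(truth$contamStart)
    else truth$division != context$declaredDivision,
    "contaminant", "clean")

  tp <- logical(nrow(truth)); fp <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    r <- records[records$seqId == truth$id[i], , drop = FALSE]
    if (role[i] == "contaminant") {
      hit <- r$action %in% corrective &
        (r$division == contamDiv[i] |
           (.isProk(contamKing[i]) & divK[r$division] == "Viruses" &
              .virusSuperkingdom(r$division) == "prok"))
      if (isChimera && any(hit, na.rm = TRUE)) {
        hit <- hit & r$end >= truth$contamStart[i] & r$start <= truth$contamEnd[i]
      }
      tp[i] <- any(hit, na.rm = TRUE)
    } else {
      fp[i] <- any(r$action %in% c(corrective, "REVIEW"))
    }
  }
  nContam <- sum(role == "contaminant"); nClean <- sum(role == "clean")
  sn <- if (nContam) 100 * sum(tp) / nContam else NA_real_
  sp <- if (nClean) 100 * (nClean - sum(fp)) / nClean else NA_real_

  totalBp <- sum(as.numeric(truth$length %||%
                              rep(NA_real_, nrow(truth))), na.rm = TRUE)
  if (!is.finite(totalBp) || totalBp == 0) {
    # fall back: lengths from the screen's sequence reports when available
    totalBp <- if (is(screen, "GxScreen"))
      sum(vapply(screen@sequenceReports, `[[`, 0, "length")) else NA_real_
  }
  callBp <- as.numeric(records$end - records$start + 1)
  sameK <- divK[records$division] == context$declaredKingdom
  spUpper <- if (is.finite(totalBp))
    100 * (1 - sum(callBp[sameK]) / (totalBp - sum(callBp[!sameK]))) else NA_real_
  spLower <- if (is.finite(totalBp))
    100 * (1 - sum(callBp) / totalBp) else NA_real_

  conf <- table(
    action = factor(records$action,
                    levels = c(corrective, "INFO", "REVIEW", "REVIEW_RARE")),
    role = factor(role[match(records$seqId, truth$id)],
                  levels = c("clean", "contaminant")))
  list(sn = sn, sp = sp, spUpper = spUpper, spLower = spLower,
       nContaminant = nContam, nClean = nClean, confusion = conf)
}
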