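#' @title GxDatabase: an h-mer-indexed reference set
#'
#' @description
#' A `GxDatabase` holds the packed reference sequences, the sorted h-mer node
#' index, and per-sequence taxonomy metadata used by the aligner. Nodes are
#' tuples (h-mer key, subject ordinal, signed subject position); on disk each
#' node occupies exactly 9 bytes (1-byte lower subkey, 4-byte ordinal, 4-byte
#' signed position whose sign encodes the orientation of the minimizing
#' strand). The 38-bit key splits into a 30-bit upper and 8-bit lower subkey;
#' lookup locates the upper-subkey bucket and binary-searches the lower
#' subkey within it.
#'
#' @slot sequences `DNAStringSet` of the (pseudorandom-filled) references.
#' @slot fill list of integer vectors: 1-based positions that were filled in
#'   for non-ACGT input bases; these never count toward identity segments.
#' @slot nodeKey,nodeOrdinal,nodePos the sorted node index. `nodePos` is
#'   1-based signed: `abs(pos) - 1` is the 0-based window start, a negative
#'   sign means the reverse-complement strand minimized the hash.
#' @slot bucketUpper,bucketStart sorted non-empty upper-subkey values and the
#'   0-based node offset where each bucket begins.
#' @slot metadata per-sequence data.frame: ordinal, seqid, taxid, species,
#'   division, kingdom, length, stride.
#' @slot taxonomy the taxonomy table the database was built against.
#' @slot k,hashBits,upperBits h-mer window size (56), key width (38) and
#'   upper subkey width (30).
#'
#' @seealso [buildGxDatabase()], [gxLookup()], [writeGxDatabase()]
#' @export
setClass("GxDatabase", representation(
  sequences = "DNAStringSet",
  fill = "list",
  nodeKey = "numeric",
  nodeOrdinal = "integer",
  nodePos = "integer",
  bucketUpper = "numeric",
  bucketStart = "numeric",
  metadata = "data.frame",
  taxonomy = "data.frame",
  k = "integer",
  hashBits = "integer",
  upperBits = "integer"
))

setValidity("GxDatabase", function(object) {
  msg <- character(0)
  n <- length(object@nodeKey)
  if (length(object@nodeOrdinal) != n || length(object@nodePos) != n)
    msg <- c(msg, "node columns must have equal length")
  if (is.unsorted(object@nodeKey))
    msg <- c(msg, "node index must be sorted by key")
  if (nrow(object@metadata) != length(object@sequences))
    msg <- c(msg, "metadata must have one row per sequence")
  if (n > 0) {
    if (is.unsorted(object@bucketUpper, strictly = TRUE))
      msg <- c(msg, "bucket upper subkeys must be strictly increasing")
    if (is.unsorted(object@bucketStart))
      msg <- c(msg, "bucket offsets must be non-decreasing")
    lens <- width(object@sequences)[object@nodeOrdinal]
    if (any(abs(object@nodePos) - 1 + object@k > lens))
      msg <- c(msg, "node positions must address valid windows")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GxDatabase", function(object) {
  md <- object@metadata
  cat(sprintf("GxDatabase: %d sequence(s), %.3f Mbp, %s node(s)\n",
              length(object@sequences),
              sum(as.numeric(width(object@sequences))) / 1e6,
              format(length(object@nodeKey), big.mark = ",")))
  cat(sprintf("  %d species in %d division(s) / %d kingdom(s)\n",
              length(unique(md$taxid)), length(unique(md$division)),
              length(unique(md$kingdom))))
  cat(sprintf("  h-mer: %d bp window, %d-bit key (%d/%d subkeys); stride %s bp\n",
              object@k, object@hashBits, object@upperBits,
              object@hashBits - object@upperBits,
              paste(sort(unique(md$stride)), collapse = "/")))
  invisible(object)
})

#' Accessors for GxDatabase components
#'
#' @param db A [GxDatabase-class] object.
#' @return `gxSequences()` the filled reference `DNAStringSet`;
#'   `gxMetadata()` the per-sequence metadata; `gxTaxonomy()` the taxonomy
#'   table; `gxNodes()` the node index as a data.frame with `key`, `ordinal`,
#'   `pos` (0-based start) and `orient`.
#' @export
gxSequences <- function(db) db@sequences

#' @rdname gxSequences
#' @export
gxMetadata <- function(db) db@metadata

#' @rdname gxSequences
#' @export
gxTaxonomy <- function(db) db@taxonomy

#' @rdname gxSequences
#' @export
gxNodes <- function(db) {
  data.frame(key = db@nodeKey, ordinal = db@nodeOrdinal,
             pos = abs(db@nodePos) - 1L,
             orient = ifelse(db@nodePos >= 0L, 1L, -1L))
}

# default stride: 10 bp for prokaryotes/viruses/synthetic, 20 bp for eukaryotes
.defaultStride <- function(kingdom) ifelse(.isEuk(kingdom), 20L, 10L)

#' Build an h-mer database from reference sequences
#'
#' Extracts h-mers from every reference at the kingdom-appropriate stride
#' (10 bp prokaryote/virus, 20 bp eukaryote, overridable), fills non-ACGT
#' bases with reproducible pseudorandom bases, and assembles the sorted node
#' index with per-upper-subkey bucket offsets.
#'
#' @param sequences `DNAStringSet` or path(s) to FASTA file(s).
#' @param taxonomy Taxonomy data.frame or path to a taxonomy TSV
#'   (see [readTaxonomy()]).
#' @param taxids Integer vector assigning a taxid to each sequence (recycled
#'   if length 1). Every taxid must resolve in `taxonomy`; a missing taxid is
#'   a hard error naming the offending sequence.
#' @param stride Optional stride override (single value or per sequence).
#' @param k h-mer window size in bp.
#' @return A [GxDatabase-class] object.
#' @examples
#' tax <- exampleTaxonomy()
#' set.seed(1)
#' refs <- Biostrings::DNAStringSet(setNames(paste(
#'   sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = ""), "chr1"))
#' db <- buildGxDatabase(refs, tax, taxids = 562)
#' db
#' @export
buildGxDatabase <- function(sequences, taxonomy, taxids, stride = NULL, k = 56L) {
  if (is.character(sequences))
    sequences <- do.call(c, lapply(sequences, readDNAStringSet))
  if (is.character(taxonomy) && length(taxonomy) == 1L)
    taxonomy <- readTaxonomy(taxonomy)
  taxonomy <- .validateTaxonomy(taxonomy)
  n <- length(sequences)
  ids <- names(sequences)
  if (is.null(ids))
    ids <- if (n) paste0("seq", seq_len(n)) else character(0)
  ids <- sub("\\s.*$", "", ids)
  taxids <- as.integer(rep_len(taxids, n))
  ti <- match(taxids, taxonomy$taxid)
  if (anyNA(ti)) {
    bad <- which(is.na(ti))[1L]
    stop("reference sequence '", ids[bad], "' has taxid ", taxids[bad],
         " which is missing from the taxonomy table")
  }
  kingdom <- taxonomy$kingdom[ti]
  if (is.null(stride)) stride <- .defaultStride(kingdom)
  stride <- as.integer(rep_len(stride, n))

  seqs <- character(n)
  fill <- vector("list", n)
  keys <- vector("list", n)
  for (i in seq_len(n)) {
    f <- cpp_fill_ambiguous(ids[i], as.character(sequences[[i]]))
    seqs[i] <- f$seq
    fill[[i]] <- as.integer(f$fill)
    h <- cpp_extract_hmers(f$seq, stride[i], as.integer(k), NULL)
    keys[[i]] <- h
  }
  nodeKey <- unlist(lapply(keys, `[[`, "key"), use.names = FALSE)
  if (is.null(nodeKey)) nodeKey <- numeric(0)
  nodeOrd <- rep.int(seq_len(n), vapply(keys, nrow, 0L))
  nodePos <- unlist(lapply(keys, function(h) h$orient * (h$pos + 1L)),
                    use.names = FALSE)
  if (is.null(nodePos)) nodePos <- integer(0)
  o <- order(nodeKey, nodeOrd, abs(nodePos))
  nodeKey <- nodeKey[o]; nodeOrd <- as.integer(nodeOrd[o])
  nodePos <- as.integer(nodePos[o])

  upper <- nodeKey %/% 256
  r <- rle(upper)
  bucketUpper <- r$values
  bucketStart <- if (length(r$lengths)) cumsum(c(0, r$lengths[-length(r$lengths)])) else numeric(0)

  md <- data.frame(
    ordinal = seq_len(n), seqid = ids, taxid = taxids,
    species = taxonomy$species[ti], division = taxonomy$division[ti],
    kingdom = kingdom, length = width(sequences), stride = stride,
    stringsAsFactors = FALSE)

  new("GxDatabase",
      sequences = DNAStringSet(setNames(seqs, ids)), fill = fill,
      nodeKey = nodeKey, nodeOrdinal = nodeOrd, nodePos = nodePos,
      bucketUpper = bucketUpper, bucketStart = bucketStart,
      metadata = md, taxonomy = taxonomy,
      k = as.integer(k), hashBits = cpp_hmer_key(strrep("A", k))$bits,
      upperBits = cpp_hmer_key(strrep("A", k))$bits - 8L)
}

#' Look up an h-mer key in the database index
#'
#' Locates the upper-subkey bucket via the precomputed bucket offsets, then
#' binary-searches the lower subkey within the bucket (cost logarithmic in
#' the bucket size). An absent key returns an empty result.
#'
#' @param db A [GxDatabase-class].
#' @param key Numeric key value(s), e.g. `canonicalHmer(w)$value`.
#' @return data.frame with one row per matching node: `key`, `ordinal`,
#'   `pos` (0-based window start on the subject), `orient` (+1/-1), `taxid`.
#' @export
gxLookup <- function(db, key) {
  key <- if (inherits(key, "HmerKey")) key$value else as.numeric(key)
  out <- lapply(key, function(k1) {
    up <- k1 %/% 256
    b <- findInterval(up, db@bucketUpper)
    if (b == 0L || db@bucketUpper[b] != up) return(integer(0))
    from <- db@bucketStart[b] + 1
    to <- if (b < length(db@bucketStart)) db@bucketStart[b + 1] else length(db@nodeKey)
    # binary search on the lower subkey inside the bucket
    lo <- from + findInterval(k1 - 0.5, db@nodeKey[from:to])
    hi <- from - 1 + findInterval(k1, db@nodeKey[from:to])
    if (lo > hi) integer(0) else seq.int(lo, hi)
  })
  idx <- unlist(out, use.names = FALSE)
  if (is.null(idx)) idx <- integer(0)
  data.frame(key = db@nodeKey[idx],
             ordinal = db@nodeOrdinal[idx],
             pos = abs(db@nodePos[idx]) - 1L,
             orient = ifelse(db@nodePos[idx] >= 0L, 1L, -1L),
             taxid = db@metadata$taxid[db@nodeOrdinal[idx]])
}

# ---- on-disk form -----------------------------------------------------------
# <prefix>.gxi : magic "GXI1", int32 version, hashBits, upperBits, k,
#                nBuckets, nNodes; then nBuckets x (uint32 upper subkey,
#                uint32 node offset); then nNodes x 9-byte nodes. Little-endian.
# <prefix>.gxs : magic "GXS1", int32 version, nSeq; per sequence: int32 name
#                length, name bytes, int32 sequence length, 2-bit packed
#                bases, int32 nFillRuns, nFillRuns x (int32 start0, int32 len).
# <prefix>.meta.tsv / .meta.json : per-sequence metadata and parameters.

#' Write / read a database in its on-disk form
#'
#' The on-disk form round-trips bit-exactly: `writeGxDatabase()` after
#' `readGxDatabase()` reproduces byte-identical `.gxi` and `.gxs` files.
#'
#' @param db A [GxDatabase-class].
#' @param prefix Path prefix; files `<prefix>.gxi`, `<prefix>.gxs`,
#'   `<prefix>.meta.tsv` and `<prefix>.meta.json` are written.
#' @return `writeGxDatabase()` returns the prefix invisibly;
#'   `readGxDatabase()` returns the [GxDatabase-class].
#' @export
writeGxDatabase <- function(db, prefix) {
  gxi <- file(paste0(prefix, ".gxi"), "wb")
  on.exit(close(gxi), add = TRUE)
  writeBin(charToRaw("GXI1"), gxi)
  writeBin(as.integer(c(1L, db@hashBits, db@upperBits, db@k,
                        length(db@bucketUpper), length(db@nodeKey))),
           gxi, size = 4L, endian = "little")
  if (length(db@bucketUpper)) {
    tab <- rbind(db@bucketUpper, db@bucketStart)
    writeBin(as.integer(tab), gxi, size = 4L, endian = "little")
  }
  writeBin(as.vector(cpp_pack_nodes(db@nodeKey, db@nodeOrdinal, db@nodePos)), gxi)

  gxs <- file(paste0(prefix, ".gxs"), "wb")
  on.exit(close(gxs), add = TRUE)
  writeBin(charToRaw("GXS1"), gxs)
  writeBin(as.integer(c(1L, length(db@sequences))), gxs, size = 4L,
           endian = "little")
  for (i in seq_along(db@sequences)) {
    nm <- charToRaw(names(db@sequences)[i])
    writeBin(length(nm), gxs, size = 4L, endian = "little")
    writeBin(nm, gxs)
    s <- as.character(db@sequences[[i]])
    writeBin(nchar(s), gxs, size = 4L, endian = "little")
    writeBin(as.vector(cpp_pack2bit(s)), gxs)
    runs <- reduce(IRanges(db@fill[[i]], width = 1L))
    writeBin(length(runs), gxs, size = 4L, endian = "little")
    if (length(runs))
      writeBin(as.integer(rbind(start(runs) - 1L, width(runs))), gxs,
               size = 4L, endian = "little")
  }

  write.table(db@metadata, paste0(prefix, ".meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(format = "gxdb", version = 1L, k = db@k, hashBits = db@hashBits,
         upperBits = db@upperBits, nSequences = length(db@sequences),
         nNodes = length(db@nodeKey),
         taxonomy = db@taxonomy),
    paste0(prefix, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname writeGxDatabase
#' @export
readGxDatabase <- function(prefix) {
  gxi <- file(paste0(prefix, ".gxi"), "rb")
  on.exit(close(gxi), add = TRUE)
  stopifnot(identical(rawToChar(readBin(gxi, "raw", 4L)), "GXI1"))
  hdr <- readBin(gxi, "integer", 6L, size = 4L, endian = "little")
  names(hdr) <- c("version", "hashBits", "upperBits", "k", "nBuckets", "nNodes")
  tab <- readBin(gxi, "integer", 2L * hdr[["nBuckets"]], size = 4L,
                 endian = "little")
  tab <- matrix(as.numeric(tab), nrow = 2L)
  raw <- readBin(gxi, "raw", 9L * hdr[["nNodes"]])
  nodes <- cpp_unpack_nodes(raw, tab[1L, ], tab[2L, ])

  gxs <- file(paste0(prefix, ".gxs"), "rb")
  on.exit(close(gxs), add = TRUE)
  stopifnot(identical(rawToChar(readBin(gxs, "raw", 4L)), "GXS1"))
  h2 <- readBin(gxs, "integer", 2L, size = 4L, endian = "little")
  nseq <- h2[2L]
  seqs <- character(nseq); ids <- character(nseq); fill <- vector("list", nseq)
  for (i in seq_len(nseq)) {
    nl <- readBin(gxs, "integer", 1L, size = 4L, endian = "little")
    ids[i] <- rawToChar(readBin(gxs, "raw", nl))
    sl <- readBin(gxs, "integer", 1L, size = 4L, endian = "little")
    packed <- readBin(gxs, "raw", (sl + 3L) %/% 4L)
    seqs[i] <- cpp_unpack2bit(packed, sl)
    nr <- readBin(gxs, "integer", 1L, size = 4L, endian = "little")
    if (nr > 0L) {
      rr <- matrix(readBin(gxs, "integer", 2L * nr, size = 4L,
                           endian = "little"), nrow = 2L)
      fill[[i]] <- as.integer(unlist(lapply(seq_len(nr), function(j)
        seq.int(rr[1L, j] + 1L, length.out = rr[2L, j]))))
    } else fill[[i]] <- integer(0)
  }

  md <- read.delim(paste0(prefix, ".meta.tsv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, ".meta.json"), simplifyVector = TRUE)
  new("GxDatabase",
      sequences = DNAStringSet(setNames(seqs, ids)), fill = fill,
      nodeKey = nodes$key, nodeOrdinal = as.integer(nodes$ordinal),
      nodePos = as.integer(nodes$pos),
      bucketUpper = tab[1L, ], bucketStart = tab[2L, ],
      metadata = md, taxonomy = .validateTaxonomy(meta$taxonomy),
      k = hdr[["k"]], hashBits = hdr[["hashBits"]],
      upperBits = hdr[["upperBits"]])
}
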