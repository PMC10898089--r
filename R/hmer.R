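#' Canonical h-mer key for a nucleotide window
#'
#' An h-mer is a hashed, modified k-mer: every third base of the window (the
#' codon-wobble position when the window is in-frame coding sequence) is
#' dropped on each strand's own 5'-to-3' reading, the retained bases are
#' encoded with a one-bit purine/pyrimidine alphabet (A,G -> 0; C,T -> 1),
#' both strand encodings are passed through a fixed 64-bit mixing hash, and
#' the lesser hash is the canonical key. A 56-bp window therefore yields a
#' 38-bit key that is invariant to strand, to transition substitutions at
#' retained positions, and to any substitution at a wobble position.
#'
#' @param window A single character string (or `DNAString`) of A/C/G/T bases.
#'   The default full-size window is 56 bp; the pass-2 query index uses 30-bp
#'   windows (20-bit keys).
#' @param k Window size; defaults to the full length of `window`. When
#'   `window` is shorter than `k` no key can be formed and `NULL` is returned
#'   (callers skip such windows).
#'
#' @return A list of class `HmerKey` with elements `value` (the key, a
#'   non-negative number below 2^bits), `upper` and `lower` (the 30-bit/8-bit
#'   subkey split used by the index for full-size keys), `orient` (+1 if the
#'   forward-strand hash minimized, -1 otherwise; ties are forward), `bits`
#'   (key width), and the pre-hash packed values `packedFwd`/`packedRc`.
#'
#' @examples
#' w <- paste(rep(c("A", "C", "G", "T"), 14), collapse = "")
#' key <- canonicalHmer(w)
#' key$bits                      # 38 retained bases -> 38-bit key
#' rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
#' identical(key$value, canonicalHmer(rc)$value)
#'
#' @export
canonicalHmer <- function(window, k = NULL) {
  window <- toupper(as.character(window))
  if (is.null(k)) k <- nchar(window)
  if (nchar(window) < k) return(NULL)
  res <- cpp_hmer_key(substr(window, 1L, k))
  structure(list(
    value = res$key,
    upper = res$key %/% 256,
    lower = res$key %% 256,
    orient = res$orient,
    bits = res$bits,
    packedFwd = res$packed_fwd,
    packedRc = res$packed_rc
  ), class = "HmerKey")
}

#' @export
print.HmerKey <- function(x, ...) {
  cat(sprintf("HmerKey: value %.0f (%d-bit), upper %.0f, lower %d, strand %s\n",
              x$value, x$bits, x$upper, as.integer(x$lower),
              if (x$orient > 0) "+" else "-"))
  invisible(x)
}

#' Extract h-mers from a sequence at a fixed stride
#'
#' Windows start at 0, `stride`, `2 * stride`, ... and a window is emitted
#' only when it fits entirely inside the sequence (`start + k <= length`).
#' Reference databases use a 10-bp stride for prokaryotes and viruses and a
#' 20-bp stride for eukaryotes.
#'
#' @param seq Character string or `DNAString` of A/C/G/T bases (ambiguous
#'   bases must have been pseudorandom-filled upstream, see
#'   [fillAmbiguousBases()]).
#' @param stride Distance between window starts, in bp (>= 1).
#' @param k Window size in bp (default 56).
#' @param skip Optional logical vector, one element per base; windows with at
#'   least half their bases flagged are suppressed (used to exclude masked
#'   regions from seeding).
#'
#' @return A data.frame with columns `pos` (0-based window start), `key`
#'   (canonical h-mer key) and `orient` (+1/-1, the strand that minimized the
#'   hash). Sequences shorter than `k` yield zero rows.
#'
#' @examples
#' s <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
#' nrow(extractHmers(s, stride = 20))  # starts 0, 20, 40
#'
#' @export
extractHmers <- function(seq, stride, k = 56L, skip = NULL) {
  stopifnot(stride >= 1L)
  seq <- toupper(as.character(seq))
  if (nchar(seq) < k)
    return(data.frame(pos = integer(0), key = numeric(0), orient = integer(0)))
  cpp_extract_hmers(seq, as.integer(stride), as.integer(k), skip)
}
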