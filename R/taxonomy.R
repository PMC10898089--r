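#' The eight kingdom-level groups used for reporting
#'
#' Taxonomic divisions are grouped into eight broad "kingdoms" that drive the
#' intra- versus inter-kingdom reporting rules: animals (Metazoa), plants
#' (Viridiplantae), Fungi, protists (other-Eukaryota), Bacteria, Archaea,
#' Viruses and Synthetic. Bacteria and Archaea are kept as distinct kingdoms.
#'
#' @return Character vector of the eight kingdom names.
#' @export
gxKingdoms <- function() {
  c("Metazoa", "Viridiplantae", "Fungi", "other-Eukaryota",
    "Bacteria", "Archaea", "Viruses", "Synthetic")
}

.eukKingdoms <- function() c("Metazoa", "Viridiplantae", "Fungi", "other-Eukaryota")
.prokKingdoms <- function() c("Bacteria", "Archaea")

.isEuk <- function(kingdom) kingdom %in% .eukKingdoms()
.isProk <- function(kingdom) kingdom %in% .prokKingdoms()

# virus divisions are split by host superkingdom to support the virus rules;
# classification is by the division name prefix convention
.virusSuperkingdom <- function(division) {
  ifelse(grepl("prok", division), "prok",
         ifelse(grepl("euk", division), "euk", "other"))
}

.validateTaxonomy <- function(tax) {
  need <- c("taxid", "species", "division", "kingdom")
  if (!all(need %in% names(tax)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  tax$taxid <- as.integer(tax$taxid)
  if (anyDuplicated(tax$taxid))
    stop("taxonomy table has duplicated taxids: ",
         paste(unique(tax$taxid[duplicated(tax$taxid)]), collapse = ", "))
  bad <- setdiff(unique(tax$kingdom), gxKingdoms())
  if (length(bad))
    stop("unknown kingdom(s) in taxonomy table: ", paste(bad, collapse = ", "),
         "; expected one of ", paste(gxKingdoms(), collapse = ", "))
  # a division must map to exactly one kingdom
  dk <- unique(tax[, c("division", "kingdom")])
  if (anyDuplicated(dk$division))
    stop("division(s) mapped to more than one kingdom: ",
         paste(unique(dk$division[duplicated(dk$division)]), collapse = ", "))
  tax[, need]
}

#' Read a taxonomy table
#'
#' The taxonomy table maps each taxid to a species name, a taxonomic division
#' (the unit at which contamination is assigned, named in
#' `kingdom-prefix:division` style, e.g. `anml:primates`) and one of the
#' eight kingdoms from [gxKingdoms()]. Every division must resolve to exactly
#' one kingdom.
#'
#' @param path Path to a tab-separated file with header columns
#'   `taxid`, `species`, `division`, `kingdom`.
#' @return A validated data.frame.
#' @seealso [exampleTaxonomy()] for the miniature table shipped with the
#'   package, [resolveLineage()] for lookups.
#' @export
readTaxonomy <- function(path) {
  tax <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    quote = "", comment.char = "#")
  .validateTaxonomy(tax)
}

#' Miniature example taxonomy
#'
#' A small taxonomy table covering all eight kingdoms with example real-world
#' taxa (e.g. human taxid 9606 in division `anml:primates`, kingdom Metazoa).
#' Intended for examples and as a template for user tables; synthetic worlds
#' built by [generateReferenceSet()] carry their own tables.
#'
#' @return A taxonomy data.frame.
#' @export
exampleTaxonomy <- function() {
  readTaxonomy(system.file("extdata", "example_taxa.tsv", package = "gxscreen"))
}

#' Resolve a taxid to its species, division and kingdom
#'
#' @param taxid Integer taxid present in the table.
#' @param taxonomy Taxonomy data.frame (see [readTaxonomy()]).
#' @return A list with `taxid`, `species`, `division`, `kingdom`.
#' @examples
#' resolveLineage(9606, exampleTaxonomy())$division  # "anml:primates"
#' @export
resolveLineage <- function(taxid, taxonomy) {
  taxonomy <- .validateTaxonomy(taxonomy)
  i <- match(as.integer(taxid), taxonomy$taxid)
  if (is.na(i))
    stop("taxid ", taxid, " is not present in the taxonomy table; ",
         "add a row (taxid, species, division, kingdom) for it or check ",
         "the declared taxid")
  as.list(taxonomy[i, c("taxid", "species", "division", "kingdom")])
}

# division -> kingdom lookup from a taxonomy table
.divisionKingdoms <- function(taxonomy) {
  dk <- unique(taxonomy[, c("division", "kingdom")])
  setNames(dk$kingdom, dk$division)
}
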