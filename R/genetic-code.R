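#' @import methods
NULL

# 20 standard amino-acid one-letter codes, the pad/gap character used for
# length normalisation, and tolerated ambiguity codes.  Pairs involving
# anything outside STANDARD_AA are non-comparable in the semihomology sense.
STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
PAD_CHAR <- "-"
AMBIGUITY_AA <- c("X", "B", "Z", "J", "U", "O", "*")

#' Full residue alphabet used for network encodings
#'
#' The 20 standard amino acids, the pad character \code{"-"} appended during
#' length normalisation, and the tolerated ambiguity codes
#' (X, B, Z, J, U, O, *). 28 symbols in total, so every symbol can receive a
#' distinct five-bit code.
#'
#' @return Character vector of single-character symbols.
#' @export
aaAlphabet <- function() c(STANDARD_AA, PAD_CHAR, AMBIGUITY_AA)

#' Genetic-code table
#'
#' Wraps a 64-entry codon-to-amino-acid table keyed by an NCBI translation
#' table number. Tables are obtained from \pkg{Biostrings}
#' (\code{\link[Biostrings]{getGeneticCode}}); table 1 (standard) and table 2
#' (vertebrate mitochondrial) are the ones relevant for nuclear- and
#' mitochondrially-encoded proteins such as cytochrome b.
#'
#' @slot tableId integer NCBI translation table number (0 for custom tables).
#' @slot codons named character vector of length 64 mapping DNA codons to
#'   amino-acid letters, with \code{"*"} marking stop codons.
#' @export
setClass("GeneticCode",
         slots = c(tableId = "integer", codons = "character"))

setValidity("GeneticCode", function(object) {
  msgs <- character()
  if (length(object@codons) != 64L)
    msgs <- c(msgs, "codon table must have exactly 64 entries")
  nm <- names(object@codons)
  if (is.null(nm) || !all(grepl("^[ACGT]{3}$", nm)))
    msgs <- c(msgs, "codon names must be DNA triplets over A/C/G/T")
  bad <- setdiff(unique(object@codons), c(STANDARD_AA, "*"))
  if (length(bad))
    msgs <- c(msgs, paste0("non-standard amino-acid letters in table: ",
                           paste(bad, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a genetic code from an NCBI translation table number
#'
#' @param table NCBI translation table id (1 = standard, 2 = vertebrate
#'   mitochondrial, ...). RNA input is not relevant here: tables are stored
#'   over the DNA alphabet (U is normalised to T on any codon input).
#' @return A \linkS4class{GeneticCode}.
#' @examples
#' geneticCode(1)
#' geneticCode(2)
#' @export
geneticCode <- function(table = 1L) {
  table <- as.integer(table)
  codons <- tryCatch(
    Biostrings::getGeneticCode(as.character(table)),
    error = function(e) stop("unknown NCBI translation table id: ", table,
                             call. = FALSE))
  attributes(codons) <- list(names = names(codons))
  new("GeneticCode", tableId = table, codons = codons)
}

#' Read a genetic code from a two-column text file
#'
#' Each non-comment line holds a codon (DNA or RNA triplet) and an
#' amino-acid letter or \code{*} for stop, whitespace-separated. All 64
#' codons must be present.
#'
#' @param path file path.
#' @param tableId id to record on the resulting object (default 0 = custom).
#' @return A \linkS4class{GeneticCode}.
#' @export
readGeneticCode <- function(path, tableId = 0L) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("codon", "aa"),
                           colClasses = "character", comment.char = "#")
  codon <- toupper(gsub("U", "T", toupper(tab$codon)))
  if (anyDuplicated(codon))
    stop("duplicated codons in genetic-code file: ",
         paste(unique(codon[duplicated(codon)]), collapse = ", "))
  codons <- stats::setNames(toupper(tab$aa), codon)
  # order canonically (TTT..GGG) to match built-ins
  ref <- names(Biostrings::getGeneticCode("1"))
  missing <- setdiff(ref, names(codons))
  if (length(missing))
    stop("genetic-code file is missing ", length(missing), " codons (e.g. ",
         missing[1L], ")")
  new("GeneticCode", tableId = as.integer(tableId), codons = codons[ref])
}

#' @describeIn geneticCode NCBI table id of a code
#' @param code a \linkS4class{GeneticCode}.
#' @export
tableId <- function(code) code@tableId

#' @describeIn geneticCode the named 64-codon character vector
#' @export
codonTable <- function(code) code@codons

#' Codons encoding one amino acid
#'
#' Stop codons are never included: a mutational path through a stop codon is
#' not a one-point amino-acid substitution.
#'
#' @param code a \linkS4class{GeneticCode}.
#' @param aa single amino-acid letter.
#' @return Character vector of codons (possibly empty).
#' @export
codonsOf <- function(code, aa) {
  names(code@codons)[code@codons == aa & code@codons != "*"]
}

#' Translate a codon string under a genetic code
#'
#' @param code a \linkS4class{GeneticCode}.
#' @param codonString character string whose length is a multiple of 3, or a
#'   \code{DNAString}/\code{DNAStringSet}.
#' @return Amino-acid character string(s).
#' @export
translateCodons <- function(code, codonString) {
  dna <- Biostrings::DNAStringSet(codonString)
  aa <- Biostrings::translate(dna, genetic.code = .asBiostringsCode(code),
                              no.init.codon = TRUE)
  out <- as.character(aa)
  if (is.character(codonString) && length(codonString) == 1L) out[[1L]] else out
}

# Biostrings::translate() wants the alt_init_codons attribute present.
.asBiostringsCode <- function(code) {
  gc <- code@codons
  attr(gc, "alt_init_codons") <- character(0)
  gc
}

setMethod("show", "GeneticCode", function(object) {
  nstop <- sum(object@codons == "*")
  cat("GeneticCode (NCBI table ", object@tableId, "): 64 codons, ",
      nstop, " stops, ", length(unique(object@codons)) - 1L,
      " amino acids\n", sep = "")
})
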