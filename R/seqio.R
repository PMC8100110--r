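#' Read amino-acid sequences from a FASTA file
#'
#' Thin wrapper around \code{\link[Biostrings]{readAAStringSet}} that
#' normalises residues to uppercase and strips a trailing \code{"*"}
#' (stop marker) from each record. Record order is preserved; record names
#' are the organism identifiers used everywhere else in the package.
#'
#' @param path FASTA file path.
#' @return An \code{AAStringSet} (possibly empty).
#' @export
readFastaRecords <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonEmpty <- which(nzchar(trimws(lines)))
  if (length(nonEmpty) && !startsWith(trimws(lines[nonEmpty[1L]]), ">"))
    stop("malformed FASTA (", path, "): expected a '>' header at line ",
         nonEmpty[1L])
  if (!length(nonEmpty)) return(Biostrings::AAStringSet())
  x <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(x))
  seqs <- sub("\\*+$", "", seqs)
  # keep only the first whitespace token of each header as the id
  ids <- sub("\\s.*$", "", names(x))
  Biostrings::AAStringSet(stats::setNames(seqs, ids))
}

#' Write amino-acid sequences to a FASTA file
#'
#' @param x an \code{AAStringSet} or named character vector.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFastaRecords <- function(x, path) {
  if (!is(x, "XStringSet")) x <- Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Normalise sequences to a fixed length
#'
#' Shorter sequences are padded at the end with the \code{"-"} character;
#' longer sequences are cut at the end. This is the only length
#' normalisation used: no alignment is ever performed.
#'
#' @param x character vector or \code{AAStringSet}.
#' @param targetLength desired length (default 400, the network input
#'   length used for cytochrome b).
#' @return Same type as the input, every element of length
#'   \code{targetLength}.
#' @examples
#' padOrTrim("MK", 4)      # "MK--"
#' padOrTrim("MKVLH", 3)   # "MKV"
#' @export
padOrTrim <- function(x, targetLength = 400L) {
  targetLength <- as.integer(targetLength)
  stopifnot(targetLength >= 1L)
  wasSet <- is(x, "XStringSet")
  s <- as.character(x)
  out <- vapply(s, function(si) {
    n <- nchar(si)
    if (n >= targetLength) substr(si, 1L, targetLength)
    else paste0(si, strrep(PAD_CHAR, targetLength - n))
  }, character(1), USE.NAMES = FALSE)
  names(out) <- names(s)
  if (wasSet) Biostrings::AAStringSet(stats::setNames(out, names(x))) else out
}

#' Read and validate a group-assignment table
#'
#' A tab-separated file with header columns \code{organism_id},
#' \code{group}, \code{role} and \code{is_reference}. Roles are
#' \code{teach} (sequence defines an output neuron) or \code{examine}
#' (sequence is only recognised). Exactly one row must be flagged as the
#' reference organism, against which semihomologous profiles and orbit
#' radii are computed.
#'
#' @param path TSV file path.
#' @return A \code{data.frame} with the four columns, \code{is_reference}
#'   logical.
#' @export
readGroupTable <- function(path) {
  if (!file.exists(path)) stop("group table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character")
  need <- c("organism_id", "group", "role", "is_reference")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("group table is missing column(s): ", paste(miss, collapse = ", "))
  tab <- tab[need]
  dup <- unique(tab$organism_id[duplicated(tab$organism_id)])
  if (length(dup))
    stop("duplicated organism id(s) in group table: ",
         paste(dup, collapse = ", "))
  badRole <- unique(tab$role[!tab$role %in% c("teach", "examine")])
  if (length(badRole))
    stop("unknown role(s) in group table (must be teach/examine): ",
         paste(badRole, collapse = ", "))
  tab$is_reference <- toupper(tab$is_reference) %in% c("TRUE", "T", "1", "YES")
  nref <- sum(tab$is_reference)
  if (nref != 1L)
    stop("group table must flag exactly one reference organism, found ",
         nref, if (nref > 1L) paste0(" (",
           paste(tab$organism_id[tab$is_reference], collapse = ", "), ")"))
  tab
}

#' Write a group-assignment table
#'
#' @param tab data.frame with columns organism_id, group, role,
#'   is_reference.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeGroupTable <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
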