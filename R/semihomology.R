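# Position classes of the semihomologous comparison.
#   R  identical residues (homologous position)
#   #  codons interconvertible by a single transition point mutation
#   $  codons interconvertible by a single transversion point mutation
#   -  every codon pair differs at two or three nucleotide positions
#   ?  non-comparable (pad character, ambiguity code, anything non-standard)
CLASS_R <- "R"
CLASS_TRANSITION <- "#"
CLASS_TRANSVERSION <- "$"
CLASS_MULTI <- "-"
CLASS_NONCOMPARABLE <- "?"
PAIR_CLASSES <- c(CLASS_R, CLASS_TRANSITION, CLASS_TRANSVERSION, CLASS_MULTI)

#' Semihomology classification matrix
#'
#' A symmetric 20x20 lookup from an unordered pair of standard amino acids to
#' its semihomologous position class, derived from a genetic code. The
#' diagonal is always \code{R}.
#'
#' @slot code the \linkS4class{GeneticCode} the matrix was derived from.
#' @slot classes 20x20 character matrix over \code{STANDARD_AA}, entries in
#'   \code{R}, \code{#}, \code{$}, \code{-}.
#' @seealso \code{\link{buildSemihomologyMatrix}}, \code{\link{classifyPair}}
#' @export
setClass("SemihomologyMatrix",
         slots = c(code = "GeneticCode", classes = "matrix"))

setValidity("SemihomologyMatrix", function(object) {
  cl <- object@classes
  msgs <- character()
  if (!identical(dim(cl), c(20L, 20L)) ||
      !identical(rownames(cl), STANDARD_AA) ||
      !identical(colnames(cl), STANDARD_AA))
    msgs <- c(msgs, "classes must be a 20x20 matrix over the standard amino acids")
  else {
    if (!all(cl %in% PAIR_CLASSES))
      msgs <- c(msgs, "invalid class symbol in matrix")
    if (!identical(cl, t(cl)))
      msgs <- c(msgs, "class matrix must be symmetric")
    if (!all(diag(cl) == CLASS_R))
      msgs <- c(msgs, "diagonal must be R (identical residues)")
  }
  if (length(msgs)) msgs else TRUE
})

# Pairwise codon relation over all 64 codons: Hamming distance and, for
# distance-1 pairs, whether the differing nucleotide exchange is a
# transition (A<->G, C<->T) or a transversion.
.codonPairRelation <- function() {
  codons <- names(Biostrings::getGeneticCode("1"))
  bases <- do.call(rbind, strsplit(codons, ""))
  purine <- array(bases %in% c("A", "G"), dim = dim(bases))
  d <- matrix(0L, 64L, 64L, dimnames = list(codons, codons))
  ts <- matrix(FALSE, 64L, 64L, dimnames = list(codons, codons))
  for (p in 1:3) {
    same <- outer(bases[, p], bases[, p], "==")
    d <- d + !same
    # exchange at this position is a transition iff both bases are purines
    # or both pyrimidines
    sameType <- outer(purine[, p], purine[, p], "==")
    ts <- ts | (!same & sameType)
  }
  list(dist = d, transition = ts)
}

#' Build the semihomology matrix from a genetic code
#'
#' For two distinct amino acids the class is determined by the minimal
#' point-mutation paths between their codon sets (stop codons excluded):
#' if some codon of one differs from some codon of the other at exactly one
#' nucleotide, the pair is semihomologous — class \code{#} when at least one
#' such single-difference pair is a transition (the more frequent mutation
#' type, hence preferred when both path types exist), otherwise \code{$};
#' if every codon pair differs at two or more positions the class is
#' \code{-}.
#'
#' @param code a \linkS4class{GeneticCode}.
#' @return A \linkS4class{SemihomologyMatrix}.
#' @examples
#' m <- buildSemihomologyMatrix(geneticCode(1))
#' classifyPair("D", "E", m)  # "$"
#' classifyPair("I", "M", m)  # "#"
#' @export
buildSemihomologyMatrix <- function(code) {
  stopifnot(is(code, "GeneticCode"))
  rel <- .codonPairRelation()
  sets <- lapply(STANDARD_AA, function(a) codonsOf(code, a))
  names(sets) <- STANDARD_AA
  empty <- STANDARD_AA[lengths(sets) == 0L]
  if (length(empty))
    stop("no codons for amino acid(s) ", paste(empty, collapse = ", "),
         " under translation table ", code@tableId)
  cl <- matrix(CLASS_MULTI, 20L, 20L,
               dimnames = list(STANDARD_AA, STANDARD_AA))
  for (i in seq_along(STANDARD_AA)) {
    for (j in seq_len(i - 1L)) {
      ca <- sets[[i]]; cb <- sets[[j]]
      d1 <- rel$dist[ca, cb, drop = FALSE] == 1L
      if (any(d1)) {
        hasTs <- any(rel$transition[ca, cb, drop = FALSE] & d1)
        cls <- if (hasTs) CLASS_TRANSITION else CLASS_TRANSVERSION
      } else cls <- CLASS_MULTI
      cl[i, j] <- cls
      cl[j, i] <- cls
    }
  }
  diag(cl) <- CLASS_R
  new("SemihomologyMatrix", code = code, classes = cl)
}

#' Classify residue pairs
#'
#' Total, vectorised lookup into a \linkS4class{SemihomologyMatrix}. Any
#' position where either symbol is not one of the 20 standard amino acids
#' (pad \code{"-"}, X, B, Z, J, U, O, \code{*}, ...) is
#' \code{"?"} (non-comparable).
#'
#' @param a,b character vectors of single residue letters (recycled).
#' @param m a \linkS4class{SemihomologyMatrix}.
#' @return Character vector of class symbols \code{R # $ - ?}.
#' @export
classifyPair <- function(a, b, m) {
  stopifnot(is(m, "SemihomologyMatrix"))
  n <- max(length(a), length(b))
  a <- rep_len(toupper(as.character(a)), n)
  b <- rep_len(toupper(as.character(b)), n)
  ia <- match(a, STANDARD_AA)
  ib <- match(b, STANDARD_AA)
  out <- rep(CLASS_NONCOMPARABLE, n)
  ok <- !is.na(ia) & !is.na(ib)
  out[ok] <- m@classes[cbind(ia[ok], ib[ok])]
  out
}

#' Position-by-position semihomologous comparison of two sequences
#'
#' Holds per-position classes and summary statistics of one pairwise
#' comparison: counts of \code{R}, \code{#}, \code{$} and \code{-}
#' positions, the corresponding percentages of the comparable length, and
#' the \code{#/$} factor (ratio of transition- to transversion-type
#' semihomologous positions; \code{NA} when no \code{$} position exists).
#' Non-comparable positions are excluded from the comparable length and
#' from every percentage denominator.
#'
#' @slot id1,id2 sequence identifiers (may be empty strings).
#' @slot lengthCompared number of positions where both symbols are standard
#'   amino acids.
#' @slot perPosition character vector of class symbols, one per aligned
#'   position (1-based).
#' @slot counts named integer vector with elements \code{R}, \code{#},
#'   \code{$}, \code{-}.
#' @slot pctR,pctSemihomologous,pctMulti percentages of
#'   \code{lengthCompared} (\code{# + $} combined for semihomologous).
#' @slot tsTvFactor numeric \code{#/$} ratio, \code{NA} if undefined.
#' @export
setClass("ComparisonProfile",
         slots = c(id1 = "character", id2 = "character",
                   lengthCompared = "integer", perPosition = "character",
                   counts = "integer", pctR = "numeric",
                   pctSemihomologous = "numeric", pctMulti = "numeric",
                   tsTvFactor = "numeric"))

setValidity("ComparisonProfile", function(object) {
  msgs <- character()
  if (!identical(names(object@counts), PAIR_CLASSES))
    msgs <- c(msgs, "counts must be named R, #, $, -")
  else if (sum(object@counts) != object@lengthCompared)
    msgs <- c(msgs, "counts must sum to lengthCompared")
  if (object@lengthCompared > 0L) {
    tot <- object@pctR + object@pctSemihomologous + object@pctMulti
    if (abs(tot - 100) > 1e-9)
      msgs <- c(msgs, "percentages must sum to 100")
    if (any(c(object@pctR, object@pctSemihomologous, object@pctMulti) < 0) ||
        any(c(object@pctR, object@pctSemihomologous, object@pctMulti) > 100))
      msgs <- c(msgs, "percentages must lie in [0, 100]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Compare two equal-length amino-acid sequences position by position
#'
#' Sequences must already share one length (see \code{\link{padOrTrim}};
#' no alignment is performed here). Each position is classified with
#' \code{\link{classifyPair}}; non-comparable positions (pads, ambiguity
#' codes) are excluded from all denominators.
#'
#' @param s1,s2 character strings or \code{AAString}s of equal length.
#' @param m a \linkS4class{SemihomologyMatrix}.
#' @param id1,id2 optional identifiers stored on the result.
#' @return A \linkS4class{ComparisonProfile}.
#' @examples
#' m <- buildSemihomologyMatrix(geneticCode(1))
#' compareSequences("DD", "EE", m)   # fully semihomologous, both positions $
#' @export
compareSequences <- function(s1, s2, m, id1 = "", id2 = "") {
  c1 <- strsplit(toupper(as.character(s1)), "")[[1L]]
  c2 <- strsplit(toupper(as.character(s2)), "")[[1L]]
  if (length(c1) != length(c2))
    stop("sequence lengths differ (", length(c1), " vs ", length(c2),
         "); pad or trim to a common length first")
  cls <- classifyPair(c1, c2, m)
  comparable <- cls != CLASS_NONCOMPARABLE
  counts <- vapply(PAIR_CLASSES, function(k) sum(cls == k), integer(1))
  lc <- sum(comparable)
  pct <- if (lc > 0L) 100 * counts / lc else stats::setNames(rep(NA_real_, 4), PAIR_CLASSES)
  tsTv <- if (counts[[CLASS_TRANSVERSION]] > 0L)
    counts[[CLASS_TRANSITION]] / counts[[CLASS_TRANSVERSION]] else NA_real_
  new("ComparisonProfile", id1 = as.character(id1), id2 = as.character(id2),
      lengthCompared = as.integer(lc), perPosition = cls, counts = counts,
      pctR = pct[[CLASS_R]],
      pctSemihomologous = pct[[CLASS_TRANSITION]] + pct[[CLASS_TRANSVERSION]],
      pctMulti = pct[[CLASS_MULTI]], tsTvFactor = tsTv)
}

#' @describeIn compareSequences counts accessor (named R, #, $, -)
#' @param x a \linkS4class{ComparisonProfile}.
#' @export
classCounts <- function(x) x@counts

#' @describeIn compareSequences per-position class symbols
#' @export
perPosition <- function(x) x@perPosition

#' @describeIn compareSequences number of comparable positions
#' @export
lengthCompared <- function(x) x@lengthCompared

#' @describeIn compareSequences the transition/transversion (#:$) factor,
#'   NA when undefined
#' @export
tsTvFactor <- function(x) x@tsTvFactor

#' @describeIn compareSequences summary percentages as a named vector
#'   (pctR, pctSemihomologous, pctMulti)
#' @export
classPercentages <- function(x) {
  c(pctR = x@pctR, pctSemihomologous = x@pctSemihomologous,
    pctMulti = x@pctMulti)
}

setMethod("show", "ComparisonProfile", function(object) {
  cat("ComparisonProfile",
      if (nzchar(object@id1) || nzchar(object@id2))
        paste0("(", object@id1, " vs ", object@id2, ")") else "", "\n")
  cat("  comparable positions:", object@lengthCompared, "of",
      length(object@perPosition), "\n")
  cat(sprintf("  R: %d (%.2f%%)   #+$: %d (%.2f%%)   -: %d (%.2f%%)\n",
              object@counts[[CLASS_R]], object@pctR,
              object@counts[[CLASS_TRANSITION]] + object@counts[[CLASS_TRANSVERSION]],
              object@pctSemihomologous,
              object@counts[[CLASS_MULTI]], object@pctMulti))
  cat("  #/$ factor:",
      if (is.na(object@tsTvFactor)) "undefined"
      else sprintf("%.4f", object@tsTvFactor), "\n")
})

#' Semihomologous dot matrix of two sequences
#'
#' Cross-product classification: cell (i, j) holds the class of residue i of
#' the first sequence against residue j of the second. Rendered as text,
#' \code{R}, \code{#} and \code{$} cells keep their symbol while \code{-}
#' and non-comparable cells print as \code{"."}.
#'
#' @slot id1,id2 sequence identifiers.
#' @slot cells character matrix (rows = residues of s1, cols = of s2).
#' @export
setClass("DotMatrix",
         slots = c(id1 = "character", id2 = "character", cells = "matrix"))

#' Compute a semihomologous dot matrix
#'
#' @param s1,s2 character strings or \code{AAString}s (may be empty).
#' @param m a \linkS4class{SemihomologyMatrix}.
#' @param id1,id2 optional identifiers stored on the result.
#' @return A \linkS4class{DotMatrix}.
#' @export
dotMatrix <- function(s1, s2, m, id1 = "", id2 = "") {
  c1 <- strsplit(toupper(as.character(s1)), "")[[1L]]
  c2 <- strsplit(toupper(as.character(s2)), "")[[1L]]
  cells <- matrix(character(0), length(c1), length(c2))
  if (length(c1) && length(c2)) {
    idx <- expand.grid(i = seq_along(c1), j = seq_along(c2))
    cells <- matrix(classifyPair(c1[idx$i], c2[idx$j], m),
                    length(c1), length(c2))
  }
  rownames(cells) <- if (length(c1)) c1 else NULL
  colnames(cells) <- if (length(c2)) c2 else NULL
  new("DotMatrix", id1 = as.character(id1), id2 = as.character(id2),
      cells = cells)
}

#' @describeIn dotMatrix text rendering: one row per residue of s1, with
#'   characters R, #, $ and "." for multi-mutation or non-comparable cells.
#' @param x a \linkS4class{DotMatrix}.
#' @export
dotMatrixText <- function(x) {
  cells <- x@cells
  cells[!(cells %in% c(CLASS_R, CLASS_TRANSITION, CLASS_TRANSVERSION))] <- "."
  apply(cells, 1L, paste0, collapse = "")
}

#' @describeIn dotMatrix long-format table: one row per cell with 1-based
#'   coordinates i, j and the class symbol.
#' @export
dotMatrixTable <- function(x) {
  if (!length(x@cells))
    return(data.frame(i = integer(0), j = integer(0), class = character(0)))
  idx <- expand.grid(i = seq_len(nrow(x@cells)), j = seq_len(ncol(x@cells)))
  data.frame(i = idx$i, j = idx$j, class = x@cells[as.matrix(idx)])
}

setMethod("show", "DotMatrix", function(object) {
  cat("DotMatrix: ", nrow(object@cells), " x ", ncol(object@cells),
      " residues\n", sep = "")
  txt <- dotMatrixText(object)
  if (length(txt) > 12L) txt <- c(txt[1:12], "...")
  cat(paste0("  ", txt, collapse = "\n"), "\n")
})
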