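# Seeded codon-level evolution simulator. Star phylogeny: one random
# ancestor, independent descendants at controlled divergence, with a
# two-parameter (transition/transversion) substitution process and
# stop-codon rejection. This provides families of related protein
# sequences resembling a set of orthologs diverged from a common
# ancestor, without any external data.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")
DNA_BASES <- c("A", "C", "G", "T")
.transitionOf <- c(A = "G", G = "A", C = "T", T = "C")
.transversionsOf <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

#' Random ancestral codon sequence
#'
#' Codons are drawn uniformly from the non-stop codons of the chosen
#' genetic code, so the translated ancestor never contains a stop symbol.
#'
#' @param nCodons number of codons (default 400, the cytochrome b scale).
#' @param code a \linkS4class{GeneticCode}.
#' @param seed integer seed; deterministic.
#' @return Character string of \code{3 * nCodons} DNA bases.
#' @export
randomAncestor <- function(nCodons = 400L, code = geneticCode(1L), seed = 1L) {
  stopifnot(nCodons >= 1L)
  nonStop <- names(code@codons)[code@codons != "*"]
  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(as.integer(seed))
  paste0(sample(nonStop, nCodons, replace = TRUE), collapse = "")
}

#' Evolve one descendant from an ancestral codon sequence
#'
#' A Kimura-style two-parameter site process: the number of substitution
#' events is Poisson with mean \code{substitutionsPerSite * 3 * nCodons};
#' each event picks a nucleotide site uniformly and proposes a transition
#' with probability \code{kappa / (kappa + 2)}, otherwise one of the two
#' transversions (equally likely). Events that would create a stop codon
#' are redrawn (site and mutation), so descendants always translate
#' cleanly. The realised event count is returned alongside the sequence.
#'
#' @param ancestor codon string from \code{\link{randomAncestor}}.
#' @param substitutionsPerSite expected substitutions per nucleotide site.
#' @param kappa transition/transversion rate ratio (>= 0); large values
#'   make transition-type (#) semihomologous positions dominate.
#' @param code a \linkS4class{GeneticCode}.
#' @param seed integer seed; deterministic.
#' @return List with \code{codons} (descendant codon string) and
#'   \code{nEvents} (realised substitution-event count).
#' @export
evolveMember <- function(ancestor, substitutionsPerSite, kappa = 2,
                         code = geneticCode(1L), seed = 1L) {
  stopifnot(substitutionsPerSite >= 0, kappa >= 0)
  bases <- strsplit(ancestor, "")[[1L]]
  nSites <- length(bases)
  stopifnot(nSites %% 3L == 0L)
  stopCodons <- names(code@codons)[code@codons == "*"]
  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(as.integer(seed))
  nEvents <- stats::rpois(1L, substitutionsPerSite * nSites)
  pTransition <- kappa / (kappa + 2)
  ev <- 0L
  while (ev < nEvents) {
    site <- sample.int(nSites, 1L)
    cur <- bases[site]
    newBase <- if (stats::runif(1L) < pTransition) .transitionOf[[cur]]
               else sample(.transversionsOf[[cur]], 1L)
    ci <- (site - 1L) %/% 3L
    codon <- bases[(ci * 3L + 1L):(ci * 3L + 3L)]
    codon[(site - 1L) %% 3L + 1L] <- newBase
    if (paste0(codon, collapse = "") %in% stopCodons) next  # redraw event
    bases[site] <- newBase
    ev <- ev + 1L
  }
  list(codons = paste0(bases, collapse = ""), nEvents = nEvents)
}

#' Synthetic protein family
#'
#' One random codon ancestor and groups of independently evolved
#' descendants at per-group divergence levels, translated to amino-acid
#' sequences. The translated ancestor is emitted as the reference
#' organism.
#'
#' @slot ancestorCodons ancestral codon string.
#' @slot members \code{AAStringSet} of translated member sequences
#'   (reference first).
#' @slot groupTable group-assignment data.frame (organism_id, group,
#'   role, is_reference).
#' @slot divergences named numeric vector of realised substitution-event
#'   counts per member.
#' @slot config list of the generating parameters.
#' @export
setClass("SyntheticFamily",
         slots = c(ancestorCodons = "character", members = "AAStringSet",
                   groupTable = "data.frame", divergences = "numeric",
                   config = "list"))

setValidity("SyntheticFamily", function(object) {
  if (any(grepl("\\*", as.character(object@members))))
    return("translated members must not contain stop symbols")
  TRUE
})

#' Generate a synthetic protein family
#'
#' @param groups data.frame with columns \code{name}, \code{nMembers},
#'   \code{substitutionsPerSite}: one row per attractor group.
#' @param nCodons codons in the ancestor (default 400).
#' @param kappa transition/transversion rate ratio (default 2, a typical
#'   empirical bias toward transitions).
#' @param code a \linkS4class{GeneticCode}.
#' @param seed master seed; member seeds derive from it deterministically.
#' @param referenceId id given to the translated ancestor (default
#'   \code{"reference"}).
#' @return A \linkS4class{SyntheticFamily}.
#' @examples
#' fam <- generateFamily(data.frame(name = c("near", "far"),
#'                                  nMembers = c(2, 2),
#'                                  substitutionsPerSite = c(0.05, 0.5)),
#'                       nCodons = 100, seed = 7)
#' familyMembers(fam)
#' @export
generateFamily <- function(groups, nCodons = 400L, kappa = 2,
                           code = geneticCode(1L), seed = 1L,
                           referenceId = "reference") {
  stopifnot(all(c("name", "nMembers", "substitutionsPerSite") %in%
                  names(groups)))
  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(as.integer(seed))
  nTotal <- sum(groups$nMembers)
  seeds <- sample.int(.Machine$integer.max - 1L, nTotal + 1L)
  ancestor <- randomAncestor(nCodons, code, seed = seeds[1L])
  ids <- character(0); grp <- character(0)
  seqs <- character(0); div <- numeric(0)
  si <- 1L
  for (g in seq_len(nrow(groups))) {
    for (mi in seq_len(groups$nMembers[g])) {
      si <- si + 1L
      id <- paste0(groups$name[g], "_", mi)
      ev <- evolveMember(ancestor, groups$substitutionsPerSite[g],
                         kappa = kappa, code = code, seed = seeds[si])
      ids <- c(ids, id); grp <- c(grp, groups$name[g])
      seqs <- c(seqs, translateCodons(code, ev$codons))
      div <- c(div, ev$nEvents)
    }
  }
  refAA <- translateCodons(code, ancestor)
  members <- Biostrings::AAStringSet(
    stats::setNames(c(refAA, seqs), c(referenceId, ids)))
  groupTable <- data.frame(
    organism_id = c(referenceId, ids),
    group = c("reference", grp),
    role = c("examine", rep("examine", length(ids))),
    is_reference = c(TRUE, rep(FALSE, length(ids))))
  new("SyntheticFamily", ancestorCodons = ancestor, members = members,
      groupTable = groupTable,
      divergences = stats::setNames(div, ids),
      config = list(groups = groups, nCodons = as.integer(nCodons),
                    kappa = kappa, tableId = code@tableId,
                    seed = as.integer(seed)))
}

#' @describeIn generateFamily translated member sequences (reference
#'   first)
#' @param fam a \linkS4class{SyntheticFamily}.
#' @export
familyMembers <- function(fam) fam@members

#' @describeIn generateFamily the group-assignment table
#' @export
familyGroupTable <- function(fam) fam@groupTable

#' @describeIn generateFamily realised substitution-event counts
#' @export
familyDivergences <- function(fam) fam@divergences

setMethod("show", "SyntheticFamily", function(object) {
  cat("SyntheticFamily: ", object@config$nCodons, " codons, ",
      length(object@members) - 1L, " members in ",
      nrow(object@config$groups), " group(s), kappa = ",
      object@config$kappa, "\n", sep = "")
})
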