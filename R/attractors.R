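#' Named attractor group of organisms
#'
#' A genome attractor is represented operationally as a named set of
#' organisms whose sequences the ensemble recognises similarly. A group
#' carries, per member, the recognition similarity vector (for orbit and
#' disturbance analysis) and/or the semihomologous comparison profile
#' against the reference organism (for group characteristics). Either
#' component may be absent when only the other analysis is wanted.
#'
#' @slot name group name.
#' @slot memberIds organism identifiers.
#' @slot similarities members x k matrix of recognition similarities
#'   (columns = teaching organisms), or a 0-row matrix.
#' @slot profiles list of \linkS4class{ComparisonProfile}s vs. the
#'   reference organism, or an empty list.
#' @export
setClass("AttractorGroup",
         slots = c(name = "character", memberIds = "character",
                   similarities = "matrix", profiles = "list"))

setValidity("AttractorGroup", function(object) {
  msgs <- character()
  if (!length(object@memberIds)) msgs <- c(msgs, "group must be nonempty")
  if (nrow(object@similarities) &&
      nrow(object@similarities) != length(object@memberIds))
    msgs <- c(msgs, "one similarity row per member required")
  if (length(object@profiles) &&
      length(object@profiles) != length(object@memberIds))
    msgs <- c(msgs, "one profile per member required")
  if (length(msgs)) msgs else TRUE
})

#' Construct an attractor group
#'
#' @param name group name.
#' @param memberIds organism ids.
#' @param similarities optional members x k similarity matrix (rows in
#'   member order).
#' @param profiles optional list of \linkS4class{ComparisonProfile}s, one
#'   per member, each computed against the common reference organism.
#' @return An \linkS4class{AttractorGroup}.
#' @export
attractorGroup <- function(name, memberIds, similarities = NULL,
                           profiles = NULL) {
  if (is.null(similarities))
    similarities <- matrix(numeric(0), 0L, 0L)
  if (is.null(profiles)) profiles <- list()
  new("AttractorGroup", name = as.character(name),
      memberIds = as.character(memberIds),
      similarities = similarities, profiles = profiles)
}

setMethod("show", "AttractorGroup", function(object) {
  cat("AttractorGroup '", object@name, "': ", length(object@memberIds),
      " member(s)\n", sep = "")
})

#' Semihomologous characteristics of an attractor group
#'
#' Arithmetic means, over the group members, of the per-member comparison
#' statistics against the reference organism: percentage of homologous
#' (R), semihomologous (# + $) and multi-mutation (-) positions, and the
#' mean transition/transversion factor. Members whose factor is undefined
#' (no $ positions) are excluded from the factor mean; if none is defined
#' the mean is \code{NA}.
#'
#' @param group an \linkS4class{AttractorGroup} carrying member profiles.
#' @return One-row \code{data.frame} with columns \code{group}, \code{n},
#'   \code{avgR}, \code{avgSemihomologous}, \code{avgMulti},
#'   \code{avgTsTv}.
#' @export
groupCharacteristics <- function(group) {
  stopifnot(is(group, "AttractorGroup"))
  if (!length(group@profiles))
    stop("group '", group@name, "' carries no comparison profiles")
  pr <- group@profiles
  tstv <- vapply(pr, tsTvFactor, numeric(1))
  tstv <- tstv[!is.na(tstv)]
  data.frame(
    group = group@name,
    n = length(pr),
    avgR = mean(vapply(pr, function(p) p@pctR, numeric(1))),
    avgSemihomologous = mean(vapply(pr, function(p) p@pctSemihomologous,
                                    numeric(1))),
    avgMulti = mean(vapply(pr, function(p) p@pctMulti, numeric(1))),
    avgTsTv = if (length(tstv)) mean(tstv) else NA_real_)
}

#' Orbit radii and distance factors of ordered attractor groups
#'
#' Each group's recognition similarity to the reference organism is the
#' mean, over its members, of the similarity at the reference teaching
#' output. Picturing the attractors on concentric orbits around the
#' reference, a group's orbit radius is the reciprocal of that mean
#' similarity, and the distance factor between two consecutive groups is
#' the ratio of the farther radius to the nearer one (always >= 1). The
#' factor is scale-invariant: rescaling all similarities by a common
#' constant leaves it unchanged.
#'
#' @param groups list of \linkS4class{AttractorGroup}s in orbit order
#'   (nearest to the reference first), each carrying member similarities.
#' @param refOutput teaching-output index or teaching organism id at which
#'   similarity to the reference is read.
#' @param teachingIds optional ids naming the similarity columns (needed
#'   when \code{refOutput} is an id and columns are unnamed).
#' @return \code{data.frame} with one row per group: \code{group},
#'   \code{n}, \code{similarity}, \code{radius}, \code{distanceFactor}
#'   (\code{NA} on the first row; row i holds the factor between orbits
#'   i-1 and i).
#' @export
orbitRadii <- function(groups, refOutput, teachingIds = NULL) {
  stopifnot(length(groups) >= 1L)
  sims <- vapply(groups, function(g) {
    stopifnot(is(g, "AttractorGroup"))
    if (!nrow(g@similarities))
      stop("group '", g@name, "' carries no similarities")
    M <- g@similarities
    if (!is.null(teachingIds)) colnames(M) <- teachingIds
    j <- if (is.character(refOutput)) {
      jj <- match(refOutput, colnames(M))
      if (is.na(jj)) stop("reference output '", refOutput,
                          "' not among teaching ids")
      jj
    } else as.integer(refOutput)
    if (j < 1L || j > ncol(M)) stop("reference output index out of range")
    mean(M[, j])
  }, numeric(1))
  if (any(sims == 0)) {
    bad <- vapply(groups, function(g) g@name, character(1))[sims == 0]
    stop("degenerate (zero) similarity to the reference for group(s): ",
         paste(bad, collapse = ", "))
  }
  radii <- 1 / sims
  factors <- rep(NA_real_, length(radii))
  if (length(radii) > 1L) {
    r1 <- radii[-length(radii)]; r2 <- radii[-1L]
    factors[-1L] <- pmax(r1, r2) / pmin(r1, r2)
  }
  data.frame(group = vapply(groups, function(g) g@name, character(1)),
             n = vapply(groups, function(g) length(g@memberIds), integer(1)),
             similarity = sims, radius = radii, distanceFactor = factors)
}

#' Disturbance ranking of an attractor group
#'
#' A disturbance is the attraction of a group toward a teaching organism
#' outside its own lineage: the mean, over group members, of the
#' recognition similarity at that organism's output. Outputs belonging to
#' the group's own lineage are excluded explicitly; the remaining outputs
#' are ranked by mean similarity, descending, ties broken by teaching
#' order.
#'
#' @param group an \linkS4class{AttractorGroup} carrying similarities.
#' @param excludeOutputs integer indices or teaching ids of the group's
#'   own lineage outputs.
#' @param topK keep only the strongest \code{topK} disturbances
#'   (default all).
#' @param teachingIds optional ids naming the similarity columns.
#' @return \code{data.frame} with columns \code{group}, \code{output}
#'   (index), \code{teachingId}, \code{meanSimilarity}, ranked descending.
#' @export
disturbances <- function(group, excludeOutputs = integer(0), topK = Inf,
                         teachingIds = NULL) {
  stopifnot(is(group, "AttractorGroup"))
  M <- group@similarities
  if (!nrow(M)) stop("group '", group@name, "' carries no similarities")
  if (!is.null(teachingIds)) colnames(M) <- teachingIds
  ids <- colnames(M)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(M)))
  excl <- if (is.character(excludeOutputs)) match(excludeOutputs, ids)
          else as.integer(excludeOutputs)
  if (anyNA(excl)) stop("unknown teaching id in excludeOutputs")
  keep <- setdiff(seq_len(ncol(M)), excl)
  if (!length(keep))
    stop("all teaching outputs excluded for group '", group@name, "'")
  ms <- colMeans(M[, keep, drop = FALSE])
  ord <- order(-ms, keep)   # descending; ties broken by teaching order
  sel <- utils::head(ord, if (is.finite(topK)) topK else length(ord))
  data.frame(group = group@name, output = keep[sel],
             teachingId = ids[keep[sel]], meanSimilarity = ms[sel],
             row.names = NULL)
}

#' Assemble attractor groups from pipeline outputs
#'
#' Convenience constructor joining a similarity matrix and/or a set of
#' comparison profiles with a group-assignment table. The reference
#' organism itself is not placed in any group.
#'
#' @param groupTable data.frame from \code{\link{readGroupTable}}.
#' @param similarityMatrix optional organisms x teaching-ids matrix with
#'   rownames.
#' @param profiles optional named list of \linkS4class{ComparisonProfile}s
#'   (one per organism, vs. the reference).
#' @param groupOrder optional character vector ordering the groups
#'   (nearest orbit first); defaults to first-appearance order.
#' @return Named list of \linkS4class{AttractorGroup}s.
#' @export
makeGroups <- function(groupTable, similarityMatrix = NULL, profiles = NULL,
                       groupOrder = NULL) {
  tab <- groupTable[!groupTable$is_reference, , drop = FALSE]
  grps <- if (is.null(groupOrder)) unique(tab$group) else groupOrder
  out <- lapply(grps, function(g) {
    ids <- tab$organism_id[tab$group == g]
    if (!length(ids)) stop("group '", g, "' has no members")
    sims <- NULL
    if (!is.null(similarityMatrix)) {
      miss <- setdiff(ids, rownames(similarityMatrix))
      if (length(miss)) stop("no similarities for organism(s): ",
                             paste(miss, collapse = ", "))
      sims <- similarityMatrix[ids, , drop = FALSE]
    }
    prof <- NULL
    if (!is.null(profiles)) {
      miss <- setdiff(ids, names(profiles))
      if (length(miss)) stop("no profiles for organism(s): ",
                             paste(miss, collapse = ", "))
      prof <- profiles[ids]
    }
    attractorGroup(g, ids, similarities = sims, profiles = prof)
  })
  stats::setNames(out, grps)
}
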