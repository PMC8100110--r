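# Plain-text model archive. Weights are written with "%.17g", which
# round-trips IEEE doubles exactly, so save/load is bit-exact.

.writeNum <- function(x, path) writeLines(sprintf("%.17g", x), path)
.readNum <- function(path) as.numeric(readLines(path))
.writeMat <- function(m, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(dim(m), collapse = " "), con)
  writeLines(sprintf("%.17g", as.vector(m)), con)
}
.readMat <- function(path) {
  lines <- readLines(path)
  d <- as.integer(strsplit(lines[1L], " ")[[1L]])
  matrix(as.numeric(lines[-1L]), d[1L], d[2L])
}

#' Save a taught ensemble to a plain-text archive directory
#'
#' The archive holds, per member, the encoding seed and code map, all
#' weight arrays, hyperparameters and the teaching RMSE history, plus the
#' ordered teaching ids. Loading it back reproduces the ensemble
#' bit-exactly.
#'
#' @param ens an \linkS4class{Ensemble}.
#' @param dir directory to create (must not already contain an archive).
#' @return \code{dir}, invisibly.
#' @seealso \code{\link{loadEnsemble}}
#' @export
saveEnsemble <- function(ens, dir) {
  stopifnot(is(ens, "Ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(teachingIds = ens@teachingIds,
                   targetLength = ens@targetLength,
                   nVersions = length(ens@members))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (v in seq_along(ens@members)) {
    mb <- ens@members[[v]]
    mdir <- file.path(dir, sprintf("member_%03d", v))
    dir.create(mdir, showWarnings = FALSE)
    p <- mb$model@params
    meta <- list(n = p@n, m = p@m, k = p@k, learningRate = p@learningRate,
                 momentum = p@momentum, rmseTarget = p@rmseTarget,
                 maxEpochs = p@maxEpochs, initSeed = p@initSeed,
                 inputActivation = p@inputActivation,
                 encodingSeed = mb$encoding@seed,
                 encodingPolicy = mb$encoding@policy,
                 converged = mb$model@converged)
    jsonlite::write_json(meta, file.path(mdir, "params.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    enc <- mb$encoding@codeMap
    utils::write.table(
      data.frame(symbol = rownames(enc),
                 code = apply(enc, 1L, paste0, collapse = "")),
      file.path(mdir, "encoding.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    .writeMat(mb$model@W1, file.path(mdir, "W1.txt"))
    .writeMat(mb$model@W2, file.path(mdir, "W2.txt"))
    .writeNum(mb$model@b1, file.path(mdir, "b1.txt"))
    .writeNum(mb$model@b2, file.path(mdir, "b2.txt"))
    .writeNum(mb$model@history, file.path(mdir, "history.txt"))
  }
  invisible(dir)
}

#' Load an ensemble from a plain-text archive directory
#'
#' @param dir directory written by \code{\link{saveEnsemble}}.
#' @return The reconstructed \linkS4class{Ensemble}.
#' @export
loadEnsemble <- function(dir) {
  manifestPath <- file.path(dir, "manifest.json")
  if (!file.exists(manifestPath)) stop("not an ensemble archive: ", dir)
  manifest <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  members <- lapply(seq_len(manifest$nVersions), function(v) {
    mdir <- file.path(dir, sprintf("member_%03d", v))
    meta <- jsonlite::read_json(file.path(mdir, "params.json"),
                                simplifyVector = TRUE)
    encTab <- utils::read.delim(file.path(mdir, "encoding.tsv"),
                                colClasses = "character")
    codeMap <- t(vapply(strsplit(encTab$code, ""),
                        function(b) as.integer(b), integer(5)))
    rownames(codeMap) <- encTab$symbol
    enc <- new("EncodingTable", seed = as.integer(meta$encodingSeed),
               codeMap = codeMap, policy = meta$encodingPolicy)
    params <- networkParams(n = meta$n, k = meta$k, m = meta$m,
                            learningRate = meta$learningRate,
                            momentum = meta$momentum,
                            rmseTarget = meta$rmseTarget,
                            maxEpochs = meta$maxEpochs,
                            initSeed = meta$initSeed,
                            inputActivation = meta$inputActivation)
    model <- new("NetworkModel", params = params,
                 W1 = .readMat(file.path(mdir, "W1.txt")),
                 b1 = .readNum(file.path(mdir, "b1.txt")),
                 W2 = .readMat(file.path(mdir, "W2.txt")),
                 b2 = .readNum(file.path(mdir, "b2.txt")),
                 dW1 = matrix(0, meta$m, meta$n), db1 = numeric(meta$m),
                 dW2 = matrix(0, meta$k, meta$m), db2 = numeric(meta$k),
                 history = .readNum(file.path(mdir, "history.txt")),
                 converged = isTRUE(meta$converged))
    list(encoding = enc, model = model)
  })
  new("Ensemble", members = members,
      teachingIds = as.character(manifest$teachingIds),
      targetLength = as.integer(manifest$targetLength))
}
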