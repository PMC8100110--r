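#' Logistic sigmoid
#'
#' The transfer function of every layer: \code{y = 1 / (1 + exp(-x))},
#' bounding activations smoothly in (0, 1).
#'
#' @param x numeric vector.
#' @return numeric vector in (0, 1).
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Random five-bit character encoding
#'
#' Maps every symbol of the residue alphabet to a five-positional binary
#' code, drawn at random under a seed. With the default \code{"distinct"}
#' policy the codes are sampled without replacement from the 32 possible
#' five-bit words, so different symbols never collide and the encoding is
#' invertible; the \code{"iid"} policy samples each code independently
#' (collisions possible).
#'
#' @slot seed integer seed the table was drawn with.
#' @slot codeMap integer 0/1 matrix, one row per symbol (rownames), five
#'   columns.
#' @slot policy \code{"distinct"} or \code{"iid"}.
#' @export
setClass("EncodingTable",
         slots = c(seed = "integer", codeMap = "matrix", policy = "character"))

setValidity("EncodingTable", function(object) {
  msgs <- character()
  if (ncol(object@codeMap) != 5L)
    msgs <- c(msgs, "codes must have exactly five bits")
  if (!all(object@codeMap %in% c(0L, 1L)))
    msgs <- c(msgs, "codes must be binary")
  if (is.null(rownames(object@codeMap)))
    msgs <- c(msgs, "codeMap rows must be named by symbol")
  if (identical(object@policy, "distinct") &&
      anyDuplicated(apply(object@codeMap, 1L, paste0, collapse = "")))
    msgs <- c(msgs, "distinct policy violated: duplicated codes")
  if (length(msgs)) msgs else TRUE
})

#' Create a seeded five-bit encoding table
#'
#' @param seed integer seed; the same seed always yields the same table.
#' @param alphabet character vector of single-character symbols (at most
#'   32 under the distinct policy). Defaults to \code{\link{aaAlphabet}}.
#' @param policy \code{"distinct"} (default, codes sampled without
#'   replacement) or \code{"iid"}.
#' @return An \linkS4class{EncodingTable}.
#' @export
makeEncoding <- function(seed, alphabet = aaAlphabet(), policy = c("distinct", "iid")) {
  policy <- match.arg(policy)
  nsym <- length(alphabet)
  if (policy == "distinct" && nsym > 32L)
    stop("alphabet has ", nsym,
         " symbols but only 32 distinct five-bit codes exist")
  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(as.integer(seed))
  words <- if (policy == "distinct") sample(0:31, nsym)
           else sample(0:31, nsym, replace = TRUE)
  codeMap <- t(vapply(words, function(w) as.integer(intToBits(w)[1:5]),
                      integer(5)))
  rownames(codeMap) <- alphabet
  new("EncodingTable", seed = as.integer(seed), codeMap = codeMap,
      policy = policy)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.saveRNG <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Encode a sequence as a bit vector
#'
#' Concatenates the five-bit code of every character, so a sequence of L
#' residues becomes a vector of 5 L bits (a 400-residue sequence encodes
#' to the 2000-bit network input).
#'
#' @param seq character string or \code{AAString}.
#' @param enc an \linkS4class{EncodingTable}.
#' @return Integer vector of 0/1 of length \code{5 * nchar(seq)}.
#' @export
encodeSequence <- function(seq, enc) {
  stopifnot(is(enc, "EncodingTable"))
  chars <- strsplit(toupper(as.character(seq)), "")[[1L]]
  if (!length(chars)) return(integer(0))
  idx <- match(chars, rownames(enc@codeMap))
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1L]
    stop("character '", chars[p], "' at position ", p,
         " has no code in the encoding table")
  }
  as.vector(t(enc@codeMap[idx, , drop = FALSE]))
}

#' Decode a bit vector back to a sequence
#'
#' Inverse of \code{\link{encodeSequence}}; only meaningful under the
#' distinct-code policy.
#'
#' @param bits integer 0/1 vector of length divisible by five.
#' @param enc an \linkS4class{EncodingTable}.
#' @return Character string.
#' @export
decodeSequence <- function(bits, enc) {
  stopifnot(length(bits) %% 5L == 0L)
  if (!length(bits)) return("")
  words <- apply(matrix(bits, nrow = 5L), 2L, paste0, collapse = "")
  keys <- apply(enc@codeMap, 1L, paste0, collapse = "")
  idx <- match(words, keys)
  if (anyNA(idx)) stop("bit pattern not present in the encoding table")
  paste0(rownames(enc@codeMap)[idx], collapse = "")
}

#' Hidden-layer size by the geometric pyramid rule
#'
#' The hidden layer is sized as the rounded geometric mean of the input
#' and output layer sizes, \code{round(sqrt(n * k))} (round half to even).
#' For the cytochrome b configuration (n = 2000 inputs, k = 36 teaching
#' organisms) this gives 268 hidden neurons.
#'
#' @param n input-layer size.
#' @param k output-layer size.
#' @return Integer hidden-layer size.
#' @examples
#' pyramidHiddenSize(2000, 36)  # 268
#' @export
pyramidHiddenSize <- function(n, k) {
  stopifnot(n >= 1, k >= 1)
  as.integer(round(sqrt(as.numeric(n) * as.numeric(k))))
}

#' Hyperparameters of the three-layer sigmoid network
#'
#' @slot n input size (five bits per residue; 2000 for 400-residue input).
#' @slot m hidden size (geometric pyramid rule by default).
#' @slot k output size = number of teaching organisms.
#' @slot learningRate on-line backpropagation step size (default 0.3).
#' @slot momentum fraction of the previous weight update added to the
#'   current one (default 0.1).
#' @slot rmseTarget stop teaching once epoch RMSE drops below this
#'   (default 0.001).
#' @slot maxEpochs safety cap on teaching epochs.
#' @slot initSeed seed for the uniform weight initialisation.
#' @slot inputActivation \code{"sigmoid"} (every layer is a sigmoid layer,
#'   the default) or \code{"linear"} (input layer passes bits through).
#' @export
setClass("NetworkParams",
         slots = c(n = "integer", m = "integer", k = "integer",
                   learningRate = "numeric", momentum = "numeric",
                   rmseTarget = "numeric", maxEpochs = "integer",
                   initSeed = "integer", inputActivation = "character"))

setValidity("NetworkParams", function(object) {
  msgs <- character()
  if (object@n < 1L || object@m < 1L || object@k < 1L)
    msgs <- c(msgs, "layer sizes must be >= 1")
  if (object@learningRate <= 0) msgs <- c(msgs, "learningRate must be > 0")
  if (object@momentum < 0 || object@momentum >= 1)
    msgs <- c(msgs, "momentum must be in [0, 1)")
  if (object@rmseTarget <= 0) msgs <- c(msgs, "rmseTarget must be > 0")
  if (!object@inputActivation %in% c("sigmoid", "linear"))
    msgs <- c(msgs, "inputActivation must be sigmoid or linear")
  if (length(msgs)) msgs else TRUE
})

#' Construct network hyperparameters
#'
#' @param n,k input and output sizes.
#' @param m hidden size; defaults to \code{\link{pyramidHiddenSize}(n, k)}.
#' @param learningRate,momentum,rmseTarget,maxEpochs,initSeed,inputActivation
#'   see \linkS4class{NetworkParams}.
#' @return A \linkS4class{NetworkParams}.
#' @export
networkParams <- function(n, k, m = pyramidHiddenSize(n, k),
                          learningRate = 0.3, momentum = 0.1,
                          rmseTarget = 0.001, maxEpochs = 10000L,
                          initSeed = 1L,
                          inputActivation = c("sigmoid", "linear")) {
  new("NetworkParams", n = as.integer(n), m = as.integer(m),
      k = as.integer(k), learningRate = learningRate, momentum = momentum,
      rmseTarget = rmseTarget, maxEpochs = as.integer(maxEpochs),
      initSeed = as.integer(initSeed),
      inputActivation = match.arg(inputActivation))
}

#' Three-layer sigmoid perceptron
#'
#' Fully connected n-m-k network: every input node feeds every hidden node
#' and every hidden node feeds every output node; hidden and output units
#' carry biases and apply the sigmoid transfer function, so outputs always
#' lie in (0, 1).
#'
#' @slot params a \linkS4class{NetworkParams}.
#' @slot W1 m x n hidden weights; \code{b1} hidden biases.
#' @slot W2 k x m output weights; \code{b2} output biases.
#' @slot dW1,db1,dW2,db2 previous updates (momentum state).
#' @slot history per-epoch RMSE of the last teaching run.
#' @slot converged TRUE if the last teaching run reached its RMSE target.
#' @export
setClass("NetworkModel",
         slots = c(params = "NetworkParams",
                   W1 = "matrix", b1 = "numeric",
                   W2 = "matrix", b2 = "numeric",
                   dW1 = "matrix", db1 = "numeric",
                   dW2 = "matrix", db2 = "numeric",
                   history = "numeric", converged = "logical"))

setValidity("NetworkModel", function(object) {
  p <- object@params
  ok <- identical(dim(object@W1), c(p@m, p@n)) &&
        identical(dim(object@W2), c(p@k, p@m)) &&
        length(object@b1) == p@m && length(object@b2) == p@k
  if (ok) TRUE else "weight shapes inconsistent with params"
})

#' Initialise a network with seeded uniform weights
#'
#' Weights and biases are drawn uniformly from [-0.5, 0.5] under
#' \code{params@initSeed}.
#'
#' @param params a \linkS4class{NetworkParams}.
#' @return An untrained \linkS4class{NetworkModel}.
#' @export
newNetwork <- function(params) {
  stopifnot(is(params, "NetworkParams"))
  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(params@initSeed)
  n <- params@n; m <- params@m; k <- params@k
  new("NetworkModel", params = params,
      W1 = matrix(stats::runif(m * n, -0.5, 0.5), m, n),
      b1 = stats::runif(m, -0.5, 0.5),
      W2 = matrix(stats::runif(k * m, -0.5, 0.5), k, m),
      b2 = stats::runif(k, -0.5, 0.5),
      dW1 = matrix(0, m, n), db1 = numeric(m),
      dW2 = matrix(0, k, m), db2 = numeric(k),
      history = numeric(0), converged = FALSE)
}

.inputLayer <- function(model, x) {
  if (model@params@inputActivation == "sigmoid") sigmoid(x) else as.numeric(x)
}

# Full forward pass returning all activations (internal).
.forwardFull <- function(model, x) {
  if (length(x) != model@params@n)
    stop("input length ", length(x), " does not match network input size ",
         model@params@n)
  a0 <- .inputLayer(model, x)
  h <- sigmoid(drop(model@W1 %*% a0) + model@b1)
  y <- sigmoid(drop(model@W2 %*% h) + model@b2)
  list(a0 = a0, h = h, y = y)
}

#' Forward pass through the network
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param x bit vector of length \code{params@n}.
#' @return Output vector of length \code{params@k}, each value in (0, 1).
#' @export
mlpForward <- function(model, x) .forwardFull(model, x)$y

# Backpropagation gradient of the summed squared error 0.5 * sum((y-t)^2)
# for a single pattern (internal; shared by training and the tests'
# finite-difference comparison).
.gradients <- function(model, x, target) {
  act <- .forwardFull(model, x)
  dout <- (act$y - target) * act$y * (1 - act$y)
  dhid <- drop(crossprod(model@W2, dout)) * act$h * (1 - act$h)
  list(dW2 = tcrossprod(dout, act$h), db2 = dout,
       dW1 = tcrossprod(dhid, act$a0), db1 = dhid,
       y = act$y)
}

.epochRMSE <- function(model, X, targets) {
  err <- 0
  for (p in seq_len(nrow(X)))
    err <- err + sum((mlpForward(model, X[p, ]) - targets[p, ])^2)
  sqrt(err / (nrow(X) * ncol(targets)))
}

#' Teach a network by on-line backpropagation
#'
#' Weights are updated after every pattern presentation:
#' \code{delta_w(t) = -learningRate * gradient + momentum * delta_w(t-1)}.
#' Patterns are presented in fixed order each epoch (optionally seeded
#' shuffling); after each epoch the RMSE over all patterns and output
#' units is evaluated and teaching stops once it falls below
#' \code{rmseTarget} (also checked once before the first update, so a
#' model that already meets the target is returned untouched) or when
#' \code{maxEpochs} is reached, in which case a warning is issued and
#' \code{converged(model)} is FALSE.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param X pattern matrix, one row per pattern, \code{params@n} columns.
#' @param targets target matrix, one row per pattern, \code{params@k}
#'   columns, values in [0, 1] (one-hot rows in normal teaching).
#' @param shuffle present patterns in a freshly drawn order each epoch.
#' @param shuffleSeed seed for the shuffling stream.
#' @return The taught \linkS4class{NetworkModel} with per-epoch RMSE in
#'   \code{rmseHistory(model)}.
#' @export
trainOnline <- function(model, X, targets, shuffle = FALSE, shuffleSeed = 1L) {
  stopifnot(is(model, "NetworkModel"), is.matrix(X), is.matrix(targets),
            nrow(X) == nrow(targets))
  p <- model@params
  if (ncol(X) != p@n) stop("pattern width ", ncol(X), " != network input ", p@n)
  if (ncol(targets) != p@k)
    stop("target width ", ncol(targets), " != network output ", p@k)
  if (any(targets < 0 | targets > 1)) stop("targets must lie in [0, 1]")
  lr <- p@learningRate; mom <- p@momentum
  W1 <- model@W1; b1 <- model@b1; W2 <- model@W2; b2 <- model@b2
  dW1 <- model@dW1; db1 <- model@db1; dW2 <- model@dW2; db2 <- model@db2
  # pre-activate inputs once: the input layer is static per pattern
  A0 <- if (p@inputActivation == "sigmoid") sigmoid(X) else X
  history <- numeric(0)
  rmse0 <- .epochRMSE(model, X, targets)
  if (rmse0 < p@rmseTarget) {
    model@history <- rmse0
    model@converged <- TRUE
    return(model)
  }
  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(as.integer(shuffleSeed))
  converged <- FALSE
  nP <- nrow(X); nOut <- p@k
  for (epoch in seq_len(p@maxEpochs)) {
    ord <- if (shuffle) sample.int(nP) else seq_len(nP)
    for (pi in ord) {
      a0 <- A0[pi, ]
      h <- sigmoid(drop(W1 %*% a0) + b1)
      y <- sigmoid(drop(W2 %*% h) + b2)
      dout <- (y - targets[pi, ]) * y * (1 - y)
      dhid <- drop(crossprod(W2, dout)) * h * (1 - h)
      dW2 <- -lr * tcrossprod(dout, h) + mom * dW2
      db2 <- -lr * dout + mom * db2
      dW1 <- -lr * tcrossprod(dhid, a0) + mom * dW1
      db1 <- -lr * dhid + mom * db1
      W2 <- W2 + dW2; b2 <- b2 + db2
      W1 <- W1 + dW1; b1 <- b1 + db1
    }
    if (!all(is.finite(W1)) || !all(is.finite(W2)))
      stop("teaching diverged (non-finite weights) at epoch ", epoch)
    # epoch RMSE over all patterns and outputs, after this epoch's updates
    err <- 0
    for (pi in seq_len(nP)) {
      h <- sigmoid(drop(W1 %*% A0[pi, ]) + b1)
      y <- sigmoid(drop(W2 %*% h) + b2)
      err <- err + sum((y - targets[pi, ])^2)
    }
    rmse <- sqrt(err / (nP * nOut))
    history <- c(history, rmse)
    if (rmse < p@rmseTarget) { converged <- TRUE; break }
  }
  if (!converged)
    warning("RMSE target ", p@rmseTarget, " not reached within ",
            p@maxEpochs, " epochs (final RMSE ",
            signif(history[length(history)], 4), ")")
  model@W1 <- W1; model@b1 <- b1; model@W2 <- W2; model@b2 <- b2
  model@dW1 <- dW1; model@db1 <- db1; model@dW2 <- dW2; model@db2 <- db2
  model@history <- history
  model@converged <- converged
  model
}

#' @describeIn trainOnline per-epoch RMSE of the last teaching run
#' @export
rmseHistory <- function(model) model@history

#' @describeIn trainOnline did the last run reach its RMSE target?
#' @export
converged <- function(model) model@converged

#' Ensemble of randomly encoded networks
#'
#' Many versions of the same network, each taught with its own random
#' five-bit character encoding and its own weight initialisation, so that
#' the arithmetic mean of their outputs — rather than any single random
#' encoding — carries the recognition signal.
#'
#' @slot members list of \code{list(encoding = EncodingTable,
#'   model = NetworkModel)}.
#' @slot teachingIds ordered organism ids; teaching sequence i is the
#'   one-hot target at output i.
#' @slot targetLength residue length every recognised sequence must have.
#' @export
setClass("Ensemble",
         slots = c(members = "list", teachingIds = "character",
                   targetLength = "integer"))

setValidity("Ensemble", function(object) {
  if (!length(object@members)) return("ensemble has no members")
  k <- length(object@teachingIds)
  for (mb in object@members) {
    if (!is(mb$encoding, "EncodingTable") || !is(mb$model, "NetworkModel"))
      return("each member must hold an EncodingTable and a NetworkModel")
    if (mb$model@params@k != k)
      return("member output size does not match number of teaching ids")
  }
  TRUE
})

#' Number of ensemble members
#' @param ens an \linkS4class{Ensemble}.
#' @export
nVersions <- function(ens) length(ens@members)

#' @describeIn nVersions ordered teaching organism ids
#' @export
teachingIds <- function(ens) ens@teachingIds

#' Teach an ensemble of randomly encoded networks
#'
#' Teaching sequence i (in file order) is assigned the one-hot target with
#' 1 at output i. Each of the \code{nVersions} members draws its own
#' encoding seed and weight-initialisation seed deterministically from
#' \code{masterSeed}, then is taught independently by
#' \code{\link{trainOnline}}. A member that exhausts \code{maxEpochs}
#' without reaching the RMSE target is kept (with a warning); its history
#' records the shortfall.
#'
#' @param teaching named \code{AAStringSet} (or named character vector) of
#'   equal-length teaching sequences, already normalised with
#'   \code{\link{padOrTrim}}.
#' @param nVersions number of ensemble members (50 in the full-scale
#'   cytochrome b configuration).
#' @param masterSeed seed from which all member seeds derive.
#' @param hiddenSize hidden-layer size; geometric pyramid rule by default.
#' @param learningRate,momentum,rmseTarget,maxEpochs,inputActivation
#'   teaching hyperparameters, see \linkS4class{NetworkParams}.
#' @param encodingPolicy code-sampling policy, see
#'   \code{\link{makeEncoding}}.
#' @return An \linkS4class{Ensemble}.
#' @export
teachEnsemble <- function(teaching, nVersions = 50L, masterSeed = 1L,
                          hiddenSize = NULL, learningRate = 0.3,
                          momentum = 0.1, rmseTarget = 0.001,
                          maxEpochs = 10000L,
                          inputActivation = c("sigmoid", "linear"),
                          encodingPolicy = c("distinct", "iid")) {
  inputActivation <- match.arg(inputActivation)
  encodingPolicy <- match.arg(encodingPolicy)
  seqs <- as.character(teaching)
  if (!length(seqs)) stop("teaching set is empty")
  if (is.null(names(seqs)) || !all(nzchar(names(seqs))))
    stop("teaching sequences must be named by organism id")
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("teaching sequences have unequal lengths (",
         paste(L, collapse = ", "), "); apply padOrTrim first")
  k <- length(seqs)
  n <- 5L * L
  m <- if (is.null(hiddenSize)) pyramidHiddenSize(n, k)
       else as.integer(hiddenSize)
  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(as.integer(masterSeed))
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * nVersions)
  targets <- diag(k)
  members <- vector("list", nVersions)
  for (v in seq_len(nVersions)) {
    enc <- makeEncoding(seeds[2L * v - 1L], policy = encodingPolicy)
    X <- t(vapply(seqs, function(s) encodeSequence(s, enc), integer(n)))
    params <- networkParams(n = n, k = k, m = m,
                            learningRate = learningRate, momentum = momentum,
                            rmseTarget = rmseTarget, maxEpochs = maxEpochs,
                            initSeed = seeds[2L * v],
                            inputActivation = inputActivation)
    model <- trainOnline(newNetwork(params), X, targets)
    members[[v]] <- list(encoding = enc, model = model)
  }
  new("Ensemble", members = members, teachingIds = names(seqs),
      targetLength = as.integer(L))
}

#' Recognition of one sequence by an ensemble
#'
#' @slot organismId identifier of the recognised sequence.
#' @slot similarity length-k vector in [0, 1]: arithmetic mean over
#'   members of the output at each teaching organism's neuron.
#' @slot perMember raw member outputs (members x k).
#' @slot teachingIds column names of both.
#' @export
setClass("RecognitionResult",
         slots = c(organismId = "character", similarity = "numeric",
                   perMember = "matrix", teachingIds = "character"))

setValidity("RecognitionResult", function(object) {
  msgs <- character()
  if (any(object@similarity < 0 | object@similarity > 1))
    msgs <- c(msgs, "similarities must lie in [0, 1]")
  if (length(object@similarity) != length(object@teachingIds))
    msgs <- c(msgs, "similarity length must equal number of teaching ids")
  if (max(abs(object@similarity - colMeans(object@perMember))) > 1e-9)
    msgs <- c(msgs, "similarity must be the mean of per-member outputs")
  if (length(msgs)) msgs else TRUE
})

#' Recognise a sequence with a taught ensemble
#'
#' The sequence is encoded with each member's own table and passed through
#' that member's network; the reported similarity vector is the arithmetic
#' mean of the member outputs, one value per teaching organism, each in
#' [0, 1] (0 = minimal, 1 = maximal recognised similarity).
#'
#' @param ens an \linkS4class{Ensemble}.
#' @param seq character string or \code{AAString} of the ensemble's target
#'   length (apply \code{\link{padOrTrim}} first).
#' @param id identifier stored on the result.
#' @return A \linkS4class{RecognitionResult}.
#' @export
recognize <- function(ens, seq, id = "") {
  stopifnot(is(ens, "Ensemble"))
  s <- as.character(seq)
  if (nchar(s) != ens@targetLength)
    stop("sequence length ", nchar(s), " != ensemble teaching length ",
         ens@targetLength, "; apply padOrTrim first")
  k <- length(ens@teachingIds)
  perMember <- t(vapply(ens@members, function(mb) {
    mlpForward(mb$model, encodeSequence(s, mb$encoding))
  }, numeric(k)))
  colnames(perMember) <- ens@teachingIds
  new("RecognitionResult", organismId = as.character(id),
      similarity = colMeans(perMember), perMember = perMember,
      teachingIds = ens@teachingIds)
}

#' @describeIn recognize mean similarity vector (named by teaching id)
#' @param x a \linkS4class{RecognitionResult}.
#' @export
similarity <- function(x) stats::setNames(x@similarity, x@teachingIds)

#' @describeIn recognize raw per-member output matrix
#' @export
perMember <- function(x) x@perMember

#' Recognise a whole set of sequences
#'
#' @param ens an \linkS4class{Ensemble}.
#' @param seqs named \code{AAStringSet} or character vector, every element
#'   at the ensemble's target length.
#' @return Numeric matrix: rows = examined organisms, columns = teaching
#'   organism ids.
#' @export
recognizeSet <- function(ens, seqs) {
  s <- as.character(seqs)
  out <- t(vapply(seq_along(s),
                  function(i) recognize(ens, s[[i]], id = names(s)[i])@similarity,
                  numeric(length(ens@teachingIds))))
  dimnames(out) <- list(names(s), ens@teachingIds)
  out
}

setMethod("show", "Ensemble", function(object) {
  conv <- vapply(object@members, function(mb) mb$model@converged, logical(1))
  p <- object@members[[1L]]$model@params
  cat("Ensemble of ", length(object@members), " networks (",
      p@n, "-", p@m, "-", p@k, "), teaching length ",
      object@targetLength, "\n", sep = "")
  cat("  teaching ids:", paste(utils::head(object@teachingIds, 5L),
                               collapse = ", "),
      if (length(object@teachingIds) > 5L) "...", "\n")
  cat("  converged members:", sum(conv), "/", length(conv), "\n")
})

setMethod("show", "RecognitionResult", function(object) {
  cat("RecognitionResult", object@organismId, "\n")
  top <- sort(similarity(object), decreasing = TRUE)
  top <- utils::head(top, 3L)
  cat("  top similarities:",
      paste(sprintf("%s=%.4f", names(top), top), collapse = ", "), "\n")
})
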