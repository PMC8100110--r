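test_that("encodings are seeded, distinct and invertible", {
  e1 <- makeEncoding(7)
  e2 <- makeEncoding(7)
  expect_identical(e1@codeMap, e2@codeMap)
  expect_identical(ncol(e1@codeMap), 5L)
  expect_false(anyDuplicated(apply(e1@codeMap, 1, paste0, collapse = "")) > 0)
  # different seeds essentially always yield different tables
  differing <- sum(vapply(1:100, function(s) {
    !identical(makeEncoding(s)@codeMap, makeEncoding(s + 1000)@codeMap)
  }, logical(1)))
  expect_gte(differing, 99L)
  expect_error(makeEncoding(1, alphabet = c(aaAlphabet(), letters[1:5])),
               "32")
})

test_that("sequences encode to five bits per residue and decode back", {
  enc <- makeEncoding(3)
  expect_length(encodeSequence(strrep("M", 400), enc), 2000L)
  expect_length(encodeSequence("", enc), 0L)
  s <- "MKV-XW"
  expect_identical(decodeSequence(encodeSequence(s, enc), enc), s)
  expect_error(encodeSequence("MK@V", enc), "'@' at position 3")
})

test_that("geometric pyramid rule sizes the hidden layer", {
  expect_identical(pyramidHiddenSize(2000, 36), 268L)
  expect_identical(pyramidHiddenSize(100, 1), 10L)
  expect_identical(pyramidHiddenSize(50, 7), 19L)  # sqrt(350) = 18.71
})

test_that("forward pass applies sigmoids layer by layer", {
  expect_equal(sigmoid(0), 0.5)
  params <- networkParams(n = 10, k = 3, m = 4, initSeed = 5)
  model <- newNetwork(params)
  # zero weights and biases: hidden = sigmoid(0) = 0.5, output = sigmoid(0) = 0.5
  zero <- model
  zero@W1[] <- 0; zero@b1[] <- 0; zero@W2[] <- 0; zero@b2[] <- 0
  expect_equal(mlpForward(zero, rep(1, 10)), rep(0.5, 3))
  # outputs bounded in (0, 1) for random inputs
  set.seed(1)
  for (i in 1:100) {
    y <- mlpForward(model, rbinom(10, 1, 0.5))
    expect_true(all(y > 0 & y < 1))
  }
  expect_error(mlpForward(model, rep(0, 4)), "input length")
})

test_that("backpropagation gradients match central finite differences", {
  params <- networkParams(n = 6, k = 2, m = 3, initSeed = 42)
  model <- newNetwork(params)
  set.seed(42)
  x <- rbinom(6, 1, 0.5)
  target <- c(1, 0)
  g <- seqAttractors:::.gradients(model, x, target)
  for (slot in c("W1", "b1", "W2", "b2")) {
    fd <- finiteDiffGrad(model, x, target, slot)
    analytic <- g[[paste0("d", slot)]]
    expect_lt(max(abs(as.vector(analytic) - as.vector(fd))) /
                max(abs(fd)), 1e-5)
  }
})

test_that("a model already at its RMSE target is returned untouched", {
  params <- networkParams(n = 4, k = 2, m = 3, initSeed = 9, rmseTarget = 1e-9)
  model <- newNetwork(params)
  X <- matrix(rbinom(8, 1, 0.5), 2, 4)
  targets <- rbind(mlpForward(model, X[1, ]), mlpForward(model, X[2, ]))
  fit <- trainOnline(model, X, targets)
  expect_true(converged(fit))
  expect_identical(fit@W1, model@W1)
  expect_equal(rmseHistory(fit), 0)
})

test_that("with momentum off, updates reduce to plain gradient steps", {
  params <- networkParams(n = 5, k = 2, m = 3, initSeed = 3,
                          learningRate = 0.2, momentum = 0,
                          rmseTarget = 1e-12, maxEpochs = 1L)
  model <- newNetwork(params)
  set.seed(3)
  x <- rbinom(5, 1, 0.5)
  target <- c(0, 1)
  # one epoch over the same pattern twice = two successive online updates
  fit <- suppressWarnings(
    trainOnline(model, rbind(x, x), rbind(target, target)))
  # replay manually: two plain gradient steps
  manual <- model
  for (i in 1:2) {
    g <- seqAttractors:::.gradients(manual, x, target)
    manual@W1 <- manual@W1 - 0.2 * g$dW1
    manual@b1 <- manual@b1 - 0.2 * g$db1
    manual@W2 <- manual@W2 - 0.2 * g$dW2
    manual@b2 <- manual@b2 - 0.2 * g$db2
  }
  expect_equal(fit@W1, manual@W1, tolerance = 1e-14)
  expect_equal(fit@W2, manual@W2, tolerance = 1e-14)
  expect_equal(fit@b2, manual@b2, tolerance = 1e-14)
})

teaching <- makeTeachingSet(k = 3, nCodons = 20, seed = 21)

test_that("ensembles are deterministic under a master seed", {
  e1 <- teachEnsemble(teaching, nVersions = 2, masterSeed = 5,
                      rmseTarget = 0.05)
  e2 <- teachEnsemble(teaching, nVersions = 2, masterSeed = 5,
                      rmseTarget = 0.05)
  expect_identical(e1@members[[1]]$model@W1, e2@members[[1]]$model@W1)
  expect_identical(e1@members[[2]]$encoding@codeMap,
                   e2@members[[2]]$encoding@codeMap)
  r1 <- recognize(e1, as.character(teaching[[1]]))
  r2 <- recognize(e2, as.character(teaching[[1]]))
  expect_identical(similarity(r1), similarity(r2))
})

test_that("recognition is the arithmetic mean of member outputs", {
  ens <- teachEnsemble(teaching, nVersions = 3, masterSeed = 8,
                       rmseTarget = 0.05)
  r <- recognize(ens, as.character(teaching[[2]]), id = "probe")
  expect_equal(unname(similarity(r)), unname(colMeans(perMember(r))),
               tolerance = 1e-12)
  expect_true(all(similarity(r) > 0 & similarity(r) < 1))
  # single-member ensemble: mean equals the raw member output
  one <- teachEnsemble(teaching, nVersions = 1, masterSeed = 8,
                       rmseTarget = 0.05)
  rOne <- recognize(one, as.character(teaching[[2]]))
  x <- encodeSequence(as.character(teaching[[2]]),
                      one@members[[1]]$encoding)
  expect_equal(unname(similarity(rOne)),
               mlpForward(one@members[[1]]$model, x))
})

test_that("length mismatches and training shortfalls are reported", {
  ens <- teachEnsemble(teaching, nVersions = 1, masterSeed = 8,
                       rmseTarget = 0.05)
  expect_error(recognize(ens, "MKV"), "length")
  expect_warning(
    teachEnsemble(teaching, nVersions = 1, masterSeed = 5,
                  rmseTarget = 1e-6, maxEpochs = 3L),
    "not reached")
})

test_that("the plain-text archive round-trips bit-exactly", {
  ens <- teachEnsemble(teaching, nVersions = 2, masterSeed = 13,
                       rmseTarget = 0.05)
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  saveEnsemble(ens, dir)
  back <- loadEnsemble(dir)
  expect_identical(teachingIds(back), teachingIds(ens))
  for (v in 1:2) {
    expect_identical(back@members[[v]]$model@W1, ens@members[[v]]$model@W1)
    expect_identical(back@members[[v]]$model@b2, ens@members[[v]]$model@b2)
    expect_identical(back@members[[v]]$encoding@codeMap,
                     ens@members[[v]]$encoding@codeMap)
  }
  s <- as.character(teaching[[3]])
  expect_identical(similarity(recognize(back, s)),
                   similarity(recognize(ens, s)))
})
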