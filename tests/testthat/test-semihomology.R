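m1 <- buildSemihomologyMatrix(geneticCode(1))
m2 <- buildSemihomologyMatrix(geneticCode(2))

test_that("pair classification matches codon-level expectations", {
  # frozen values from brute-force codon-pair enumeration
  expect_identical(classifyPair("L", "L", m1), "R")
  expect_identical(classifyPair("D", "E", m1), "$")
  expect_identical(classifyPair("F", "P", m1), "-")
  # I/M: ATA<->ATG transition exists alongside transversion paths; the
  # transition wins the tie-break under the standard code
  expect_identical(classifyPair("I", "M", m1), "#")
  # under the vertebrate mitochondrial code ATA codes M, so only
  # transversion paths remain between I and M
  expect_identical(classifyPair("I", "M", m2), "$")
  # non-comparable symbols: pad, ambiguity codes, stops
  expect_identical(classifyPair("A", "-", m1), "?")
  expect_identical(classifyPair(c("X", "*", "B"), c("A", "A", "A"), m1),
                   c("?", "?", "?"))
})

test_that("matrix is symmetric with an all-R diagonal", {
  expect_identical(m1@classes, t(m1@classes))
  expect_true(all(diag(m1@classes) == "R"))
  expect_identical(m2@classes, t(m2@classes))
})

test_that("standard and mitochondrial tables differ exactly where the codes differ", {
  # AGA/AGG become stops and ATA moves I -> M in table 2; the affected
  # amino-acid pairs were frozen from brute-force enumeration
  d <- which(m1@classes != m2@classes, arr.ind = TRUE)
  pairs <- unique(apply(d, 1L, function(i)
    paste(sort(c(rownames(m1@classes)[i[1]], colnames(m1@classes)[i[2]])),
          collapse = "")))
  expect_setequal(pairs, c("GR", "IK", "IM", "IR", "KR", "MR", "RT"))
})

test_that("unknown translation table is a configuration error", {
  expect_error(geneticCode(99L), "unknown NCBI translation table")
})

test_that("custom code files reproduce the built-in classification", {
  tab <- codonTable(geneticCode(2))
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path))
  writeLines(paste(names(tab), tab), path)
  mFile <- buildSemihomologyMatrix(readGeneticCode(path, tableId = 2L))
  expect_identical(mFile@classes, m2@classes)
})

test_that("pairwise comparison counts, percentages and factor are consistent", {
  s <- randomProtein(80, seed = 402)
  self <- compareSequences(s, s, m1)
  expect_equal(self@pctR, 100)
  expect_equal(self@pctSemihomologous, 0)
  expect_true(is.na(tsTvFactor(self)))

  dd <- compareSequences("DD", "EE", m1)
  expect_identical(classCounts(dd),
                   c(R = 0L, "#" = 0L, "$" = 2L, "-" = 0L))
  expect_equal(dd@pctSemihomologous, 100)
  expect_equal(tsTvFactor(dd), 0)   # zero transitions over two transversions

  # pad positions drop out of the comparable length
  fp <- compareSequences("FF-", "PF-", m1)
  expect_identical(lengthCompared(fp), 2L)
  expect_identical(classCounts(fp)[["R"]], 1L)
  expect_identical(classCounts(fp)[["-"]], 1L)
  expect_equal(fp@pctR, 50)
  expect_identical(perPosition(fp), c("-", "R", "?"))

  expect_error(compareSequences("MK", "MKV", m1), "lengths differ")
})

test_that("profile counts always sum to the comparable length", {
  for (seed in 1:20) {
    a <- randomProtein(60, seed)
    b <- mutateProtein(a, 0.4, seed + 1000)
    p <- compareSequences(a, b, m1)
    expect_identical(sum(classCounts(p)), lengthCompared(p))
    expect_equal(p@pctR + p@pctSemihomologous + p@pctMulti, 100,
                 tolerance = 1e-12)
  }
})

test_that("dot matrix classifies the full cross product", {
  expect_identical(dotMatrix("A", "A", m1)@cells,
                   matrix("R", 1, 1, dimnames = list("A", "A")))
  dm <- dotMatrix("DF", "E", m1)
  expect_identical(unname(dm@cells), matrix(c("$", "-"), 2, 1))
  s <- randomProtein(12, seed = 9)
  expect_true(all(diag(dotMatrix(s, s, m1)@cells) == "R"))
  # empty input is an empty matrix, not an error
  expect_identical(dim(dotMatrix("", "A", m1)@cells), c(0L, 1L))
})

test_that("dot matrix renders as text and long-format table", {
  dm <- dotMatrix("DF", "AE", m1)
  txt <- dotMatrixText(dm)
  expect_length(txt, 2L)
  expect_true(all(grepl("^[R#$.]{2}$", txt)))
  tab <- dotMatrixTable(dm)
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$class[tab$i == 1 & tab$j == 2], "$")  # (D,E)
})
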