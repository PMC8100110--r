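# Shared fixtures and independent oracles, all generated in code.

# Independent brute-force semihomology classifier: enumerates every codon
# pair of two amino acids with plain string handling and takes the minimal
# Hamming distance, classifying distance-1 pairs by the exchange type of
# the single differing base. Deliberately written unlike the package's
# vectorised relation-matrix implementation.
oracleClass <- function(a, b, codonTable) {
  if (a == b) return("R")
  ca <- names(codonTable)[codonTable == a & codonTable != "*"]
  cb <- names(codonTable)[codonTable == b & codonTable != "*"]
  purines <- c("A", "G"); pyrimidines <- c("C", "T")
  sawTransition <- FALSE; sawTransversion <- FALSE
  for (x in ca) for (y in cb) {
    cx <- substring(x, 1:3, 1:3); cy <- substring(y, 1:3, 1:3)
    diffs <- which(cx != cy)
    if (length(diffs) == 1L) {
      n1 <- cx[diffs]; n2 <- cy[diffs]
      if ((n1 %in% purines && n2 %in% purines) ||
          (n1 %in% pyrimidines && n2 %in% pyrimidines))
        sawTransition <- TRUE
      else sawTransversion <- TRUE
    }
  }
  if (sawTransition) "#" else if (sawTransversion) "$" else "-"
}

oracleMatrix <- function(tableId) {
  codonTable <- Biostrings::getGeneticCode(as.character(tableId))
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  m <- matrix("", 20, 20, dimnames = list(aas, aas))
  for (a in aas) for (b in aas) m[a, b] <- oracleClass(a, b, codonTable)
  m
}

# Random amino-acid string over the 20 standard residues.
randomProtein <- function(len, seed) {
  set.seed(seed)
  paste0(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                len, replace = TRUE), collapse = "")
}

# Small synthetic teaching set: k related proteins diverged from a common
# codon ancestor (star phylogeny), mimicking orthologs of one gene.
makeTeachingSet <- function(k = 6L, nCodons = 60L, divergence = 0.75,
                            seed = 11L) {
  fam <- generateFamily(
    data.frame(name = "teach", nMembers = k,
               substitutionsPerSite = divergence),
    nCodons = nCodons, seed = seed)
  familyMembers(fam)[-1L]   # drop the reference ancestor
}

# Substitute a fraction of residues with random different standard amino
# acids (seeded); emulates a held-out variant of a teaching organism.
mutateProtein <- function(s, rate, seed) {
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  set.seed(seed)
  chars <- strsplit(s, "")[[1L]]
  npos <- max(1L, round(rate * length(chars)))
  pos <- sample(seq_along(chars), npos)
  for (p in pos) chars[p] <- sample(setdiff(aas, chars[p]), 1L)
  paste0(chars, collapse = "")
}

# Central finite-difference gradient of the per-pattern summed squared
# error 0.5 * sum((y - t)^2) with respect to one weight array.
finiteDiffGrad <- function(model, x, target, slot, eps = 1e-6) {
  w <- slot(model, slot)
  g <- array(0, dim = dim(w) %||% length(w))
  lossAt <- function(m) 0.5 * sum((mlpForward(m, x) - target)^2)
  for (i in seq_along(w)) {
    mp <- model; wp <- w; wp[i] <- wp[i] + eps; slot(mp, slot) <- wp
    mm <- model; wm <- w; wm[i] <- wm[i] - eps; slot(mm, slot) <- wm
    g[i] <- (lossAt(mp) - lossAt(mm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
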