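m1 <- buildSemihomologyMatrix(geneticCode(1))

# designed profiles: ref AAAAAAAAAA vs members with D substitutions
# ((A,D) is a transversion pair, so pctR is directly controlled)
profileWithR <- function(pctR) {
  nR <- round(pctR / 10)
  member <- paste0(c(rep("A", nR), rep("D", 10 - nR)), collapse = "")
  compareSequences(strrep("A", 10), member, m1)
}

test_that("group characteristics are member means with undefined factors dropped", {
  gSelf <- attractorGroup("self", "a", profiles = list(
    compareSequences("MKVH", "MKVH", m1)))
  chSelf <- groupCharacteristics(gSelf)
  expect_equal(chSelf$avgR, 100)
  expect_equal(chSelf$avgMulti, 0)
  expect_true(is.na(chSelf$avgTsTv))   # all factors undefined

  g <- attractorGroup("pair", c("a", "b"),
                      profiles = list(profileWithR(60), profileWithR(80)))
  ch <- groupCharacteristics(g)
  expect_equal(ch$avgR, 70)
  expect_equal(ch$avgR + ch$avgSemihomologous + ch$avgMulti, 100,
               tolerance = 1e-9)

  # one member with a defined factor, one without: mean over defined only
  withTs <- compareSequences("II", "MM", m1)    # two # positions, no $
  withBoth <- compareSequences("ID", "ME", m1)  # one #, one $
  gMix <- attractorGroup("mix", c("a", "b"),
                         profiles = list(withTs, withBoth))
  expect_equal(groupCharacteristics(gMix)$avgTsTv, 1)

  expect_error(groupCharacteristics(attractorGroup("none", "a")),
               "no comparison profiles")
})

test_that("group characteristics equal a brute-force recomputation", {
  set.seed(77)
  ref <- randomProtein(50, seed = 77)
  members <- vapply(1:4, function(i) mutateProtein(ref, 0.3, 500 + i),
                    character(1))
  profiles <- lapply(members, function(s) compareSequences(ref, s, m1))
  g <- attractorGroup("bf", paste0("m", 1:4), profiles = profiles)
  ch <- groupCharacteristics(g)
  # recompute from raw per-position classes
  pctOf <- function(p, cls) 100 * sum(perPosition(p) == cls) /
    sum(perPosition(p) != "?")
  expect_equal(ch$avgR, mean(vapply(profiles, pctOf, numeric(1), "R")))
  expect_equal(ch$avgMulti, mean(vapply(profiles, pctOf, numeric(1), "-")))
  expect_equal(ch$avgSemihomologous,
               mean(vapply(profiles, function(p)
                 pctOf(p, "#") + pctOf(p, "$"), numeric(1))))
})

simGroup <- function(name, rows) {
  attractorGroup(name, paste0(name, seq_len(nrow(rows))), similarities = rows)
}

test_that("orbit radii are reciprocal similarities with >= 1 factors", {
  gNear <- simGroup("near", matrix(c(0.5, 0.1, 0.5, 0.1), 2, byrow = TRUE))
  gFar <- simGroup("far", matrix(c(0.25, 0.3), 1))
  rep2 <- orbitRadii(list(gNear, gFar), refOutput = 1)
  expect_equal(rep2$similarity, c(0.5, 0.25))
  expect_equal(rep2$radius, c(2, 4))
  expect_equal(rep2$distanceFactor, c(NA, 2))

  # identical similarities: factor exactly 1
  same <- orbitRadii(list(gNear, gNear), refOutput = 1)
  expect_equal(same$distanceFactor[2], 1)

  # a single group has a radius but no factor
  single <- orbitRadii(list(gFar), refOutput = 1)
  expect_equal(single$radius, 4)
  expect_true(is.na(single$distanceFactor))

  zero <- simGroup("z", matrix(c(0, 0.2), 1))
  expect_error(orbitRadii(list(zero), refOutput = 1), "degenerate.*z")
})

test_that("distance factors are scale-invariant and reproduce the ratio identity", {
  set.seed(31)
  mats <- lapply(1:4, function(i) matrix(runif(6, 0.05, 0.9), 2, 3))
  groups <- lapply(1:4, function(i) simGroup(paste0("g", i), mats[[i]]))
  f1 <- orbitRadii(groups, refOutput = 2)$distanceFactor
  scaled <- lapply(1:4, function(i) simGroup(paste0("g", i), 0.37 * mats[[i]]))
  f2 <- orbitRadii(scaled, refOutput = 2)$distanceFactor
  expect_equal(f1, f2, tolerance = 1e-12)

  # two orbits whose similarities stand in ratio 1.0013 have distance
  # factor 1.0013 for any absolute similarity level
  for (x in c(0.9, 0.2, 1e-3)) {
    gi <- simGroup("inner", matrix(1.0013 * x, 1, 1))
    go <- simGroup("outer", matrix(x, 1, 1))
    expect_equal(orbitRadii(list(gi, go), 1)$distanceFactor[2], 1.0013,
                 tolerance = 1e-12)
  }
})

test_that("disturbances rank outside attractions by mean similarity", {
  oneHot <- simGroup("hot", matrix(c(0, 0, 1, 0), 1))
  d <- disturbances(oneHot, excludeOutputs = integer(0))
  expect_identical(d$output[1], 3L)
  expect_equal(d$meanSimilarity[1], 1)

  # uniform vector: all tie, broken by teaching order
  flat <- simGroup("flat", matrix(0.2, 2, 4))
  dFlat <- disturbances(flat, excludeOutputs = 2)
  expect_identical(dFlat$output, c(1L, 3L, 4L))
  expect_error(disturbances(flat, excludeOutputs = 1:4), "all.*excluded")

  # planted secondary signal: members carry a bump at output 4
  set.seed(91)
  base <- matrix(runif(15, 0, 0.05), 3, 5)
  base[, 1] <- runif(3, 0.8, 0.9)   # own lineage
  base[, 4] <- base[, 4] + 0.3      # planted disturbance
  planted <- simGroup("planted", base)
  dP <- disturbances(planted, excludeOutputs = 1, topK = 2)
  expect_identical(dP$output[1], 4L)
  expect_identical(nrow(dP), 2L)
})

test_that("makeGroups joins similarity and profile data by group table", {
  tab <- data.frame(
    organism_id = c("ref", "a1", "a2", "b1"),
    group = c("reference", "A", "A", "B"),
    role = "examine",
    is_reference = c(TRUE, FALSE, FALSE, FALSE))
  sims <- matrix(runif(8), 4, 2,
                 dimnames = list(c("a1", "a2", "b1", "ref"), c("t1", "t2")))
  groups <- makeGroups(tab, similarityMatrix = sims,
                       groupOrder = c("B", "A"))
  expect_identical(names(groups), c("B", "A"))
  expect_identical(groups$A@memberIds, c("a1", "a2"))
  expect_equal(groups$A@similarities, sims[c("a1", "a2"), ])
  expect_error(makeGroups(tab, similarityMatrix = sims[1:2, ]),
               "no similarities for")
})
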