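test_that("readPedigree validates structure and orders topologically", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam,birth_date,sex",
               "C,A,B,1995-03,unknown",
               "A,0,0,1993-01-10,male",
               "B,0,0,1993-02,female"), f)
  ped <- readPedigree(f)
  expect_s4_class(ped, "Pedigree")
  expect_equal(length(ped), 3L)
  expect_setequal(founders(ped), c("A", "B"))
  expect_equal(pedIds(ped), c("A", "B", "C"))   # ancestors first
  expect_equal(unname(birthDates(ped)["B"]), as.Date("1993-02-15"))

  fBad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam,birth_date,sex",
               "C,C,B,1995-03,unknown",
               "B,0,0,1993-02,female"), fBad)
  expect_error(readPedigree(fBad), "cycle.*C")

  fMiss <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam,birth_date,sex",
               "C,A,B,1995-03,unknown"), fMiss)
  expect_error(readPedigree(fMiss), "without a pedigree record")
  pedAuto <- readPedigree(fMiss, addMissingFounders = TRUE)
  expect_setequal(founders(pedAuto), c("A", "B"))
})

test_that("construction is invariant to input row order", {
  ped <- randomPedigree(8, 92, seed = 11)
  df <- as.data.frame(ped)
  set.seed(99)
  sh <- sample(nrow(df))
  ped2 <- Pedigree(df$id[sh], df$sire[sh], df$dam[sh],
                   birthDate = df$birth_date[sh], sex = df$sex[sh])
  expect_identical(as.data.frame(ped2), df)
})

test_that("duplicate ids and longer cycles are rejected with names", {
  expect_error(Pedigree(c("A", "A"), c(NA, NA), c(NA, NA)),
               "duplicated id 'A'")
  # two-node cycle: X and Y each other's parent
  expect_error(Pedigree(c("X", "Y"), sire = c("Y", "X"), dam = c(NA, NA)),
               "cycle")
})

test_that("dummy progenies are unique per mating pair and never parents", {
  ped <- Pedigree(c("S1", "S2", "D1"), sire = c(NA, NA, NA),
                  dam = c(NA, NA, NA), sex = c("male", "male", "female"))
  out <- addDummyProgenies(ped, dam = c("D1", "D1", "D1"),
                           sire = c("S1", "S1", "S2"))
  expect_equal(length(out), 5L)
  expect_equal(sum(pedSex(out) == "dummy"), 2L)
  expect_identical(addDummyProgenies(ped, character(), character()), ped)
  expect_error(addDummyProgenies(ped, "nope", "S1"), "unknown dam")
  # dummies cannot be parents: validity blocks it
  dumId <- litterDummyId("D1", "S1")
  expect_error(Pedigree(c(pedIds(out), "K"),
                        c(pedSires(out), dumId),
                        c(pedDams(out), "D1"),
                        sex = c(pedSex(out), "unknown")),
               "dummy")
})

test_that("dummy count equals the number of distinct mating pairs", {
  sim <- smallStudy()
  kind <- sim$kindlings
  nPairs <- nrow(unique(kind[c("dam", "sire")]))
  expect_equal(sum(pedSex(sim$pedigree) == "dummy"), nPairs)
})

test_that("exact inbreeding matches closed forms and the enumeration oracle", {
  trio <- Pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"),
                   sex = c("male", "female", "unknown"))
  expect_equal(unname(exactInbreeding(trio)["C"]), 0)

  fs <- fullSibLine(2)
  expect_equal(unname(exactInbreeding(fs)["S2"]), 0.25)

  line5 <- fullSibLine(5)
  fTab <- exactInbreeding(line5)
  fEnum <- coefficientTable(exactCoefficients(line5))$F
  expect_equal(unname(fTab), fEnum, tolerance = 1e-12)
  # classical repeated full-sib recursion F_t = (1 + 2F_{t-1} + F_{t-2})/4
  expect_equal(unname(fTab[c("S2", "S3", "S4", "S5")]),
               c(0.25, 0.375, 0.5, 0.59375))
})

test_that("relationship matrix agrees with the recursive kinship oracle", {
  trio <- Pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"),
                   sex = c("male", "female", "unknown"))
  A <- relationshipMatrix(trio)
  expect_equal(diag(A), c(A = 1, B = 1, C = 1))
  expect_equal(A["A", "C"], 0.5)
  expect_equal(A["A", "B"], 0)

  fs <- fullSibLine(1)
  expect_equal(relationshipMatrix(fs)["S1", "D1"], 0.5)

  ped <- randomPedigree(6, 44, seed = 21)
  ids <- pedIds(ped)
  A <- relationshipMatrix(ped, ids)
  expect_equal(unname(A), 2 * naiveKinshipMatrix(ped, ids),
               tolerance = 1e-12)
  # PSD and consistency with exact F
  expect_true(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
              > -1e-10)
  expect_equal(unname(diag(A)) - 1, unname(exactInbreeding(ped)),
               tolerance = 1e-12)
  expect_error(relationshipMatrix(ped, "ghost"), "not in pedigree")
})

test_that("sparse A-inverse inverts the tabular A", {
  ped <- randomPedigree(6, 44, seed = 31)
  ids <- sample(pedIds(ped), 20)
  ri <- relationshipInverse(ped, ids)
  A <- relationshipMatrix(ped, ri$ids)
  expect_lt(max(abs(as.matrix(ri$Ainv %*% A) - diag(nrow(A)))), 1e-10)
  expect_equal(ri$logdetA, as.numeric(determinant(A)$modulus),
               tolerance = 1e-10)
})

test_that("complete generation equivalents count per path", {
  trio <- Pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"))
  expect_equal(unname(completeGenerationEquivalent(trio, "C")), 1)

  line3 <- fullSibLine(3)   # fully known to depth 3
  expect_equal(unname(completeGenerationEquivalent(line3, "S3")), 3)

  # one known grandparent on the sire side only
  ped <- Pedigree(c("G", "S", "D", "X"), sire = c(NA, "G", NA, "S"),
                  dam = c(NA, NA, NA, "D"),
                  sex = c("male", "male", "female", "unknown"))
  expect_equal(unname(completeGenerationEquivalent(ped, "X")), 1.25)
  expect_equal(cgePathOracle(ped, "X"), 1.25)

  rp <- randomPedigree(5, 30, seed = 41)
  cge <- completeGenerationEquivalent(rp)
  oracle <- vapply(pedIds(rp), cgePathOracle, 0, ped = rp)
  expect_equal(cge, oracle, tolerance = 1e-12)
  expect_true(all(cge[founders(rp)] == 0))
})

test_that("CGE is monotone when ancestors are added", {
  ped <- Pedigree(c("S", "D", "X"), c(NA, NA, "S"), c(NA, NA, "D"))
  before <- completeGenerationEquivalent(ped)
  extended <- Pedigree(c("GS", "GD", "S", "D", "X"),
                       sire = c(NA, NA, "GS", NA, "S"),
                       dam = c(NA, NA, "GD", NA, "D"))
  after <- completeGenerationEquivalent(extended, names(before))
  expect_true(all(after >= before))
})

test_that("Ne follows 1/(2 deltaF) and the regression estimator works", {
  expect_equal(neFromDeltaF(0.005)@Ne, 100)
  expect_error(neFromDeltaF(1.2), "deltaF")

  sim <- smallStudy()
  ne <- estimateNe(sim$pedigree)
  expect_s4_class(ne, "NeEstimate")
  expect_true(ne@deltaF > 0 && ne@deltaF < 1)
  expect_equal(ne@Ne, round(1 / (2 * ne@deltaF)))
  ne2 <- estimateNe(sim$pedigree, method = "individual_deltaF")
  expect_equal(ne2@Ne, round(1 / (2 * ne2@deltaF)))

  # regression needs >= 2 distinct equivalent-generation values
  flat <- Pedigree(c("A", "B"), c(NA, NA), c(NA, NA))
  expect_error(estimateNe(flat), "distinct equivalent-generation|not positive")
})

test_that("founder contributions are recursive averages that sum to one", {
  trio <- Pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"),
                   sex = c("male", "female", "unknown"))
  fc <- founderContributions(trio, "C")
  expect_equal(fc, c(A = 0.5, B = 0.5))

  ped <- randomPedigree(6, 20, seed = 51)
  fcF <- founderContributions(ped, founders(ped))
  expect_equal(unname(fcF), rep(1 / 6, 6))

  # complete pedigree: contributions sum to 1 per cohort
  cohort <- setdiff(pedIds(ped), founders(ped))
  expect_equal(sum(founderContributions(ped, cohort)), 1, tolerance = 1e-9)
})

test_that("founder contributions match gene-dropping allele frequencies", {
  ped <- randomPedigree(4, 12, seed = 61)
  cohortId <- pedIds(ped)[length(ped)]
  fc <- founderContributions(ped, cohortId)
  # founder -> allele label map (labels are assigned in pedigree order)
  lab <- 0L
  alleleOwner <- character()
  for (i in seq_along(pedIds(ped))) {
    for (side in c("sire", "dam")) {
      par <- if (side == "sire") pedSires(ped)[i] else pedDams(ped)[i]
      if (is.na(par)) {
        alleleOwner[as.character(lab)] <- pedIds(ped)[i]
        lab <- lab + 1L
      }
    }
  }
  nRep <- 1000L
  set.seed(71)
  counts <- setNames(numeric(length(fc)), names(fc))
  pos <- match(cohortId, pedIds(ped))
  for (r in seq_len(nRep)) {
    d <- dropOnce(ped)
    for (al in c(d$allele1[pos], d$allele2[pos])) {
      own <- alleleOwner[as.character(al)]
      counts[own] <- counts[own] + 0.5
    }
  }
  freq <- counts / nRep
  se <- sqrt(pmax(fc * (1 - fc), 1e-4) / (2 * nRep))
  expect_true(all(abs(freq - fc) <= 3 * se + 1e-8))
})
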