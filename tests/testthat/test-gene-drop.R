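# replay a dropOnce() transmission record independently in R and return the
# recomputed genotype table
replayDrop <- function(ped, d) {
  n <- length(ped)
  sires <- match(pedSires(ped), pedIds(ped))
  dams <- match(pedDams(ped), pedIds(ped))
  a1 <- a2 <- integer(n)
  f1 <- f2 <- logical(n)
  nextAllele <- 0L
  for (i in seq_len(n)) {
    s <- sires[i]
    if (is.na(s)) {
      a1[i] <- nextAllele; nextAllele <- nextAllele + 1L; f1[i] <- FALSE
    } else {
      autoS <- a1[s] == a2[s]
      if (d$pickSire[i] == 1L) { a1[i] <- a2[s]; f1[i] <- f2[s] || autoS }
      else { a1[i] <- a1[s]; f1[i] <- f1[s] || autoS }
    }
    dd <- dams[i]
    if (is.na(dd)) {
      a2[i] <- nextAllele; nextAllele <- nextAllele + 1L; f2[i] <- FALSE
    } else {
      autoD <- a1[dd] == a2[dd]
      if (d$pickDam[i] == 1L) { a2[i] <- a2[dd]; f2[i] <- f2[dd] || autoD }
      else { a2[i] <- a1[dd]; f2[i] <- f1[dd] || autoD }
    }
  }
  data.frame(allele1 = a1, allele2 = a2, flag1 = f1, flag2 = f2)
}

test_that("a single replicate obeys the transmission and flag semantics", {
  ped <- fullSibLine(6)
  set.seed(5)
  sawFlag <- FALSE
  for (r in 1:40) {
    d <- dropOnce(ped)
    rep <- replayDrop(ped, d)
    expect_identical(d$allele1, rep$allele1)
    expect_identical(d$allele2, rep$allele2)
    expect_identical(d$flag1, rep$flag1)
    expect_identical(d$flag2, rep$flag2)
    # a flagged copy implies an autozygous ancestor in this replicate
    auto <- d$autozygous
    sires <- match(pedSires(ped), pedIds(ped))
    dams <- match(pedDams(ped), pedIds(ped))
    for (i in seq_along(d$id)) {
      if (d$flag1[i] || d$flag2[i]) {
        sawFlag <- TRUE
        anc <- integer()
        frontier <- c(sires[i], dams[i])
        while (length(frontier)) {
          frontier <- frontier[!is.na(frontier)]
          anc <- union(anc, frontier)
          frontier <- c(sires[frontier], dams[frontier])
        }
        expect_true(any(auto[anc]))
      }
    }
  }
  expect_true(sawFlag)   # deep full-sib line must produce flagged copies
})

test_that("founder-only pedigrees never show autozygosity", {
  ped <- Pedigree(paste0("f", 1:6), rep(NA, 6), rep(NA, 6))
  set.seed(2)
  for (r in 1:5) expect_false(any(dropOnce(ped)$autozygous))
  cs <- coefficientTable(geneDropCoefficients(ped, 1000, seed = 3))
  expect_true(all(cs[, c("F", "Fnew", "Fak", "Fab")] == 0))
})

test_that("full-sib offspring autozygosity frequency matches F = 0.25", {
  ped <- fullSibLine(2)
  cs <- coefficientTable(geneDropCoefficients(ped, 2e4, seed = 13))
  expect_lt(abs(cs["S2", "F"] - 0.25), 4 * cs["S2", "seF"])
  # no ancestor of S2 can be autozygous: ancestral coefficients exactly zero
  expect_identical(cs["S2", "Fab"], 0)
  expect_identical(cs["S2", "Fak"], 0)
})

test_that("gene-drop estimates agree with exact enumeration on a deep line", {
  ped <- fullSibLine(4)
  ex <- coefficientTable(exactCoefficients(ped))
  gd <- coefficientTable(geneDropCoefficients(ped, 5e4, seed = 17))
  for (cc in c("F", "Fnew", "Fak", "Fab")) {
    se <- pmax(gd[[paste0("se", sub("^F", "F", cc))]], 1e-4)
    expect_true(all(abs(gd[[cc]] - ex[[cc]]) <= 4 * se),
                info = cc)
  }
})

test_that("the exact enumeration equals the tabular method for F", {
  for (s in 1:6) {
    ped <- randomPedigree(3, 7, seed = 100 + s)
    ex <- coefficientTable(exactCoefficients(ped))
    expect_equal(ex$F, unname(exactInbreeding(ped)), tolerance = 1e-12)
  }
})

test_that("enumeration refuses pedigrees above the cap", {
  ped <- randomPedigree(3, 11, seed = 8)
  expect_error(exactCoefficients(ped), "cap")
  expect_s4_class(exactCoefficients(ped, maxNonFounders = 11),
                  "CoefficientSet")
})

test_that("doubly inbred full-sib matings expose ancestral autozygosity", {
  # offspring of two full sibs who are themselves offspring of full sibs:
  # the parents (F = 0.25) can be autozygous, so Fak becomes positive
  ped <- fullSibLine(3)
  ex <- coefficientTable(exactCoefficients(ped))
  x <- ex["S3", ]
  expect_identical(x$F, x$Fnew + x$Fak)
  expect_gt(x$Fak, 0)
  expect_gte(x$Fab, x$Fak)
  expect_equal(x$F, 0.375)
})

test_that("decomposition and ordering hold exactly on random pedigrees", {
  for (s in 1:5) {
    ped <- randomPedigree(4, 16, seed = 200 + s)
    cs <- coefficientTable(geneDropCoefficients(ped, 2000, seed = s))
    expect_identical(cs$F, cs$Fnew + cs$Fak)
    expect_true(all(cs$Fak <= cs$Fab))
    expect_true(all(cs$Fab <= 1))
    fTab <- exactInbreeding(ped)
    expect_true(all(abs(cs$F - fTab) <= 4 * pmax(cs$seF, 2e-3)))
  }
})

test_that("identical seed and iterations reproduce bit-identical results", {
  ped <- randomPedigree(4, 10, seed = 33)
  a <- geneDropCoefficients(ped, 5000, seed = 42)
  b <- geneDropCoefficients(ped, 5000, seed = 42)
  expect_identical(coefficientTable(a), coefficientTable(b))
  c2 <- geneDropCoefficients(ped, 5000, seed = 43)
  expect_false(identical(coefficientTable(a), coefficientTable(c2)))
})
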