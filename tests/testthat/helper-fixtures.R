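# Fixture builders and independent oracles used across the test files.

# repeated full-sib line: founders S0, D0; generation t has full sibs St, Dt
# whose parents are S(t-1), D(t-1); returns the pedigree and the terminal ids
fullSibLine <- function(generations) {
  id <- c("S0", "D0")
  sire <- dam <- c(NA_character_, NA_character_)
  sex <- c("male", "female")
  for (t in seq_len(generations)) {
    id <- c(id, paste0(c("S", "D"), t))
    sire <- c(sire, rep(paste0("S", t - 1L), 2L))
    dam <- c(dam, rep(paste0("D", t - 1L), 2L))
    sex <- c(sex, "male", "female")
  }
  Pedigree(id, sire, dam, sex = sex)
}

# random pedigree: founders f1..fk, then nNonFounders individuals whose two
# parents are drawn (distinct) from all earlier individuals
randomPedigree <- function(nFounders, nNonFounders, seed) {
  set.seed(seed)
  n <- nFounders + nNonFounders
  ids <- c(paste0("f", seq_len(nFounders)), paste0("x", seq_len(nNonFounders)))
  sire <- dam <- rep(NA_character_, n)
  for (i in (nFounders + 1L):n) {
    pr <- sample(i - 1L, 2L)
    sire[i] <- ids[pr[1L]]
    dam[i] <- ids[pr[2L]]
  }
  Pedigree(ids, sire, dam)
}

# independent kinship oracle: direct recursion on parent identifiers with
# memoisation; phi(i,i) = (1 + phi(sire, dam)) / 2, and for i later in the
# pedigree than j, phi(i,j) = (phi(sire_i, j) + phi(dam_i, j)) / 2
naiveKinshipMatrix <- function(ped, ids) {
  sires <- pedSires(ped)
  dams <- pedDams(ped)
  posn <- setNames(seq_along(pedIds(ped)), pedIds(ped))
  memo <- new.env(parent = emptyenv())
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- if (posn[i] < posn[j]) paste(i, j) else paste(j, i)
    got <- get0(key, envir = memo)
    if (!is.null(got)) return(got)
    val <- if (i == j) {
      (1 + phi(sires[[i]], dams[[i]])) / 2
    } else {
      late <- if (posn[i] > posn[j]) i else j
      other <- if (posn[i] > posn[j]) j else i
      (phi(sires[[late]], other) + phi(dams[[late]], other)) / 2
    }
    assign(key, val, envir = memo)
    val
  }
  outer(ids, ids, Vectorize(function(a, b) phi(a, b)))
}

# independent CGE oracle: explicit depth-first enumeration of every descent
# path, adding (1/2)^depth for each known ancestor encountered
cgePathOracle <- function(ped, id) {
  sires <- pedSires(ped)
  dams <- pedDams(ped)
  total <- 0
  stack <- list(list(node = id, depth = 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (p in c(sires[[top$node]], dams[[top$node]])) {
      if (!is.na(p)) {
        total <- total + 0.5^(top$depth + 1L)
        stack[[length(stack) + 1L]] <- list(node = p, depth = top$depth + 1L)
      }
    }
  }
  total
}

# small kindling-record set over one pedigree of unrelated dams
unrelatedDamRecords <- function(nDams, recsPerDam, seed, sigma2 = 0.4,
                                intercept = 1.8, betaSeason = -0.3) {
  set.seed(seed)
  dams <- paste0("d", seq_len(nDams))
  ped <- Pedigree(id = dams, sire = rep(NA, nDams), dam = rep(NA, nDams),
                  sex = rep("female", nDams))
  dat <- data.frame(
    dam = rep(dams, each = recsPerDam),
    kindlingDate = as.Date("1995-01-10") +
      sample(0:360, nDams * recsPerDam, replace = TRUE),
    parity = rep_len(1:6, nDams * recsPerDam),
    nTotal = 8L + rpois(nDams * recsPerDam, 2))
  dat$season <- encodeSeason(dat$kindlingDate)
  dat$parityClass <- encodeParity(dat$parity)
  a <- rnorm(nDams, 0, sqrt(sigma2))
  eta <- intercept + betaSeason * (dat$season == "summer") +
    a[match(dat$dam, dams)]
  dat$nAlive <- rbinom(nrow(dat), dat$nTotal, plogis(eta))
  dat$nDead <- dat$nTotal - dat$nAlive
  list(ped = ped, records = dat)
}

# fabricated SurvivalModelFit for selection/averaging arithmetic tests
fakeFit <- function(aiccValue, terms, estimates = NULL, ses = NULL,
                    converged = TRUE) {
  est <- if (is.null(estimates)) rep(0.1, length(terms)) else estimates
  se <- if (is.null(ses)) rep(0.05, length(terms)) else ses
  new("SurvivalModelFit",
      coefficients = data.frame(term = terms, estimate = est, se = se,
                                stringsAsFactors = FALSE),
      sigma2a = 0.1, logLik = -aiccValue / 2, k = length(terms) + 1L,
      n = 1000L, aic = aiccValue, aicc = aiccValue, converged = converged,
      inbreedingTerms = setdiff(terms, c("intercept", "season")),
      approach = "custom")
}

# small simulated study shared by several test files (cached per session)
smallStudy <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateStudy(simConfig(years = 5, seed = 101))
    cache
  }
})
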