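## Synthetic closed-population generator: overlapping generations, yearly
## recruitment of replacement breeders, optional truncation selection on a
## neutral heritable index (to induce declining founder contributions), and
## binomial kit survival driven by a known logit model.

#' Default simulation configuration
#'
#' The default scenario emulates a closed selected rabbit population over 25
#' years — overlapping generations, a few breeding bucks per ~4 does, about
#' four kindlings per doe and year, litter sizes around nine — at roughly a
#' tenth of the size of a national breeding programme so that a full run
#' stays interactive. The true response model applies, on the logit scale,
#' the fixed effects of parity and season, the named z-standardised
#' inbreeding covariates, and a polygenic dam effect with variance
#' `sigma2a`; its defaults encode an early-phase population with inbreeding
#' depression through new litter inbreeding (negative `zFNEWL`) and purging
#' (positive `zFAKL`).
#'
#' @param ... named overrides of any default.
#' @return a `SimConfig` list.
#' @export
simConfig <- function(...) {
  cfg <- list(
    nFounders = 80,
    years = 25,
    doesPerYear = 8,          # replacement does recruited each year
    bucksPerYear = 2,         # replacement bucks recruited each year
    littersPerDoeYear = 4,
    meanLitterSize = 9,       # shifted Poisson: 1 + Poisson(mean - 1)
    replacementFraction = 1 / 3,  # breeders stay ~3 years
    matingScheme = "random",  # or "circular", "within_line"
    nLines = 4,               # lines used by the within_line scheme
    selection = TRUE,         # truncation on a neutral heritable index
    startYear = 1993,
    trueModel = list(intercept = 3.2, season = -0.25,
                     parityA = 0.19, parityB = 0.31, parityC = 0.37,
                     zFNEWL = -0.4, zFAKL = 0.3, zFNEWD = 0,
                     zFL = 0, zFD = 0, zFABL = 0,
                     sigma2a = 0.3),
    dropIterations = 1e4,     # gene-drop replicates for the truth table
    standardisation = "z_1sd",
    seed = 20200708
  )
  over <- list(...)
  if ("trueModel" %in% names(over)) {
    cfg$trueModel[names(over$trueModel)] <- over$trueModel
    over$trueModel <- NULL
  }
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown SimConfig field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$nFounders > 3, cfg$years >= 0, cfg$doesPerYear >= 1,
            cfg$bucksPerYear >= 1, cfg$littersPerDoeYear >= 1,
            cfg$meanLitterSize >= 1, cfg$replacementFraction > 0,
            cfg$trueModel$sigma2a >= 0)
  cfg
}

randomDate <- function(year, n = 1L) {
  as.Date(sprintf("%d-01-01", year)) + floor(runif(n, 0, 365))
}

#' Simulate a closed pedigreed population
#'
#' Founders form year 0; each subsequent year every breeding doe produces
#' its kindlings with a buck chosen by the mating scheme, and a fixed number
#' of replacement does and bucks are recruited from the year's litters
#' (optionally by truncation on a neutral heritable index, which makes
#' founder contributions decline). No immigration ever occurs. Dummy
#' progenies for every distinct mating pair are appended to the returned
#' pedigree so litters carry their own coefficients.
#'
#' @param cfg a [simConfig()] list.
#' @return list with `pedigree` (a [Pedigree-class] including litter
#'   dummies) and `kindlings` (data.frame `dam`, `sire`, `litter`,
#'   `kindlingDate`, `parity`, `nTotal`; no survival outcomes yet).
#' @export
simulatePedigree <- function(cfg = simConfig()) {
  set.seed(cfg$seed)
  lifespan <- max(1L, round(1 / cfg$replacementFraction))
  nB <- max(2L, round(cfg$nFounders * cfg$bucksPerYear /
                        (cfg$bucksPerYear + cfg$doesPerYear)))
  nD <- cfg$nFounders - nB
  founders <- data.frame(
    id = sprintf("F%03d", seq_len(cfg$nFounders)),
    sire = NA_character_, dam = NA_character_,
    sex = rep(c("male", "female"), c(nB, nD)),
    birthDate = randomDate(cfg$startYear - 1L, cfg$nFounders),
    index = rnorm(cfg$nFounders),
    line = rep_len(seq_len(cfg$nLines), cfg$nFounders),
    age = 0L, stringsAsFactors = FALSE)
  rows <- founders
  pool <- founders
  kindl <- list()
  parityCount <- new.env(parent = emptyenv())
  nextId <- 1L

  for (year in seq_len(cfg$years) + cfg$startYear - 1L) {
    bucks <- pool[pool$sex == "male", , drop = FALSE]
    does <- pool[pool$sex == "female", , drop = FALSE]
    if (nrow(bucks) == 0L || nrow(does) == 0L)
      stop("population extinct in year ", year, ": no eligible mates")
    yearLitters <- list()
    for (di in seq_len(nrow(does))) {
      doe <- does[di, ]
      for (l in seq_len(cfg$littersPerDoeYear)) {
        sire <- switch(cfg$matingScheme,
          random = bucks[sample.int(nrow(bucks), 1L), ],
          circular = bucks[1L + (di + l + year) %% nrow(bucks), ],
          within_line = {
            same <- bucks[bucks$line == doe$line, , drop = FALSE]
            if (nrow(same) == 0L) same <- bucks
            same[sample.int(nrow(same), 1L), ]
          },
          stop("unknown mating scheme: ", cfg$matingScheme))
        par <- (get0(doe$id, envir = parityCount, ifnotfound = 0L)) + 1L
        assign(doe$id, par, envir = parityCount)
        size <- 1L + rpois(1L, cfg$meanLitterSize - 1)
        yearLitters[[length(yearLitters) + 1L]] <- data.frame(
          dam = doe$id, sire = sire$id,
          kindlingDate = randomDate(year), parity = par, nTotal = size,
          midIndex = (doe$index + sire$index) / 2,
          line = doe$line, stringsAsFactors = FALSE)
      }
    }
    yl <- do.call(rbind, yearLitters)
    kindl[[length(kindl) + 1L]] <-
      yl[c("dam", "sire", "kindlingDate", "parity", "nTotal")]

    # recruit replacements from distinct litters of this year
    nRecruit <- cfg$doesPerYear + cfg$bucksPerYear
    ord <- if (cfg$selection)
      order(-(yl$midIndex + rnorm(nrow(yl), 0, 0.5))) else
      sample.int(nrow(yl))
    src <- yl[ord[seq_len(min(nRecruit, nrow(yl)))], , drop = FALSE]
    nNew <- nrow(src)
    recruits <- data.frame(
      id = sprintf("Y%d_%03d", year, seq_len(nNew) + nextId - 1L),
      sire = src$sire, dam = src$dam,
      sex = rep_len(c(rep("female", cfg$doesPerYear),
                      rep("male", cfg$bucksPerYear)), nNew),
      birthDate = src$kindlingDate,
      index = src$midIndex + rnorm(nNew, 0, sqrt(0.5)),
      line = src$line, age = 0L, stringsAsFactors = FALSE)
    nextId <- nextId + nNew
    rows <- rbind(rows, recruits)
    pool$age <- pool$age + 1L
    pool <- rbind(pool[pool$age < lifespan, , drop = FALSE], recruits)
  }

  kindlings <- if (length(kindl)) do.call(rbind, kindl) else
    data.frame(dam = character(), sire = character(),
               kindlingDate = as.Date(character()), parity = integer(),
               nTotal = integer())
  kindlings$litter <- litterDummyId(kindlings$dam, kindlings$sire)
  ped <- Pedigree(rows$id, rows$sire, rows$dam,
                  birthDate = rows$birthDate, sex = rows$sex)
  if (nrow(kindlings))
    ped <- addDummyProgenies(ped, kindlings$dam, kindlings$sire)
  list(pedigree = ped, kindlings = kindlings)
}

#' Simulate binomial survival outcomes for kindling records
#'
#' Applies the configured true logit model: for each kindling,
#' `p = plogis(X beta + a_dam)` with `a ~ N(0, sigma2a * A)` over the dams'
#' additive relationship matrix, and `nAlive ~ Binomial(nTotal, p)`.
#' Covariates are z-standardised within the supplied records, exactly as
#' the analysis pipeline does, so the true coefficients live on the
#' reported scale.
#'
#' @param sim output of [simulatePedigree()].
#' @param coeffs a [CoefficientSet-class] for `sim$pedigree` (the truth
#'   table).
#' @param cfg the [simConfig()] used.
#' @return the kindling records with columns `nAlive`, `nDead`, the model
#'   frame covariates, and the realised dam effect `aDam`.
#' @export
simulateKindlings <- function(sim, coeffs, cfg = simConfig()) {
  rec <- sim$kindlings
  if (!nrow(rec)) return(rec)
  set.seed(cfg$seed + 1L)
  mf <- buildModelFrame(rec, coeffs, standardisation = cfg$standardisation)
  tm <- cfg$trueModel
  dams <- sort(unique(mf$dam))
  a <- numeric(length(dams))
  if (tm$sigma2a > 0) {
    A <- relationshipMatrix(sim$pedigree, dams)
    a <- sqrt(tm$sigma2a) * drop(t(chol(A)) %*% rnorm(length(dams)))
  }
  names(a) <- dams
  eta <- tm$intercept +
    tm$season * (mf$season == "summer") +
    tm$parityA * (mf$parityClass == "P2") +
    tm$parityB * (mf$parityClass == "P3_10") +
    tm$parityC * (mf$parityClass == "P11plus") +
    tm$zFNEWL * mf$zFNEWL + tm$zFAKL * mf$zFAKL + tm$zFNEWD * mf$zFNEWD +
    tm$zFL * mf$zFL + tm$zFD * mf$zFD + tm$zFABL * mf$zFABL +
    a[mf$dam]
  mf$aDam <- unname(a[mf$dam])
  mf$nAlive <- rbinom(nrow(mf), mf$nTotal, plogis(eta))
  mf$nDead <- mf$nTotal - mf$nAlive
  mf
}

#' Simulate a complete synthetic study
#'
#' Chains [simulatePedigree()], [geneDropCoefficients()] (the truth table,
#' at `cfg$dropIterations` replicates) and [simulateKindlings()]. The same
#' seed gives a bit-identical result.
#'
#' @param cfg a [simConfig()] list.
#' @return a `SimOutput` list: `pedigree`, `kindlings` (with outcomes),
#'   `coefficients` (truth [CoefficientSet-class]), `config`.
#' @export
simulateStudy <- function(cfg = simConfig()) {
  sim <- simulatePedigree(cfg)
  coeffs <- geneDropCoefficients(sim$pedigree,
                                 iterations = cfg$dropIterations,
                                 seed = cfg$seed + 2L)
  kind <- simulateKindlings(sim, coeffs, cfg)
  structure(list(pedigree = sim$pedigree, kindlings = kind,
                 coefficients = coeffs, config = cfg),
            class = "SimOutput")
}

#' Write a simulated study to plain-text files
#'
#' Writes `pedigree.csv`, `kindlings.csv` and `truth.csv` (the coefficient
#' table) into a directory, in the formats [readPedigree()] and
#' [readKindlings()] read back.
#'
#' @param sim a `SimOutput` from [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimOutput <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(sim$pedigree),
            file.path(dir, "pedigree.csv"), row.names = FALSE, na = "")
  keep <- c("dam", "sire", "kindlingDate", "parity", "nTotal", "nAlive")
  kd <- sim$kindlings[intersect(keep, names(sim$kindlings))]
  names(kd) <- c(dam = "dam", sire = "sire", kindlingDate = "kindling_date",
                 parity = "parity", nTotal = "n_total",
                 nAlive = "n_alive")[names(kd)]
  write.csv(kd, file.path(dir, "kindlings.csv"), row.names = FALSE)
  write.csv(sim$coefficients@coefficients, file.path(dir, "truth.csv"),
            row.names = FALSE)
  invisible(dir)
}
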