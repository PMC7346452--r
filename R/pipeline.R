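## Study orchestration: period splitting, coefficient estimation, dual
## modelling approaches per period, selection/averaging and report tables.

#' Default study configuration
#'
#' @param ... named overrides. Fields: `periods` (list of `c(from, to)`
#'   month-precision boundaries, inclusive of the named months),
#'   `dropIterations` and `dropSeed` for gene dropping, `standardisation`,
#'   `threshold` (delta-AICc selection cut-off), `neMethod`, `verbose`
#'   (stage-level timing messages), `outDir`
#'   (optional directory for CSV outputs).
#' @return a `StudyConfig` list.
#' @export
studyConfig <- function(...) {
  cfg <- list(
    periods = list(c("1992-12", "1997-08"),
                   c("1997-09", "2007-10"),
                   c("2007-11", "2017-11")),
    dropIterations = 1e6,
    dropSeed = 20200708,
    standardisation = "z_1sd",
    threshold = 2.0,
    neMethod = "regression_logF",
    outDir = NULL,
    verbose = FALSE
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown StudyConfig field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

# month-precision period boundaries -> inclusive Date range
periodRange <- function(period) {
  from <- as.Date(paste0(period[1L], "-01"))
  toFirst <- as.Date(paste0(period[2L], "-01"))
  to <- seq(toFirst, by = "1 month", length.out = 2L)[2L] - 1L
  c(from, to)
}

#' Assign records to analysis periods
#'
#' @param dates kindling dates.
#' @param periods list of `c(from, to)` month-precision boundaries.
#' @return integer period index per date (`NA` when outside every period).
#' @export
assignPeriod <- function(dates, periods) {
  d <- parseDates(dates)
  out <- rep(NA_integer_, length(d))
  for (i in seq_along(periods)) {
    r <- periodRange(periods[[i]])
    out[!is.na(d) & d >= r[1L] & d <= r[2L]] <- i
  }
  out
}

corrWithNA <- function(m) {
  out <- suppressWarnings(cor(m))
  const <- apply(m, 2L, function(x) sd(x) == 0 || !is.finite(sd(x)))
  out[const, ] <- NA_real_
  out[, const] <- NA_real_
  diag(out) <- 1
  out
}

#' Correlations among inbreeding coefficients, by role
#'
#' Pearson correlations among F, Fnew, Fak and Fab within the dam and
#' litter roles. Zero-variance coefficients give undefined (`NA`)
#' off-diagonal cells.
#'
#' @param coeffs a [CoefficientSet-class].
#' @param damIds,litterIds the individuals making up each role (at least 3
#'   per role to be meaningful).
#' @return list with symmetric unit-diagonal matrices `dam` and `litter`.
#' @export
correlationReport <- function(coeffs, damIds, litterIds) {
  cf <- coefficientTable(coeffs)
  one <- function(ids) {
    if (length(ids) < 3L) stop("need >= 3 individuals per role")
    corrWithNA(as.matrix(cf[ids, c("F", "Fnew", "Fak", "Fab")]))
  }
  list(dam = one(unique(damIds)), litter = one(unique(litterIds)))
}

#' Descriptive statistics of coefficients, per kindling record
#'
#' Mean, median, SD and maximum of the eight inbreeding coefficients (dam
#' and litter roles) and the two complete generation equivalents, computed
#' across kindling records.
#'
#' @param records kindling records (columns `dam`, `litter`).
#' @param coeffs a [CoefficientSet-class].
#' @param ped a [Pedigree-class] (for the CGE values).
#' @return data.frame with one row per parameter.
#' @export
descriptiveTable <- function(records, coeffs, ped) {
  cf <- coefficientTable(coeffs)
  cge <- completeGenerationEquivalent(ped)
  vals <- list(
    FL = cf[records$litter, "F"], FD = cf[records$dam, "F"],
    FNEWL = cf[records$litter, "Fnew"], FNEWD = cf[records$dam, "Fnew"],
    FABL = cf[records$litter, "Fab"], FABD = cf[records$dam, "Fab"],
    FAKL = cf[records$litter, "Fak"], FAKD = cf[records$dam, "Fak"],
    CGEL = unname(cge[records$litter]), CGED = unname(cge[records$dam]))
  data.frame(parameter = names(vals),
             mean = vapply(vals, mean, 0), median = vapply(vals, median, 0),
             sd = vapply(vals, sd, 0), max = vapply(vals, max, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Founder-contribution trend over birth-year cohorts
#'
#' For each birth year, the expected founder contributions to that cohort
#' (dummies excluded) and the number of contributing founders
#' (contribution > 0).
#'
#' @param ped a [Pedigree-class].
#' @return data.frame with columns `year`, `cohortSize`, `nContributing`,
#'   `maxContribution`.
#' @export
founderContributionTrend <- function(ped) {
  bd <- birthDates(ped)
  real <- pedSex(ped) != "dummy" & !is.na(bd)
  years <- sort(unique(as.integer(format(bd[real], "%Y"))))
  rows <- lapply(years, function(y) {
    ids <- names(bd)[real & as.integer(format(bd, "%Y")) == y]
    fc <- founderContributions(ped, ids)
    data.frame(year = y, cohortSize = length(ids),
               nContributing = sum(fc > 1e-12),
               maxContribution = max(fc))
  })
  do.call(rbind, rows)
}

#' Run the complete inbreeding-depression study
#'
#' Executes the whole analysis: dummy-progeny completion, gene-dropping
#' coefficient estimation, per-period standardisation, candidate-model
#' enumeration for both modelling approaches, delta-AICc selection and
#' natural-average averaging, plus descriptive statistics, coefficient
#' correlations, Ne per period and the founder-contribution trend.
#' Deterministic given the configured seed; a period without records is
#' reported as empty.
#'
#' @param ped a [Pedigree-class] (dummy progenies are added as needed).
#' @param records kindling records (see [readKindlings()]).
#' @param config a [studyConfig()] list.
#' @return a `StudyReport` list with elements `descriptives`,
#'   `correlations`, `ne` (overall and per period), `founderTrend`,
#'   `periods` (per period: per approach `selection` and `averaged`
#'   tables plus the fit objects), `coefficients`, `config`.
#' @export
runStudy <- function(ped, records, config = studyConfig()) {
  stopifnot(is(ped, "Pedigree"))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("study stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    if (isTRUE(config$verbose))
      message(sprintf("[%s] %.1fs", name, proc.time()[["elapsed"]] - t0))
    out
  }
  records <- stage("validate_records", {
    if (!"litter" %in% names(records))
      records$litter <- litterDummyId(records$dam, records$sire)
    records
  })
  ped <- stage("dummy_progenies", {
    newPairs <- !(records$litter %in% pedIds(ped))
    if (any(newPairs))
      addDummyProgenies(ped, records$dam[newPairs], records$sire[newPairs])
    else ped
  })
  coeffs <- stage("gene_drop",
    geneDropCoefficients(ped, iterations = config$dropIterations,
                         seed = config$dropSeed))

  period <- assignPeriod(records$kindlingDate, config$periods)
  perPeriod <- vector("list", length(config$periods))
  for (i in seq_along(config$periods)) {
    recs <- records[!is.na(period) & period == i, , drop = FALSE]
    if (!nrow(recs)) { perPeriod[[i]] <- list(empty = TRUE); next }
    mf <- stage(paste0("standardise_period", i),
                buildModelFrame(recs, coeffs,
                                standardisation = config$standardisation))
    res <- list(empty = FALSE, n = nrow(recs))
    for (appr in c("ballou_boakes", "kalinowski")) {
      sel <- stage(paste0("models_period", i, "_", appr), {
        cands <- enumerateCandidates(mf, ped, approach = appr)
        selectModels(cands, threshold = config$threshold)
      })
      res[[appr]] <- list(selection = selectionTable(sel),
                          averaged = averagedTable(sel),
                          fits = sel)
    }
    ne <- tryCatch(
      estimateNe(ped, window = vapply(periodRange(config$periods[[i]]),
                                      format, ""),
                 method = config$neMethod),
      error = function(e) NULL)
    res$ne <- ne
    res$descriptives <- descriptiveTable(recs, coeffs, ped)
    perPeriod[[i]] <- res
  }

  damIds <- unique(records$dam)
  litterIds <- unique(records$litter)
  report <- structure(list(
    descriptives = stage("descriptives",
                         descriptiveTable(records, coeffs, ped)),
    correlations = stage("correlations",
                         correlationReport(coeffs, damIds, litterIds)),
    ne = stage("ne", tryCatch(estimateNe(ped, method = config$neMethod),
                              error = function(e) NULL)),
    founderTrend = stage("founder_trend", founderContributionTrend(ped)),
    periods = perPeriod,
    coefficients = coeffs,
    config = config
  ), class = "StudyReport")
  if (!is.null(config$outDir)) writeStudyReport(report, config$outDir)
  report
}

#' Write a study report to CSV files
#'
#' Flushes the report tables (descriptives, correlations, founder trend,
#' and per period/approach the selection and averaged-estimate tables) plus
#' a plain-text run manifest to a directory.
#'
#' @param report a `StudyReport` from [runStudy()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeStudyReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(df, name)
    write.csv(df, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
  out(report$descriptives, "descriptives")
  out(report$founderTrend, "founder_trend")
  for (role in c("dam", "litter"))
    write.csv(report$correlations[[role]],
              file.path(dir, paste0("correlations_", role, ".csv")))
  writeCoefficients(report$coefficients, file.path(dir, "coefficients.csv"))
  for (i in seq_along(report$periods)) {
    p <- report$periods[[i]]
    if (isTRUE(p$empty)) next
    for (appr in c("ballou_boakes", "kalinowski")) {
      out(p[[appr]]$selection, sprintf("selection_p%d_%s", i, appr))
      out(p[[appr]]$averaged, sprintf("averaged_p%d_%s", i, appr))
    }
  }
  manifest <- c(
    sprintf("pedpurge version: %s",
            as.character(utils::packageVersion("pedpurge"))),
    sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("gene-drop iterations: %g, seed: %g",
            report$config$dropIterations, report$config$dropSeed),
    sprintf("standardisation: %s, selection threshold: %g",
            report$config$standardisation, report$config$threshold),
    sprintf("periods: %s",
            paste(vapply(report$config$periods, paste, "", collapse = ".."),
                  collapse = "; ")))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @exportS3Method base::print
print.StudyReport <- function(x, ...) {
  cat("StudyReport\n")
  if (!is.null(x$ne)) { cat("  overall "); show(x$ne) }
  for (i in seq_along(x$periods)) {
    p <- x$periods[[i]]
    if (isTRUE(p$empty)) { cat(sprintf("  period %d: no records\n", i)); next }
    cat(sprintf("  period %d: %d records; best models: %s | %s\n", i, p$n,
                p$ballou_boakes$selection$model[1L],
                p$kalinowski$selection$model[1L]))
  }
  invisible(x)
}
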