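## Candidate enumeration, AICc-based selection, Akaike weights and
## natural-average model averaging with unconditional confidence intervals.

#' Inbreeding-covariate family of a modelling approach
#'
#' The Ballou–Boakes family combines the classical inbreeding of the dam and
#' litter with the Ballou ancestral coefficient of the litter; the Kalinowski
#' family uses the decomposition into new and ancestral components. The two
#' families are never mixed in one candidate set.
#'
#' @param approach `"ballou_boakes"` or `"kalinowski"`.
#' @return character vector of the three z-covariate column names.
#' @export
approachCovariates <- function(approach = c("ballou_boakes", "kalinowski")) {
  switch(match.arg(approach),
         ballou_boakes = c("zFD", "zFL", "zFABL"),
         kalinowski = c("zFNEWD", "zFNEWL", "zFAKL"))
}

subsetLabel <- function(covs) {
  if (!length(covs)) "none" else paste(covs, collapse = "+")
}

#' Fit all candidate models of one approach
#'
#' Fits the `2^3 = 8` subsets of the approach's three inbreeding covariates;
#' parity, season and the polygenic animal effect are always included.
#'
#' @param data model frame from [buildModelFrame()] (already restricted to
#'   one analysis period).
#' @param ped a [Pedigree-class].
#' @param approach `"ballou_boakes"` or `"kalinowski"`.
#' @param ... passed to [fitSurvivalGlmm()].
#' @return a `CandidateSet`: list with elements `approach` and `fits` (a
#'   named list of [SurvivalModelFit-class], keyed by covariate subset).
#' @export
enumerateCandidates <- function(data, ped,
                                approach = c("ballou_boakes", "kalinowski"),
                                ...) {
  approach <- match.arg(approach)
  covs <- approachCovariates(approach)
  fits <- list()
  for (mask in 0:7) {
    subset <- covs[bitwAnd(mask, c(1L, 2L, 4L)) > 0L]
    lbl <- subsetLabel(subset)
    fits[[lbl]] <- tryCatch(
      fitSurvivalGlmm(data, ped, covariates = subset,
                      approach = approach, ...),
      error = function(e) {
        warning("candidate '", lbl, "' failed and is excluded: ",
                conditionMessage(e), call. = FALSE)
        new("SurvivalModelFit",
            coefficients = data.frame(term = character(),
                                      estimate = numeric(), se = numeric(),
                                      stringsAsFactors = FALSE),
            sigma2a = 0, logLik = -Inf, k = 0L, n = nrow(data),
            aic = Inf, aicc = Inf, converged = FALSE,
            inbreedingTerms = subset, approach = approach)
      })
  }
  structure(list(approach = approach, fits = fits), class = "CandidateSet")
}

#' Akaike weights
#'
#' @param aiccValues numeric vector of AICc values.
#' @return weights proportional to `exp(-deltaAICc / 2)`, normalised over
#'   the supplied set.
#' @export
akaikeWeights <- function(aiccValues) {
  if (!length(aiccValues)) stop("need at least one AICc value")
  d <- aiccValues - min(aiccValues)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Select candidate models by the delta-AICc criterion
#'
#' Non-converged fits are dropped (with a warning) before selection. Fits
#' within `threshold` AICc units of the best are retained and their Akaike
#' weights renormalised.
#'
#' @param cands a `CandidateSet` from [enumerateCandidates()], or a plain
#'   (named) list of [SurvivalModelFit-class].
#' @param threshold retain fits with `deltaAICc <= threshold` (default 2).
#' @return a `SelectionResult`: list with `fits` (retained, best first),
#'   `aicc`, `delta`, `weights` (renormalised, summing to 1) and `approach`.
#' @export
selectModels <- function(cands, threshold = 2.0) {
  fits <- if (inherits(cands, "CandidateSet")) cands$fits else cands
  approach <- if (inherits(cands, "CandidateSet")) cands$approach else NA
  conv <- vapply(fits, function(f) f@converged, logical(1L))
  if (any(!conv)) {
    warning("excluding ", sum(!conv), " non-converged candidate(s): ",
            paste(names(fits)[!conv], collapse = ", "))
    fits <- fits[conv]
  }
  if (!length(fits)) stop("no converged candidate models")
  av <- vapply(fits, function(f) f@aicc, numeric(1L))
  delta <- av - min(av)
  keep <- delta <= threshold
  fits <- fits[keep]
  av <- av[keep]
  delta <- delta[keep]
  ord <- order(delta, names(fits))
  w <- akaikeWeights(av[ord])
  structure(list(fits = fits[ord], aicc = av[ord], delta = delta[ord],
                 weights = w, approach = approach),
            class = "SelectionResult")
}

#' Model-selection table
#'
#' One row per retained model with its AICc, renormalised Akaike weight and
#' delta-AICc (best model first).
#'
#' @param sel a `SelectionResult` from [selectModels()].
#' @return data.frame with columns `model`, `AICc`, `weight`, `deltaAICc`.
#' @export
selectionTable <- function(sel) {
  data.frame(model = names(sel$fits),
             AICc = unname(sel$aicc),
             weight = unname(sel$weights),
             deltaAICc = unname(sel$delta),
             stringsAsFactors = FALSE)
}

termRows <- function(fit, term) {
  cf <- fit@coefficients
  cf[cf$term == term, , drop = FALSE]
}

#' Natural-average model averaging for one term
#'
#' Averages the coefficient over the selected models that contain the term,
#' with Akaike weights renormalised among those models. The unconditional
#' standard error follows the Burnham–Anderson formula
#' `sum(w * sqrt(se^2 + (b - bbar)^2))`, and the 95% CI is
#' `bbar +/- 1.96 * SE`. Relative importance (RI) is the summed weight, over
#' the full selected set, of the models containing the term, so a term
#' present in every selected model has RI = 1.
#'
#' @param sel a `SelectionResult` from [selectModels()].
#' @param term coefficient label (e.g. `"season"`, `"zFNEWL"`).
#' @param level confidence level (default 0.95 with the conventional 1.96
#'   multiplier).
#' @return data.frame row with `term`, `estimate`, `se`, `lower`, `upper`,
#'   `RI`, `nModels`; a term absent from every selected model gets RI = 0
#'   and `NA` estimates.
#' @export
naturalAverage <- function(sel, term, level = 0.95) {
  has <- vapply(sel$fits, function(f) nrow(termRows(f, term)) > 0L,
                logical(1L))
  ri <- sum(sel$weights[has])
  if (!any(has))
    return(data.frame(term = term, estimate = NA_real_, se = NA_real_,
                      lower = NA_real_, upper = NA_real_, RI = 0,
                      nModels = 0L, stringsAsFactors = FALSE))
  b <- vapply(sel$fits[has], function(f) termRows(f, term)$estimate,
              numeric(1L))
  s <- vapply(sel$fits[has], function(f) termRows(f, term)$se, numeric(1L))
  w <- sel$weights[has] / sum(sel$weights[has])
  bbar <- sum(w * b)
  seu <- sum(w * sqrt(s^2 + (b - bbar)^2))
  zq <- if (identical(level, 0.95)) 1.96 else qnorm(1 - (1 - level) / 2)
  data.frame(term = term, estimate = bbar, se = seu,
             lower = bbar - zq * seu, upper = bbar + zq * seu,
             RI = ri, nModels = sum(has), stringsAsFactors = FALSE)
}

#' Averaged-estimate table over all terms
#'
#' Applies [naturalAverage()] to every fixed-effect term appearing in any
#' selected model (mirrors the published estimate/CI/RI tables).
#'
#' @param sel a `SelectionResult`.
#' @param level confidence level.
#' @return data.frame, one row per term, with a `significant` flag (95% CI
#'   excluding zero).
#' @export
averagedTable <- function(sel, level = 0.95) {
  terms <- unique(unlist(lapply(sel$fits, function(f) f@coefficients$term)))
  out <- do.call(rbind, lapply(terms, naturalAverage, sel = sel,
                               level = level))
  out$significant <- !is.na(out$lower) & (out$lower > 0 | out$upper < 0)
  rownames(out) <- NULL
  out
}
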