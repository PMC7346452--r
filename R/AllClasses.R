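#' Pedigree: a validated, topologically ordered parentage structure
#'
#' Individuals are stored parents-before-offspring. Parent slots hold integer
#' indices into the same object (0 = unknown parent). Unknown parents are
#' treated downstream as unique, unrelated, non-inbred founders (the standard
#' tabular-method convention).
#'
#' @slot id character, unique non-empty individual identifiers.
#' @slot sire,dam integer indices of the parents within `id` (0 = unknown).
#' @slot birthDate `Date` of birth (`NA` allowed).
#' @slot sex one of `"male"`, `"female"`, `"dummy"`, `"unknown"` per
#'   individual. Dummy progenies carry litter-level coefficients and must
#'   never appear as parents.
#'
#' @export
setClass("Pedigree",
  representation(
    id = "character",
    sire = "integer",
    dam = "integer",
    birthDate = "Date",
    sex = "character"
  )
)

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  msg <- character()
  if (n == 0L) return(TRUE)
  if (anyNA(object@id) || any(!nzchar(object@id)))
    msg <- c(msg, "ids must be non-empty")
  if (anyDuplicated(object@id))
    msg <- c(msg, sprintf("duplicated id '%s'",
                          object@id[anyDuplicated(object@id)]))
  if (length(object@sire) != n || length(object@dam) != n ||
      length(object@birthDate) != n || length(object@sex) != n)
    msg <- c(msg, "all slots must have one entry per individual")
  bad <- object@sire < 0L | object@sire > n | object@dam < 0L | object@dam > n
  if (any(bad)) msg <- c(msg, "parent indices out of range")
  idx <- seq_len(n)
  if (any(object@sire == idx | object@dam == idx))
    msg <- c(msg, sprintf("individual '%s' is its own parent",
                          object@id[which(object@sire == idx |
                                          object@dam == idx)[1L]]))
  # topological invariant: parents precede offspring
  if (any(object@sire > idx) || any(object@dam > idx))
    msg <- c(msg, "pedigree is not in topological order")
  if (!all(object@sex %in% c("male", "female", "dummy", "unknown")))
    msg <- c(msg, "sex must be male, female, dummy or unknown")
  if (any(object@sire > 0L & object@sire == object@dam))
    msg <- c(msg, "sire and dam must be distinct individuals")
  ps <- object@sex[object@sire[object@sire > 0L]]
  pd <- object@sex[object@dam[object@dam > 0L]]
  if (any(ps == "dummy") || any(pd == "dummy"))
    msg <- c(msg, "dummy progenies must not appear as parents")
  if (any(ps == "female") || any(pd == "male"))
    msg <- c(msg, "parent sexes are incompatible with their role")
  if (length(msg)) msg else TRUE
})

#' CoefficientSet: per-individual inbreeding coefficients
#'
#' Holds, for every individual of a pedigree, the classical inbreeding
#' coefficient `F`, Kalinowski's new (`Fnew`) and ancestral (`Fak`)
#' components, and Ballou's ancestral coefficient (`Fab`), together with
#' Monte-Carlo standard errors (zero for exact enumeration). The
#' decomposition `F = Fnew + Fak` holds exactly because all four are
#' estimated from the same replicates.
#'
#' @slot coefficients data.frame with columns `id`, `F`, `Fnew`, `Fak`,
#'   `Fab`, `seF`, `seFnew`, `seFak`, `seFab`.
#' @slot iterations number of gene-dropping replicates (`Inf` for exact).
#' @slot seed RNG seed used (`NA` for exact enumeration).
#' @slot method `"gene_drop"` or `"exact_enumeration"`.
#'
#' @export
setClass("CoefficientSet",
  representation(
    coefficients = "data.frame",
    iterations = "numeric",
    seed = "numeric",
    method = "character"
  )
)

setValidity("CoefficientSet", function(object) {
  cf <- object@coefficients
  need <- c("id", "F", "Fnew", "Fak", "Fab", "seF", "seFnew", "seFak", "seFab")
  if (!all(need %in% names(cf)))
    return(sprintf("missing column(s): %s",
                   paste(setdiff(need, names(cf)), collapse = ", ")))
  p <- as.matrix(cf[c("F", "Fnew", "Fak", "Fab")])
  if (any(p < 0) || any(p > 1)) return("coefficients must lie in [0, 1]")
  if (any(cf$F != cf$Fnew + cf$Fak))
    return("decomposition F = Fnew + Fak violated")
  if (any(cf$Fak > cf$Fab)) return("Fak must not exceed Fab")
  TRUE
})

#' NeEstimate: per-generation inbreeding rate and effective population size
#'
#' @slot deltaF per-generation rate of inbreeding (dimensionless, in (0,1)).
#' @slot Ne effective population size, `round(1 / (2 * deltaF))`.
#' @slot method `"regression_logF"`, `"individual_deltaF"` or `"direct"`.
#' @slot n number of individuals the estimate is based on.
#'
#' @export
setClass("NeEstimate",
  representation(deltaF = "numeric", Ne = "numeric",
                 method = "character", n = "integer")
)

setValidity("NeEstimate", function(object) {
  if (object@deltaF <= 0 || object@deltaF >= 1)
    return("deltaF must lie in (0, 1)")
  if (object@Ne != round(1 / (2 * object@deltaF)))
    return("Ne must equal round(1 / (2 * deltaF))")
  TRUE
})

#' SurvivalModelFit: one fitted binomial logit mixed model
#'
#' @slot coefficients data.frame with columns `term`, `estimate`, `se`.
#' @slot sigma2a additive polygenic variance on the logit scale.
#' @slot logLik Laplace-approximated maximised marginal log-likelihood.
#' @slot k parameter count (fixed coefficients + 1 variance component).
#' @slot n number of kindling records.
#' @slot aic,aicc information criteria (`aicc >= aic`).
#' @slot converged optimizer convergence flag.
#' @slot inbreedingTerms the inbreeding-covariate subset of this candidate.
#' @slot approach `"ballou_boakes"`, `"kalinowski"` or `"custom"`.
#'
#' @export
setClass("SurvivalModelFit",
  representation(
    coefficients = "data.frame",
    sigma2a = "numeric",
    logLik = "numeric",
    k = "integer",
    n = "integer",
    aic = "numeric",
    aicc = "numeric",
    converged = "logical",
    inbreedingTerms = "character",
    approach = "character"
  )
)

setValidity("SurvivalModelFit", function(object) {
  if (length(object@sigma2a) && object@sigma2a < 0)
    return("sigma2a must be non-negative")
  if (length(object@aicc) && length(object@aic) &&
      object@aicc < object@aic - 1e-12)
    return("AICc must be >= AIC")
  TRUE
})
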