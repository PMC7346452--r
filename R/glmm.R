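## Binomial logit mixed models for survival at birth, with a polygenic
## "animal" random effect attached to the dam of each kindling record.
## The Laplace machinery lives in glmm-engine.R.

#' Encode the kindling season
#'
#' Summer runs from 15 June to 15 September, both ends inclusive; everything
#' else is non-summer.
#'
#' @param dates dates (anything [parseDates()] accepts).
#' @return factor with levels `non_summer` (reference), `summer`.
#' @export
encodeSeason <- function(dates) {
  d <- parseDates(dates)
  key <- as.integer(format(d, "%m")) * 100L + as.integer(format(d, "%d"))
  factor(ifelse(key >= 615L & key <= 915L, "summer", "non_summer"),
         levels = c("non_summer", "summer"))
}

#' Encode parity classes
#'
#' Parity (the order of the kindling within the doe's reproductive life) is
#' categorised as 1 (reference), 2, 3-10, and 11 or higher.
#'
#' @param parity positive integer vector.
#' @return factor with levels `P1`, `P2`, `P3_10`, `P11plus`.
#' @export
encodeParity <- function(parity) {
  parity <- as.integer(parity)
  if (anyNA(parity) || any(parity < 1L)) stop("parity must be >= 1")
  cls <- ifelse(parity == 1L, "P1",
         ifelse(parity == 2L, "P2",
         ifelse(parity <= 10L, "P3_10", "P11plus")))
  factor(cls, levels = c("P1", "P2", "P3_10", "P11plus"))
}

#' z-standardise a covariate
#'
#' Centres at the mean and scales by the sample standard deviation
#' (`z_1sd`, default) or by twice the sample SD (`gelman_2sd`, the rescaling
#' used by the arm package to make continuous and binary inputs comparable).
#'
#' @param x numeric vector with at least two distinct values.
#' @param method `"z_1sd"` or `"gelman_2sd"`.
#' @return list with elements `z`, `center`, `scale`, `method`.
#' @export
standardise <- function(x, method = c("z_1sd", "gelman_2sd")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot standardise a constant (zero-variance) covariate")
  scale <- if (method == "gelman_2sd") 2 * s else s
  structure(list(z = (x - mean(x)) / scale, center = mean(x),
                 scale = scale, method = method),
            class = "StandardisedCovariate")
}

#' Read kindling records from CSV
#'
#' @param path CSV with a header.
#' @param columns named character vector mapping roles `dam`, `sire`,
#'   `kindlingDate`, `parity`, `nTotal`, `nAlive` to file columns.
#' @return data.frame with columns `dam`, `sire`, `litter` (the
#'   [litterDummyId()] of the pair), `kindlingDate`, `parity`, `nTotal`,
#'   `nAlive`.
#' @export
readKindlings <- function(path,
                          columns = c(dam = "dam", sire = "sire",
                                      kindlingDate = "kindling_date",
                                      parity = "parity", nTotal = "n_total",
                                      nAlive = "n_alive")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (role in names(columns))
    if (!columns[[role]] %in% names(df))
      stop("column '", columns[[role]], "' (", role, ") not found in ", path)
  out <- data.frame(dam = as.character(df[[columns[["dam"]]]]),
                    sire = as.character(df[[columns[["sire"]]]]),
                    kindlingDate = parseDates(df[[columns[["kindlingDate"]]]]),
                    parity = as.integer(df[[columns[["parity"]]]]),
                    nTotal = as.integer(df[[columns[["nTotal"]]]]),
                    nAlive = as.integer(df[[columns[["nAlive"]]]]),
                    stringsAsFactors = FALSE)
  out$litter <- litterDummyId(out$dam, out$sire)
  if (any(out$nAlive < 0L | out$nAlive > out$nTotal) || any(out$nTotal < 1L))
    stop("kindling counts must satisfy 0 <= n_alive <= n_total, n_total >= 1")
  out
}

#' Assemble the model frame for survival models
#'
#' Attaches season, parity class and the six z-standardised inbreeding
#' covariates (dam and litter roles) to a set of kindling records.
#' Standardisation is computed within the supplied records, so subset to an
#' analysis period before calling.
#'
#' @param records data.frame as returned by [readKindlings()] (columns
#'   `dam`, `litter`, `kindlingDate`, `parity`, `nTotal`, `nAlive`).
#' @param coeffs a [CoefficientSet-class] covering all dams and litters.
#' @param standardisation `"z_1sd"` or `"gelman_2sd"`.
#' @return the records with added columns `season`, `parityClass`, `nDead`,
#'   and `zFD`, `zFL`, `zFABL`, `zFNEWD`, `zFNEWL`, `zFAKL` (plus the raw
#'   coefficient columns `FD`, `FL`, ...).
#' @export
buildModelFrame <- function(records, coeffs,
                            standardisation = c("z_1sd", "gelman_2sd")) {
  standardisation <- match.arg(standardisation)
  cf <- coefficientTable(coeffs)
  missDam <- setdiff(records$dam, rownames(cf))
  missLit <- setdiff(records$litter, rownames(cf))
  if (length(missDam) || length(missLit))
    stop("coefficients missing for: ",
         paste(head(c(missDam, missLit), 5L), collapse = ", "))
  out <- records
  out$season <- encodeSeason(records$kindlingDate)
  out$parityClass <- encodeParity(records$parity)
  if (!is.null(out$nAlive)) out$nDead <- out$nTotal - out$nAlive
  raw <- list(FD = cf[records$dam, "F"], FL = cf[records$litter, "F"],
              FABL = cf[records$litter, "Fab"],
              FNEWD = cf[records$dam, "Fnew"],
              FNEWL = cf[records$litter, "Fnew"],
              FAKL = cf[records$litter, "Fak"])
  constant <- character()
  for (nm in names(raw)) {
    out[[nm]] <- raw[[nm]]
    if (sd(raw[[nm]]) == 0) {
      # a coefficient without variation (e.g. no ancestral inbreeding yet
      # in a shallow pedigree) carries no information; its z column is all
      # zero and any candidate including it is dropped as rank-deficient
      out[[paste0("z", nm)]] <- rep(0, nrow(out))
      constant <- c(constant, paste0("z", nm))
    } else {
      out[[paste0("z", nm)]] <- standardise(raw[[nm]], standardisation)$z
    }
  }
  attr(out, "constantCovariates") <- constant
  out
}

# pretty term labels used throughout reports
renameTerms <- function(terms) {
  map <- c("(Intercept)" = "intercept", "seasonsummer" = "season",
           "parityClassP2" = "parityA", "parityClassP3_10" = "parityB",
           "parityClassP11plus" = "parityC")
  ifelse(terms %in% names(map), map[terms], terms)
}

#' Second-order Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`; always larger than AIC and
#' converging to it as n grows.
#'
#' @param loglik maximised log-likelihood.
#' @param k number of estimated parameters (fixed coefficients plus variance
#'   components).
#' @param n number of records.
#' @return the AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# shared set-up for the fitting functions: response, design matrix and
# pedigree precision structure
glmmContext <- function(data, ped, covariates, response) {
  need <- c("dam", "nAlive", "nDead", "parityClass", "season", covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data lacks column(s): ",
                         paste(miss, collapse = ", "))
  missDam <- setdiff(unique(as.character(data$dam)), pedIds(ped))
  if (length(missDam)) stop("dam(s) not in pedigree: ",
                            paste(head(missDam, 5L), collapse = ", "))
  nRecords <- nrow(data)
  if (response == "bernoulli") {
    idx <- rep(seq_len(nrow(data)), times = data$nTotal)
    alive <- unlist(lapply(seq_len(nrow(data)), function(i)
      rep(c(1L, 0L), c(data$nAlive[i], data$nDead[i]))))
    data <- data[idx, , drop = FALSE]
    data$nAlive <- alive
    data$nDead <- 1L - alive
  }
  data$parityClass <- droplevels(data$parityClass)
  data$season <- droplevels(data$season)
  terms <- c(if (nlevels(data$parityClass) > 1L) "parityClass",
             if (nlevels(data$season) > 1L) "season",
             covariates)
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  X <- stats::model.matrix(as.formula(paste("~", rhs)), data = data)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design matrix is not full rank")
  ri <- relationshipInverse(ped, sort(unique(as.character(data$dam))))
  damIdx <- match(as.character(data$dam), ri$ids)
  eng <- glmmEngine(data$nAlive, data$nDead, X, damIdx, ri$Ainv, ri$logdetA)
  list(eng = eng, termNames = colnames(X), nRecords = nRecords)
}

#' Fit a binomial logit animal model for survival at birth
#'
#' Maximises the Laplace-approximated marginal likelihood of
#' `logit P(alive) = parity + season + covariates + a_dam`, where the
#' polygenic effect satisfies `a ~ N(0, sigma2a * A)` with A the additive
#' relationship matrix from the pedigree. The latent vector spans the dams
#' and their ancestors so that the precision matrix stays sparse
#' (Henderson's rules, see [relationshipInverse()]); for each candidate
#' variance the fixed effects and latent effects are profiled by a joint
#' penalised Newton step, and the variance itself by a one-dimensional
#' search on the log scale. The default response is the binomial count
#' (`nAlive` of `nTotal`) per kindling record; a per-kit Bernoulli
#' expansion gives identical inference up to an additive constant in the
#' likelihood.
#'
#' @param data model frame from [buildModelFrame()] (needs `dam`, `nAlive`,
#'   `nDead`, `parityClass`, `season` and any requested covariate columns).
#' @param ped a [Pedigree-class] containing every dam.
#' @param covariates character vector of z-covariate columns to include
#'   (e.g. `c("zFNEWL", "zFAKL")`); may be empty.
#' @param response `"binomial"` (default) or `"bernoulli"`.
#' @param sigmaA2 if non-`NULL`, the additive variance is fixed at this
#'   value (0 gives a plain logistic regression fitted through the same
#'   Newton machinery) and only the fixed effects are optimised.
#' @param approach label stored on the fit.
#' @return a [SurvivalModelFit-class]. `k` counts the fixed coefficients
#'   plus one variance parameter (when estimated); `n` is the number of
#'   kindling records.
#' @export
fitSurvivalGlmm <- function(data, ped, covariates = character(),
                            response = c("binomial", "bernoulli"),
                            sigmaA2 = NULL, approach = "custom") {
  response <- match.arg(response)
  stopifnot(is(ped, "Pedigree"))
  ctx <- glmmContext(data, ped, covariates, response)
  if (is.null(sigmaA2)) {
    fit <- laplaceML(ctx$eng)
    sigma2a <- fit$sigma2
    k <- ctx$eng$p + 1L
  } else if (sigmaA2 == 0) {
    fit <- irlsFixed(ctx$eng)
    sigma2a <- 0
    k <- ctx$eng$p
  } else {
    fit <- laplaceInner(ctx$eng, sigmaA2,
                        numeric(ctx$eng$p), numeric(ctx$eng$q))
    sigma2a <- sigmaA2
    k <- ctx$eng$p
  }
  cfs <- data.frame(term = renameTerms(ctx$termNames),
                    estimate = unname(fit$beta),
                    se = unname(sqrt(diag(fit$vcovBeta))),
                    stringsAsFactors = FALSE)
  n <- as.integer(ctx$nRecords)
  ll <- unname(fit$logLik)
  sigma2a <- unname(sigma2a)
  obj <- new("SurvivalModelFit", coefficients = cfs,
             sigma2a = sigma2a, logLik = ll,
             k = as.integer(k), n = n,
             aic = -2 * ll + 2 * k, aicc = unname(aicc(ll, k, n)),
             converged = fit$converged,
             inbreedingTerms = as.character(covariates),
             approach = approach)
  validObject(obj)
  obj
}

#' Laplace marginal log-likelihood at given parameter values
#'
#' Evaluates the Laplace-approximated marginal log-likelihood of the
#' survival animal model at user-supplied fixed effects and additive
#' variance (only the latent polygenic effects are maximised). Useful for
#' comparing the approximation against numerical integration on small
#' problems.
#'
#' @inheritParams fitSurvivalGlmm
#' @param beta fixed-effect vector, in the order of the model matrix
#'   (intercept, parity classes, season, then `covariates`).
#' @param sigmaA2 additive variance (> 0).
#' @return the Laplace log-likelihood (a scalar).
#' @export
survivalLaplaceLogLik <- function(data, ped, covariates = character(),
                                  beta, sigmaA2,
                                  response = c("binomial", "bernoulli")) {
  response <- match.arg(response)
  ctx <- glmmContext(data, ped, covariates, response)
  stopifnot(length(beta) == ctx$eng$p, sigmaA2 > 0)
  eng <- ctx$eng
  # maximise over the latent effects only: Newton on a at fixed beta
  a <- numeric(eng$q)
  etaFix <- drop(eng$X %*% beta)
  for (it in 1:100) {
    eta <- etaFix + a[eng$idx]
    mu <- plogis(eta)
    ga <- aggAt(eng$yA - eng$N * mu, eng$idx, eng$q) -
      as.numeric(eng$Ainv %*% a) / sigmaA2
    if (max(abs(ga)) < 1e-10) break
    Wd <- aggAt(eng$N * mu * (1 - mu), eng$idx, eng$q)
    Haa <- Matrix::Diagonal(x = Wd) + eng$Ainv / sigmaA2
    a <- a + drop(as.matrix(Matrix::solve(Haa, ga)))
  }
  eta <- etaFix + a[eng$idx]
  mu <- plogis(eta)
  Wd <- aggAt(eng$N * mu * (1 - mu), eng$idx, eng$q)
  Haa <- Matrix::Diagonal(x = Wd) + eng$Ainv / sigmaA2
  ldH <- as.numeric(Matrix::determinant(Haa, logarithm = TRUE)$modulus)
  binomLogLik(eng, eta) - sum(a * as.numeric(eng$Ainv %*% a)) / (2 * sigmaA2) -
    0.5 * (eng$logdetA + eng$q * log(sigmaA2) + ldH)
}

#' Fitted-model accessors
#'
#' @param object,x a [SurvivalModelFit-class].
#' @return `coef()` returns a named vector of fixed-effect estimates;
#'   `logLik()` the Laplace log-likelihood.
#' @export
setMethod("coef", "SurvivalModelFit", function(object)
  setNames(object@coefficients$estimate, object@coefficients$term))

setMethod("show", "SurvivalModelFit", function(object) {
  lbl <- if (length(object@inbreedingTerms))
    paste(object@inbreedingTerms, collapse = " + ") else "none"
  cat(sprintf(
    "SurvivalModelFit [%s | covariates: %s]\n  n = %d, k = %d, logLik = %.2f, AICc = %.2f, sigma2a = %.4f%s\n",
    object@approach, lbl, object@n, object@k, object@logLik, object@aicc,
    object@sigma2a, if (object@converged) "" else "  (NOT converged)"))
  print(object@coefficients, row.names = FALSE, digits = 3)
})
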