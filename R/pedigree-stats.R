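## Deterministic pedigree statistics: exact F, relationship matrix, complete
## generation equivalents, founder contributions, effective population size.

#' Exact inbreeding coefficients (Meuwissen–Luo)
#'
#' Classical inbreeding coefficient F — the probability that the two alleles
#' at a locus are identical by descent — computed deterministically by the
#' Meuwissen & Luo recursion (equivalent to the tabular method). Unknown
#' parents act as unique unrelated non-inbred founders.
#'
#' @param ped a [Pedigree-class].
#' @return named numeric vector of F in pedigree order; founders have 0.
#' @export
exactInbreeding <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  setNames(cpp_inbreeding(ped@sire, ped@dam), ped@id)
}

# indices (pedigree order) of `ids` plus all their ancestors
ancestorClosure <- function(ped, idx) {
  inset <- logical(length(ped@id))
  inset[idx] <- TRUE
  # walk from the highest index down; parents always have lower indices
  for (i in rev(seq_along(inset))) {
    if (!inset[i]) next
    if (ped@sire[i] > 0L) inset[ped@sire[i]] <- TRUE
    if (ped@dam[i] > 0L) inset[ped@dam[i]] <- TRUE
  }
  which(inset)
}

#' Additive (numerator) relationship matrix for a subset
#'
#' Computes A by the tabular method on the pedigree pruned to the subset's
#' ancestors, then returns the subset block. Diagonal entries equal
#' `1 + F`; the matrix is symmetric positive semi-definite.
#'
#' @param ped a [Pedigree-class].
#' @param ids individuals to return (default: all).
#' @return numeric matrix with `dimnames` equal to `ids` in the given order.
#' @export
relationshipMatrix <- function(ped, ids = pedIds(ped)) {
  stopifnot(is(ped, "Pedigree"))
  idx <- match(ids, ped@id)
  if (anyNA(idx)) stop("id(s) not in pedigree: ",
                       paste(head(ids[is.na(idx)], 5L), collapse = ", "))
  keep <- ancestorClosure(ped, idx)
  remap <- integer(length(ped@id))
  remap[keep] <- seq_along(keep)
  sire <- ifelse(ped@sire[keep] > 0L, remap[pmax(ped@sire[keep], 1L)], 0L)
  dam <- ifelse(ped@dam[keep] > 0L, remap[pmax(ped@dam[keep], 1L)], 0L)
  A <- cpp_tabular_a(as.integer(sire), as.integer(dam))
  sub <- remap[idx]
  out <- A[sub, sub, drop = FALSE]
  dimnames(out) <- list(ids, ids)
  out
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules with Meuwissen–Luo inbreeding adjustment:
#' `A^{-1} = (I - P)' D^{-1} (I - P)`, where P holds 0.5 at the parent
#' positions and `D_i` is the Mendelian-sampling variance
#' `0.5 - 0.25 (F_sire + F_dam)` (with `-1` substituted for the F of an
#' unknown parent). Computed on the pedigree pruned to the ancestors of
#' `ids`, where the inverse is sparse even though A itself is dense.
#'
#' @param ped a [Pedigree-class].
#' @param ids individuals whose ancestor closure defines the sub-pedigree
#'   (default: all).
#' @return list with `Ainv` (sparse symmetric `Matrix`), `logdetA`
#'   (`sum(log D)`, the log-determinant of the corresponding A), and `ids`
#'   (the closure, in pedigree order; rows of `Ainv` match it).
#' @export
relationshipInverse <- function(ped, ids = pedIds(ped)) {
  stopifnot(is(ped, "Pedigree"))
  idx <- match(ids, ped@id)
  if (anyNA(idx)) stop("id(s) not in pedigree: ",
                       paste(head(ids[is.na(idx)], 5L), collapse = ", "))
  keep <- ancestorClosure(ped, idx)
  q <- length(keep)
  remap <- integer(length(ped@id))
  remap[keep] <- seq_len(q)
  s <- ifelse(ped@sire[keep] > 0L, remap[pmax(ped@sire[keep], 1L)], 0L)
  d <- ifelse(ped@dam[keep] > 0L, remap[pmax(ped@dam[keep], 1L)], 0L)
  f <- cpp_inbreeding(as.integer(s), as.integer(d))
  fpad <- c(-1, f)  # F of the "unknown" parent is -1
  Dm <- 0.5 - 0.25 * (fpad[s + 1L] + fpad[d + 1L])
  alpha <- 1 / Dm
  i <- seq_len(q)
  ti <- c(i, s[s > 0L], i[s > 0L], s[s > 0L],
          d[d > 0L], i[d > 0L], d[d > 0L],
          s[s > 0L & d > 0L], d[s > 0L & d > 0L])
  tj <- c(i, i[s > 0L], s[s > 0L], s[s > 0L],
          i[d > 0L], d[d > 0L], d[d > 0L],
          d[s > 0L & d > 0L], s[s > 0L & d > 0L])
  tx <- c(alpha,
          rep(-alpha[s > 0L] / 2, 2L), alpha[s > 0L] / 4,
          rep(-alpha[d > 0L] / 2, 2L), alpha[d > 0L] / 4,
          rep(alpha[s > 0L & d > 0L] / 4, 2L))
  Ainv <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(q, q))
  list(Ainv = Ainv, logdetA = sum(log(Dm)), ids = ped@id[keep])
}

#' Complete generation equivalents
#'
#' Pedigree-completeness measure: the sum of (1/2)^n over all known
#' ancestors, counted once per distinct path, where n is the number of
#' generations separating the individual from the ancestor. A fully known
#' pedigree of depth g yields exactly g; founders yield 0.
#'
#' @param ped a [Pedigree-class].
#' @param ids individuals to return (default: all).
#' @return named numeric vector of CGE values.
#' @export
completeGenerationEquivalent <- function(ped, ids = pedIds(ped)) {
  stopifnot(is(ped, "Pedigree"))
  n <- length(ped@id)
  g <- numeric(n)
  for (i in seq_len(n)) {
    val <- 0
    if (ped@sire[i] > 0L) val <- val + 0.5 * (1 + g[ped@sire[i]])
    if (ped@dam[i] > 0L) val <- val + 0.5 * (1 + g[ped@dam[i]])
    g[i] <- val
  }
  idx <- match(ids, ped@id)
  if (anyNA(idx)) stop("id(s) not in pedigree: ",
                       paste(head(ids[is.na(idx)], 5L), collapse = ", "))
  setNames(g[idx], ids)
}

#' Effective population size from a printed or estimated inbreeding rate
#'
#' @param deltaF per-generation rate of inbreeding.
#' @param method label recorded on the estimate.
#' @param n number of individuals behind the estimate.
#' @return a [NeEstimate-class] with `Ne = round(1 / (2 * deltaF))`.
#' @export
neFromDeltaF <- function(deltaF, method = "direct", n = NA_integer_) {
  obj <- new("NeEstimate", deltaF = as.numeric(deltaF),
             Ne = round(1 / (2 * as.numeric(deltaF))),
             method = method, n = as.integer(n))
  validObject(obj)
  obj
}

#' Estimate the effective population size of a cohort
#'
#' Default method regresses `-log(1 - F)` on the equivalent generation
#' number `t = CGE + 1` of each individual; the slope b gives
#' `deltaF = 1 - exp(-b)`. The alternative averages individual rates
#' `deltaF_i = 1 - (1 - F_i)^(1 / (t_i - 1))` over non-founders. Either way
#' `Ne = round(1 / (2 * deltaF))`.
#'
#' @param ped a [Pedigree-class].
#' @param window optional `c(from, to)` dates (anything [parseDates()]
#'   accepts); individuals born inside it form the cohort.
#' @param ids optional explicit cohort (overrides `window`).
#' @param method `"regression_logF"` (default) or `"individual_deltaF"`.
#' @param includeDummies dummy progenies are excluded from demographic
#'   cohorts unless `TRUE`.
#' @return a [NeEstimate-class].
#' @export
estimateNe <- function(ped, window = NULL, ids = NULL,
                       method = c("regression_logF", "individual_deltaF"),
                       includeDummies = FALSE) {
  stopifnot(is(ped, "Pedigree"))
  method <- match.arg(method)
  if (is.null(ids)) {
    keep <- rep(TRUE, length(ped@id))
    if (!is.null(window)) {
      w <- parseDates(window)
      keep <- !is.na(ped@birthDate) &
        ped@birthDate >= w[1L] & ped@birthDate <= w[2L]
    }
    if (!includeDummies) keep <- keep & ped@sex != "dummy"
    ids <- ped@id[keep]
  }
  if (!length(ids)) stop("empty cohort for Ne estimation")
  f <- exactInbreeding(ped)[ids]
  t <- completeGenerationEquivalent(ped, ids) + 1
  if (method == "regression_logF") {
    if (length(unique(round(t, 10))) < 2L)
      stop("regression Ne needs >= 2 distinct equivalent-generation values")
    b <- unname(coef(lm(-log(1 - f) ~ t))["t"])
    deltaF <- 1 - exp(-b)
  } else {
    use <- t > 1
    if (!any(use)) stop("no individuals with equivalent generations > 1")
    deltaF <- mean(1 - (1 - f[use])^(1 / (t[use] - 1)))
  }
  if (deltaF <= 0)
    stop("estimated deltaF is not positive; cohort shows no inbreeding trend")
  neFromDeltaF(deltaF, method = method, n = length(ids))
}

#' Expected founder contributions to a cohort
#'
#' The genetic contribution of founder f to individual i is defined
#' recursively as the average of the parental contributions, with
#' contribution 1 to itself; contributions are averaged over the cohort. For
#' fully pedigreed cohorts they sum to 1. Founders with contribution > 0 are
#' the "contributing founders".
#'
#' @param ped a [Pedigree-class].
#' @param ids cohort (default: all non-dummy individuals).
#' @return named numeric vector over the founders that are ancestors of the
#'   cohort (cohort founders contribute to themselves).
#' @export
founderContributions <- function(ped, ids = NULL) {
  stopifnot(is(ped, "Pedigree"))
  if (is.null(ids)) ids <- ped@id[ped@sex != "dummy"]
  idx <- match(ids, ped@id)
  if (anyNA(idx)) stop("id(s) not in pedigree: ",
                       paste(head(ids[is.na(idx)], 5L), collapse = ", "))
  keep <- ancestorClosure(ped, idx)
  sire <- ped@sire[keep]
  dam <- ped@dam[keep]
  remap <- integer(length(ped@id))
  remap[keep] <- seq_along(keep)
  fidx <- which(sire == 0L & dam == 0L)
  C <- matrix(0, nrow = length(keep), ncol = length(fidx),
              dimnames = list(ped@id[keep], ped@id[keep][fidx]))
  C[cbind(fidx, seq_along(fidx))] <- 1
  isf <- logical(length(keep))
  isf[fidx] <- TRUE
  for (i in seq_along(keep)) {
    if (isf[i]) next
    v <- 0
    if (sire[i] > 0L) v <- v + 0.5 * C[remap[sire[i]], ]
    if (dam[i] > 0L) v <- v + 0.5 * C[remap[dam[i]], ]
    C[i, ] <- v
  }
  colMeans(C[remap[idx], , drop = FALSE])
}

#' @rdname NeEstimate-class
#' @param object a `NeEstimate`.
#' @export
setMethod("show", "NeEstimate", function(object) {
  cat(sprintf("Ne = %d (deltaF = %.5f, method = %s, n = %s)\n",
              object@Ne, object@deltaF, object@method,
              ifelse(is.na(object@n), "?", object@n)))
})
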