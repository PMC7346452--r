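## Monte-Carlo gene dropping and the exact enumeration oracle.
##
## Each replicate drops one unlinked locus: founders (and unknown-parent
## slots) receive unique allele labels, every non-founder inherits one
## uniformly random copy from each parent, and a transmitted copy is flagged
## once any ancestor genotype carrying it was autozygous. From the replicate
## indicators we estimate, per individual:
##   F    = P(autozygous)                                (classical)
##   Fak  = E[autozygous * fraction of flagged copies]   (Kalinowski "old")
##   Fnew = F - Fak                                      (Kalinowski "new")
##   Fab  = E[fraction of flagged copies]                (Ballou)
## The decomposition F = Fnew + Fak is exact because all quantities come
## from the same replicates; Fak <= Fab holds replicate by replicate.

buildCoefficientSet <- function(ped, raw, iterations, seed, method) {
  Fnew <- raw[, 1L]
  Fak <- raw[, 2L]
  Fab <- raw[, 3L]
  F <- Fnew + Fak
  se <- function(p) if (is.finite(iterations))
    sqrt(p * (1 - p) / iterations) else rep(0, length(p))
  cf <- data.frame(id = ped@id, F = F, Fnew = Fnew, Fak = Fak, Fab = Fab,
                   seF = se(F), seFnew = se(Fnew), seFak = se(Fak),
                   seFab = se(Fab), stringsAsFactors = FALSE)
  obj <- new("CoefficientSet", coefficients = cf,
             iterations = iterations, seed = seed, method = method)
  validObject(obj)
  obj
}

#' Estimate inbreeding coefficients by gene dropping
#'
#' Monte-Carlo estimation of the classical (F), Kalinowski new (Fnew) and
#' ancestral (Fak), and Ballou ancestral (Fab) inbreeding coefficients for
#' every individual of a pedigree, with binomial standard errors
#' `sqrt(p(1-p)/iterations)`. Identical `seed` and `iterations` give a
#' bit-identical result.
#'
#' @param ped a [Pedigree-class].
#' @param iterations number of replicates (default `1e6`).
#' @param seed RNG seed (default 20200708).
#' @return a [CoefficientSet-class].
#' @examples
#' ped <- Pedigree(c("A", "B", "X", "Y", "Z"),
#'                 sire = c(NA, NA, "A", "A", "X"),
#'                 dam = c(NA, NA, "B", "B", "Y"),
#'                 sex = c("male", "female", "male", "female", "unknown"))
#' cs <- geneDropCoefficients(ped, iterations = 1e4)
#' coefficientTable(cs)["Z", "F"]   # ~ 0.25 (full-sib offspring)
#' @export
geneDropCoefficients <- function(ped, iterations = 1e6, seed = 20200708) {
  stopifnot(is(ped, "Pedigree"), iterations >= 1)
  set.seed(seed)
  raw <- cpp_gene_drop(ped@sire, ped@dam, as.integer(iterations))
  buildCoefficientSet(ped, raw, iterations = as.numeric(iterations),
                      seed = as.numeric(seed), method = "gene_drop")
}

#' Exact inbreeding coefficients by enumeration (small pedigrees)
#'
#' Enumerates all `4^m` Mendelian transmission outcomes (m = individuals
#' with a known parent) with equal weight, applying the same flag semantics
#' as the stochastic gene drop. Intended as an exact oracle for small
#' pedigrees; refuses when m exceeds `maxNonFounders`.
#'
#' @param ped a [Pedigree-class].
#' @param maxNonFounders enumeration cap (default 10, i.e. at most `4^10`
#'   outcomes).
#' @return a [CoefficientSet-class] with zero standard errors.
#' @export
exactCoefficients <- function(ped, maxNonFounders = 10) {
  stopifnot(is(ped, "Pedigree"))
  raw <- cpp_enumerate(ped@sire, ped@dam, as.integer(maxNonFounders))
  buildCoefficientSet(ped, raw, iterations = Inf, seed = NA_real_,
                      method = "exact_enumeration")
}

#' One gene-dropping replicate with its transmission record
#'
#' Drops a single unlinked locus through the pedigree and returns the full
#' per-individual genotype: the founder-allele labels of the two copies,
#' their ancestral-autozygosity flags, and which parental copy was picked on
#' each side (0 = first copy, 1 = second), so a replicate can be replayed.
#'
#' @param ped a [Pedigree-class].
#' @return data.frame with columns `id`, `allele1`, `allele2`, `flag1`,
#'   `flag2`, `autozygous`, `pickSire`, `pickDam`.
#' @export
dropOnce <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  r <- cpp_gene_drop_once(ped@sire, ped@dam)
  data.frame(id = ped@id, allele1 = r$allele1, allele2 = r$allele2,
             flag1 = r$flag1, flag2 = r$flag2,
             autozygous = r$allele1 == r$allele2,
             pickSire = r$pickSire, pickDam = r$pickDam,
             stringsAsFactors = FALSE)
}

#' @rdname CoefficientSet-class
#' @param x a `CoefficientSet`.
#' @return `coefficientTable()` returns the coefficient data.frame with row
#'   names set to the individual ids.
#' @export
setMethod("coefficientTable", "CoefficientSet", function(x) {
  cf <- x@coefficients
  rownames(cf) <- cf$id
  cf
})

setMethod("show", "CoefficientSet", function(object) {
  cf <- object@coefficients
  cat(sprintf("CoefficientSet for %d individuals (%s%s)\n", nrow(cf),
              object@method,
              if (is.finite(object@iterations))
                sprintf(", %g iterations, seed %g",
                        object@iterations, object@seed) else ""))
  cat(sprintf("  mean F = %.4f, Fnew = %.4f, Fak = %.4f, Fab = %.4f\n",
              mean(cf$F), mean(cf$Fnew), mean(cf$Fak), mean(cf$Fab)))
})

#' Write a coefficient table to CSV
#'
#' @param x a [CoefficientSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCoefficients <- function(x, path) {
  stopifnot(is(x, "CoefficientSet"))
  write.csv(x@coefficients, path, row.names = FALSE)
  invisible(path)
}
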