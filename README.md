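# pedpurge

Pedigree-based quantification of inbreeding depression and its purging for
a binomial survival trait in closed, fully pedigreed populations — the
setting of long-term selected rabbit lines, where the trait is the
survival of kits at birth and the analysis unit is the kindling (one
litter of one doe).

## Who this is for

Animal breeders and population geneticists who have a deep pedigree and
per-litter counts of offspring born and born alive, and who want to ask:
is inbreeding depressing survival, and is there evidence that the
deleterious load is being purged?

## What it computes

**Inbreeding coefficients by gene dropping.** Uniquely labelled founder
alleles are dropped through the pedigree (default 10⁶ replicates); per
individual the package estimates the classical inbreeding coefficient
*F*, Kalinowski's decomposition *F* = *F*<sub>NEW</sub> + *F*<sub>A-K</sub>
(autozygosity occurring for the first time vs. autozygosity at loci that
were already autozygous in an ancestor), and Ballou's ancestral
coefficient *F*<sub>A-B</sub> (probability a random allele has been in an
autozygous genotype in some ancestor). The decomposition holds exactly,
not within tolerance, and an exact enumeration oracle covers small
pedigrees. Litters get their own coefficients through one dummy progeny
per distinct (dam, sire) mating pair.

**Pedigree demography.** Complete generation equivalents (Σ(1/2)ⁿ over
known ancestors, per path), founder contributions and their attrition over
birth-year cohorts, and effective population size
*N*<sub>e</sub> = 1 / (2Δ*F*), with Δ*F* from the regression of
−ln(1 − *F*) on equivalent generations (or from mean individual rates).

**Survival animal model.** For each kindling,
`logit P(alive) = parity class + season + z-standardised inbreeding
covariates + a_dam`, with *a* ~ N(0, σ²ₐ·**A**) over the pedigree
relationship matrix. The fitter maximises the Laplace-approximated
marginal likelihood on a sparse Henderson system (the A-inverse over the
dams' ancestor closure), finished by quasi-Newton on the exact Laplace
objective.

**Multi-model inference.** Per period and per covariate family
(Ballou–Boakes: z.F_D, z.F_L, z.F_A-BL; Kalinowski: z.F_NEWD, z.F_NEWL,
z.F_A-KL) all 2³ candidate models are fitted; models within 2 AICc of the
best are retained, and coefficients are combined by natural-average model
averaging with Akaike weights, unconditional 95% intervals and relative
importance. A negative z.F_NEWL alongside a positive z.F_A-KL is the
purging signature.

**Synthetic data.** `simulateStudy()` generates a closed population with
overlapping generations, truncation selection on a neutral index, and
binomial survival driven by a known logit model — so the entire pipeline
is testable without access to any proprietary data set.

## Worked example

```r
library(pedpurge)

sim <- simulateStudy(simConfig(years = 10, seed = 7))
sim$pedigree
#> Pedigree with 1243 individuals ( 80 founders, 1063 dummy progenies )
#>   birth dates: 1992-01-04 to 2002-12-29

fit <- fitSurvivalGlmm(sim$kindlings, sim$pedigree,
                       covariates = c("zFNEWL", "zFAKL"),
                       approach = "kalinowski")
fit
#> SurvivalModelFit [kalinowski | covariates: zFNEWL + zFAKL]
#>   n = 1536, k = 8, logLik = -1129.84, AICc = 2275.78, sigma2a = 0.2992
#>       term estimate     se
#>  intercept    3.126 0.1590
#>    parityA    0.343 0.1981
#>    parityB    0.324 0.1405
#>    parityC    0.452 0.1759
#>     season   -0.237 0.0981
#>     zFNEWL   -0.491 0.0520
#>      zFAKL    0.379 0.0810

sel <- selectModels(enumerateCandidates(sim$kindlings, sim$pedigree,
                                        "kalinowski"))
print(averagedTable(sel), digits = 2)
#>        term estimate    se  lower  upper   RI nModels significant
#> 1 intercept    3.124 0.160  2.810  3.437 1.00       2        TRUE
#> 2   parityA    0.343 0.198 -0.046  0.731 1.00       2       FALSE
#> 3   parityB    0.324 0.140  0.049  0.599 1.00       2        TRUE
#> 4   parityC    0.451 0.176  0.107  0.796 1.00       2        TRUE
#> 5    season   -0.237 0.098 -0.429 -0.045 1.00       2        TRUE
#> 6    zFNEWL   -0.491 0.052 -0.593 -0.389 1.00       2        TRUE
#> 7     zFAKL    0.380 0.083  0.219  0.542 1.00       2        TRUE
#> 8    zFNEWD   -0.019 0.095 -0.206  0.168 0.27       1       FALSE

estimateNe(sim$pedigree)
#> Ne = 11 (deltaF = 0.04486, method = regression_logF, n = 180)
```

Reading the table: the baseline (first-parity, non-summer) survival is
`plogis(3.12) ≈ 96%`. Summer kindlings survive less (−0.24 on the logit
scale, interval excluding zero); one standard deviation of *new* litter
inbreeding costs −0.49, while one standard deviation of Kalinowski
ancestral inbreeding *adds* +0.38 — the purging pattern this generator
was configured to produce (true values −0.4 and +0.3; the per-period
standardisation makes the recovered scale approximate). The polygenic
variance 0.299 recovers its true value 0.3. Relative importance 1.00 means
a term appears in every model that survived the ΔAICc ≤ 2 cut; z.F_NEWD,
present in one of the two retained models, carries that model's weight
(0.27). This simulated population is a small nucleus, hence the small
effective size (Ne = 11).

`runStudy()` wraps the whole sequence — dummy progenies, gene dropping,
per-period standardisation, both covariate families, selection, averaging,
descriptive and correlation reports — and writes CSV tables plus a run
manifest when given an output directory.

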