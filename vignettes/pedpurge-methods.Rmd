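---
title: "Pedigree-based inbreeding depression and purging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based inbreeding depression and purging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedpurge)
```

## The scientific problem

In a closed breeding population, inbreeding is unavoidable: every
individual eventually descends from the same finite set of founders.
Inbreeding depression (ID) is the resulting decline in fitness-related
traits — here, the survival of rabbit kits at birth — caused by deleterious
recessive alleles being exposed in homozygous (autozygous) state. Purging
is the counteracting force: once exposed, those alleles are visible to
selection and can be removed, so that *ancestral* inbreeding (having had
inbred ancestors) may carry a survival benefit even while *new* inbreeding
is harmful.

pedpurge quantifies both forces from two plain-text inputs — a pedigree and
a table of kindling (litter) records — by combining:

1. **gene-dropping estimation** of four inbreeding coefficients per
   individual,
2. **pedigree demography** (complete generation equivalents, founder
   contributions, effective population size),
3. **binomial logit animal models** for kit survival with a pedigree-
   structured polygenic effect, and
4. **AICc-based multi-model inference** with natural-average model
   averaging, run separately for consecutive time periods.

Because the motivating data sets of this kind are rarely deposited, the
package ships a first-class synthetic-data generator that emulates the
relevant population structure with a *known* response model, so the whole
pipeline is testable end to end.

## Inbreeding coefficients by gene dropping

For every replicate, each founder receives two uniquely labelled alleles
and every non-founder inherits one uniformly random copy from each parent
(one unlinked locus per replicate). An individual is *autozygous* when its
two copies carry the same founder label. A transmitted copy is *flagged*
when the parent copy was already flagged or the parent genotype itself was
autozygous at this locus; flags are therefore set on transmission and are
monotone down the pedigree. From `iterations` replicates we estimate, per
individual:

* `F` — P(autozygous), the classical inbreeding coefficient;
* `Fak` — Kalinowski's ancestral coefficient: the probability of being
  autozygous *at a locus that was autozygous in some ancestor*, estimated
  as E[autozygous × fraction of flagged copies];
* `Fnew` — Kalinowski's new coefficient, `F - Fak`, autozygosity occurring
  for the first time;
* `Fab` — Ballou's ancestral coefficient: E[fraction of flagged copies],
  regardless of current autozygosity.

Two estimator details matter. First, when an individual is autozygous but
its two copies disagree in their flags (possible, because flags attach to
copies), the replicate is counted with weight equal to the fraction of
flagged copies; this keeps the decomposition `F = Fnew + Fak` an exact
identity on the same replicates, not an approximation. Second, the "new"
and "ancestral" counts are accumulated directly (both are multiples of 0.5
per replicate, hence exactly representable), so the identity holds to the
last bit, and `Fak <= Fab` holds replicate by replicate. Standard errors
are binomial, `sqrt(p(1-p)/iterations)`.

The default is `1e6` iterations, which puts Monte-Carlo standard errors
near 5e-4; an exact enumeration oracle (`exactCoefficients()`) computes all
four coefficients by summing over all `4^m` transmission outcomes for
pedigrees with at most `m = 10` individuals having known parents, and backs
the stochastic engine in the test suite. The classical `F` has a second,
independent check: the deterministic Meuwissen–Luo recursion
(`exactInbreeding()`).

Unknown parents everywhere in the package follow the tabular-method
convention: they act as unique, unrelated, non-inbred founders.

## Pedigree demography

*Complete generation equivalents* (CGE) measure pedigree completeness as
the sum of `(1/2)^n` over known ancestors, counted once per distinct
descent path (so a fully known pedigree of depth `g` scores exactly `g`).
Per-path counting is the convention of the established pedigree software in
this field; the alternative reading ("each distinct ancestor once") would
not reach `g` in complete pedigrees with inbreeding loops.

*Founder contributions* are propagated down the pedigree as the average of
the parental contributions and averaged over a cohort; the number of
founders with positive contribution per birth-year cohort gives the
founder-attrition trend that accompanies purging episodes.

*Effective population size* uses `Ne = round(1 / (2 * deltaF))`. Two
estimators of the per-generation rate `deltaF` are exposed, because the
source methodology names the approach but not the formula:

* `regression_logF` (default): regress `-log(1 - F)` on the equivalent
  generation number `t = CGE + 1`; the slope `b` gives
  `deltaF = 1 - exp(-b)`;
* `individual_deltaF`: average of `1 - (1 - F_i)^(1/(t_i - 1))` over
  non-founders.

Either way the reported Ne is rounded to the nearest integer, matching how
such values are printed. Dummy litter progenies are excluded from
demographic cohorts: they exist only to carry litter-level coefficients.

## The survival model

The analysis unit is the kindling record: a dam, a sire, a date, a parity,
and counts of kits born and born alive. One dummy progeny per distinct
(dam, sire) pair is appended to the pedigree so that each litter has
well-defined coefficients; repeated kindlings of the same pair share the
dummy.

The model for `nAlive` of `nTotal` kits is binomial with logit link:

```
logit P(alive) = parity class + season + z-standardised inbreeding
                 covariates + a_dam,        a ~ N(0, sigma2a * A)
```

* **Parity** is categorised 1 / 2 / 3–10 / 11+ (first parity is the
  reference; the three contrasts are reported as parity A, B, C).
* **Season** is summer (15 June – 15 September, both ends inclusive)
  versus non-summer; the reported coefficient is the summer effect.
* **Inbreeding covariates** come in two families that are never mixed:
  the Ballou–Boakes family (`z.F_D`, `z.F_L`, `z.F_ABL`) and the
  Kalinowski family (`z.F_NEWD`, `z.F_NEWL`, `z.F_AKL`), each
  z-standardised within the analysis period (mean 0, sample-SD scale by
  default; the 2-SD rescaling popularised for comparing binary and
  continuous inputs is available as `gelman_2sd`). The interaction between
  classical and ancestral inbreeding is deliberately not modelled, and
  neither is kindling year, which is collinear with the inbreeding
  trend in a closed population.
* **The polygenic effect** attaches to the dam of each record: dams are
  the repeated, pedigreed unit, whereas each dummy litter appears exactly
  once, which would make a litter-level genetic effect inseparable from
  the residual.

### Fitting: sparse Henderson system + Laplace likelihood

The latent vector spans the dams *and all their ancestors*. On that space
the precision matrix `A^{-1}` is sparse by Henderson's rules (with the
Meuwissen–Luo inbreeding adjustment of the Mendelian-sampling variances),
while the restriction of `A` to the dams alone would be dense. Because
every record maps to exactly one dam, the joint Newton system over the
fixed and latent effects stays sparse, and marginalising the ancestor
coordinates is Gaussian-exact, so the Laplace approximation on the
augmented space equals the one on the dam subset.

Maximum likelihood proceeds in two stages:

1. a fast profile over `log(sigma2a)` in which the fixed and latent
   effects are maximised jointly (penalised Newton with step halving) —
   cheap and close to the optimum, but not exactly ML because the
   log-determinant's dependence on the fixed effects is ignored;
2. a quasi-Newton (BFGS) polish of the exact Laplace objective over
   `(beta, log sigma2a)`, with the latent mode recomputed at every
   evaluation, an analytic gradient for the fixed effects (envelope
   theorem plus the log-determinant chain rule; verified against central
   differences to ~1e-7) and a central difference for the variance.

Stage 2 guarantees the properties one expects of a true ML fit — notably
that adding a covariate never decreases the maximised log-likelihood —
which a profiled-only scheme does not. At `sigma2a = 0` the same machinery
reduces to IRLS and reproduces `glm()` to ~1e-9; on a single shared random
intercept the Laplace log-likelihood is within ~2e-3 of adaptive
quadrature; on unrelated dams the fit agrees with `lme4::glmer`
(Laplace, `nAGQ = 1`) to three decimals in coefficients and ~1e-3 in
log-likelihood. These three independent oracles are exercised in the test
suite.

Numerical safeguards: the Newton solves use a ridge-escalation fallback,
because near the large-variance limit with few records per dam the dam
effects can absorb the fixed effects and the Schur complement becomes
singular (the optimum itself is regular whenever the model is
identifiable); candidates that still fail are returned as non-converged
and excluded from selection with a logged warning rather than aborting the
study. Covariates with zero variance within a period (e.g. no ancestral
inbreeding yet in a young pedigree) yield an all-zero z-column, so any
candidate containing them is dropped as rank-deficient.

The likelihood includes the binomial normalising constant, so the optional
per-kit Bernoulli expansion shifts the log-likelihood by exactly
`sum(log choose(n, y))` and leaves the inference unchanged.

## Multi-model inference

For each period and family, all `2^3 = 8` subsets of the three inbreeding
covariates are fitted (parity, season and the animal effect are always
included). Model support uses AICc,

```
AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1),
```

with `k` counting the fixed coefficients plus one variance component and
`n` the number of kindling records; the convention for `k` is constant
across candidates, so it cannot affect their ranking. Models within 2 AICc
units of the best are retained and their Akaike weights
(`w ∝ exp(-deltaAICc/2)`) renormalised.

Averaging follows the *natural average* method: a coefficient is averaged
only over the retained models that contain it, with weights renormalised
among those models; the unconditional standard error is the
Burnham–Anderson combination `sum(w * sqrt(se^2 + (b - bbar)^2))` and the
95% interval uses the conventional 1.96 multiplier. Relative importance
(RI) is the summed weight, over the full retained set, of the models
containing the term — so a term present in every retained model has RI = 1
and a term present in a single model of weight `w` has RI = `w`. The
intervals are unconditional (averaged); the single best model remains
available through the selection table for a conditional reading.

## The synthetic-data generator

`simulatePedigree()` builds a closed population: founders in year zero,
then yearly cohorts in which each breeding doe produces its kindlings with
a buck chosen by the mating scheme (`random`, `circular`, or `within_line`
for accelerated inbreeding), and a fixed number of replacement does and
bucks recruited from the year's litters. Recruitment can truncate on a
neutral heritable index, which concentrates ancestry and produces the
declining founder-contribution trend typical of selected populations. No
immigration ever occurs. Generations overlap because breeders stay for
about `1/replacementFraction` years.

`simulateKindlings()` draws `nAlive ~ Binomial(nTotal, p)` with
`logit(p) = X beta + a_dam`, where `a` is drawn from `N(0, sigma2a * A)`
using the true pedigree, and the covariates are the package's own
gene-dropped coefficients standardised exactly as the analysis pipeline
standardises them — so the configured `beta` live on the reported scale.

Default scenario (`simConfig()`): 80 founders, 25 years, 8 replacement
does and 2 bucks per year (breeders stay ~3 years), 4 kindlings per doe
and year, litter size `1 + Poisson(8)` — roughly one tenth of a national
breeding programme (~2,400 kindlings, ~3,000 pedigree entries including
litter dummies), chosen so a full study runs in minutes. Litter size is a
nuisance input here, not a modelled trait. The default true response
encodes an early-phase population with inbreeding depression and purging:
intercept 3.2 (≈96% baseline survival), summer effect −0.25, parity
contrasts +0.19/+0.31/+0.37, `z.F_NEWL` −0.4, `z.F_AKL` +0.3, and
polygenic variance 0.3 on the logit scale. The truth table uses `1e4`
gene-dropping replicates (coefficient SEs ≈ 5e-3), which is ample for
generating data; the analysis default remains `1e6`.

The validation harness (used by the acceptance tests and
`scripts/acceptance.R`) scales the same scenario to a single 6-year period
with ~5,000 litters (140 founders, 50 replacement does and 10 bucks per
year, 5 kindlings per doe-year) and checks that the Kalinowski-family
averaged estimates recover the signs of both inbreeding effects and that
the season interval covers its true value at the nominal rate.

What the generator does *not* emulate: explicit deleterious loci (the
logit model with inbreeding covariates *is* the data-generating truth, so
the harness validates estimation, not the biological model itself),
maternal-environment or dominance variance, seasonal management changes,
and missing or erroneous pedigree links. Passing tests therefore
demonstrate that the estimation machinery recovers known effects under the
model's own assumptions — they cannot certify those assumptions for any
real population.

## Numerical and design choices

* Pedigrees are stored in a deterministic topological order (ancestral
  depth, then identifier), so the same rows give the same object whatever
  their input order; cycles are reported with the name of an individual
  involved.
* Dates parse as ISO-8601; month-precision values take day 15, because
  period boundaries are month-level (periods are inclusive of the named
  months on both ends).
* The gene-drop RNG is R's own generator under a documented seed (default
  20200708), making every `CoefficientSet` bit-reproducible; tests use
  1e4–1e5 iterations for speed.
* The inner Newton tolerance is 1e-8 on the gradient norm; the outer
  variance search runs on the log scale in `[1e-6, 25]`, and a boundary
  solution at the lower end is an effectively zero variance.
* `Ne` uses the regression estimator by default because the cited
  methodology does not print its formula; both estimators are exposed and
  the analytic identity `Ne = round(1/(2 deltaF))` is what the published
  Ne/deltaF pairs pin down.
* Standardisation uses the sample SD (n−1). A worked two-point example:
  `c(0, 2)` has mean 1 and sample SD `sqrt(2)`, giving `z = ±0.707` (and
  `±0.354` under `gelman_2sd`).

## Known limitations

* Single-locus gene dropping: no linkage, no chromosomes, no ROH-based or
  genomic inbreeding.
* One variance component (additive, dam-attached); no dominance or
  maternal-environment effects, and no interaction between classical and
  ancestral inbreeding.
* The Laplace approximation is least accurate for tiny groups with
  extreme survival probabilities; the quadrature cross-check bounds the
  error only for the structures tested.
* Periods with very few records per dam can render the variance
  unidentifiable; such candidates are excluded as non-converged, and a
  period in which *no* candidate converges aborts the study with a
  stage-named error.
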