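test_that("season encoding is inclusive of both boundary days", {
  expect_equal(as.character(encodeSeason("1997-07-20")), "summer")
  expect_equal(as.character(encodeSeason("1997-06-14")), "non_summer")
  expect_equal(as.character(encodeSeason("1997-06-15")), "summer")
  expect_equal(as.character(encodeSeason("1997-09-15")), "summer")
  expect_equal(as.character(encodeSeason("1997-09-16")), "non_summer")
  expect_equal(as.character(encodeSeason("1997-12-31")), "non_summer")
})

test_that("parity classes follow 1 / 2 / 3-10 / 11+", {
  expect_equal(as.character(encodeParity(c(1, 2, 3, 7, 10, 11, 15))),
               c("P1", "P2", "P3_10", "P3_10", "P3_10", "P11plus", "P11plus"))
  expect_equal(levels(encodeParity(1)), c("P1", "P2", "P3_10", "P11plus"))
  expect_error(encodeParity(0), "parity")
})

test_that("standardisation uses the sample SD (or twice it)", {
  z1 <- standardise(c(0, 2), "z_1sd")
  expect_equal(z1$z, c(-1, 1) / sqrt(2))
  expect_equal(z1$center, 1)
  expect_equal(z1$scale, sqrt(2))
  z2 <- standardise(c(0, 2), "gelman_2sd")
  expect_equal(z2$z, c(-0.5, 0.5) / sqrt(2))
  expect_error(standardise(rep(3, 10)), "constant")
  x <- rnorm(50)
  z <- standardise(x)$z
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
})

test_that("zero additive variance reproduces plain logistic regression", {
  h <- unrelatedDamRecords(40, 6, seed = 3)
  fit0 <- fitSurvivalGlmm(h$records, h$ped, sigmaA2 = 0)
  g <- glm(cbind(nAlive, nDead) ~ parityClass + season, family = binomial(),
           data = h$records)
  expect_lt(max(abs(coef(fit0) - coef(g))), 1e-6)
  expect_equal(fit0@logLik, as.numeric(logLik(g)), tolerance = 1e-8)
  expect_equal(unname(fit0@coefficients$se),
               unname(summary(g)$coefficients[, 2]), tolerance = 1e-5)
})

test_that("Laplace log-likelihood matches adaptive quadrature on one effect", {
  set.seed(9)
  ped <- Pedigree("D", NA, NA, sex = "female")
  n <- 30
  dat <- data.frame(dam = "D", nTotal = 8L,
                    kindlingDate = as.Date("1995-03-01") +
                      round(seq(0, 330, length.out = n)),
                    parity = rep(1:3, each = 10))
  dat$nAlive <- rbinom(n, dat$nTotal, plogis(1.9))
  dat$season <- encodeSeason(dat$kindlingDate)
  dat$parityClass <- droplevels(encodeParity(dat$parity))
  dat$nDead <- dat$nTotal - dat$nAlive
  beta <- c(1.6, 0.1, 0.2, -0.2)
  s2 <- 0.3
  lap <- survivalLaplaceLogLik(dat, ped, beta = beta, sigmaA2 = s2)
  X <- model.matrix(~ parityClass + season, dat)
  etaF <- drop(X %*% beta)
  integrand <- function(u) vapply(u, function(v)
    exp(sum(dbinom(dat$nAlive, dat$nTotal, plogis(etaF + v), log = TRUE)) +
          dnorm(v, 0, sqrt(s2), log = TRUE)), 0)
  oracle <- log(integrate(integrand, -5, 5, rel.tol = 1e-12)$value)
  expect_lt(abs(lap - oracle), 0.05)
})

test_that("the animal-model fit agrees with glmer on unrelated dams", {
  skip_if_not_installed("lme4")
  h <- unrelatedDamRecords(60, 5, seed = 7)
  fit <- fitSurvivalGlmm(h$records, h$ped)
  g <- lme4::glmer(cbind(nAlive, nDead) ~ parityClass + season + (1 | dam),
                   data = h$records, family = binomial())
  expect_equal(unname(coef(fit)), unname(lme4::fixef(g)), tolerance = 1e-3)
  expect_equal(fit@sigma2a,
               unname(lme4::VarCorr(g)$dam[1, 1]), tolerance = 1e-2)
  expect_equal(fit@logLik, as.numeric(logLik(g)), tolerance = 1e-3)
})

test_that("estimated variance responds to the pedigree structure", {
  sim <- smallStudy()
  fit <- fitSurvivalGlmm(sim$kindlings, sim$pedigree,
                         covariates = c("zFNEWL", "zFAKL"))
  expect_true(fit@converged)
  expect_gt(fit@sigma2a, 0.05)   # truth is 0.3
  expect_lt(fit@sigma2a, 1.5)
  # fitted survival probabilities are proper probabilities
  expect_true(all(plogis(range(coef(fit)["intercept"])) > 0 &
                    plogis(range(coef(fit)["intercept"])) < 1))
})

test_that("adding a covariate never decreases the Laplace log-likelihood", {
  sim <- smallStudy()
  mf <- sim$kindlings
  ll <- function(covs) fitSurvivalGlmm(mf, sim$pedigree,
                                       covariates = covs)@logLik
  l0 <- ll(character())
  l1 <- ll("zFNEWL")
  l2 <- ll(c("zFNEWL", "zFAKL"))
  expect_gte(l1, l0 - 1e-6)
  expect_gte(l2, l1 - 1e-6)
})

test_that("intercept-only fit reproduces the overall survival proportion", {
  h <- unrelatedDamRecords(30, 4, seed = 15)
  rec <- h$records
  rec$parity <- 1L
  rec$parityClass <- droplevels(encodeParity(rec$parity))
  rec$kindlingDate <- as.Date("1995-02-01")   # all non-summer
  rec$season <- droplevels(encodeSeason(rec$kindlingDate))
  fit <- fitSurvivalGlmm(rec, h$ped, sigmaA2 = 0)
  expect_equal(plogis(unname(coef(fit)["intercept"])),
               sum(rec$nAlive) / sum(rec$nTotal), tolerance = 1e-8)
})

test_that("the Bernoulli expansion shifts the likelihood by a constant", {
  h <- unrelatedDamRecords(25, 4, seed = 19)
  fb <- fitSurvivalGlmm(h$records, h$ped, sigmaA2 = 0.2)
  fe <- fitSurvivalGlmm(h$records, h$ped, sigmaA2 = 0.2,
                        response = "bernoulli")
  const <- sum(lchoose(h$records$nTotal, h$records$nAlive))
  expect_equal(fb@logLik - fe@logLik, const, tolerance = 1e-4)
  expect_equal(coef(fb), coef(fe), tolerance = 1e-5)
  expect_equal(fb@n, fe@n)   # n stays the number of kindling records
})

test_that("AICc follows the small-sample correction", {
  expect_equal(aicc(-7, 3, 10), 24)
  expect_equal(-2 * -7 + 2 * 3, 20)            # plain AIC of the same fit
  expect_lt(aicc(-7, 3, 1e9) - 20, 1e-6)
  expect_error(aicc(-7, 3, 4), "n > k")
  sim <- smallStudy()
  fit <- fitSurvivalGlmm(sim$kindlings, sim$pedigree)
  expect_gt(fit@aicc, fit@aic)
})

test_that("missing dams and rank-deficient designs are rejected", {
  h <- unrelatedDamRecords(10, 3, seed = 23)
  bad <- h$records
  bad$dam[1] <- "ghost"
  expect_error(fitSurvivalGlmm(bad, h$ped), "not in pedigree")
  dup <- h$records
  dup$zdup <- as.numeric(dup$season == "summer")
  expect_error(fitSurvivalGlmm(dup, h$ped, covariates = "zdup"),
               "full rank")
})
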