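## Laplace-approximation engine for the binomial logit animal model.
##
## Latent parametrisation: the polygenic vector a spans the dams and all
## their ancestors (the pruned pedigree), a ~ N(0, sigma2 * A).  Only dams
## enter the linear predictor, so the record-to-effect design is an
## indicator and A^{-1} is sparse by Henderson's rules; the joint Newton
## system over (beta, a) stays sparse, unlike the dense Cholesky-transform
## formulation on the dam subset.
##
## For a given sigma2, (beta, a) are profiled by maximising the penalised
## log-likelihood jointly (Newton with step halving); the Laplace marginal
## log-likelihood is
##   ll(eta) - a' A^{-1} a / (2 sigma2)
##          - 0.5 * [logdet A + q log sigma2 + logdet(W_d + A^{-1}/sigma2)]
## (the last bracket is logdet(sigma2 * A * W_d + I)).  The outer profile
## over log(sigma2) is a 1-D golden-section/parabolic search.

# scatter per-record values into the q-length effect vector
aggAt <- function(x, idx, q) {
  t <- rowsum(x, idx)
  if (is.matrix(x)) {
    out <- matrix(0, q, ncol(x))
    out[as.integer(rownames(t)), ] <- t
  } else {
    out <- numeric(q)
    out[as.integer(rownames(t))] <- t
  }
  out
}

# linear solve with ridge escalation: near the large-variance limit the
# dam effects can absorb the fixed effects entirely and the Schur
# complement becomes numerically singular; a tiny ridge keeps the Newton
# iteration moving through that region (the optimum itself is regular)
safeSolve <- function(S, b) {
  ridge <- 0
  for (k in 0:8) {
    out <- tryCatch(solve(S + diag(ridge, nrow(S)), b),
                    error = function(e) NULL)
    if (!is.null(out) && all(is.finite(out))) return(out)
    ridge <- if (ridge == 0) 1e-8 * max(abs(diag(S)), 1) else ridge * 100
  }
  stop("fixed-effect system is singular beyond repair")
}

# one per-fit context: response, design, pedigree precision structure
glmmEngine <- function(yAlive, yDead, X, damIdx, Ainv, logdetA) {
  list(yA = yAlive, yD = yDead, N = yAlive + yDead, X = X,
       idx = damIdx, q = nrow(Ainv), p = ncol(X),
       Ainv = Ainv, logdetA = logdetA)
}

binomLogLik <- function(eng, eta) {
  # binomial log-likelihood including the constant choose(N, y) term
  sum(lchoose(eng$N, eng$yA) + eng$yA * eta - eng$N * log1p(exp(eta)))
}

# joint Newton over (beta, a) for fixed sigma2 > 0; warm-startable
laplaceInner <- function(eng, sigma2, beta, a, tol = 1e-8, maxit = 60L) {
  X <- eng$X
  q <- eng$q
  penll <- function(beta, a) {
    eta <- drop(X %*% beta) + a[eng$idx]
    binomLogLik(eng, eta) -
      sum(a * as.numeric(eng$Ainv %*% a)) / (2 * sigma2)
  }
  obj <- penll(beta, a)
  conv <- FALSE
  S <- NULL
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + a[eng$idx]
    mu <- plogis(eta)
    w <- eng$N * mu * (1 - mu)
    res <- eng$yA - eng$N * mu
    gb <- drop(crossprod(X, res))
    ga <- aggAt(res, eng$idx, q) - as.numeric(eng$Ainv %*% a) / sigma2
    if (max(abs(c(gb, ga))) < tol) { conv <- TRUE; break }
    Wd <- aggAt(w, eng$idx, q)
    Haa <- Matrix::Diagonal(x = Wd) + eng$Ainv / sigma2
    Ch <- Matrix::Cholesky(Matrix::forceSymmetric(Haa), LDL = FALSE)
    B <- aggAt(X * w, eng$idx, q)                       # q x p
    HiB <- as.matrix(Matrix::solve(Ch, B))
    Higa <- drop(as.matrix(Matrix::solve(Ch, ga)))
    S <- crossprod(X, X * w) - crossprod(B, HiB)        # Schur complement
    db <- safeSolve(S, gb - drop(crossprod(B, Higa)))
    da <- Higa - drop(HiB %*% db)
    step <- 1
    repeat {
      newObj <- penll(beta + step * db, a + step * da)
      if (is.finite(newObj) && newObj >= obj - 1e-10) break
      step <- step / 2
      if (step < 1e-8) break
    }
    beta <- beta + step * db
    a <- a + step * da
    obj <- newObj
  }
  # Laplace log-likelihood at the profiled optimum
  eta <- drop(X %*% beta) + a[eng$idx]
  mu <- plogis(eta)
  w <- eng$N * mu * (1 - mu)
  Wd <- aggAt(w, eng$idx, q)
  Haa <- Matrix::Diagonal(x = Wd) + eng$Ainv / sigma2
  ldH <- as.numeric(Matrix::determinant(Haa, logarithm = TRUE)$modulus)
  ll <- binomLogLik(eng, eta) -
    sum(a * as.numeric(eng$Ainv %*% a)) / (2 * sigma2) -
    0.5 * (eng$logdetA + q * log(sigma2) + ldH)
  if (is.null(S)) {
    B <- aggAt(X * w, eng$idx, q)
    Ch <- Matrix::Cholesky(Matrix::forceSymmetric(Haa), LDL = FALSE)
    S <- crossprod(X, X * w) - crossprod(B, as.matrix(Matrix::solve(Ch, B)))
  }
  list(beta = beta, a = a, logLik = ll, vcovBeta = solve(S),
       converged = conv)
}

# plain IRLS logistic regression (the sigma2 = 0 degenerate limit)
irlsFixed <- function(eng, tol = 1e-10, maxit = 50L) {
  beta <- numeric(eng$p)
  conv <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(eng$X %*% beta)
    mu <- plogis(eta)
    res <- eng$yA - eng$N * mu
    gb <- drop(crossprod(eng$X, res))
    if (max(abs(gb)) < tol) { conv <- TRUE; break }
    w <- eng$N * mu * (1 - mu)
    H <- crossprod(eng$X, eng$X * w)
    beta <- beta + safeSolve(H, gb)
  }
  eta <- drop(eng$X %*% beta)
  w <- eng$N * plogis(eta) * (1 - plogis(eta))
  list(beta = beta, a = numeric(eng$q), logLik = binomLogLik(eng, eta),
       vcovBeta = solve(crossprod(eng$X, eng$X * w)), converged = conv)
}

# profile the Laplace log-likelihood over log(sigma2), with (beta, a)
# profiled jointly at each variance -- fast, and a good neighbourhood of
# the maximum-likelihood solution, but not exactly ML because the
# log-determinant's dependence on beta is ignored during profiling
laplaceProfile <- function(eng, lower = 1e-6, upper = 25, tol = 1e-3) {
  state <- new.env(parent = emptyenv())
  state$beta <- numeric(eng$p)
  state$a <- numeric(eng$q)
  evalS <- function(ls2) {
    f <- laplaceInner(eng, exp(ls2), state$beta, state$a)
    state$beta <- f$beta
    state$a <- f$a
    -f$logLik
  }
  opt <- optimize(evalS, interval = log(c(lower, upper)), tol = tol)
  sigma2 <- exp(opt$minimum)
  fit <- laplaceInner(eng, sigma2, state$beta, state$a)
  c(fit, list(sigma2 = sigma2))
}

# Newton maximisation over the latent effects only, at fixed (beta, sigma2);
# returns the mode, its Cholesky factor pieces and the Laplace logLik
latentMode <- function(eng, beta, sigma2, a, tol = 1e-9, maxit = 50L) {
  etaFix <- drop(eng$X %*% beta)
  pen <- function(a) {
    eta <- etaFix + a[eng$idx]
    binomLogLik(eng, eta) - sum(a * as.numeric(eng$Ainv %*% a)) / (2 * sigma2)
  }
  obj <- pen(a)
  for (it in seq_len(maxit)) {
    eta <- etaFix + a[eng$idx]
    mu <- plogis(eta)
    ga <- aggAt(eng$yA - eng$N * mu, eng$idx, eng$q) -
      as.numeric(eng$Ainv %*% a) / sigma2
    if (max(abs(ga)) < tol) break
    Wd <- aggAt(eng$N * mu * (1 - mu), eng$idx, eng$q)
    Haa <- Matrix::Diagonal(x = Wd) + eng$Ainv / sigma2
    Ch <- Matrix::Cholesky(Matrix::forceSymmetric(Haa), LDL = FALSE)
    da <- drop(as.matrix(Matrix::solve(Ch, ga)))
    step <- 1
    repeat {
      newObj <- pen(a + step * da)
      if (is.finite(newObj) && newObj >= obj - 1e-12) break
      step <- step / 2
      if (step < 1e-8) break
    }
    a <- a + step * da
    obj <- newObj
  }
  eta <- etaFix + a[eng$idx]
  mu <- plogis(eta)
  w <- eng$N * mu * (1 - mu)
  Wd <- aggAt(w, eng$idx, eng$q)
  Haa <- Matrix::Diagonal(x = Wd) + eng$Ainv / sigma2
  ldH <- as.numeric(Matrix::determinant(Haa, logarithm = TRUE)$modulus)
  ll <- binomLogLik(eng, eta) -
    sum(a * as.numeric(eng$Ainv %*% a)) / (2 * sigma2) -
    0.5 * (eng$logdetA + eng$q * log(sigma2) + ldH)
  list(a = a, logLik = ll, mu = mu, w = w, Haa = Haa)
}

# Exact Laplace maximum likelihood: BFGS over (beta, log sigma2) of the
# Laplace objective with the latent mode recomputed at every evaluation.
# The beta-gradient is analytic (envelope theorem for the penalised part
# plus the log-determinant chain rule); the variance component uses a
# central difference. Warm-started from laplaceProfile().
laplaceML <- function(eng) {
  prof <- laplaceProfile(eng)
  state <- new.env(parent = emptyenv())
  state$a <- prof$a
  evalLap <- function(par) {
    m <- latentMode(eng, par[seq_len(eng$p)], exp(par[eng$p + 1L]), state$a)
    state$a <- m$a
    -m$logLik
  }
  gradLap <- function(par) {
    beta <- par[seq_len(eng$p)]
    sigma2 <- exp(par[eng$p + 1L])
    m <- latentMode(eng, beta, sigma2, state$a)
    state$a <- m$a
    res <- eng$yA - eng$N * m$mu
    wp <- m$w * (1 - 2 * m$mu)              # d w_r / d eta_r
    Ch <- Matrix::Cholesky(Matrix::forceSymmetric(m$Haa), LDL = FALSE)
    Mi <- as.matrix(Matrix::solve(Ch, diag(eng$q)))
    dvec <- diag(Mi)[eng$idx]
    B <- aggAt(eng$X * m$w, eng$idx, eng$q)  # q x p
    DA <- -Mi %*% B                          # d a-hat / d beta_j (columns)
    # d logdet(Haa) / d beta_j = sum_r diag(Mi)[dam_r] w'_r d eta_r/d beta_j
    term <- drop(crossprod(eng$X, dvec * wp)) +
      drop(crossprod(DA[eng$idx, , drop = FALSE], dvec * wp))
    gbeta <- drop(crossprod(eng$X, res)) - 0.5 * term
    # variance component by central difference on the 1-D section
    h <- 1e-4
    ls <- par[eng$p + 1L]
    lp <- latentMode(eng, beta, exp(ls + h), state$a)$logLik
    lmn <- latentMode(eng, beta, exp(ls - h), state$a)$logLik
    -c(gbeta, (lp - lmn) / (2 * h))
  }
  opt <- optim(c(prof$beta, log(prof$sigma2)), evalLap, gradLap,
               method = "BFGS",
               control = list(maxit = 200, reltol = 1e-12))
  beta <- opt$par[seq_len(eng$p)]
  sigma2 <- exp(opt$par[eng$p + 1L])
  m <- latentMode(eng, beta, sigma2, state$a)
  # Wald covariance of beta from the joint penalised information
  B <- aggAt(eng$X * m$w, eng$idx, eng$q)
  Ch <- Matrix::Cholesky(Matrix::forceSymmetric(m$Haa), LDL = FALSE)
  S <- crossprod(eng$X, eng$X * m$w) -
    crossprod(B, as.matrix(Matrix::solve(Ch, B)))
  list(beta = beta, a = m$a, logLik = m$logLik, vcovBeta = solve(S),
       converged = opt$convergence == 0L, sigma2 = sigma2)
}
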