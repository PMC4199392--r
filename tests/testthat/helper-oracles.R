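# Independent oracles, deliberately not sharing code with the package's
# fitting routines.

# Hand-coded probit log-likelihood.
oracle_probit_loglik <- function(beta, x, y) {
  p <- pnorm(drop(x %*% beta))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(log(ifelse(y, p, 1 - p)))
}

# Coarse-to-fine direct search for the probit maximum likelihood: a coarse
# Nelder-Mead pass followed by cyclic per-coordinate golden-section line
# searches until the objective stops improving.
oracle_probit_maximum <- function(x, y) {
  nll <- function(b) -oracle_probit_loglik(b, x, y)
  b <- rep(0, ncol(x))
  b <- optim(b, nll, method = "Nelder-Mead",
             control = list(maxit = 5000, reltol = 1e-10))$par
  best <- -nll(b)
  for (cycle in 1:500) {
    for (j in seq_along(b)) {
      f1 <- function(v) {
        bb <- b
        bb[j] <- v
        nll(bb)
      }
      b[j] <- optimize(f1, lower = b[j] - 2, upper = b[j] + 2,
                       tol = 1e-10)$minimum
    }
    now <- -nll(b)
    if (now - best < 1e-10) break
    best <- now
  }
  list(par = b, loglik = best)
}

# Gaussian max log-likelihood by numerical optimisation over (mu, log sd),
# used to cross-check the closed-form AIC Bayes factor.
oracle_gaussian_maxll <- function(x, fix_mu_zero = FALSE) {
  nll <- function(p) {
    mu <- if (fix_mu_zero) 0 else p[1]
    s <- exp(p[length(p)])
    -sum(dnorm(x, mu, s, log = TRUE))
  }
  p0 <- if (fix_mu_zero) 0 else c(mean(x), log(sd(x)))
  -optim(p0, nll, method = if (fix_mu_zero) "Brent" else "Nelder-Mead",
         lower = if (fix_mu_zero) -10 else -Inf,
         upper = if (fix_mu_zero) 10 else Inf,
         control = list(reltol = 1e-14, maxit = 5000))$value
}
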