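# Internal negative-binomial helpers.
#
# Throughout the package a gene's counts are parametrized by the mean mu and
# the dispersion phi, with Var = mu + phi * mu^2 (the mean-variance relation
# the dispersion is estimated under).  In R's parametrization this is
# size = 1/phi.  The classical (alpha, p) NB parametrization (number of
# failures before the alpha-th success with success probability p) is
# equivalent with alpha = 1/phi and p(t) = 1 / (1 + phi * mu(t)); fitting on
# log mu(t) is therefore the same model as fitting a logit-linked p(t).
# phi below .phi_poisson is treated as the Poisson limit so that tails and
# quantiles stay numerically exact as phi -> 0.

.phi_poisson <- 1e-12
.phi_min <- 1e-8
.phi_max <- 10

nb_quantile <- function(p, mu, phi) {
  if (phi <= .phi_poisson) qpois(p, lambda = mu) else qnbinom(p, size = 1 / phi, mu = mu)
}

# P(X <= q) (lower) or P(X >= q) (!lower), q integer-valued
nb_tail <- function(q, mu, phi, lower = TRUE) {
  if (phi <= .phi_poisson) {
    if (lower) ppois(q, lambda = mu) else ppois(q - 1, lambda = mu, lower.tail = FALSE)
  } else {
    if (lower) {
      pnbinom(q, size = 1 / phi, mu = mu)
    } else {
      pnbinom(q - 1, size = 1 / phi, mu = mu, lower.tail = FALSE)
    }
  }
}

nb_loglik <- function(y, mu, phi) {
  if (phi <= .phi_poisson) sum(dpois(y, lambda = mu, log = TRUE))
  else sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

nb_rand <- function(n, mu, phi) {
  if (phi <= .phi_poisson) rpois(n, lambda = mu) else rnbinom(n, size = 1 / phi, mu = mu)
}

# format a numeric time compactly for pattern labels ("2", "0.5")
format_time <- function(t) {
  vapply(t, function(x) format(x, trim = TRUE, drop0trailing = TRUE), character(1))
}
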