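# simulation + brute-force oracles shared across test files; everything here
# is deliberately independent of the package's own estimation code paths

sim_rasch_rm <- function(n, alpha, seed = 1, theta = NULL, a = NULL,
                         group = NULL, age = NULL) {
  set.seed(seed)
  if (is.null(theta)) theta <- stats::rnorm(n)
  if (is.null(a)) a <- rep(1, length(alpha))
  eta <- sweep(outer(theta, alpha, "-"), 2, a, "*")
  Y <- matrix(stats::rbinom(n * length(alpha), 1, stats::plogis(eta)), n)
  list(rm = response_matrix(Y, group = group, age = age), theta = theta)
}

toy_bank <- function(difficulties, a = 1) {
  item_bank(data.frame(item_id = sprintf("i%03d", seq_along(difficulties)),
                       difficulty = difficulties, discrimination = a),
            model_tag = if (all(a == 1)) "rasch" else "2pl")
}

# two-stage grid search for the ML ability: coarse 0.01 grid over [-10, 10],
# then a 1e-5 grid around the coarse maximum
grid_ml_theta <- function(y, alpha) {
  ll <- function(th) vapply(th, function(t)
    sum(y * (t - alpha) - log1p(exp(t - alpha))), numeric(1))
  g1 <- seq(-10, 10, by = 0.01)
  m <- g1[which.max(ll(g1))]
  g2 <- seq(m - 0.02, m + 0.02, by = 1e-5)
  g2[which.max(ll(g2))]
}

# marginal Rasch/2PL log-likelihood by plain midpoint quadrature on a fixed
# theta grid (independent of the package's Gauss-Hermite E-step)
oracle_marginal_loglik <- function(Y, alpha, a) {
  th <- seq(-6, 6, length.out = 121)
  w <- stats::dnorm(th) * (th[2] - th[1])
  lp <- t(stats::plogis(outer(a, th) - a * alpha, log.p = TRUE))   # grid x J
  lq <- t(stats::plogis(-(outer(a, th) - a * alpha), log.p = TRUE))
  ll <- Y %*% t(lp) + (1 - Y) %*% t(lq)                            # n x grid
  mx <- apply(ll, 1, max)
  sum(mx + log(exp(ll - mx) %*% w))
}

# likelihood-ratio refit oracle for the modification index: profile refit of
# one item's (difficulty, slope) with all other items fixed
lr_refit_oracle <- function(Y, alpha, item) {
  base <- oracle_marginal_loglik(Y, alpha, rep(1, length(alpha)))
  obj <- function(par) {
    al <- alpha; a <- rep(1, length(alpha))
    al[item] <- par[1]; a[item] <- exp(par[2])
    -oracle_marginal_loglik(Y, al, a)
  }
  opt <- stats::optim(c(alpha[item], 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-10))
  2 * (-opt$value - base)
}
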