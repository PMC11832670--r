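test_that("icc evaluates the logistic curve with the right anchors", {
  expect_equal(icc(1.2, list(difficulty = 1.2)), 0.5)
  expect_equal(icc(100, list(difficulty = 0)), 1, tolerance = 1e-12)
  expect_equal(icc(1, list(difficulty = 0)), 0.7310586, tolerance = 1e-7)
  # slope scales the curve around its inflection
  expect_equal(icc(0.5, list(difficulty = 0, discrimination = 2)),
               plogis(1))
  expect_error(icc(Inf, list(difficulty = 0)), "finite")
  expect_error(icc(0, list(difficulty = 0, discrimination = -1)), "positive")
})

test_that("icc is strictly increasing in theta and crosses 0.5 at the difficulty", {
  set.seed(1)
  for (k in 1:20) {
    item <- list(difficulty = runif(1, -3, 3),
                 discrimination = runif(1, 0.2, 3))
    th <- sort(runif(25, -6, 6))
    p <- icc(th, item)
    expect_true(all(diff(p) > 0))
    expect_true(all(p > 0 & p < 1))
    expect_equal(icc(item$difficulty, item), 0.5)
  }
})

test_that("fit_rasch recovers the difficulty difference of a two-item toy", {
  # conditional-likelihood closed form: alpha2 - alpha1 ~ log(n10 / n01)
  Y <- rbind(matrix(c(1, 0), 20, 2, byrow = TRUE),
             matrix(c(0, 1), 10, 2, byrow = TRUE),
             matrix(c(1, 1), 15, 2, byrow = TRUE),
             matrix(c(0, 0), 15, 2, byrow = TRUE))
  fit <- fit_rasch(response_matrix(Y))
  expect_true(fit$converged)
  expect_lt(abs(diff(fit$bank$difficulty) - log(20 / 10)), 0.15)
})

test_that("fit_rasch recovers simulated difficulties and reports degenerate items", {
  alpha <- seq(-2.5, 2.5, length.out = 25)
  sim <- sim_rasch_rm(800, alpha, seed = 42)
  fit <- fit_rasch(sim$rm)
  expect_true(fit$converged)
  expect_gt(cor(fit$bank$difficulty, alpha), 0.98)
  expect_equal(nrow(fit$abilities), 800)
  expect_true(all(fit$abilities$se > 0))
  # EAP abilities track the truth
  expect_gt(cor(fit$abilities$theta, sim$theta), 0.85)

  # an all-1 column carries no difficulty information
  Y <- sim$rm$responses
  Y[, 3] <- 1L
  expect_warning(fit2 <- fit_rasch(response_matrix(Y)), "degenerate")
  expect_equal(fit2$n_excluded_degenerate, 1L)
  expect_false("i0003" %in% fit2$bank$item_id)
})

test_that("fit_2pl preserves slope rank order and is near 1 on Rasch data", {
  alpha <- rep(seq(-1.5, 1.5, length.out = 6), 3)
  a_true <- rep(c(0.5, 1, 2), each = 6)
  sim <- sim_rasch_rm(1500, alpha, seed = 7, a = a_true)
  fit <- fit_2pl(sim$rm)
  grp <- tapply(fit$bank$discrimination, a_true, mean)
  expect_true(all(diff(grp[order(as.numeric(names(grp)))]) > 0))

  sim0 <- sim_rasch_rm(1000, seq(-2, 2, length.out = 20), seed = 8)
  fit0 <- fit_2pl(sim0$rm)
  expect_gt(mean(fit0$bank$discrimination), 0.9)
  expect_lt(mean(fit0$bank$discrimination), 1.1)
})

test_that("ML ability matches closed forms, conventions, and the grid oracle", {
  b <- toy_bank(c(-1, 1))
  est <- estimate_ability_ml(c(1, 0), b)
  expect_equal(est$theta, 0, tolerance = 1e-8)
  expect_identical(est$method, "ml")

  expect_equal(estimate_ability_ml(c(0, 0), b)$theta, -10)
  expect_identical(estimate_ability_ml(c(0, 0), b)$method, "convention")
  expect_equal(estimate_ability_ml(c(1, 1), b)$theta, 10)

  expect_error(estimate_ability_ml(integer(0), b), "empty")
  expect_error(estimate_ability_ml(c(1, 0, 1), b), "differ in length")

  set.seed(99)
  checked <- 0
  while (checked < 100) {
    alpha <- runif(10, -3, 3)
    y <- rbinom(10, 1, 0.5)
    if (all(y == y[1])) next
    est <- estimate_ability_ml(y, toy_bank(alpha))
    expect_lt(abs(est$theta - grid_ml_theta(y, alpha)), 1e-4)
    checked <- checked + 1
  }
})

test_that("under Rasch the ability estimate depends only on the sum score", {
  alpha <- c(-2.1, -1.3, -0.6, -0.1, 0.4, 0.9, 1.6, 2.3)
  b <- toy_bank(alpha)
  pats <- as.matrix(expand.grid(rep(list(0:1), 8)))
  theta <- apply(pats, 1, function(y) estimate_ability_ml(y, b)$theta)
  for (s in split(theta, rowSums(pats))) {
    expect_lt(diff(range(s)), 1e-6)
  }
})

test_that("ability_se matches closed forms and the likelihood curvature", {
  one <- toy_bank(0.7)
  expect_equal(ability_se(0.7, one), 2)
  expect_equal(ability_se(0, toy_bank(c(0, 0))), sqrt(2), tolerance = 1e-12)

  set.seed(3)
  alpha <- runif(5, -2, 2)
  b <- toy_bank(alpha)
  for (y in list(c(1, 0, 1, 0, 1), c(0, 0, 1, 1, 0))) {
    est <- estimate_ability_ml(y, b)
    ll <- function(t) sum(y * (t - alpha) - log1p(exp(t - alpha)))
    h <- 1e-4
    curv <- (ll(est$theta + h) - 2 * ll(est$theta) + ll(est$theta - h)) / h^2
    expect_equal(est$se, 1 / sqrt(-curv), tolerance = 1e-3)
  }

  # information grows with the item set, so the SE weakly decreases
  expect_lte(ability_se(0.3, toy_bank(c(-1, 0, 1, 2))),
             ability_se(0.3, toy_bank(c(-1, 0, 1))))
})
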