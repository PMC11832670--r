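bank89 <- toy_bank(seq(-3, 3, length.out = 89))

test_that("provisional ability follows the session conventions", {
  expect_equal(provisional_ability(integer(0), bank89[0, ])$theta, 0)
  one <- bank_ <- toy_bank(0.3)
  expect_equal(provisional_ability(1L, one)$theta, 10)
  expect_equal(provisional_ability(0L, one)$theta, -10)
  expect_identical(provisional_ability(0L, one)$method, "convention")
  est <- provisional_ability(c(1L, 0L), toy_bank(c(-1, 1)))
  expect_equal(est$theta, 0, tolerance = 1e-8)
  expect_identical(est$method, "ml")
})

test_that("next_item picks the nearest difficulty with deterministic tie-breaks", {
  b <- toy_bank(c(-1, 0.1, 0.5))
  expect_equal(next_item(b, character(0), 0.2)$difficulty, 0.1)
  b2 <- toy_bank(c(-0.5, 0.5))
  expect_equal(next_item(b2, character(0), 0)$difficulty, -0.5)
  expect_null(next_item(b2, b2$item_id, 0))
  expect_error(next_item(b2, character(0), NaN), "finite")
})

test_that("the nearest item maximizes Fisher information among free items", {
  set.seed(90)
  b <- toy_bank(sort(runif(30, -3, 3)))
  for (theta in c(-2.2, -0.3, 0.8, 2.9)) {
    admin <- sample(b$item_id, 10)
    pick <- next_item(b, admin, theta)
    free <- setdiff(b$item_id, admin)
    info <- vapply(free, function(id) {
      p <- icc(theta, b[b$item_id == id, ])
      p * (1 - p)
    }, numeric(1))
    expect_equal(max(info), info[[pick$item_id]])
  }
})

test_that("sessions stop correctly, never repeat items, and replay exactly", {
  responses <- c(1, 0, 1, 1, 0, 0, 1, 0, 1, 0, 1, 1, 0, 1, 0, 0, 1, 0, 1, 1,
                 0, 1, 0, 1, 0, 1, 1, 0, 0, 1, 0, 1, 1, 0, 1, 0, 1, 0, 1, 0)
  make_responder <- function() {
    i <- 0
    function(item) { i <<- i + 1; responses[i] }
  }
  s1 <- run_session(bank89, make_responder(), cat_config(se_threshold = 0.4))
  s2 <- run_session(bank89, make_responder(), cat_config(se_threshold = 0.4))
  expect_identical(s1$administered, s2$administered)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_false(anyDuplicated(s1$administered$item_id) > 0)
  expect_equal(nrow(s1$trajectory), length(s1$responses))
  expect_true(s1$stop_reason %in% c("se_reached", "pool_exhausted"))
  if (s1$stop_reason == "se_reached") expect_lte(s1$final$se, 0.4)

  # transcript is self-contained: re-estimating from it reproduces the record
  re <- estimate_ability_ml(s1$responses, bank_subset(bank89, s1$administered$item_id))
  expect_equal(re$theta, s1$final$theta, tolerance = 1e-6)
  expect_equal(re$se, s1$final$se, tolerance = 1e-6)
})

test_that("a convention-valued ability never terminates the session", {
  # all-yes start: theta pinned at +10, so the engine must keep administering
  s <- run_session(bank89, function(item) 1L, cat_config(se_threshold = 0.4))
  expect_identical(s$stop_reason, "pool_exhausted")
  expect_identical(s$final$method, "convention")
  expect_equal(length(s$responses), 89)
})

test_that("a misbehaving responder aborts with the partial transcript preserved", {
  calls <- 0
  bad <- function(item) { calls <<- calls + 1; if (calls > 1) 2 else 1 }
  cond <- tryCatch(run_session(bank89, bad, cat_config(0.4)),
                   cat_responder_error = function(e) e)
  expect_s3_class(cond, "cat_responder_error")
  expect_s3_class(cond$session, "cat_session")
  expect_identical(cond$session$stop_reason, "aborted")
  expect_gte(nrow(cond$session$administered), 1)
})

test_that("max_items caps the session", {
  s <- run_session(bank89, function(item) rbinom(1, 1, 0.5),
                   cat_config(se_threshold = 0.05, max_items = 7, seed = 3))
  expect_identical(s$stop_reason, "max_items")
  expect_length(s$responses, 7)
})

test_that("a 0.2 SE target usually exhausts an 89-item pool", {
  set.seed(91)
  exhausted <- vapply(1:30, function(i) {
    s <- run_session(bank89, function(item) rbinom(1, 1, icc(0, item)),
                     cat_config(se_threshold = 0.2))
    s$stop_reason == "pool_exhausted"
  }, logical(1))
  expect_gt(mean(exhausted), 0.5)
})

test_that("simulated sessions are unbiased, covered, and lengthen with precision", {
  sim <- simulate_cat(bank89, theta_true = c(-2, -1, 0, 1, 2),
                      config = cat_config(0.4), n_replicates = 100, seed = 7)
  expect_true(all(abs(sim$summary$bias) < 0.15))
  ml <- sim$sessions[sim$sessions$method == "ml", ]
  cover <- mean(abs(ml$theta_hat - ml$theta_true) <= 1.96 * ml$se)
  expect_gte(cover, 0.90)

  sim3 <- simulate_cat(bank89, theta_true = 0, config = cat_config(0.3),
                       n_replicates = 40, seed = 8)
  sim5 <- simulate_cat(bank89, theta_true = 0, config = cat_config(0.5),
                       n_replicates = 40, seed = 8)
  expect_gt(mean(sim3$sessions$n_items), mean(sim5$sessions$n_items))

  rerun <- simulate_cat(bank89, theta_true = 0, config = cat_config(0.3),
                        n_replicates = 40, seed = 8)
  expect_identical(sim3$sessions, rerun$sessions)
})
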