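mk_stats <- function(bank, infit = 1, outfit = 1, mi = 0) {
  structure(data.frame(item_id = bank$item_id,
                       infit = rep_len(infit, nrow(bank)),
                       outfit = rep_len(outfit, nrow(bank)),
                       mod_index = rep_len(mi, nrow(bank)),
                       stringsAsFactors = FALSE),
            class = c("item_fit_stats", "data.frame"))
}

test_that("adjacent spacing SD matches hand values and ignores input order", {
  expect_equal(adjacent_spacing_sd(c(-1, 0, 1)), 0)
  expect_equal(adjacent_spacing_sd(c(0, 1, 3)), sd(c(1, 2)))
  expect_equal(adjacent_spacing_sd(c(0, 1, 3)), 0.7071, tolerance = 1e-4)
  expect_equal(adjacent_spacing_sd(c(3, 0, 1)), adjacent_spacing_sd(c(0, 1, 3)))
  expect_error(adjacent_spacing_sd(c(0, 1)), "at least 3")
})

test_that("the objective reproduces the weighted hand computation", {
  # ideal subset: equally spaced, perfect fit, no modification pressure
  b <- toy_bank(c(-1, 0, 1))
  expect_equal(pool_objective(b$item_id, mk_stats(b), b), 0)

  # spacing SD 0.5, mean |infit-1| 0.1, mean |outfit-1| 0.2, mean MI 2:
  # -(0.5/3) - 4*0.1 - 2*0.2 - 2/100
  b2 <- toy_bank(c(0, 1, 1 + 1 + sqrt(2) / 2))       # gaps 1, 1.7071 -> sd 0.5
  st2 <- mk_stats(b2, infit = 1.1, outfit = 0.8, mi = 2)
  expect_equal(pool_objective(b2$item_id, st2, b2),
               -0.5 / 3 - 4 * 0.1 - 2 * 0.2 - 2 / 100, tolerance = 1e-10)
  expect_equal(pool_objective(b2$item_id, st2, b2), -0.98667, tolerance = 1e-5)

  # raw-sum aggregation is the literal reading
  w <- selection_weights(aggregation = "raw_sum")
  expect_equal(pool_objective(b2$item_id, st2, b2, w),
               -0.5 / 3 - 4 * 3.3 - 2 * 2.4 - 6 / 100)
})

test_that("worsening any single component strictly lowers the objective", {
  b <- toy_bank(c(-1.5, -0.5, 0.5, 1.5))
  base <- pool_objective(b$item_id, mk_stats(b), b)
  worse_sp <- toy_bank(c(-1.5, -0.5, 0.5, 2.5))
  expect_lt(pool_objective(worse_sp$item_id, mk_stats(worse_sp), worse_sp), base)
  expect_lt(pool_objective(b$item_id, mk_stats(b, infit = 1.05), b), base)
  expect_lt(pool_objective(b$item_id, mk_stats(b, outfit = 0.9), b), base)
  expect_lt(pool_objective(b$item_id, mk_stats(b, mi = 0.5), b), base)
  expect_error(pool_objective(c("i001", "nope"), mk_stats(b), b), "not in bank")
})

test_that("annealing matches exhaustive search on small pools", {
  for (case in list(c(10, 4, 101), c(12, 3, 102), c(11, 4, 103))) {
    set.seed(case[3])
    n <- case[1]; k <- case[2]
    b <- toy_bank(sort(runif(n, -3, 3)))
    st <- mk_stats(b, infit = runif(n, 0.8, 1.2), outfit = runif(n, 0.8, 1.2),
                   mi = runif(n, 0, 3))
    best <- max(apply(utils::combn(n, k), 2, function(ix)
      pool_objective(b$item_id[ix], st, b)))
    sa <- simulated_annealing_select(b, st, k, seed = case[3])
    expect_equal(sa$objective_value, best)
    expect_equal(pool_objective(sa$chosen, st, b), sa$objective_value)
  }
})

test_that("annealing is deterministic, bounded by its trace, and handles edges", {
  set.seed(5)
  b <- toy_bank(sort(runif(15, -3, 3)))
  st <- mk_stats(b, infit = runif(15, 0.8, 1.2), outfit = runif(15, 0.8, 1.2),
                 mi = runif(15, 0, 2))
  s1 <- simulated_annealing_select(b, st, 6, seed = 77)
  s2 <- simulated_annealing_select(b, st, 6, seed = 77)
  expect_identical(s1$chosen, s2$chosen)
  expect_identical(s1$trace, s2$trace)
  expect_equal(s1$objective_value, max(s1$trace))

  whole <- simulated_annealing_select(b, st, 15, seed = 1)
  expect_identical(whole$chosen, b$item_id)
  expect_error(simulated_annealing_select(b, st, 16), "exceeds pool size")
})

test_that("consensus selection is deterministic and returns the requested size", {
  set.seed(6)
  b <- toy_bank(sort(runif(14, -3, 3)))
  st <- mk_stats(b, infit = runif(14, 0.85, 1.15), outfit = runif(14, 0.85, 1.15),
                 mi = runif(14, 0, 2))
  c1 <- sa_consensus_select(b, st, 6, restarts = 5, seed = 11)
  c2 <- sa_consensus_select(b, st, 6, restarts = 5, seed = 11)
  expect_identical(c1$chosen, c2$chosen)
  expect_length(c1$chosen, 6)
  expect_equal(c1$objective_value, pool_objective(c1$chosen, st, b))
})

test_that("model comparison obeys the 2-SE rule and detects varying slopes", {
  alpha <- seq(-2, 2, length.out = 20)
  sim <- sim_rasch_rm(600, alpha, seed = 50)
  cmp <- compare_rasch_2pl(sim$rm, seed = 1)
  expect_true(cmp$preferred %in% c("equivalent", "rasch", "2pl"))
  expect_identical(cmp$preferred == "equivalent",
                   abs(cmp$elpd_diff) <= 2 * cmp$se_diff)

  sim2 <- sim_rasch_rm(800, alpha, seed = 51, a = runif(20, 0.3, 3))
  cmp2 <- compare_rasch_2pl(sim2$rm, seed = 1)
  expect_identical(cmp2$preferred, "2pl")
  expect_gt(cmp2$elpd_diff, 2 * cmp2$se_diff)

  expect_error(compare_rasch_2pl(sim$rm, folds = 1), "folds")
})

test_that("DIF screening flags an injected shift and validates its groups", {
  n <- 1000
  g <- rep(c("female", "male"), each = n / 2)
  alpha <- seq(-2, 2, length.out = 16)
  set.seed(60)
  theta <- rnorm(n)
  A <- matrix(alpha, n, 16, byrow = TRUE)
  A[g == "male", 4] <- A[g == "male", 4] + 1.5
  Y <- matrix(rbinom(n * 16, 1, plogis(theta - A)), n)
  rep <- dif_analysis(response_matrix(Y, group = g))
  expect_true("i0004" %in% rep$flagged)
  expect_true(all(rep$table$ci_low < rep$table$ci_high))

  # null data: at most a small fraction of spurious flags
  Y0 <- matrix(rbinom(n * 16, 1, plogis(theta - matrix(alpha, n, 16, byrow = TRUE))), n)
  rep0 <- dif_analysis(response_matrix(Y0, group = g))
  expect_lte(length(rep0$flagged), 1)

  expect_error(dif_analysis(response_matrix(Y)), "no group")
  expect_error(dif_analysis(response_matrix(Y, group = rep("x", n))), "exactly 2")
  g1 <- c("a", rep("b", n - 1))
  expect_error(dif_analysis(response_matrix(Y, group = g1)), "at least 2 persons")
})

test_that("build_pool removes injected misfits and is reproducible end to end", {
  cfg <- generator_config(n_items = 60, n_persons = 800,
                          word_type_counts = c(noun = 30, verb = 15, adjective = 15),
                          misfit_fraction = 0.25, seed = 4L)
  study <- simulate_study(cfg)
  misfits <- study$item_truth$item_id[study$item_truth$discrimination != 1]
  expect_length(misfits, 15)
  rep1 <- suppressWarnings(build_pool(study$data, sizes = c(25, 35),
                                      restarts = 5, seed = 2L))
  expect_gte(sum(!misfits %in% rep1$bank$item_id), 12)
  expect_equal(nrow(rep1$bank),
               rep1$step2$chosen_size - length(rep1$step3$dropped))

  rep2 <- suppressWarnings(build_pool(study$data, sizes = c(25, 35),
                                      restarts = 5, seed = 2L))
  expect_identical(rep1$bank$item_id, rep2$bank$item_id)
})

test_that("build_pool keeps a clean filtered pool when asked for all of it", {
  sim <- sim_rasch_rm(700, seq(-2, 2, length.out = 24), seed = 70,
                      group = sample(c("female", "male"), 700, replace = TRUE))
  fit <- fit_rasch(sim$rm)
  kept <- filter_by_fit(infit_outfit(fit, sim$rm, mod_index = FALSE))
  rep <- suppressWarnings(build_pool(sim$rm, sizes = length(kept),
                                     restarts = 3, seed = 3L))
  expect_setequal(rep$step2$chosen, kept)
})
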