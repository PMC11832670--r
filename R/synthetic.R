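#' Configuration of the synthetic vocabulary-study generator
#'
#' Defaults emulate the statistical structure of a large parent-report
#' vocabulary calibration study: 1190 complete respondents (children aged
#' 3–8, caregivers reporting) by 379 words, of which 197 are nouns, 92
#' verbs and 90 adjectives; item difficulties increase monotonically with a
#' simulated age-of-acquisition (AoA) grade, mapped affinely onto
#' `difficulty_range` logits; person abilities increase linearly with age
#' (`theta = theta_intercept + theta_slope * age + N(0, theta_sd^2)`, so
#' that abilities centre near 0 for the mid-age child and older children
#' say more words); sex is assigned at random as the grouping variable.
#' `misfit_fraction` items get a non-unit true discrimination (half low,
#' half high) and `dif_items` injects group-specific difficulty shifts, so
#' screening procedures have known targets to recover.
#'
#' @param n_items,n_persons pool and sample size.
#' @param word_type_counts named counts for noun/verb/adjective; must sum
#'   to `n_items`.
#' @param difficulty_range logits spanned by the AoA-to-difficulty map.
#' @param theta_intercept,theta_slope,theta_sd ability-on-age model
#'   (logits, logits/year, logits).
#' @param age_range years, uniform ages.
#' @param misfit_fraction share of items with discrimination != 1.
#' @param misfit_discriminations the low/high true slopes used for misfit
#'   items.
#' @param dif_items optional data.frame with `item_id` (or 1-based `item`),
#'   `group` and `shift` (logits added to the item's difficulty for that
#'   group).
#' @param seed master seed; every random draw in the generator flows from
#'   it.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_items = 379L, n_persons = 1190L,
                             word_type_counts = c(noun = 197L, verb = 92L,
                                                  adjective = 90L),
                             difficulty_range = c(-4, 4),
                             theta_intercept = -5.5, theta_slope = 1,
                             theta_sd = 1, age_range = c(3, 8),
                             misfit_fraction = 0,
                             misfit_discriminations = c(0.3, 3),
                             dif_items = NULL, seed = 1L) {
  stopifnot(n_items > 0, n_persons > 0, misfit_fraction >= 0,
            misfit_fraction <= 1, length(age_range) == 2,
            age_range[1] < age_range[2])
  if (sum(word_type_counts) != n_items)
    stop("word_type_counts sum to ", sum(word_type_counts),
         ", not n_items = ", n_items)
  if (!setequal(names(word_type_counts), WORD_TYPES))
    stop("word_type_counts must be named noun/verb/adjective")
  structure(list(n_items = as.integer(n_items),
                 n_persons = as.integer(n_persons),
                 word_type_counts = word_type_counts,
                 difficulty_range = difficulty_range,
                 theta_intercept = theta_intercept,
                 theta_slope = theta_slope, theta_sd = theta_sd,
                 age_range = age_range, misfit_fraction = misfit_fraction,
                 misfit_discriminations = misfit_discriminations,
                 dif_items = dif_items, seed = seed),
            class = "generator_config")
}

#' Generate a synthetic item bank with known truth
#'
#' Items get an AoA grade on a 1–10 scale (evenly spread, as if drawn from
#' ten AoA-ordered candidate lists), a difficulty that is a strictly
#' increasing affine map of that grade onto `difficulty_range`, a word type
#' per the configured counts (assigned at random across the AoA range) and
#' a synthetic word label. The returned truth record carries the generating
#' parameters — including the true discriminations of injected misfit items
#' and any DIF shifts — for recovery tests; the bank itself is tagged
#' Rasch, as an analyst would assume before screening.
#'
#' @param config a [generator_config()].
#' @return list with `bank` (an [item_bank()]) and `truth` (data.frame
#'   item_id, aoa_grade, difficulty, discrimination, dif_group, dif_shift).
#' @export
make_item_bank <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  J <- config$n_items
  aoa <- seq(1, 10, length.out = J)
  difficulty <- config$difficulty_range[1] +
    (aoa - 1) / 9 * diff(config$difficulty_range)
  types <- sample(rep(WORD_TYPES, times = config$word_type_counts[WORD_TYPES]))
  a_true <- rep(1, J)
  n_misfit <- round(config$misfit_fraction * J)
  misfit_idx <- integer(0)
  if (n_misfit > 0) {
    misfit_idx <- sort(sample.int(J, n_misfit))
    a_true[misfit_idx] <- rep_len(config$misfit_discriminations, n_misfit)
  }
  ids <- sprintf("w%03d", seq_len(J))
  truth <- data.frame(item_id = ids, aoa_grade = aoa, difficulty = difficulty,
                      discrimination = a_true,
                      dif_group = NA_character_, dif_shift = 0,
                      stringsAsFactors = FALSE)
  if (!is.null(config$dif_items)) {
    di <- as.data.frame(config$dif_items)
    idx <- if (!is.null(di$item_id)) match(as.character(di$item_id), ids)
      else as.integer(di$item)
    if (anyNA(idx) || any(idx < 1 | idx > J)) stop("dif_items out of range")
    truth$dif_group[idx] <- as.character(di$group)
    truth$dif_shift[idx] <- di$shift
  }
  bank <- item_bank(data.frame(item_id = ids,
                               word = paste0("word_", seq_len(J)),
                               word_type = types, difficulty = difficulty,
                               discrimination = 1, stringsAsFactors = FALSE),
                    model_tag = "rasch")
  list(bank = bank, truth = truth)
}

#' Simulate complete response data from a synthetic bank
#'
#' Ages are uniform over `age_range`; abilities follow the linear age model
#' with normal noise; each response is Bernoulli with probability
#' `icc(theta_p, item)` using the item's *true* discrimination and — for
#' persons in a DIF-target group — its group-shifted difficulty. Sex
#' ("female"/"male") is assigned at random and serves as the grouping
#' variable. Reproducible: the same config yields bit-identical output.
#'
#' @param bank_truth the list returned by [make_item_bank()].
#' @param config the same [generator_config()].
#' @return list with `data` (a [response_matrix()]) and `truth` (data.frame
#'   person_id, age, group, theta).
#' @export
simulate_responses <- function(bank_truth, config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  truth_i <- bank_truth$truth
  set.seed(config$seed + 1L)
  n <- config$n_persons
  J <- nrow(truth_i)
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  theta <- config$theta_intercept + config$theta_slope * age +
    stats::rnorm(n, 0, config$theta_sd)
  group <- sample(c("female", "male"), n, replace = TRUE)
  alpha <- matrix(truth_i$difficulty, n, J, byrow = TRUE)
  for (j in which(truth_i$dif_shift != 0)) {
    hit <- group == truth_i$dif_group[j]
    alpha[hit, j] <- alpha[hit, j] + truth_i$dif_shift[j]
  }
  eta <- sweep(theta - alpha, 2, truth_i$discrimination, "*")
  Y <- matrix(stats::rbinom(n * J, 1, stats::plogis(eta)), n, J)
  data <- response_matrix(Y, person_ids = sprintf("p%04d", seq_len(n)),
                          item_ids = truth_i$item_id, age = age, group = group)
  list(data = data,
       truth = data.frame(person_id = rownames(data$responses), age = age,
                          group = group, theta = theta,
                          stringsAsFactors = FALSE))
}

#' One-call synthetic study
#'
#' Convenience wrapper: builds the bank and simulates responses under one
#' config.
#'
#' @param config a [generator_config()].
#' @return list with `bank`, `item_truth`, `data`, `person_truth`.
#' @export
simulate_study <- function(config = generator_config()) {
  bt <- make_item_bank(config)
  sr <- simulate_responses(bt, config)
  list(bank = bt$bank, item_truth = bt$truth,
       data = sr$data, person_truth = sr$truth)
}
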