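#' Spread of gaps between adjacent item difficulties
#'
#' Sorts the difficulties, takes successive differences and returns their
#' sample standard deviation (n-1 denominator). Zero means perfectly even
#' coverage of the difficulty range; large values mean clumping and gaps.
#'
#' @param difficulties numeric vector of at least 3 difficulties (logits).
#' @return non-negative scalar, logits.
#' @examples
#' adjacent_spacing_sd(c(-1, 0, 1))  # 0: equal spacing
#' adjacent_spacing_sd(c(0, 1, 3))   # sd(c(1, 2)) = 0.707...
#' @export
adjacent_spacing_sd <- function(difficulties) {
  if (length(difficulties) < 3)
    stop("need at least 3 difficulties (2 gaps)")
  stats::sd(diff(sort(difficulties)))
}

#' Selection weights for the pool objective
#'
#' The four objective components are weighted 1/3 (difficulty spacing), 4
#' (Infit), 2 (Outfit) and 1/100 (modification index) and each enters with a
#' negative sign, so the score is maximal (0) for a perfectly even,
#' perfectly fitting subset. Under the default `deviation_mean` aggregation
#' the fit components are mean absolute deviations from their ideal value 1
#' and the MI component is a mean; `raw_sum` instead sums the raw per-item
#' values (the literal reading, which penalizes a subset for its size).
#'
#' @param w_spacing,w_infit,w_outfit,w_mi non-negative component weights.
#' @param aggregation `"deviation_mean"` or `"raw_sum"`.
#' @return list of class `selection_weights`.
#' @export
selection_weights <- function(w_spacing = 1 / 3, w_infit = 4, w_outfit = 2,
                              w_mi = 1 / 100,
                              aggregation = c("deviation_mean", "raw_sum")) {
  stopifnot(w_spacing >= 0, w_infit >= 0, w_outfit >= 0, w_mi >= 0)
  structure(list(w_spacing = w_spacing, w_infit = w_infit,
                 w_outfit = w_outfit, w_mi = w_mi,
                 aggregation = match.arg(aggregation)),
            class = "selection_weights")
}

#' Objective function for item-subset assembly
#'
#' Combines evenness of difficulty spacing with Rasch fit:
#' `-w_spacing * spacing_sd - w_infit * f(infit) - w_outfit * f(outfit)
#'  - w_mi * f(mi)`, where under `deviation_mean` aggregation
#' `f(infit) = mean(|infit - 1|)` (likewise outfit) and `f(mi) = mean(mi)`.
#' The score is always `<= 0` and equals 0 only for an equally spaced subset
#' of perfectly fitting items. Worsening any single component strictly
#' lowers the score.
#'
#' @param subset character vector of item ids (>= 3).
#' @param stats `item_fit_stats` with `infit`, `outfit`, `mod_index` for at
#'   least all subset items.
#' @param bank [item_bank()] holding the difficulties.
#' @param weights a [selection_weights()].
#' @return scalar score (to be maximized).
#' @export
pool_objective <- function(subset, stats, bank, weights = selection_weights()) {
  idx <- match(subset, bank$item_id)
  if (anyNA(idx)) stop("subset item not in bank: ", subset[is.na(idx)][1])
  sdx <- match(subset, stats$item_id)
  if (anyNA(sdx)) stop("missing fit statistics for item: ", subset[is.na(sdx)][1])
  if (is.null(stats$mod_index) || anyNA(stats$mod_index[sdx]))
    stop("missing modification indices for subset")
  spacing <- adjacent_spacing_sd(bank$difficulty[idx])
  infit <- stats$infit[sdx]
  outfit <- stats$outfit[sdx]
  mi <- stats$mod_index[sdx]
  if (weights$aggregation == "deviation_mean") {
    -weights$w_spacing * spacing -
      weights$w_infit * mean(abs(infit - 1)) -
      weights$w_outfit * mean(abs(outfit - 1)) -
      weights$w_mi * mean(mi)
  } else {
    -weights$w_spacing * spacing -
      weights$w_infit * sum(infit) -
      weights$w_outfit * sum(outfit) -
      weights$w_mi * sum(mi)
  }
}

#' Annealing schedule
#'
#' Geometric cooling: the temperature starts at `t_initial` and is
#' multiplied by `cooling` after every block of `proposals` proposals until
#' it falls below `t_final`, by which point only improving moves are
#' accepted in practice (pure hill climbing). Each proposal exchanges
#' `swap_size` items (drawn from the given options) between the subset and
#' the remainder of the pool.
#'
#' @param t_initial,t_final temperatures, `t_initial > t_final > 0`.
#' @param cooling multiplicative factor in (0, 1).
#' @param proposals proposals per temperature.
#' @param swap_size integer options for the number of items exchanged.
#' @param seed optional RNG seed for the run.
#' @return list of class `anneal_schedule`.
#' @export
anneal_schedule <- function(t_initial = 1, t_final = 1e-3, cooling = 0.95,
                            proposals = 200L, swap_size = 1:3, seed = NULL) {
  stopifnot(t_initial > t_final, t_final > 0, cooling > 0, cooling < 1,
            all(swap_size >= 1))
  structure(list(t_initial = t_initial, t_final = t_final, cooling = cooling,
                 proposals = as.integer(proposals),
                 swap_size = as.integer(swap_size), seed = seed),
            class = "anneal_schedule")
}

#' Simulated-annealing item subset search
#'
#' Searches for the size-`size` subset maximizing [pool_objective()].
#' Starting from a random subset, item exchanges are proposed; improving
#' proposals are always accepted and worsening ones with Metropolis
#' probability `exp(delta / T)`, where the temperature `T` follows the
#' [anneal_schedule()]. The best subset ever visited is tracked and
#' returned, so the result is never worse than anything on the trace. Given
#' a seed the run is fully reproducible.
#'
#' @param bank [item_bank()] to select from.
#' @param stats fit statistics for all bank items.
#' @param size requested subset size (>= 3 so that spacing is defined;
#'   `size = nrow(bank)` short-circuits to the whole bank).
#' @param weights a [selection_weights()].
#' @param schedule an [anneal_schedule()].
#' @param seed overrides `schedule$seed` when given.
#' @return list of class `selection_result`: `chosen` (item ids, in bank
#'   order), `objective_value`, `trace` (best objective after each
#'   proposal), `seed`.
#' @export
simulated_annealing_select <- function(bank, stats, size,
                                       weights = selection_weights(),
                                       schedule = anneal_schedule(),
                                       seed = schedule$seed) {
  J <- nrow(bank)
  if (size > J) stop("requested size ", size, " exceeds pool size ", J)
  if (size < 3) stop("subsets need at least 3 items")
  obj <- function(idx) pool_objective(bank$item_id[idx], stats, bank, weights)
  if (size == J) {
    ids <- bank$item_id
    return(structure(list(chosen = ids, objective_value = obj(seq_len(J)),
                          trace = obj(seq_len(J)), seed = seed),
                     class = "selection_result"))
  }
  if (!is.null(seed)) set.seed(seed)
  cur <- sort(sample.int(J, size))
  cur_val <- obj(cur)
  best <- cur
  best_val <- cur_val
  temps <- schedule$t_initial * schedule$cooling ^
    (0:floor(log(schedule$t_final / schedule$t_initial) / log(schedule$cooling)))
  trace <- numeric(length(temps) * schedule$proposals)
  step <- 0L
  all_idx <- seq_len(J)
  for (temp in temps) {
    for (p in seq_len(schedule$proposals)) {
      k <- if (length(schedule$swap_size) == 1) schedule$swap_size else
        sample(schedule$swap_size, 1)
      k <- min(k, size, J - size)
      out_pos <- sample.int(size, k)
      pool_out <- setdiff(all_idx, cur)
      in_items <- if (length(pool_out) == 1) pool_out else sample(pool_out, k)
      prop <- sort(c(cur[-out_pos], in_items))
      prop_val <- obj(prop)
      delta <- prop_val - cur_val
      if (delta >= 0 || stats::runif(1) < exp(delta / temp)) {
        cur <- prop
        cur_val <- prop_val
        if (cur_val > best_val) { best <- cur; best_val <- cur_val }
      }
      step <- step + 1L
      trace[step] <- best_val
    }
  }
  structure(list(chosen = bank$item_id[best], objective_value = best_val,
                 trace = trace, seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", length(x$chosen), " items, objective ",
      sprintf("%.5f", x$objective_value), "\n", sep = "")
  invisible(x)
}

#' Consensus selection over repeated annealing runs
#'
#' Runs the annealing search `restarts` times with distinct seeds and keeps
#' the `size` items returned most often. Frequency ties at the selection
#' boundary are resolved greedily by the objective value of the growing
#' subset, then by item order in the bank, so the result is deterministic.
#'
#' @inheritParams simulated_annealing_select
#' @param restarts number of independent runs (default 20).
#' @param seed base seed; run r uses `seed + r`.
#' @return a `selection_result` with extra fields `votes` (named count
#'   vector) and `runs` (list of per-run results).
#' @export
sa_consensus_select <- function(bank, stats, size,
                                weights = selection_weights(),
                                schedule = anneal_schedule(),
                                restarts = 20L, seed = 1L) {
  runs <- lapply(seq_len(restarts), function(r)
    simulated_annealing_select(bank, stats, size, weights, schedule,
                               seed = seed + r))
  votes <- table(factor(unlist(lapply(runs, `[[`, "chosen")),
                        levels = bank$item_id))
  votes <- as.vector(votes)
  names(votes) <- bank$item_id
  ord <- order(-votes, seq_along(votes))
  ranked <- votes[ord]
  if (length(ranked) > size && ranked[size] == ranked[size + 1]) {
    cut_freq <- ranked[size]
    sure <- names(ranked)[ranked > cut_freq]
    tied <- names(votes)[votes == cut_freq]           # bank order
    chosen <- sure
    while (length(chosen) < size) {
      cand_scores <- vapply(tied, function(id) {
        s <- c(chosen, id)
        if (length(s) < 3) 0 else pool_objective(s, stats, bank, weights)
      }, numeric(1))
      pick <- tied[which.max(cand_scores)]            # which.max: first on tie
      chosen <- c(chosen, pick)
      tied <- setdiff(tied, pick)
    }
  } else {
    chosen <- names(ranked)[seq_len(size)]
  }
  chosen <- bank$item_id[bank$item_id %in% chosen]    # bank order
  structure(list(chosen = chosen,
                 objective_value = pool_objective(chosen, stats, bank, weights),
                 trace = vapply(runs, `[[`, numeric(1), "objective_value"),
                 seed = seed, votes = votes, runs = runs),
            class = "selection_result")
}

#' Cross-validated Rasch versus 2PL comparison
#'
#' Person-level k-fold cross-validation of the expected log predictive
#' density (ELPD): both models are calibrated on the training folds, and
#' each held-out person's complete response vector gets a predictive log
#' density with the latent ability integrated over N(0, 1) by quadrature.
#' The models are called equivalent while the absolute ELPD difference does
#' not exceed twice its standard error; beyond that the better-predicting
#' model is preferred.
#'
#' By default (`shrink_slopes = TRUE`) the comparison isolates the question
#' that distinguishes the models — do discriminations *vary* between items?
#' — the way a hierarchical Bayesian fit would. The Rasch side is the
#' common-slope model (one shared discrimination, equivalent to a free
#' latent scale, which Bayesian Rasch fits also have through the person-SD
#' hyperparameter). The 2PL side partially pools the log-discriminations:
#' treating them as exchangeable draws from a normal distribution whose
#' variance is estimated from the data (empirical Bayes), each slope is
#' shrunk toward the common mean in proportion to its sampling noise, and
#' the intercepts are re-estimated with the shrunk slopes held fixed. When
#' the data are Rasch, the estimated between-slope variance is near zero
#' and the two sides collapse onto each other (equivalent); when slopes
#' truly vary, little shrinkage occurs and the 2PL wins.
#' `shrink_slopes = FALSE` gives the literal plug-in route (fixed-scale
#' Rasch vs unpooled ML 2PL), whose extra free parameters systematically
#' lose held-out density through overfitting and read as a spurious Rasch
#' preference even on Rasch data.
#'
#' @param data a [response_matrix()].
#' @param folds number of folds (default 5, >= 2).
#' @param seed RNG seed for the fold split.
#' @param n_quad quadrature nodes for fitting and prediction.
#' @param shrink_slopes partially pool the 2PL discriminations (default
#'   TRUE).
#' @return list of class `model_comparison`: `elpd_diff` (positive favors
#'   2PL), `se_diff`, `preferred` (`"rasch"`, `"2pl"` or `"equivalent"`),
#'   `pointwise` (per-person differences).
#' @export
compare_rasch_2pl <- function(data, folds = 5L, seed = NULL, n_quad = 61L,
                              shrink_slopes = TRUE) {
  stopifnot(inherits(data, "response_matrix"), folds >= 2)
  n <- n_persons(data)
  if (n < 2 * folds) stop("not enough persons for ", folds, " folds")
  if (!is.null(seed)) set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))
  quad <- gh_normal(n_quad)
  diff_pt <- numeric(n)
  for (f in seq_len(folds)) {
    train <- subset_response_matrix(data, persons = which(fold_id != f))
    if (isTRUE(shrink_slopes)) {
      f2 <- suppressWarnings(fit_2pl(train, n_quad = n_quad))
      if (f2$n_iter >= 500)
        stop("calibration did not converge in fold ", f, "; comparison aborted")
      ids <- f2$bank$item_id
      Yh <- data$responses[fold_id == f, ids, drop = FALSE]
      Yt <- train$responses[, ids, drop = FALSE]
      sh <- shrink_slopes_eb(f2$bank$discrimination, f2$slope_se)
      # rasch side: common slope (free latent scale); 2pl side: pooled slopes
      a_r <- rep(exp(mean(log(f2$bank$discrimination))), length(ids))
      c0_r <- em_intercepts(Yt, -f2$bank$difficulty * a_r, a_r, quad)
      c0_2 <- em_intercepts(Yt, -f2$bank$difficulty * sh, sh, quad)
      lpd_r <- marginal_log_density(Yh, -c0_r / a_r, a_r, quad)
      lpd_2 <- marginal_log_density(Yh, -c0_2 / sh, sh, quad)
    } else {
      fr <- suppressWarnings(fit_rasch(train, n_quad = n_quad))
      f2 <- suppressWarnings(fit_2pl(train, n_quad = n_quad))
      if (!fr$converged || f2$n_iter >= 500)
        stop("calibration did not converge in fold ", f, "; comparison aborted")
      ids <- intersect(fr$bank$item_id, f2$bank$item_id)
      Yh <- data$responses[fold_id == f, ids, drop = FALSE]
      br <- bank_subset(fr$bank, ids)
      b2 <- bank_subset(f2$bank, ids)
      lpd_r <- marginal_log_density(Yh, br$difficulty, br$discrimination, quad)
      lpd_2 <- marginal_log_density(Yh, b2$difficulty, b2$discrimination, quad)
    }
    diff_pt[fold_id == f] <- lpd_2 - lpd_r
  }
  elpd_diff <- sum(diff_pt)
  se_diff <- sqrt(n * stats::var(diff_pt))
  preferred <- if (abs(elpd_diff) <= 2 * se_diff) "equivalent"
    else if (elpd_diff > 0) "2pl" else "rasch"
  structure(list(elpd_diff = elpd_diff, se_diff = se_diff,
                 preferred = preferred, pointwise = diff_pt, folds = folds),
            class = "model_comparison")
}

# empirical-Bayes partial pooling of 2PL slopes on the log scale:
# log a_j ~ N(mu, tau^2), tau^2 by the method of moments, but set to 0
# unless the homogeneity chi-square rejects at `gate` (heterogeneity must
# be supported by the data before the slopes are allowed to differ)
shrink_slopes_eb <- function(a, se_a, gate = 0.01) {
  la <- log(a)
  se_la <- se_a / a
  mu <- mean(la)
  Q <- sum(((la - mu) / se_la)^2)
  if (Q < stats::qchisq(1 - gate, length(la) - 1)) return(rep(exp(mu), length(a)))
  tau2 <- max(0, stats::var(la) - mean(se_la^2))
  w <- tau2 / (tau2 + se_la^2)
  exp(mu + w * (la - mu))
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> ELPD(2PL) - ELPD(Rasch) = %.2f (SE %.2f): %s\n",
              x$elpd_diff, x$se_diff, x$preferred))
  invisible(x)
}

#' Differential item functioning screen
#'
#' Calibrates the Rasch model separately in the two person groups, aligns
#' the two difficulty scales by equating their means over the shared item
#' set, and flags items whose 95% Wald intervals in the two groups do not
#' overlap.
#'
#' @param data a [response_matrix()] whose `group` has exactly two levels,
#'   each with at least 2 persons.
#' @param subset optional item ids to screen (default all).
#' @param conf_level interval coverage (default 0.95).
#' @return list of class `dif_report`: `table` (item_id, group, difficulty,
#'   ci_low, ci_high), `flagged` (item ids), `untested` (items degenerate in
#'   at least one group), `shift` (scale alignment applied to group 2).
#' @export
dif_analysis <- function(data, subset = NULL, conf_level = 0.95) {
  stopifnot(inherits(data, "response_matrix"))
  g <- data$group
  if (is.null(g)) stop("data has no group variable")
  lev <- sort(unique(g))
  if (length(lev) != 2)
    stop("need exactly 2 groups, found ", length(lev))
  if (any(table(g) < 2))
    stop("each group needs at least 2 persons")
  subset <- subset %||% colnames(data$responses)
  fits <- lapply(lev, function(l)
    suppressWarnings(fit_rasch(subset_response_matrix(
      data, persons = which(g == l), items = subset))))
  shared <- intersect(fits[[1]]$bank$item_id, fits[[2]]$bank$item_id)
  if (length(shared) < 2) stop("fewer than 2 items estimable in both groups")
  b1 <- bank_subset(fits[[1]]$bank, shared)
  b2 <- bank_subset(fits[[2]]$bank, shared)
  shift <- mean(b1$difficulty) - mean(b2$difficulty)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- rbind(
    data.frame(item_id = shared, group = lev[1], difficulty = b1$difficulty,
               se = b1$difficulty_se, stringsAsFactors = FALSE),
    data.frame(item_id = shared, group = lev[2],
               difficulty = b2$difficulty + shift,
               se = b2$difficulty_se, stringsAsFactors = FALSE))
  tab$ci_low <- tab$difficulty - z * tab$se
  tab$ci_high <- tab$difficulty + z * tab$se
  lo1 <- tab$ci_low[tab$group == lev[1]]; hi1 <- tab$ci_high[tab$group == lev[1]]
  lo2 <- tab$ci_low[tab$group == lev[2]]; hi2 <- tab$ci_high[tab$group == lev[2]]
  flagged <- shared[lo1 > hi2 | lo2 > hi1]
  structure(list(table = tab, flagged = flagged,
                 untested = setdiff(subset, shared), shift = shift,
                 groups = lev, conf_level = conf_level),
            class = "dif_report")
}

#' @export
print.dif_report <- function(x, ...) {
  cat("<dif_report> groups ", paste(x$groups, collapse = " vs "), "; ",
      length(x$flagged), " flagged of ",
      length(unique(x$table$item_id)), " tested\n", sep = "")
  if (length(x$flagged)) cat("  flagged: ", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Three-step item pool construction
#'
#' Orchestrates the full pipeline on a calibration data set:
#' \enumerate{
#'   \item Rasch calibration, Infit/Outfit computation, and exclusion of
#'     items outside the fit cut-offs (default 0.7/1.3).
#'   \item Modification indices on the filtered pool, consensus
#'     simulated-annealing selection at each candidate size, and a
#'     cross-validated Rasch-vs-2PL comparison per size; the final size is
#'     the largest at which the Rasch model is not beaten by the 2PL.
#'   \item DIF screening of the selected subset (when a group variable is
#'     present); flagged items are dropped.
#' }
#' Difficulties of the surviving items are recalibrated on the full sample
#' before the bank is returned.
#'
#' @param data a [response_matrix()].
#' @param sizes candidate pool sizes for step 2 (any order).
#' @param lower,upper fit cut-offs for step 1.
#' @param weights,schedule step-2 objective weights and annealing schedule.
#' @param restarts annealing restarts per size for the consensus vote.
#' @param folds cross-validation folds for the model comparison.
#' @param dif run the DIF screen (default: whenever `data$group` exists).
#' @param seed master seed; all stage seeds are derived from it.
#' @return list of class `pool_report`: `bank` (final recalibrated
#'   [item_bank()]), `step1`, `step2`, `step3` stage records, `seed`.
#' @export
build_pool <- function(data, sizes, lower = 0.7, upper = 1.3,
                       weights = selection_weights(),
                       schedule = anneal_schedule(),
                       restarts = 20L, folds = 5L,
                       dif = !is.null(data$group), seed = 1L) {
  # Step 1: fit screen
  fit <- suppressWarnings(fit_rasch(data))
  stats <- infit_outfit(fit, data, mod_index = FALSE)
  retained <- filter_by_fit(stats, lower, upper)
  excluded1 <- setdiff(stats$item_id, retained)
  if (length(retained) < max(sizes))
    stop("only ", length(retained), " items pass the fit screen; ",
         "largest requested size is ", max(sizes))
  # Step 2: refit on the filtered pool, MI, annealing per size, comparison
  data_f <- subset_response_matrix(data, items = retained)
  fit_f <- suppressWarnings(fit_rasch(data_f))
  stats_f <- infit_outfit(fit_f, data_f, mod_index = TRUE)
  sizes <- sort(unique(sizes))
  per_size <- lapply(seq_along(sizes), function(i) {
    sel <- sa_consensus_select(fit_f$bank, stats_f, sizes[i], weights,
                               schedule, restarts = restarts,
                               seed = seed + 1000L * i)
    cmp <- compare_rasch_2pl(subset_response_matrix(data, items = sel$chosen),
                             folds = folds, seed = seed + 7L)
    list(size = sizes[i], selection = sel, comparison = cmp)
  })
  ok <- vapply(per_size, function(s) s$comparison$preferred != "2pl", logical(1))
  if (any(ok)) {
    pick <- max(which(ok))
  } else {
    warning("2PL preferred at every candidate size; keeping the smallest")
    pick <- 1L
  }
  chosen <- per_size[[pick]]$selection$chosen
  # Step 3: DIF screen
  dif_report <- NULL
  dropped_dif <- character(0)
  if (isTRUE(dif)) {
    dif_report <- dif_analysis(data, subset = chosen)
    dropped_dif <- dif_report$flagged
    chosen <- setdiff(chosen, dropped_dif)
  }
  # final recalibration on the surviving pool
  final_fit <- suppressWarnings(fit_rasch(subset_response_matrix(data, items = chosen)))
  structure(list(bank = final_fit$bank,
                 final_fit = final_fit,
                 step1 = list(stats = stats, retained = retained,
                              excluded = excluded1,
                              cutoffs = c(lower = lower, upper = upper)),
                 step2 = list(stats = stats_f, per_size = per_size,
                              chosen_size = sizes[pick], chosen = per_size[[pick]]$selection$chosen),
                 step3 = list(report = dif_report, dropped = dropped_dif),
                 seed = seed),
            class = "pool_report")
}

#' @export
print.pool_report <- function(x, ...) {
  cat("<pool_report>\n")
  cat("  step 1: ", length(x$step1$excluded), " of ",
      nrow(x$step1$stats), " items excluded by fit cut-offs\n", sep = "")
  cat("  step 2: size ", x$step2$chosen_size, " selected\n", sep = "")
  cat("  step 3: ", length(x$step3$dropped), " item(s) dropped for DIF\n", sep = "")
  cat("  final pool: ", nrow(x$bank), " items\n", sep = "")
  invisible(x)
}

#' Write a selection report as JSON (with the per-item CSV mirror)
#'
#' @param report a `pool_report` from [build_pool()].
#' @param path output JSON path; a sibling `<path>_items.csv` holds the
#'   per-item step-1 table.
#' @export
write_pool_report <- function(report, path) {
  stopifnot(inherits(report, "pool_report"))
  out <- list(
    seed = report$seed,
    step1 = list(cutoffs = as.list(report$step1$cutoffs),
                 n_excluded = length(report$step1$excluded),
                 excluded = report$step1$excluded),
    step2 = list(chosen_size = report$step2$chosen_size,
                 sizes = lapply(report$step2$per_size, function(s)
                   list(size = s$size,
                        objective = round6(s$selection$objective_value),
                        elpd_diff = round6(s$comparison$elpd_diff),
                        se_diff = round6(s$comparison$se_diff),
                        preferred = s$comparison$preferred))),
    step3 = list(dropped = report$step3$dropped),
    final_pool = report$bank$item_id)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_fit_stats(report$step1$stats, sub("\\.json$", "_items.csv", path),
                  report$step1$cutoffs["lower"], report$step1$cutoffs["upper"])
  invisible(path)
}
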