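#' Configuration for an adaptive session
#'
#' @param se_threshold stop once the ability standard error falls to or
#'   below this value (logits); typical choices are 0.3, 0.4 or 0.5. A
#'   threshold of 0.2 usually exhausts an 89-item pool before it is
#'   reached.
#' @param max_items optional hard cap on the number of administered items
#'   (default: the whole pool).
#' @param seed optional seed applied at session start (relevant for
#'   stochastic responders).
#' @return list of class `cat_config`.
#' @export
cat_config <- function(se_threshold = 0.4, max_items = Inf, seed = NULL) {
  stopifnot(se_threshold > 0, max_items >= 1)
  structure(list(se_threshold = se_threshold, max_items = max_items,
                 seed = seed), class = "cat_config")
}

#' Provisional ability during an adaptive session
#'
#' Before any response the ability is the scale origin 0. While the
#' response pattern is uniform the maximum likelihood estimate diverges and
#' the conventional values -10 (all "no") / +10 (all "yes") are used. Once
#' the pattern is mixed, estimation is delegated to
#' [estimate_ability_ml()].
#'
#' @param responses 0/1 responses so far (may be empty).
#' @param items [item_bank()] rows for the administered items, aligned with
#'   `responses`.
#' @return an `ability_estimate`.
#' @export
provisional_ability <- function(responses, items) {
  if (length(responses) == 0) return(ability_estimate(0, Inf, "convention"))
  estimate_ability_ml(responses, items)
}

#' Nearest-difficulty item selection
#'
#' Returns the unadministered item whose difficulty is closest to the
#' current ability — for a Rasch-calibrated bank this is the maximum
#' (Fisher) information criterion. Equidistant candidates are resolved
#' toward the lower difficulty, then by bank order. When every item has
#' been used the function returns `NULL` (a distinct exhaustion signal, not
#' an error).
#'
#' @param bank an [item_bank()].
#' @param administered item ids already used.
#' @param theta current ability (logits, finite).
#' @return a one-row item data.frame, or `NULL` when the pool is exhausted.
#' @export
next_item <- function(bank, administered, theta) {
  if (!is.finite(theta)) stop("theta must be finite")
  free <- !(bank$item_id %in% administered)
  if (!any(free)) return(NULL)
  cand <- which(free)
  d <- abs(bank$difficulty[cand] - theta)
  pick <- cand[order(d, bank$difficulty[cand], cand)][1]
  as.data.frame(bank)[pick, , drop = FALSE]
}

new_cat_session <- function(administered, responses, trajectory, final,
                            stop_reason, config) {
  structure(list(administered = administered, responses = responses,
                 trajectory = trajectory, final = final,
                 stop_reason = stop_reason, config = config),
            class = "cat_session")
}

#' @export
print.cat_session <- function(x, ...) {
  cat(sprintf("<cat_session> %d items, theta = %.3f (se %.3f), stopped: %s\n",
              length(x$responses), x$final$theta, x$final$se, x$stop_reason))
  invisible(x)
}

#' Run one adaptive session
#'
#' Loops provisional ability -> nearest-difficulty item -> response ->
#' update until the ability standard error reaches the threshold, the pool
#' is exhausted, or `max_items` is hit. The stopping rule is only evaluated
#' once the maximum likelihood estimate is finite; the conventional +/-10
#' abilities never terminate a session. The returned transcript carries
#' every administered item (id, word, difficulty), the response pattern,
#' and the full ability/SE trajectory.
#'
#' If the responder returns anything but 0 or 1 the session is aborted with
#' an error condition of class `cat_responder_error` whose `session` field
#' preserves the partial transcript.
#'
#' @param bank a calibrated [item_bank()].
#' @param responder function taking a one-row item data.frame and returning
#'   0 or 1.
#' @param config a [cat_config()].
#' @return a `cat_session`.
#' @export
run_session <- function(bank, responder, config = cat_config()) {
  stopifnot(inherits(bank, "item_bank"), is.function(responder))
  if (!is.null(config$seed)) set.seed(config$seed)
  admin <- character(0)
  responses <- integer(0)
  traj <- data.frame(theta = numeric(0), se = numeric(0),
                     method = character(0), stringsAsFactors = FALSE)
  est <- provisional_ability(integer(0), bank[0, , drop = FALSE])
  stop_reason <- NULL
  repeat {
    if (est$method == "ml" && est$se <= config$se_threshold) {
      stop_reason <- "se_reached"; break
    }
    if (length(admin) >= config$max_items) { stop_reason <- "max_items"; break }
    item <- next_item(bank, admin, est$theta)
    if (is.null(item)) { stop_reason <- "pool_exhausted"; break }
    resp <- responder(item)
    if (length(resp) != 1 || !(resp %in% c(0, 1))) {
      partial <- new_cat_session(bank_frame(bank, admin), responses, traj,
                                 est, "aborted", config)
      cond <- structure(class = c("cat_responder_error", "error", "condition"),
                        list(message = paste0("responder returned non-binary value for item '",
                                              item$item_id, "'"),
                             call = sys.call(), session = partial))
      stop(cond)
    }
    admin <- c(admin, item$item_id)
    responses <- c(responses, as.integer(resp))
    est <- provisional_ability(responses, bank_subset(bank, admin))
    traj <- rbind(traj, data.frame(theta = est$theta, se = est$se,
                                   method = est$method,
                                   stringsAsFactors = FALSE))
  }
  new_cat_session(bank_frame(bank, admin), responses, traj, est,
                  stop_reason, config)
}

bank_frame <- function(bank, ids) {
  if (!length(ids))
    return(data.frame(item_id = character(0), word = character(0),
                      difficulty = numeric(0), stringsAsFactors = FALSE))
  b <- as.data.frame(bank_subset(bank, ids))
  data.frame(item_id = b$item_id, word = b$word, difficulty = b$difficulty,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate adaptive sessions for Rasch responders
#'
#' For each true ability and replicate, draws responses
#' `y ~ Bernoulli(icc(theta_true, item))` and runs a full adaptive session,
#' then aggregates administration length and estimation error. Fully
#' reproducible given `seed`.
#'
#' @param bank a calibrated [item_bank()].
#' @param theta_true numeric vector of generating abilities.
#' @param config a [cat_config()].
#' @param n_replicates sessions per ability value.
#' @param seed RNG seed.
#' @return list of class `cat_simulation`: `summary` (per ability:
#'   mean items, bias, RMSE over sessions with finite ML estimates,
#'   n_convention), `sessions` (data.frame of per-session results).
#' @export
simulate_cat <- function(bank, theta_true, config = cat_config(),
                         n_replicates = 1L, seed = NULL) {
  stopifnot(n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", length(theta_true) * n_replicates)
  k <- 0L
  for (tt in theta_true) {
    for (r in seq_len(n_replicates)) {
      responder <- function(item) stats::rbinom(1, 1, icc(tt, item))
      s <- run_session(bank, responder, cat_config(config$se_threshold,
                                                   config$max_items))
      k <- k + 1L
      rows[[k]] <- data.frame(theta_true = tt, replicate = r,
                              theta_hat = s$final$theta, se = s$final$se,
                              method = s$final$method,
                              n_items = length(s$responses),
                              stop_reason = s$stop_reason,
                              stringsAsFactors = FALSE)
    }
  }
  sess <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(sess, sess$theta_true), function(d) {
    ml <- d[d$method == "ml", , drop = FALSE]
    data.frame(theta_true = d$theta_true[1],
               mean_items = mean(d$n_items),
               bias = mean(ml$theta_hat - ml$theta_true),
               rmse = sqrt(mean((ml$theta_hat - ml$theta_true)^2)),
               n_convention = sum(d$method == "convention"),
               n_sessions = nrow(d))
  }))
  rownames(agg) <- NULL
  structure(list(summary = agg, sessions = sess, config = config, seed = seed),
            class = "cat_simulation")
}

#' Write / read an adaptive-session transcript
#'
#' The JSON transcript mirrors the file a test taker downloads: final
#' ability and SE, the administered items (id, word, difficulty), the 0/1
#' response pattern, the stop reason and the session configuration. A CSV
#' flattening (one row per administered item with the running trajectory)
#' is available for tabular pipelines.
#'
#' @param session a `cat_session`.
#' @param path output path (`.json` or `.csv`).
#' @export
write_cat_session <- function(session, path) {
  stopifnot(inherits(session, "cat_session"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- cbind(session$administered,
                response = session$responses,
                theta = session$trajectory$theta,
                se = session$trajectory$se)
    write_table6(df, path)
  } else {
    out <- list(theta = session$final$theta,
                se = if (is.finite(session$final$se)) session$final$se else NULL,
                method = session$final$method,
                items = lapply(seq_len(nrow(session$administered)), function(i)
                  list(item_id = session$administered$item_id[i],
                       word = session$administered$word[i],
                       difficulty = round6(session$administered$difficulty[i]))),
                responses = session$responses,
                stop_reason = session$stop_reason,
                config = list(se_threshold = session$config$se_threshold,
                              max_items = if (is.finite(session$config$max_items))
                                session$config$max_items else NULL))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
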