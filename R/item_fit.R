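#' Infit and Outfit mean-square item-fit statistics
#'
#' Wright–Masters mean squares computed at the point estimates of a fitted
#' model: with `P_pi = icc(theta_p, item_i)` the squared standardized
#' residual of person p on item i is `z2 = (y - P)^2 / (P (1 - P))`. Outfit
#' is the plain mean of `z2` over persons; Infit weights the squared raw
#' residuals by item information `P (1 - P)`:
#' `infit_i = sum (y - P)^2 / sum P (1 - P)`. Both have expectation ~1 when
#' the model holds; Outfit reacts more strongly to surprising responses from
#' persons far from the item's difficulty.
#'
#' With `method = "posterior"` (the default) the squared standardized
#' residual is averaged over each person's ability posterior from the
#' marginal fit instead of being evaluated at the EAP point; the point
#' plug-in shrinks abilities toward 0 and biases both mean squares a few
#' percent below 1, whereas the posterior expectation is calibrated at 1
#' under the model. `method = "point"` gives the plug-in version (with
#' probabilities clamped to `[1e-10, 1 - 1e-10]`, warning when the clamp
#' binds).
#'
#' @param fit an `irt_fit` produced on `data`.
#' @param data the [response_matrix()] the model was fitted to.
#' @param mod_index also compute modification indices (slower); default TRUE
#'   when the fit is Rasch.
#' @param method `"posterior"` or `"point"` (see above).
#' @return data.frame of class `item_fit_stats`: `item_id`, `infit`,
#'   `outfit` and (for Rasch fits with `mod_index = TRUE`) `mod_index`.
#' @export
infit_outfit <- function(fit, data, mod_index = fit$model == "rasch",
                         method = c("posterior", "point")) {
  stopifnot(inherits(fit, "irt_fit"), inherits(data, "response_matrix"))
  method <- match.arg(method)
  ids <- fit$bank$item_id
  if (!all(ids %in% colnames(data$responses)))
    stop("fit and data item ids do not match")
  if (!identical(fit$abilities$person_id, rownames(data$responses)))
    stop("fit and data person ids do not match")
  Y <- data$responses[, ids, drop = FALSE]
  a <- fit$bank$discrimination
  if (method == "posterior") {
    es <- irt_estep(Y, 1L - Y, fit$bank$difficulty, a, fit$quad)
    pj <- es$p                                  # J x Q node probabilities
    # E_post[(y - P)^2 / (P(1-P))] = y E[(1-P)/P] + (1-y) E[P/(1-P)]
    z2 <- Y * (es$post %*% t((1 - pj) / pj)) +
      (1L - Y) * (es$post %*% t(pj / (1 - pj)))
    EP <- es$post %*% t(pj)
    EP2 <- es$post %*% t(pj^2)
    num <- Y * (1 - 2 * EP + EP2) + (1L - Y) * EP2   # E[(y - P)^2]
    den <- EP - EP2                                  # E[P(1-P)]
    out <- data.frame(item_id = ids,
                      infit = colSums(num) / colSums(den),
                      outfit = colMeans(z2),
                      stringsAsFactors = FALSE)
  } else {
    theta <- fit$abilities$theta
    # P[p, i] = plogis(a_i * (theta_p - alpha_i))
    P <- stats::plogis(sweep(outer(theta, fit$bank$difficulty, "-"), 2, a, "*"))
    if (any(P < 1e-10 | P > 1 - 1e-10)) {
      warning("response probabilities clamped away from 0/1")
      P <- pmin(pmax(P, 1e-10), 1 - 1e-10)
    }
    R2 <- (Y - P)^2
    W <- P * (1 - P)
    out <- data.frame(item_id = ids,
                      infit = colSums(R2) / colSums(W),
                      outfit = colMeans(R2 / W),
                      stringsAsFactors = FALSE)
  }
  if (isTRUE(mod_index)) {
    if (fit$model != "rasch")
      stop("modification indices are defined for Rasch fits")
    out$mod_index <- modification_index(fit, data)
  }
  rownames(out) <- NULL
  class(out) <- c("item_fit_stats", "data.frame")
  out
}

#' Modification index for the equal-discrimination constraint
#'
#' Score (Lagrange-multiplier) statistic for freeing one item's
#' discrimination from the common Rasch value 1, evaluated at the Rasch
#' marginal ML estimates. The per-person score for item i's slope is the
#' posterior expectation `E[(y_i - P_i(theta)) * (theta - alpha_i)]`; its
#' variance is estimated after projecting out the difficulty scores, which
#' makes the statistic an efficient score test on the 1-df chi-square scale
#' and asymptotically equivalent to a likelihood-ratio refit with that
#' slope free. Larger values mean the common-slope constraint fits that
#' item worse (cf. dropping the item improves model fit).
#'
#' @inheritParams infit_outfit
#' @param item_id optional subset of items; default all items in the fit.
#' @return named numeric vector of chi-square-scale indices.
#' @export
modification_index <- function(fit, data, item_id = NULL) {
  stopifnot(inherits(fit, "irt_fit"))
  if (fit$model != "rasch") stop("modification indices require a Rasch fit")
  ids <- fit$bank$item_id
  if (!is.null(item_id)) {
    missing_ids <- setdiff(item_id, ids)
    if (length(missing_ids))
      stop("item not in fit (degenerate or unknown): ", missing_ids[1])
  }
  Y <- data$responses[fit$abilities$person_id, ids, drop = FALSE]
  quad <- fit$quad
  alpha <- fit$bank$difficulty
  es <- irt_estep(Y, 1L - Y, alpha, rep(1, length(alpha)), quad)
  # per-person scores wrt each difficulty (sign-free for projection purposes)
  Pbar <- es$post %*% t(es$p)                       # n x J
  T_alpha <- Y - Pbar
  # per-person scores wrt each slope a_j at a_j = 1:
  #   E_post[(y - P(theta)) (theta - alpha_j)]
  Ex <- as.vector(es$post %*% quad$x)
  ExP <- sweep(es$post, 2, quad$x, "*") %*% t(es$p) # E[theta P_j(theta)]
  S_a <- Y * Ex - ExP - sweep(T_alpha, 2, alpha, "*")
  # efficient score: project slope scores on the difficulty score space
  qr_t <- qr(T_alpha)
  resid <- qr.resid(qr_t, S_a)
  num <- colSums(S_a)^2
  den <- colSums(resid^2)
  mi <- num / pmax(den, 1e-12)
  names(mi) <- ids
  if (!is.null(item_id)) mi <- mi[as.character(item_id)]
  mi
}

#' Fit-based item filter
#'
#' Retains items whose Infit *and* Outfit both lie inside the closed
#' interval `[lower, upper]`; the conventional cut-offs 0.7 and 1.3 are the
#' defaults, and boundary values are kept (only values strictly below/above
#' the cut-offs are excluded).
#'
#' @param stats an `item_fit_stats` data.frame (from [infit_outfit()]).
#' @param lower,upper mean-square cut-offs, `0 < lower < upper`.
#' @return character vector of retained `item_id`s.
#' @export
filter_by_fit <- function(stats, lower = 0.7, upper = 1.3) {
  if (!nrow(stats)) stop("empty fit statistics")
  if (!(lower > 0 && lower < upper)) stop("need 0 < lower < upper")
  keep <- stats$infit >= lower & stats$infit <= upper &
    stats$outfit >= lower & stats$outfit <= upper
  stats$item_id[keep]
}

#' Write per-item fit statistics with the retained flag
#'
#' @param stats an `item_fit_stats` data.frame.
#' @param path output CSV path.
#' @param lower,upper cut-offs passed to [filter_by_fit()].
#' @export
write_fit_stats <- function(stats, path, lower = 0.7, upper = 1.3) {
  kept <- filter_by_fit(stats, lower, upper)
  df <- as.data.frame(stats)
  if (is.null(df$mod_index)) df$mod_index <- NA_real_
  df$retained <- as.integer(df$item_id %in% kept)
  write_table6(df[c("item_id", "infit", "outfit", "mod_index", "retained")],
               path)
  invisible(path)
}
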