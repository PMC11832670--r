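#' Item characteristic curve
#'
#' Probability of a positive response as a function of latent ability,
#' `P(theta) = logistic(a * (theta - alpha))` with difficulty `alpha` and
#' discrimination `a` (1 under the Rasch model). The curve is strictly
#' increasing in `theta` and passes through 0.5 at `theta = alpha`.
#'
#' @param theta ability value(s), logits; must be finite.
#' @param item a single item: one row of an [item_bank()] or any list with
#'   `difficulty` and (optionally) `discrimination`.
#' @return probabilities in (0, 1), one per element of `theta`.
#' @examples
#' icc(1, list(difficulty = 0))            # 0.731...
#' icc(0.3, list(difficulty = 0.3))        # exactly 0.5
#' @export
icc <- function(theta, item) {
  if (!all(is.finite(theta))) stop("theta must be finite")
  a <- item$discrimination %||% 1
  if (is.na(a)) a <- 1
  if (a <= 0) stop("discrimination must be positive")
  stats::plogis(a * (theta - item$difficulty))
}

# ---- marginal (MML) machinery ----------------------------------------------

# log P and log(1-P) at the quadrature nodes; items in rows, nodes in columns
node_logprobs <- function(alpha, a, quad) {
  eta <- outer(a, quad$x) - a * alpha          # J x Q: a_j * (x_q - alpha_j)
  list(eta = eta,
       p = stats::plogis(eta),
       lp = stats::plogis(eta, log.p = TRUE),
       lq = stats::plogis(-eta, log.p = TRUE))
}

# E-step: posterior over nodes per person + marginal log-likelihood
irt_estep <- function(Y, Yc, alpha, a, quad) {
  np <- node_logprobs(alpha, a, quad)
  ll <- Y %*% np$lp + Yc %*% np$lq             # n x Q (J x Q logprob blocks)
  llw <- sweep(ll, 2, log(quad$w), "+")
  mx <- apply(llw, 1L, max)
  w <- exp(llw - mx)
  denom <- rowSums(w)
  list(post = w / denom, log_lik = sum(mx + log(denom)), p = np$p)
}

drop_degenerate <- function(Y) {
  cs <- colSums(Y)
  degen <- cs == 0L | cs == nrow(Y)
  list(Y = Y[, !degen, drop = FALSE], excluded = colnames(Y)[degen])
}

eap_abilities <- function(post, quad, person_ids) {
  theta <- as.vector(post %*% quad$x)
  v <- as.vector(post %*% quad$x^2) - theta^2
  data.frame(person_id = person_ids, theta = theta,
             se = sqrt(pmax(v, 1e-12)), method = "eap",
             stringsAsFactors = FALSE)
}

# BHHH standard errors for item parameters from per-person marginal scores.
# score columns: for each item, d logL_p / d alpha_j = -a_j (y_pj - Pbar_pj)
marginal_scores_alpha <- function(Y, post, p, a) {
  Pbar <- post %*% t(p)                        # n x J
  sweep(Y - Pbar, 2, -a, "*")
}

bhhh_se <- function(S) {
  I <- crossprod(S)
  se <- tryCatch(sqrt(diag(solve(I))), error = function(e) NULL)
  if (is.null(se) || any(!is.finite(se))) se <- 1 / sqrt(diag(I))
  se
}

new_irt_fit <- function(model, bank, abilities, log_lik, converged,
                        n_iter, grad_norm, excluded, quad, n_capped = 0L) {
  structure(list(model = model, bank = bank, abilities = abilities,
                 log_lik = log_lik, converged = converged, n_iter = n_iter,
                 grad_norm = grad_norm,
                 n_excluded_degenerate = length(excluded),
                 excluded_items = excluded, quad = quad,
                 n_capped = n_capped),
            class = "irt_fit")
}

#' @export
print.irt_fit <- function(x, ...) {
  cat("<irt_fit> ", toupper(x$model), ", ", nrow(x$bank), " items, ",
      nrow(x$abilities), " persons\n", sep = "")
  cat(sprintf("  log-likelihood %.2f; %s after %d EM iterations\n",
              x$log_lik, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  if (x$n_excluded_degenerate)
    cat("  excluded ", x$n_excluded_degenerate, " degenerate item(s)\n", sep = "")
  invisible(x)
}

#' Fit a Rasch model by marginal maximum likelihood
#'
#' Item difficulties are estimated by Bock–Aitkin EM with Gauss–Hermite
#' quadrature over a standard-normal latent ability (the identification
#' convention: latent mean 0, variance 1, all discriminations 1). Person
#' abilities are returned as EAP estimates with posterior standard
#' deviations; per-item standard errors come from the outer-product
#' (BHHH) estimate of the marginal information matrix.
#'
#' Constant item columns carry no information about difficulty and are
#' excluded up front with a warning; their ids are reported in
#' `excluded_items`.
#'
#' @param data a [response_matrix()]
#' @param n_quad number of quadrature nodes (default 61).
#' @param max_iter,tol EM iteration cap and stopping tolerance on the
#'   largest absolute difficulty update (logits).
#' @return an object of class `irt_fit` with elements `bank`
#'   ([item_bank()]), `abilities` (data.frame person_id/theta/se/method),
#'   `log_lik`, `converged`, `n_iter`, `grad_norm`,
#'   `n_excluded_degenerate`, `excluded_items`.
#' @export
fit_rasch <- function(data, n_quad = 61L, max_iter = 500L, tol = 1e-6) {
  stopifnot(inherits(data, "response_matrix"))
  if (nrow(data$responses) < 2 || ncol(data$responses) < 2)
    stop("need at least 2 persons and 2 items")
  dd <- drop_degenerate(data$responses)
  if (length(dd$excluded))
    warning("excluding ", length(dd$excluded), " degenerate item(s): ",
            paste(utils::head(dd$excluded, 5), collapse = ", "))
  Y <- dd$Y
  if (ncol(Y) < 2) stop("fewer than 2 informative items remain")
  Yc <- 1L - Y
  quad <- gh_normal(n_quad)
  J <- ncol(Y)
  cs <- colSums(Y)
  # moment-style start: logit of proportion incorrect, inflated for the
  # latent variance (logistic-normal scaling)
  alpha <- -stats::qlogis(colMeans(Y)) * sqrt(1 + 1 / 1.7^2)
  a1 <- rep(1, J)
  conv <- FALSE
  it <- 0L
  es <- NULL
  for (it in seq_len(max_iter)) {
    es <- irt_estep(Y, Yc, alpha, a1, quad)
    nq <- colSums(es$post)
    alpha_new <- alpha
    for (k in 1:3) {                           # Newton refinement of M-step
      P <- stats::plogis(outer(-alpha_new, quad$x, "+"))
      u <- cs - as.vector(P %*% nq)
      info <- as.vector((P * (1 - P)) %*% nq)
      alpha_new <- alpha_new - u / info
    }
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol) { conv <- TRUE; break }
  }
  es <- irt_estep(Y, Yc, alpha, a1, quad)
  nq <- colSums(es$post)
  P <- stats::plogis(outer(-alpha, quad$x, "+"))
  grad <- max(abs(cs - as.vector(P %*% nq)))   # marginal score, infinity norm
  S <- marginal_scores_alpha(Y, es$post, es$p, a1)
  bank <- item_bank(data.frame(item_id = colnames(Y), difficulty = alpha,
                               discrimination = 1, difficulty_se = bhhh_se(S)),
                    model_tag = "rasch")
  new_irt_fit("rasch", bank, eap_abilities(es$post, quad, rownames(Y)),
              es$log_lik, conv && grad < nrow(Y) * 1e-4, it, grad,
              dd$excluded, quad)
}

#' Fit a two-parameter logistic (2PL) model by marginal maximum likelihood
#'
#' As [fit_rasch()], but each item additionally gets its own discrimination
#' (slope). Estimation uses the same EM scheme with a bivariate Newton
#' M-step per item in the slope–intercept parametrization, in which the
#' expected complete-data log-likelihood is concave. Discrimination
#' estimates are capped to `a_range`; a binding cap is reported with a
#' warning, not silently accepted.
#'
#' @inheritParams fit_rasch
#' @param a_range admissible discrimination interval (default `c(0.05, 10)`).
#' @return an `irt_fit`; `bank` has per-item `discrimination`.
#' @export
fit_2pl <- function(data, n_quad = 61L, max_iter = 500L, tol = 1e-6,
                    a_range = c(0.05, 10)) {
  stopifnot(inherits(data, "response_matrix"))
  if (nrow(data$responses) < 2 || ncol(data$responses) < 2)
    stop("need at least 2 persons and 2 items")
  dd <- drop_degenerate(data$responses)
  if (length(dd$excluded))
    warning("excluding ", length(dd$excluded), " degenerate item(s): ",
            paste(utils::head(dd$excluded, 5), collapse = ", "))
  Y <- dd$Y
  if (ncol(Y) < 2) stop("fewer than 2 informative items remain")
  if (nrow(Y) < 2 * ncol(Y))
    warning("fewer persons than twice the number of items; ",
            "2PL slopes may be poorly determined")
  Yc <- 1L - Y
  quad <- gh_normal(n_quad)
  J <- ncol(Y)
  x <- quad$x
  # slope-intercept parametrization: logit P = c0 + c1 * x
  c1 <- rep(1, J)
  c0 <- stats::qlogis(colMeans(Y)) * sqrt(1 + 1 / 1.7^2)
  conv <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    es <- irt_estep(Y, Yc, -c0 / c1, c1, quad)
    nq <- colSums(es$post)
    R <- crossprod(Y, es$post)                 # J x Q expected correct
    c0_old <- c0; c1_old <- c1
    for (k in 1:3) {
      P <- stats::plogis(outer(c0, rep(1, length(x))) + outer(c1, x))
      E <- R - sweep(P, 2, nq, "*")
      W <- sweep(P * (1 - P), 2, nq, "*")
      g0 <- rowSums(E)
      g1 <- as.vector(E %*% x)
      h00 <- rowSums(W)
      h01 <- as.vector(W %*% x)
      h11 <- as.vector(W %*% x^2)
      det <- pmax(h00 * h11 - h01^2, 1e-12)
      c0 <- c0 + (h11 * g0 - h01 * g1) / det
      c1 <- c1 + (-h01 * g0 + h00 * g1) / det
      c1 <- pmin(pmax(c1, a_range[1]), a_range[2])
    }
    delta <- max(abs(c(c0 - c0_old, c1 - c1_old)))
    if (delta < tol) { conv <- TRUE; break }
  }
  alpha <- -c0 / c1
  capped <- c1 <= a_range[1] + 1e-10 | c1 >= a_range[2] - 1e-10
  if (any(capped))
    warning(sum(capped), " discrimination estimate(s) at the cap ",
            sprintf("[%g, %g]", a_range[1], a_range[2]))
  es <- irt_estep(Y, Yc, alpha, c1, quad)
  nq <- colSums(es$post)
  R <- crossprod(Y, es$post)
  P <- stats::plogis(outer(c0, rep(1, length(x))) + outer(c1, x))
  E <- R - sweep(P, 2, nq, "*")
  grad <- max(abs(c(rowSums(E), as.vector(E %*% x))))
  # difficulty SEs by delta method on (c0, c1) with BHHH information
  S0 <- Y - es$post %*% t(P)                   # scores wrt c0
  S1 <- compute_s1(Y, es$post, P, x)           # scores wrt c1
  ses <- twopl_param_se(S0, S1, c0, c1)
  se_alpha <- ses$alpha
  bank <- item_bank(data.frame(item_id = colnames(Y), difficulty = alpha,
                               discrimination = c1, difficulty_se = se_alpha),
                    model_tag = "2pl")
  out <- new_irt_fit("2pl", bank, eap_abilities(es$post, quad, rownames(Y)),
                     es$log_lik, conv && !any(capped), it, grad, dd$excluded,
                     quad, n_capped = sum(capped))
  out$slope_se <- ses$slope
  out
}

# per-person marginal score wrt the slope c1 of item j:
#   E_post[ (y_pj - P_j(theta)) * theta ]
compute_s1 <- function(Y, post, P, x) {
  Ex <- as.vector(post %*% x)                  # posterior mean theta per person
  ExP <- sweep(post, 2, x, "*") %*% t(P)       # E_post[theta * P_j(theta)]
  Y * Ex - ExP
}

twopl_param_se <- function(S0, S1, c0, c1) {
  J <- length(c0)
  S <- cbind(S0, S1)                           # n x 2J
  I <- crossprod(S)
  V <- tryCatch(solve(I), error = function(e) NULL)
  se_a <- se_c1 <- numeric(J)
  for (j in seq_len(J)) {
    g <- c(-1 / c1[j], c0[j] / c1[j]^2)        # d alpha / d (c0, c1)
    if (is.null(V)) {
      v <- g[1]^2 / I[j, j] + g[2]^2 / I[J + j, J + j]
      v1 <- 1 / I[J + j, J + j]
    } else {
      Vj <- V[c(j, J + j), c(j, J + j)]
      v <- drop(t(g) %*% Vj %*% g)
      v1 <- Vj[2, 2]
    }
    se_a[j] <- sqrt(max(v, 0))
    se_c1[j] <- sqrt(max(v1, 0))
  }
  list(alpha = se_a, slope = se_c1)
}

# re-estimate the intercepts c0 (logit P = c0 + c1 x) with the slopes held
# fixed; used after empirical-Bayes slope shrinkage
em_intercepts <- function(Y, c0, c1, quad, max_iter = 100L, tol = 1e-6) {
  Yc <- 1L - Y
  for (it in seq_len(max_iter)) {
    es <- irt_estep(Y, Yc, -c0 / c1, c1, quad)
    nq <- colSums(es$post)
    R <- crossprod(Y, es$post)
    c0_old <- c0
    for (k in 1:2) {
      P <- stats::plogis(outer(c0, rep(1, length(quad$x))) + outer(c1, quad$x))
      E <- R - sweep(P, 2, nq, "*")
      W <- sweep(P * (1 - P), 2, nq, "*")
      c0 <- c0 + rowSums(E) / pmax(rowSums(W), 1e-12)
    }
    if (max(abs(c0 - c0_old)) < tol) break
  }
  c0
}

# ---- ability estimation -----------------------------------------------------

ability_estimate <- function(theta, se, method) {
  structure(list(theta = theta, se = se, method = method),
            class = "ability_estimate")
}

#' @export
print.ability_estimate <- function(x, ...) {
  cat(sprintf("<ability_estimate> theta = %.4f, se = %.4f (%s)\n",
              x$theta, x$se, x$method))
  invisible(x)
}

#' Maximum likelihood ability estimate for a fixed item set
#'
#' Maximizes `L(theta) = prod_i exp(y_i (theta - alpha_i)) /
#' (1 + exp(theta - alpha_i))` (with discriminations entering as slopes when
#' present) by damped Newton iteration; the log-likelihood is strictly
#' concave so the maximizer is unique whenever the response pattern is
#' mixed. For a uniform pattern the likelihood has no interior maximum and
#' the conventional ability is returned instead: -10 after all-"no", +10
#' after all-"yes", with `method = "convention"` and an infinite standard
#' error.
#'
#' @param responses 0/1 vector, one response per row of `items`.
#' @param items an [item_bank()] (or subset) aligned with `responses`.
#' @return an `ability_estimate`: `theta`, `se` (from the Fisher
#'   information at `theta`, see [ability_se()]), `method` (`"ml"` or
#'   `"convention"`).
#' @export
estimate_ability_ml <- function(responses, items) {
  if (length(responses) == 0) stop("empty response vector")
  if (length(responses) != nrow(items))
    stop("responses (", length(responses), ") and items (", nrow(items),
         ") differ in length")
  if (!all(responses %in% c(0, 1))) stop("responses must be 0/1")
  if (all(responses == 0)) return(ability_estimate(-10, Inf, "convention"))
  if (all(responses == 1)) return(ability_estimate(10, Inf, "convention"))
  alpha <- items$difficulty
  a <- items$discrimination %||% rep(1, length(alpha))
  a[is.na(a)] <- 1
  theta <- 0
  for (i in 1:200) {
    p <- stats::plogis(a * (theta - alpha))
    g <- sum(a * (responses - p))
    info <- sum(a^2 * p * (1 - p))
    step <- g / max(info, 1e-12)
    step <- max(min(step, 3), -3)              # damping far from the optimum
    theta <- theta + step
    if (abs(g) < 1e-12 || abs(step) < 1e-12) break
  }
  ability_estimate(theta, ability_se(theta, items), "ml")
}

#' Standard error of an ability estimate
#'
#' Square root of the inverse Fisher information of the (Rasch/2PL)
#' likelihood at `theta`: `1 / sqrt(sum a_i^2 P_i (1 - P_i))`. Adding items
#' can only increase information, so the value decreases weakly with test
#' length at fixed `theta`.
#'
#' @param theta ability, logits (finite scalar).
#' @param items an [item_bank()] or subset with at least one item.
#' @return positive scalar, logits.
#' @export
ability_se <- function(theta, items) {
  if (!is.finite(theta)) stop("theta must be finite")
  if (nrow(items) < 1) stop("need at least one item")
  alpha <- items$difficulty
  a <- items$discrimination %||% rep(1, length(alpha))
  a[is.na(a)] <- 1
  p <- stats::plogis(a * (theta - alpha))
  1 / sqrt(sum(a^2 * p * (1 - p)))
}

# predictive log density of complete response vectors under item parameters,
# integrating the latent ability over N(0,1) by quadrature (one value per row)
marginal_log_density <- function(Y, alpha, a, quad) {
  np <- node_logprobs(alpha, a, quad)
  ll <- Y %*% np$lp + (1L - Y) %*% np$lq
  row_logsumexp(sweep(ll, 2, log(quad$w), "+"))
}
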