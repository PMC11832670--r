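#' Kuder–Richardson formula 20
#'
#' Internal-consistency reliability for dichotomous items:
#' `KR20 = k/(k-1) * (1 - sum p_j (1 - p_j) / s2_X)`, with `p_j` the item
#' proportion-correct and `s2_X` the sample (n-1) variance of person total
#' scores. Invariant to person and item order; at most 1.
#'
#' @param data a [response_matrix()] with >= 2 items and non-constant total
#'   scores.
#' @return scalar reliability estimate.
#' @export
kr20 <- function(data) {
  stopifnot(inherits(data, "response_matrix"))
  Y <- data$responses
  k <- ncol(Y)
  if (k < 2) stop("KR-20 needs at least 2 items")
  s2 <- stats::var(rowSums(Y))
  if (s2 == 0) stop("total-score variance is zero")
  p <- colMeans(Y)
  (k / (k - 1)) * (1 - sum(p * (1 - p)) / s2)
}

#' Andrich (person-separation) reliability
#'
#' The proportion of observed ability-estimate variance not attributable to
#' estimation error: `(Var(theta_hat) - mean(se^2)) / Var(theta_hat)`,
#' floored at 0. Persons whose ability carries the `convention` tag (the
#' +/-10 pseudo-values assigned to uniform response patterns) are excluded,
#' since their placeholder values and infinite standard errors would
#' corrupt both terms.
#'
#' @param fit an `irt_fit`, or a data.frame of abilities with columns
#'   `theta`, `se` and optionally `method`.
#' @return scalar in `[0, 1)`.
#' @export
andrich_reliability <- function(fit) {
  ab <- if (inherits(fit, "irt_fit")) fit$abilities else as.data.frame(fit)
  if (!is.null(ab$method)) ab <- ab[ab$method != "convention", , drop = FALSE]
  ab <- ab[is.finite(ab$theta) & is.finite(ab$se), , drop = FALSE]
  if (nrow(ab) < 2) stop("need at least 2 persons with finite ability SEs")
  v <- stats::var(ab$theta)
  if (v == 0) stop("ability-estimate variance is zero")
  max(0, (v - mean(ab$se^2)) / v)
}

#' Reliability report for a response data set
#'
#' Convenience wrapper computing both indices on the same data: KR-20 from
#' the raw responses and Andrich reliability from a Rasch calibration.
#'
#' @param data a [response_matrix()].
#' @param fit optional pre-computed `irt_fit`; fitted on `data` when absent.
#' @return list of class `reliability_report` with `kr20`, `andrich`,
#'   `n_persons`, `n_items`.
#' @export
reliability_report <- function(data, fit = NULL) {
  fit <- fit %||% suppressWarnings(fit_rasch(data))
  structure(list(kr20 = kr20(data), andrich = andrich_reliability(fit),
                 n_persons = n_persons(data), n_items = nrow(fit$bank)),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> KR-20 = %.3f; Andrich = %.3f (%d persons, %d items)\n",
              x$kr20, x$andrich, x$n_persons, x$n_items))
  invisible(x)
}

#' @rdname reliability_report
#' @param report a `reliability_report`
#' @param path output JSON path
#' @export
write_reliability_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
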