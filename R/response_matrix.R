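#' Person-by-item binary response data
#'
#' Container for a complete persons x items matrix of dichotomous responses
#' (1 = "says the word" / correct, 0 = not), with optional person metadata.
#' Responses must be complete: missing values are rejected rather than
#' silently dropped, so any missingness handling happens explicitly upstream.
#'
#' @param responses matrix (or coercible) of 0/1 values, persons in rows.
#' @param person_ids,item_ids unique identifiers; default to the dimnames or
#'   to generated labels.
#' @param age optional numeric vector of ages in years (positive), one per
#'   person.
#' @param group optional person-level grouping factor (e.g. sex), used by
#'   [dif_analysis()].
#' @return An object of class `response_matrix`: a list with elements
#'   `responses` (integer matrix with person/item dimnames), `age`, `group`.
#' @examples
#' y <- matrix(c(1, 0, 1, 1, 0, 0), nrow = 3)
#' response_matrix(y, person_ids = c("a", "b", "c"), item_ids = c("i1", "i2"))
#' @export
response_matrix <- function(responses,
                            person_ids = rownames(responses),
                            item_ids = colnames(responses),
                            age = NULL, group = NULL) {
  responses <- as.matrix(responses)
  if (is.null(person_ids)) person_ids <- sprintf("p%04d", seq_len(nrow(responses)))
  if (is.null(item_ids)) item_ids <- sprintf("i%04d", seq_len(ncol(responses)))
  person_ids <- as.character(person_ids)
  item_ids <- as.character(item_ids)
  if (length(person_ids) != nrow(responses))
    stop("person_ids length (", length(person_ids), ") does not match ",
         nrow(responses), " rows")
  if (length(item_ids) != ncol(responses))
    stop("item_ids length (", length(item_ids), ") does not match ",
         ncol(responses), " columns")
  if (anyDuplicated(person_ids))
    stop("duplicate person_ids: ", person_ids[duplicated(person_ids)][1])
  if (anyDuplicated(item_ids))
    stop("duplicate item_ids: ", item_ids[duplicated(item_ids)][1])
  if (anyNA(responses))
    stop("responses contain missing values; the response matrix must be complete")
  bad <- which(!(responses %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(responses)) + 1
    j <- ((bad[1] - 1) %/% nrow(responses)) + 1
    stop("non-binary value '", responses[bad[1]], "' at person '",
         person_ids[i], "', item '", item_ids[j], "'")
  }
  storage.mode(responses) <- "integer"
  dimnames(responses) <- list(person_ids, item_ids)
  if (!is.null(age)) {
    age <- as.numeric(age)
    if (length(age) != nrow(responses))
      stop("age must have one value per person")
    if (any(is.finite(age) & age <= 0))
      stop("ages must be positive")
  }
  if (!is.null(group)) {
    group <- as.character(group)
    if (length(group) != nrow(responses))
      stop("group must have one value per person")
  }
  structure(list(responses = responses, age = age, group = group),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("<response_matrix> ", nrow(x$responses), " persons x ",
      ncol(x$responses), " items; ",
      sprintf("%.1f%% positive", 100 * mean(x$responses)), "\n", sep = "")
  if (!is.null(x$age))
    cat("  age: ", sprintf("%.1f-%.1f years", min(x$age), max(x$age)), "\n", sep = "")
  if (!is.null(x$group))
    cat("  groups: ", paste(names(table(x$group)), table(x$group),
                            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname response_matrix
#' @param x a `response_matrix`
#' @export
n_persons <- function(x) nrow(x$responses)

#' @rdname response_matrix
#' @export
n_items <- function(x) ncol(x$responses)

#' Subset a response matrix by persons and/or items
#'
#' @param x a `response_matrix`
#' @param persons,items indices or id vectors; default keeps all.
#' @return a `response_matrix`
#' @export
subset_response_matrix <- function(x, persons = NULL, items = NULL) {
  p <- persons %||% seq_len(nrow(x$responses))
  j <- items %||% seq_len(ncol(x$responses))
  response_matrix(x$responses[p, j, drop = FALSE],
                  age = x$age[if (is.character(p)) match(p, rownames(x$responses)) else p],
                  group = x$group[if (is.character(p)) match(p, rownames(x$responses)) else p])
}

#' Read / write the response-matrix CSV dialect
#'
#' The on-disk layout is one header row and the columns `person_id`, `age`,
#' `sex` (either may be empty) followed by one 0/1 column per item.
#'
#' @param path file path
#' @return `read_response_matrix()` returns a `response_matrix`.
#' @export
read_response_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("person_id", "age", "sex")
  if (!all(need %in% names(df)[1:3]))
    stop("expected leading columns person_id, age, sex in ", path)
  item_cols <- setdiff(names(df), need)
  if (!length(item_cols)) stop("no item columns in ", path)
  resp <- as.matrix(df[item_cols])
  num <- suppressWarnings(matrix(as.numeric(resp), nrow(resp)))
  bad <- which(is.na(num) | !(num %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(num)) + 1
    j <- ((bad[1] - 1) %/% nrow(num)) + 1
    stop("non-binary value '", resp[bad[1]], "' at person '",
         df$person_id[i], "', item '", item_cols[j], "' in ", path)
  }
  age <- suppressWarnings(as.numeric(df$age))
  if (all(is.na(age))) age <- NULL
  group <- df$sex
  if (all(!nzchar(group))) group <- NULL
  rm <- response_matrix(num, person_ids = df$person_id, item_ids = item_cols,
                        age = age, group = group)
  message(sprintf("read %d persons x %d items (%.1f%% yes) from %s",
                  n_persons(rm), n_items(rm), 100 * mean(rm$responses), path))
  rm
}

#' @rdname read_response_matrix
#' @param x a `response_matrix`
#' @export
write_response_matrix <- function(x, path) {
  stopifnot(inherits(x, "response_matrix"))
  df <- data.frame(person_id = rownames(x$responses),
                   age = if (is.null(x$age)) "" else round6(x$age),
                   sex = x$group %||% "",
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(x$responses, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
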