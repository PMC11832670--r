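WORD_TYPES <- c("noun", "verb", "adjective")

#' Calibrated item bank
#'
#' An ordered collection of items with word labels, word types and Rasch/2PL
#' parameters. Difficulties are on the logit scale of a standard-normal
#' latent ability; discrimination is fixed at 1 under the Rasch model.
#'
#' @param items data.frame with at least `item_id` and `difficulty`; optional
#'   `word`, `word_type` (`noun`/`verb`/`adjective` or NA), `discrimination`
#'   and `difficulty_se`.
#' @param model_tag `"rasch"` or `"2pl"`. Under `"rasch"` every
#'   discrimination must equal 1.
#' @return data.frame of class `item_bank` with the canonical column set and
#'   a `model_tag` attribute.
#' @export
item_bank <- function(items, model_tag = c("rasch", "2pl")) {
  model_tag <- match.arg(model_tag)
  items <- as.data.frame(items)
  if (!all(c("item_id", "difficulty") %in% names(items)))
    stop("items need at least item_id and difficulty columns")
  items$item_id <- as.character(items$item_id)
  if (anyDuplicated(items$item_id))
    stop("duplicate item_ids in bank: ",
         items$item_id[duplicated(items$item_id)][1])
  if (is.null(items$word)) items$word <- items$item_id
  if (is.null(items$word_type)) items$word_type <- NA_character_
  ok <- is.na(items$word_type) | items$word_type %in% WORD_TYPES
  if (!all(ok))
    stop("word_type must be one of ", paste(WORD_TYPES, collapse = "/"),
         "; got '", items$word_type[!ok][1], "'")
  if (is.null(items$discrimination)) items$discrimination <- 1
  if (any(!is.na(items$discrimination) & items$discrimination <= 0))
    stop("discriminations must be positive")
  if (model_tag == "rasch" && any(abs(items$discrimination - 1) > 1e-8))
    stop("model_tag 'rasch' requires all discriminations equal to 1")
  if (is.null(items$difficulty_se)) items$difficulty_se <- NA_real_
  if (!all(is.finite(items$difficulty))) stop("difficulties must be finite")
  out <- items[c("item_id", "word", "word_type", "difficulty",
                 "discrimination", "difficulty_se")]
  rownames(out) <- out$item_id
  structure(out, class = c("item_bank", "data.frame"), model_tag = model_tag)
}

#' @export
print.item_bank <- function(x, ...) {
  cat("<item_bank> ", nrow(x), " items (", attr(x, "model_tag"), ")\n", sep = "")
  cat(sprintf("  difficulty: [%.2f, %.2f] logits\n",
              min(x$difficulty), max(x$difficulty)))
  if (any(!is.na(x$word_type))) {
    tab <- table(x$word_type)
    cat("  word types: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Subset an item bank by item ids (order taken from `ids`)
#'
#' @param bank an [item_bank()]
#' @param ids item ids present in the bank
#' @return an `item_bank` with the requested items
#' @export
bank_subset <- function(bank, ids) {
  idx <- match(as.character(ids), bank$item_id)
  if (anyNA(idx)) stop("item_id not in bank: ", ids[is.na(idx)][1])
  item_bank(as.data.frame(bank)[idx, , drop = FALSE],
            model_tag = attr(bank, "model_tag"))
}

#' Read / write item banks (JSON or CSV)
#'
#' JSON banks are arrays of objects with fields `item_id`, `word`,
#' `word_type`, `difficulty`, `discrimination`, `difficulty_se`; the CSV
#' mirror uses identical column names. Format is chosen by file extension.
#'
#' @param path file path ending in `.json` or `.csv`
#' @param model_tag stored alongside (JSON) or inferred (`rasch` when all
#'   discriminations are 1).
#' @return `read_item_bank()` returns an `item_bank`.
#' @export
read_item_bank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.data.frame(obj)) {
      items <- obj
      tag <- NULL
    } else {
      items <- as.data.frame(obj$items)
      tag <- obj$model_tag
    }
  } else {
    items <- utils::read.csv(path)
    tag <- NULL
  }
  if (is.null(tag))
    tag <- if (is.null(items$discrimination) ||
               all(abs(items$discrimination - 1) < 1e-8)) "rasch" else "2pl"
  item_bank(items, model_tag = tag)
}

#' @rdname read_item_bank
#' @param bank an `item_bank`
#' @export
write_item_bank <- function(bank, path) {
  stopifnot(inherits(bank, "item_bank"))
  df <- as.data.frame(bank)
  df[] <- lapply(df, round6)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(model_tag = attr(bank, "model_tag"), items = df),
                         path, auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
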