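#' Item metadata
#'
#' Describes a set of questionnaire items: a unique short label, the construct
#' the item measures, and the admissible integer score range. The default
#' instrument set of [default_items()] covers the Three-Item Loneliness Scale
#' (`Ln1`--`Ln3`, scored 1--3), the PHQ-9 depression items (`PHQ1`--`PHQ9`,
#' scored 0--3) and the GAD-7 anxiety items (`GAD1`--`GAD7`, scored 0--3).
#'
#' @param item_id character vector of unique item labels.
#' @param construct character vector; one of `"loneliness"`, `"depression"`,
#'   `"anxiety"` per item.
#' @param min_score,max_score integer vectors of per-item score bounds, with
#'   `min_score < max_score`.
#' @return A data frame of class `item_metadata`.
#' @examples
#' it <- item_metadata(c("A", "B"), c("anxiety", "anxiety"), 0, 3)
#' @export
item_metadata <- function(item_id, construct, min_score, max_score) {
  item_id <- as.character(item_id)
  construct <- as.character(construct)
  df <- data.frame(item_id = item_id, construct = construct,
                   min_score = as.integer(min_score),
                   max_score = as.integer(max_score),
                   stringsAsFactors = FALSE)
  validate_item_metadata(df)
}

validate_item_metadata <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("item_id", "construct", "min_score", "max_score") %in% names(df)))
  if (anyDuplicated(df$item_id))
    stop("item_ids must be unique", call. = FALSE)
  bad <- setdiff(unique(df$construct), c("loneliness", "depression", "anxiety"))
  if (length(bad))
    stop("unknown construct(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(df$min_score >= df$max_score))
    stop("min_score must be < max_score for every item", call. = FALSE)
  class(df) <- c("item_metadata", "data.frame")
  df
}

#' @rdname item_metadata
#' @export
default_items <- function() {
  item_metadata(
    item_id = c(paste0("Ln", 1:3), paste0("PHQ", 1:9), paste0("GAD", 1:7)),
    construct = c(rep("loneliness", 3), rep("depression", 9), rep("anxiety", 7)),
    min_score = c(rep(1L, 3), rep(0L, 16)),
    max_score = rep(3L, 19))
}

#' Read or write item metadata as JSON
#'
#' @param path file path.
#' @param items an `item_metadata` data frame.
#' @return `read_item_metadata()` returns an `item_metadata` data frame.
#' @export
read_item_metadata <- function(path) {
  df <- jsonlite::fromJSON(path)
  validate_item_metadata(as.data.frame(df))
}

#' @rdname read_item_metadata
#' @export
write_item_metadata <- function(items, path) {
  jsonlite::write_json(as.data.frame(unclass(items)), path, pretty = TRUE)
  invisible(path)
}

#' Ordinal item response table
#'
#' Couples an integer response matrix (rows = respondents, columns = items)
#' with its item metadata. Missing entries are rejected: the estimation
#' pipeline assumes complete data (reject, never impute), and every entry must
#' lie within its item's score range.
#'
#' @param responses integer matrix or data frame, one column per item.
#' @param items an `item_metadata` data frame whose `item_id`s match the
#'   column names (columns are reordered to the metadata order).
#' @return An object of class `response_table` with elements `items`,
#'   `responses` (integer matrix with item_id column names) and `n`.
#' @examples
#' it <- default_items()
#' x <- matrix(1L, nrow = 4, ncol = 19, dimnames = list(NULL, it$item_id))
#' x[, 4:19] <- 0L
#' rt <- response_table(x, it)
#' @export
response_table <- function(responses, items) {
  items <- validate_item_metadata(items)
  responses <- as.matrix(responses)
  if (is.null(colnames(responses))) {
    if (ncol(responses) != nrow(items))
      stop("responses has ", ncol(responses), " columns but metadata lists ",
           nrow(items), " items", call. = FALSE)
    colnames(responses) <- items$item_id
  }
  missing_cols <- setdiff(items$item_id, colnames(responses))
  if (length(missing_cols))
    stop("responses lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  responses <- responses[, items$item_id, drop = FALSE]
  if (anyNA(responses))
    stop("missing values are not supported; remove incomplete rows upstream",
         call. = FALSE)
  storage.mode(responses) <- "integer"
  for (k in seq_len(nrow(items))) {
    v <- responses[, k]
    if (any(v < items$min_score[k] | v > items$max_score[k]))
      stop("item ", items$item_id[k], " has responses outside [",
           items$min_score[k], ", ", items$max_score[k], "]", call. = FALSE)
  }
  structure(list(items = items, responses = responses, n = nrow(responses)),
            class = "response_table")
}

#' @export
print.response_table <- function(x, ...) {
  cat("<response_table> ", x$n, " respondents x ", nrow(x$items), " items (",
      paste(table(x$items$construct)[c("loneliness", "depression", "anxiety")],
            c("loneliness", "depression", "anxiety"), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Read or write a response table as CSV/TSV
#'
#' The file must have a header row of item ids; the field separator is
#' inferred from the file extension (`.tsv` uses tab).
#'
#' @param path file path.
#' @param items item metadata to validate against.
#' @param data a `response_table`.
#' @export
read_response_table <- function(path, items) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  response_table(as.matrix(df), items)
}

#' @rdname read_response_table
#' @export
write_response_table <- function(data, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(data$responses, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Construct total scores and their descriptive statistics
#'
#' Sums each respondent's items within construct (loneliness 3--9, depression
#' 0--27, anxiety 0--21 for the default instruments), and summarises the
#' totals: mean, sample SD, min, max, and the 3x3 Pearson correlation matrix.
#'
#' @param data a `response_table` covering all three constructs.
#' @return A list of class `scale_scores` with `totals` (n x 3 matrix, columns
#'   `loneliness`, `depression`, `anxiety`), `summary` (data frame of mean, sd,
#'   min, max per construct) and `correlations` (3x3 matrix).
#' @export
compute_scale_scores <- function(data) {
  stopifnot(inherits(data, "response_table"))
  constructs <- c("loneliness", "depression", "anxiety")
  present <- constructs %in% data$items$construct
  if (!all(present))
    stop("no items for construct(s): ",
         paste(constructs[!present], collapse = ", "), call. = FALSE)
  totals <- sapply(constructs, function(g) {
    idx <- data$items$construct == g
    rowSums(data$responses[, idx, drop = FALSE])
  })
  if (data$n == 1L) totals <- matrix(totals, nrow = 1,
                                     dimnames = list(NULL, constructs))
  summ <- data.frame(
    construct = constructs,
    mean = colMeans(totals),
    sd = apply(totals, 2, stats::sd),
    min = apply(totals, 2, min),
    max = apply(totals, 2, max),
    row.names = NULL)
  # constant totals (degenerate but legal input) give NA correlations
  corr <- if (data$n >= 3) suppressWarnings(stats::cor(totals)) else
    matrix(NA_real_, 3, 3, dimnames = list(constructs, constructs))
  structure(list(totals = totals, summary = summ, correlations = corr),
            class = "scale_scores")
}

#' @export
print.scale_scores <- function(x, ...) {
  cat("<scale_scores>\n")
  print(x$summary, digits = 4)
  cat("correlations:\n")
  print(round(x$correlations, 3))
  invisible(x)
}
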