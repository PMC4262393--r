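#' Encode ordinal severity labels as integers
#'
#' Maps the four-point ordinal severity scale to integers for averaging:
#' Mild = 1, Moderate = 2, Severe = 3, Profound = 4. Matching is
#' case-insensitive. The mapping is fixed and not configurable.
#'
#' @param label character vector of severity labels.
#' @return integer vector in 1--4.
#' @examples
#' encode_severity_label(c("Mild", "profound"))
#' @export
encode_severity_label <- function(label) {
  lev <- severity_labels()
  idx <- match(tolower(label), tolower(lev))
  if (anyNA(idx)) {
    bad <- unique(label[is.na(idx)])
    stop("unknown severity label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  idx
}

#' Decode severity ordinals to labels
#'
#' Inverse of [encode_severity_label()].
#'
#' @param ordinal integer vector in 1--4.
#' @return character vector of labels.
#' @export
severity_label <- function(ordinal) {
  stopifnot(all(ordinal %in% 1:4))
  severity_labels()[ordinal]
}

#' Summarise respondent-level ratings per item
#'
#' Computes, for each rated item, the arithmetic mean, median (midpoint
#' convention for even counts), observed minimum and maximum, and the
#' number of contributing ratings. Respondents who skipped an item simply
#' contribute nothing to that item; there is no listwise deletion.
#'
#' @param records data frame with columns `respondent_id`, `item_id`,
#'   `value` (one row per rating).
#' @param items optional character vector of item ids that must be present;
#'   an item with no records is then an error.
#' @return data frame with columns `item_id`, `mean`, `median`, `min`,
#'   `max`, `n`, ordered by `items` when given, otherwise by first
#'   appearance.
#' @examples
#' rec <- data.frame(respondent_id = c("r1", "r2"),
#'                   item_id = "vision_impairment", value = c(2, 4))
#' aggregate_ratings(rec)
#' @export
aggregate_ratings <- function(records, items = NULL) {
  stopifnot(is.data.frame(records),
            all(c("respondent_id", "item_id", "value") %in% names(records)))
  if (!nrow(records)) stop("no rating records supplied", call. = FALSE)
  if (!is.numeric(records$value) || anyNA(records$value))
    stop("rating values must be non-missing numerics", call. = FALSE)
  found <- unique(records$item_id)
  if (is.null(items)) items <- found
  missing <- setdiff(items, found)
  if (length(missing))
    stop("no ratings for requested item(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  split_vals <- split(records$value, factor(records$item_id, levels = items))
  out <- data.frame(
    item_id = items,
    mean   = vapply(split_vals, mean, numeric(1)),
    median = vapply(split_vals, stats::median, numeric(1)),
    min    = vapply(split_vals, min, numeric(1)),
    max    = vapply(split_vals, max, numeric(1)),
    n      = vapply(split_vals, length, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

penetrance_options <- function() c(">0%", ">25%", ">50%", ">75%", "100%")

#' Distribution of penetrance-threshold responses
#'
#' Tabulates responses to the question of what fraction of affected
#' individuals should present a characteristic for it to count towards
#' disease severity. Percentages are computed against all respondents and
#' rounded half-up to one decimal for display.
#'
#' @param responses data frame with columns `respondent_id` and `option`;
#'   `option` must be one of `">0%"`, `">25%"`, `">50%"`, `">75%"`,
#'   `"100%"`.
#' @return data frame with columns `option`, `n`, `pct` (rounded to one
#'   decimal) and `is_mode` (`TRUE` for the most frequent option or
#'   options), one row per option in scale order.
#' @examples
#' resp <- data.frame(respondent_id = c("r1", "r2", "r3"),
#'                    option = c(">25%", ">25%", ">50%"))
#' penetrance_distribution(resp)
#' @export
penetrance_distribution <- function(responses) {
  stopifnot(is.data.frame(responses),
            all(c("respondent_id", "option") %in% names(responses)))
  if (!nrow(responses)) stop("no penetrance responses supplied", call. = FALSE)
  opts <- penetrance_options()
  bad <- setdiff(unique(responses$option), opts)
  if (length(bad))
    stop("unknown penetrance option(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  counts <- table(factor(responses$option, levels = opts))
  total <- sum(counts)
  out <- data.frame(
    option = opts,
    n = as.integer(counts),
    pct = round_half_up(100 * as.integer(counts) / total, 1),
    stringsAsFactors = FALSE
  )
  out$is_mode <- out$n == max(out$n)
  out
}

#' Read respondent-level ratings from CSV
#'
#' Expects a header row `respondent_id,item_id,value`, UTF-8 encoded.
#'
#' @param path file path.
#' @return data frame of rating records.
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("respondent_id", "item_id", "value")
  if (!all(need %in% names(df)))
    stop("ratings CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$value <- as.numeric(df$value)
  df
}

#' Read penetrance responses from CSV
#'
#' Expects a header row `respondent_id,option`.
#'
#' @param path file path.
#' @return data frame of penetrance responses.
#' @export
read_penetrance_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        check.names = FALSE)
  need <- c("respondent_id", "option")
  if (!all(need %in% names(df)))
    stop("penetrance CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' Write a rating summary table to CSV
#'
#' Emits the `item,mean,median,min,max,n` layout mirroring the survey
#' summary tables.
#'
#' @param summary data frame as returned by [aggregate_ratings()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_rating_summary_csv <- function(summary, path) {
  out <- summary[, c("item_id", "mean", "median", "min", "max", "n")]
  names(out)[1] <- "item"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
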