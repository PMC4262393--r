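#' Concordance between algorithmic classes and survey-derived groups
#'
#' Builds the 4x4 confusion matrix (predicted x reference, indexed
#' Mild..Profound) between the classifier's output and severity groups
#' obtained independently from per-disease survey ratings, and reports
#' simple agreement.
#'
#' @param predicted named character vector (or list of `severity_class`
#'   objects) of predicted labels, keyed by disease id.
#' @param reference named character vector of reference group labels,
#'   same key set.
#' @return An object of class `concordance_report`: list with `confusion`
#'   (4x4 integer matrix), `accuracy` (trace / total) and `mismatches`
#'   (data frame `disease_id`, `predicted`, `reference`, sorted by id).
#' @examples
#' ref <- load_reference_diseases()
#' panel <- classify_panel(reference_profiles())
#' rep <- concordance(stats::setNames(panel$per_disease$label,
#'                                    panel$per_disease$disease_id),
#'                    stats::setNames(ref$group, ref$disease_id))
#' rep$accuracy
#' @export
concordance <- function(predicted, reference) {
  if (is.list(predicted))
    predicted <- vapply(predicted, function(x)
      if (inherits(x, "severity_class")) x$label else as.character(x),
      character(1))
  if (is.null(names(predicted)) || is.null(names(reference)))
    stop("predicted and reference must be named by disease id", call. = FALSE)
  only_pred <- setdiff(names(predicted), names(reference))
  only_ref <- setdiff(names(reference), names(predicted))
  if (length(only_pred) || length(only_ref))
    stop("disease key sets differ; only in predicted: {",
         paste(only_pred, collapse = ", "), "}, only in reference: {",
         paste(only_ref, collapse = ", "), "}", call. = FALSE)
  reference <- reference[names(predicted)]
  lev <- severity_labels()
  stopifnot(all(predicted %in% lev), all(reference %in% lev))
  confusion <- table(factor(predicted, levels = lev),
                     factor(reference, levels = lev))
  confusion <- unclass(confusion)
  dimnames(confusion) <- list(predicted = lev, reference = lev)
  hit <- predicted == reference
  mism <- data.frame(disease_id = names(predicted)[!hit],
                     predicted = unname(predicted[!hit]),
                     reference = unname(reference[!hit]),
                     stringsAsFactors = FALSE)
  mism <- mism[order(mism$disease_id), , drop = FALSE]
  rownames(mism) <- NULL
  structure(list(confusion = confusion,
                 accuracy = sum(hit) / length(predicted),
                 mismatches = mism),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Concordance: accuracy %.3f (%d/%d)\n", x$accuracy,
              sum(diag(x$confusion)), sum(x$confusion)))
  print(x$confusion)
  if (nrow(x$mismatches)) {
    cat("Mismatches:\n")
    print(x$mismatches)
  }
  invisible(x)
}

#' Bootstrap stability of derived tiers
#'
#' Resamples respondents with replacement, re-derives the tier map from
#' each resample's mean ratings, and reports how often each characteristic
#' lands in each tier. The resampling unit is the respondent (whole
#' questionnaires), matching the survey design. Respondents are sorted
#' canonically before resampling so the result depends only on the data
#' and the seed, not on input row order.
#'
#' @param records respondent-level rating records (see
#'   [aggregate_ratings()]).
#' @param k number of tiers per replicate (default 4).
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @return matrix of frequencies, characteristics x tiers `1..k`; each row
#'   sums to 1. A degenerate replicate in which all item means coincide
#'   contributes a single-cluster (all Tier 1) assignment, with a notice.
#' @export
bootstrap_tier_stability <- function(records, k = 4, B, seed) {
  stopifnot(is.data.frame(records), B >= 1)
  respondents <- sort(unique(records$respondent_id))
  if (length(respondents) < 2L)
    stop("need at least 2 respondents to resample", call. = FALSE)
  items <- unique(records$item_id)
  by_resp <- split(records, records$respondent_id)
  freq <- matrix(0, nrow = length(items), ncol = k,
                 dimnames = list(items, paste0("tier", seq_len(k))))
  set.seed(seed)
  for (b in seq_len(B)) {
    draw <- sample(respondents, length(respondents), replace = TRUE)
    boot <- do.call(rbind, by_resp[draw])
    means <- as_mean_vector(aggregate_ratings(boot, items = items))
    if (length(unique(means)) == 1L) {
      message("bootstrap replicate ", b,
              ": all item means identical; single-cluster assignment")
      assign <- stats::setNames(rep(1L, length(items)), items)
    } else {
      assign <- ward_cut(ward_linkage(means), k)$assignment
    }
    for (it in items) freq[it, assign[[it]]] <- freq[it, assign[[it]]] + 1
  }
  freq / B
}
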