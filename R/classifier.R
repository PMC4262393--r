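#' Classifier configuration
#'
#' Bundles the tunable inputs of the severity decision algorithm: the
#' penetrance threshold below which a characteristic is ignored, whether
#' the comparison is inclusive, the tier map, and the reading of the
#' Severe rule's "three other Tier 2 or 3 characteristics".
#'
#' @param penetrance_threshold fraction in \[0, 1\]; characteristics shown
#'   by fewer affected individuals than this are excluded. Default 0.25.
#' @param threshold_inclusive if `TRUE` (default) a penetrance equal to the
#'   threshold passes ("at least 25\%"); if `FALSE` it must strictly
#'   exceed it.
#' @param tier_map a `tier_map`; defaults to the packaged assignment.
#' @param r3_others_tier3 alternative reading of the second Severe path:
#'   if `TRUE`, the three characteristics beyond the qualifying Tier 2 item
#'   must all be Tier 3; the default (`FALSE`) counts any mix of Tier 2
#'   and Tier 3 items towards the total of four.
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(penetrance_threshold = 0.25,
                              threshold_inclusive = TRUE,
                              tier_map = packaged_tier_map(),
                              r3_others_tier3 = FALSE) {
  stopifnot(is.numeric(penetrance_threshold),
            penetrance_threshold >= 0, penetrance_threshold <= 1,
            is.logical(threshold_inclusive),
            inherits(tier_map, "tier_map"),
            is.logical(r3_others_tier3))
  structure(list(penetrance_threshold = penetrance_threshold,
                 threshold_inclusive = threshold_inclusive,
                 tier_map = tier_map,
                 r3_others_tier3 = r3_others_tier3),
            class = "classifier_config")
}

#' Effective characteristic set of a disease
#'
#' Applies the penetrance filter and the modifier/Tier-4 exclusions, then
#' buckets the surviving characteristics by tier. A characteristic is
#' considered only if at least the configured fraction of affected
#' individuals show it (unspecified penetrance passes). The two severity
#' modifiers (availability of treatment, variable expressivity) and the
#' single Tier 4 characteristic (reduced fertility) never contribute to
#' classification.
#'
#' @param profile a validated [disease_profile()].
#' @param config a [classifier_config()].
#' @return An object of class `effective_traits`: list with character
#'   vectors `tier1`, `tier2`, `tier3` and a data frame `excluded`
#'   (`characteristic_id`, `reason` in `below_penetrance` / `modifier` /
#'   `tier4`).
#' @export
effective_characteristics <- function(profile, config = classifier_config()) {
  stopifnot(inherits(profile, "disease_profile"),
            inherits(config, "classifier_config"))
  tm <- config$tier_map
  ids <- profile$traits$characteristic_id
  pen <- profile$traits$penetrance
  no_tier <- setdiff(ids, names(tm$assignment))
  if (length(no_tier))
    stop("no tier assignment for characteristic(s): ",
         paste(no_tier, collapse = ", "), call. = FALSE)

  tiers <- list(tier1 = character(0), tier2 = character(0),
                tier3 = character(0))
  excluded <- data.frame(characteristic_id = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  drop <- function(id, reason)
    rbind(excluded, data.frame(characteristic_id = id, reason = reason,
                               stringsAsFactors = FALSE))
  for (i in seq_along(ids)) {
    id <- ids[i]
    passes <- is.na(pen[i]) ||
      (if (config$threshold_inclusive) pen[i] >= config$penetrance_threshold
       else pen[i] > config$penetrance_threshold)
    if (!passes) { excluded <- drop(id, "below_penetrance"); next }
    a <- tm$assignment[[id]]
    if (a == "modifier") {
      message("modifier characteristic '", id,
              "' ignored for classification")
      excluded <- drop(id, "modifier")
    } else if (a == "4") {
      excluded <- drop(id, "tier4")
    } else if (a %in% c("1", "2", "3")) {
      key <- paste0("tier", a)
      tiers[[key]] <- c(tiers[[key]], id)
    } else {
      stop("unsupported tier label '", a, "' for '", id, "'", call. = FALSE)
    }
  }
  structure(c(tiers, list(excluded = excluded)), class = "effective_traits")
}

#' Classify a disease into a severity class
#'
#' Evaluates the tiered decision rules in strict precedence over the
#' disease's effective characteristic set:
#' \itemize{
#'   \item R1 -- Profound: more than one Tier 1 characteristic.
#'   \item R2 -- Severe: exactly one Tier 1 characteristic.
#'   \item R3 -- Severe: no Tier 1, but a Tier 2 characteristic plus at
#'     least three other Tier 2 or Tier 3 characteristics.
#'   \item R4 -- Moderate: at least one Tier 2 or Tier 3 characteristic,
#'     but not Severe.
#'   \item R5 -- Mild: everything else.
#' }
#'
#' @param profile a [disease_profile()]; validated against the packaged
#'   vocabulary first unless `validate = FALSE`.
#' @param config a [classifier_config()].
#' @param validate run [validate_profile()] first (default `TRUE`).
#' @return An object of class `severity_class`: list with `label`,
#'   `ordinal` (Mild = 1 ... Profound = 4), `rule_trace` (character vector
#'   recording each rule evaluated and its outcome) and `effective`
#'   (the [effective_characteristics()] result).
#' @examples
#' profs <- reference_profiles()
#' classify_disease(profs[["canavan"]])$label  # "Profound"
#' @export
classify_disease <- function(profile, config = classifier_config(),
                             validate = TRUE) {
  if (validate) profile <- validate_profile(profile)
  eff <- effective_characteristics(profile, config)
  n1 <- length(eff$tier1); n2 <- length(eff$tier2); n3 <- length(eff$tier3)
  trace <- character(0)
  note <- function(rule, pass, why)
    c(trace, sprintf("%s:%s (%s)", rule, if (pass) "pass" else "fail", why))

  r1 <- n1 >= 2
  trace <- note("R1", r1, sprintf("|tier1|=%d", n1))
  if (r1) return(new_severity_class("Profound", trace, eff))

  r2 <- n1 == 1
  trace <- note("R2", r2, sprintf("|tier1|=%d", n1))
  if (r2) return(new_severity_class("Severe", trace, eff))

  r3 <- if (config$r3_others_tier3) n2 >= 1 && n3 >= 3
        else n2 >= 1 && (n2 + n3) >= 4
  trace <- note("R3", r3, sprintf("|tier2|=%d, |tier3|=%d", n2, n3))
  if (r3) return(new_severity_class("Severe", trace, eff))

  r4 <- (n2 + n3) >= 1
  trace <- note("R4", r4, sprintf("|tier2|+|tier3|=%d", n2 + n3))
  if (r4) return(new_severity_class("Moderate", trace, eff))

  trace <- note("R5", TRUE, "no qualifying characteristics")
  new_severity_class("Mild", trace, eff)
}

new_severity_class <- function(label, trace, effective) {
  structure(list(label = label,
                 ordinal = encode_severity_label(label),
                 rule_trace = trace,
                 effective = effective),
            class = "severity_class")
}

#' @export
print.severity_class <- function(x, ...) {
  cat(sprintf("<severity_class> %s (%d)\n", x$label, x$ordinal))
  cat(paste0("  ", x$rule_trace, "\n"), sep = "")
  invisible(x)
}

#' Classify a panel of diseases
#'
#' Applies [classify_disease()] to each profile and summarises how the
#' panel distributes over the four severity bins -- the per-bin fractions
#' a provider can quote when describing a screening panel.
#'
#' @param profiles list of [disease_profile()] objects.
#' @param config a [classifier_config()].
#' @param validate validate each profile first (default `TRUE`).
#' @return list with `per_disease` (data frame: `disease_id`, `label`,
#'   `ordinal`, `rule_id` of the rule that fired), `classes` (named list
#'   of full `severity_class` objects) and `summary` (data frame: `label`,
#'   `n`, `fraction` over the four bins; fractions sum to 1).
#' @export
classify_panel <- function(profiles, config = classifier_config(),
                           validate = TRUE) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  classes <- lapply(profiles, classify_disease, config = config,
                    validate = validate)
  ids <- vapply(profiles, function(p) p$disease_id, character(1))
  names(classes) <- ids
  fired <- vapply(classes, function(cl) {
    last <- cl$rule_trace[length(cl$rule_trace)]
    sub(":.*$", "", last)
  }, character(1))
  per_disease <- data.frame(
    disease_id = ids,
    label = vapply(classes, `[[`, character(1), "label"),
    ordinal = vapply(classes, `[[`, integer(1), "ordinal"),
    rule_id = fired,
    stringsAsFactors = FALSE, row.names = NULL
  )
  counts <- table(factor(per_disease$label, levels = severity_labels()))
  summary <- data.frame(label = severity_labels(),
                        n = as.integer(counts),
                        fraction = as.integer(counts) / length(ids),
                        stringsAsFactors = FALSE)
  list(per_disease = per_disease, classes = classes, summary = summary)
}
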