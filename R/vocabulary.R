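#' Controlled vocabulary of disease characteristics
#'
#' Returns the 15 clinical characteristics used to describe the untreated
#' natural course of an inherited disease, together with their packaged
#' importance-rating summaries (1--10 scale, 1 = least important) and tier
#' assignments. Thirteen characteristics describe disease progression
#' ("core"); two -- availability of treatment and variable expressivity --
#' are severity "modifiers" that are rated but excluded from classification.
#'
#' @return A data frame with one row per characteristic and columns
#'   `id` (stable snake-case token), `name` (display string), `category`
#'   (`"core"` or `"modifier"`), `lifespan_flag` (`TRUE` for the three
#'   shortened-life-span items), `tier` (`"1"`--`"4"` or `"modifier"`),
#'   `co_tier` (the tier the item co-clusters with, identical to `tier`
#'   for core items), and rating summary columns `mean`, `median`, `min`,
#'   `max`.
#' @examples
#' chars <- load_default_characteristics()
#' chars[chars$tier == "1", c("id", "mean")]
#' @export
load_default_characteristics <- function() {
  df <- utils::read.csv(extdata_path("characteristics.csv"),
                        stringsAsFactors = FALSE)
  df$tier <- as.character(df$tier)
  stopifnot(
    nrow(df) == 15L,
    !anyDuplicated(df$id),
    sum(df$category == "modifier") == 2L,
    sum(df$lifespan_flag) == 3L,
    all(df$min <= df$median & df$median <= df$max),
    all(df$min <= df$mean & df$mean <= df$max)
  )
  class(df) <- c("sev_characteristics", "data.frame")
  df
}

#' Packaged tier map
#'
#' The assignment of each characteristic to an importance tier, as shipped
#' with the package. Core characteristics map to Tiers 1--4; the two
#' modifiers carry their co-clustered tier for reporting but are never used
#' as Tier 1--4 items in classification.
#'
#' @param include_modifiers if `TRUE` (default) modifiers appear in the map
#'   with tier `"modifier"`; if `FALSE` they are dropped entirely.
#' @return An object of class `tier_map`: a list with elements
#'   `assignment` (named character vector, id -> `"1"`..`"4"` or
#'   `"modifier"`), `co_tier` (named integer vector, id -> co-clustered
#'   tier for every item), `category` (named character vector) and
#'   `provenance` (`"packaged"`).
#' @seealso [derive_tiers()] for deriving a tier map from rating summaries.
#' @export
packaged_tier_map <- function(include_modifiers = TRUE) {
  chars <- load_default_characteristics()
  if (!include_modifiers) chars <- chars[chars$category == "core", ]
  new_tier_map(
    assignment = stats::setNames(chars$tier, chars$id),
    co_tier    = stats::setNames(as.integer(chars$co_tier), chars$id),
    category   = stats::setNames(chars$category, chars$id),
    provenance = "packaged"
  )
}

new_tier_map <- function(assignment, co_tier, category, provenance,
                         cluster_means = NULL) {
  stopifnot(provenance %in% c("packaged", "derived"))
  core <- names(category)[category == "core"]
  stopifnot(all(assignment[core] %in% as.character(1:9)))
  structure(
    list(assignment = assignment, co_tier = co_tier, category = category,
         provenance = provenance, cluster_means = cluster_means),
    class = "tier_map"
  )
}

#' @export
print.tier_map <- function(x, ...) {
  cat(sprintf("Tier map (%s), %d characteristics\n",
              x$provenance, length(x$assignment)))
  for (t in sort(unique(x$co_tier))) {
    ids <- names(x$co_tier)[x$co_tier == t]
    mods <- ids[x$category[ids] == "modifier"]
    lab <- vapply(ids, function(i)
      if (i %in% mods) paste0(i, " [modifier]") else i, character(1))
    cat(sprintf("  Tier %d: %s\n", t, paste(lab, collapse = ", ")))
  }
  invisible(x)
}

#' Reference diseases from the 15-disease pilot survey
#'
#' The fifteen diseases surveyed in the expanded-carrier-screening severity
#' pilot, with their survey-derived severity rating summaries (1--4 scale),
#' severity group from three-class clustering, survey-set assignment, and
#' screening-guideline status flags.
#'
#' @return A data frame with columns `disease_id`, `name`, `survey_set`,
#'   `set_respondents`, `group` (`Profound`/`Severe`/`Moderate`), rating
#'   summary columns `mean`, `median`, `min`, `max`, and logical flags
#'   `acmg_acog` (recommended for universal or ethnicity-specific carrier
#'   screening), `assessed_nbs` (assessed in the ACMG newborn-screening
#'   report) and `included_nbs` (recommended for newborn screening).
#' @examples
#' ref <- load_reference_diseases()
#' table(ref$group)
#' @export
load_reference_diseases <- function() {
  df <- utils::read.csv(extdata_path("diseases.csv"), stringsAsFactors = FALSE)
  stopifnot(
    nrow(df) == 15L,
    !anyDuplicated(df$disease_id),
    all(df$group %in% c("Profound", "Severe", "Moderate")),
    all(df$min <= df$median & df$median <= df$max),
    all(df$min <= df$mean & df$mean <= df$max)
  )
  df$acmg_acog <- as.logical(df$acmg_acog)
  df$assessed_nbs <- as.logical(df$assessed_nbs)
  df$included_nbs <- as.logical(df$included_nbs)
  df
}

#' Characteristic profiles of the reference diseases
#'
#' The untreated-course characteristic profile of each reference disease.
#' Penetrance is unspecified for all packaged profiles (the source survey
#' listed presence only); unspecified penetrance passes the classifier's
#' penetrance filter.
#'
#' @return A named list of 15 [disease_profile()] objects, keyed and
#'   ordered as in [load_reference_diseases()].
#' @export
reference_profiles <- function() {
  ref <- load_reference_diseases()
  long <- utils::read.csv(extdata_path("profiles.csv"), stringsAsFactors = FALSE)
  stopifnot(all(long$disease_id %in% ref$disease_id))
  profs <- lapply(seq_len(nrow(ref)), function(i) {
    ids <- long$characteristic_id[long$disease_id == ref$disease_id[i]]
    disease_profile(ref$disease_id[i], ref$name[i], ids)
  })
  stats::setNames(profs, ref$disease_id)
}

#' Construct a disease characteristic profile
#'
#' @param disease_id stable token identifying the disease.
#' @param name display name; must be non-empty.
#' @param characteristic_ids character vector of characteristic ids from the
#'   controlled vocabulary (see [load_default_characteristics()]).
#' @param penetrance optional numeric vector parallel to
#'   `characteristic_ids`, each value a fraction in \[0, 1\] or `NA` for
#'   unspecified. Defaults to all unspecified.
#' @return An object of class `disease_profile`: a list with `disease_id`,
#'   `name` and a `traits` data frame (`characteristic_id`, `penetrance`).
#' @examples
#' p <- disease_profile("toy", "Toy disease",
#'                      c("intellectual_disability", "vision_impairment"),
#'                      penetrance = c(0.9, NA))
#' @export
disease_profile <- function(disease_id, name, characteristic_ids,
                            penetrance = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name)))
    stop("disease name must be a non-empty string", call. = FALSE)
  characteristic_ids <- as.character(characteristic_ids)
  if (is.null(penetrance)) {
    penetrance <- rep(NA_real_, length(characteristic_ids))
  }
  stopifnot(length(penetrance) == length(characteristic_ids))
  if (any(!is.na(penetrance) & (penetrance < 0 | penetrance > 1)))
    stop("penetrance values must be fractions in [0, 1]", call. = FALSE)
  structure(
    list(disease_id = as.character(disease_id), name = name,
         traits = data.frame(characteristic_id = characteristic_ids,
                             penetrance = as.numeric(penetrance),
                             stringsAsFactors = FALSE)),
    class = "disease_profile"
  )
}

#' @export
print.disease_profile <- function(x, ...) {
  cat(sprintf("<disease_profile> %s (%s): %d trait(s)\n",
              x$name, x$disease_id, nrow(x$traits)))
  if (nrow(x$traits)) {
    pen <- ifelse(is.na(x$traits$penetrance), "unspecified",
                  sprintf("%.0f%%", 100 * x$traits$penetrance))
    cat(paste0("  ", x$traits$characteristic_id, " (", pen, ")\n"), sep = "")
  }
  invisible(x)
}

#' Validate a disease profile against the controlled vocabulary
#'
#' Checks characteristic ids against the packaged vocabulary, collapses
#' duplicated traits (keeping the first occurrence, with a warning), and
#' warns when a profile lists more than one shortened-life-span
#' characteristic -- each reference disease lists at most one, and listing
#' several makes the two-Tier-1 rule fire on life span alone.
#'
#' @param profile a [disease_profile()].
#' @param vocabulary characteristic table; defaults to the packaged one.
#' @return The validated (possibly de-duplicated) profile, invisibly
#'   classed as before.
#' @export
validate_profile <- function(profile, vocabulary = load_default_characteristics()) {
  stopifnot(inherits(profile, "disease_profile"))
  ids <- profile$traits$characteristic_id
  unknown <- setdiff(ids, vocabulary$id)
  if (length(unknown))
    stop(sprintf("unknown characteristic id(s) in profile '%s': %s",
                 profile$disease_id, paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning(sprintf("profile '%s': duplicated characteristic(s) collapsed: %s",
                    profile$disease_id, paste(dup, collapse = ", ")),
            call. = FALSE)
    profile$traits <- profile$traits[!duplicated(ids), , drop = FALSE]
    rownames(profile$traits) <- NULL
  }
  lifespan <- vocabulary$id[vocabulary$lifespan_flag]
  n_ls <- sum(profile$traits$characteristic_id %in% lifespan)
  if (n_ls > 1L)
    warning(sprintf(
      "profile '%s' lists %d shortened-life-span characteristics; reference profiles list at most one",
      profile$disease_id, n_ls), call. = FALSE)
  profile
}
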