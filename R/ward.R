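#' Ward minimum-variance linkage of a 1-D rating vector
#'
#' Agglomerative clustering that at each step merges the two clusters whose
#' union gives the smallest increase in total within-cluster sum of squares.
#' For clusters A and B the merge cost is the exact increase
#' \deqn{\Delta ESS = \frac{|A||B|}{|A|+|B|} (\bar{x}_A - \bar{x}_B)^2.}
#' Ties are broken deterministically: among equal-cost candidate pairs the
#' pair whose smallest member index (in input order) is lowest wins, then
#' the smaller second index.
#'
#' @param values named numeric vector: item id -> rating (e.g. a mean
#'   importance rating). At least two finite values are required.
#' @return An object of class `ward_tree`: a list with `items` (ids in
#'   input order), `values`, and `merges`, a list of n-1 merge steps, each
#'   a list with `step`, `left` and `right` (member-id character vectors)
#'   and `cost` (the \eqn{\Delta ESS} of the merge).
#' @examples
#' tree <- ward_linkage(c(a = 1, b = 2, c = 10))
#' tree$merges[[1]]$cost  # 0.5: merging {a} and {b}
#' @export
ward_linkage <- function(values) {
  if (length(values) < 2L)
    stop("ward_linkage requires at least 2 items", call. = FALSE)
  if (is.null(names(values)) || anyDuplicated(names(values)) ||
      any(!nzchar(names(values))))
    stop("values must be uniquely named by item id", call. = FALSE)
  if (any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  n <- length(values)
  ids <- names(values)

  # active clusters: member input-index vectors (kept sorted)
  clusters <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  means <- as.numeric(values)
  merges <- vector("list", n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        cost <- sizes[i] * sizes[j] / (sizes[i] + sizes[j]) *
          (means[i] - means[j])^2
        key <- sort(c(clusters[[i]][1L], clusters[[j]][1L]))
        if (is.null(best) ||
            cost < best$cost - 1e-12 ||
            (abs(cost - best$cost) <= 1e-12 &&
             (key[1L] < best$key[1L] ||
              (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
          best <- list(i = i, j = j, cost = cost, key = key)
        }
      }
    }
    li <- clusters[[best$i]]; rj <- clusters[[best$j]]
    # report left/right with left = cluster holding the lower input index
    if (li[1L] > rj[1L]) { tmp <- li; li <- rj; rj <- tmp }
    merges[[step]] <- list(step = step, left = ids[li], right = ids[rj],
                           cost = best$cost)
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    new_mean <- (sizes[best$i] * means[best$i] + sizes[best$j] * means[best$j]) /
      (sizes[best$i] + sizes[best$j])
    new_size <- sizes[best$i] + sizes[best$j]
    keep <- setdiff(seq_len(m), c(best$i, best$j))
    clusters <- c(clusters[keep], list(merged))
    sizes <- c(sizes[keep], new_size)
    means <- c(means[keep], new_mean)
  }

  structure(list(items = ids, values = stats::setNames(as.numeric(values), ids),
                 merges = merges),
            class = "ward_tree")
}

#' @export
print.ward_tree <- function(x, ...) {
  cat(sprintf("Ward linkage of %d items\n", length(x$items)))
  for (m in x$merges)
    cat(sprintf("  step %2d  cost %8.4f  {%s} + {%s}\n", m$step, m$cost,
                paste(m$left, collapse = ","), paste(m$right, collapse = ",")))
  invisible(x)
}

#' Cut a Ward tree into k clusters
#'
#' Replays the merge history, stopping before the last k-1 merges, i.e.
#' undoing them. `k = n` gives singletons and `k = 1` a single cluster.
#' Cluster indices are assigned in descending order of cluster mean, so
#' cluster 1 always holds the highest-rated items.
#'
#' @param tree a [ward_linkage()] result.
#' @param k number of clusters, between 1 and the number of items.
#' @return An object of class `cluster_cut`: list with `k`, `assignment`
#'   (named integer vector, item id -> cluster index) and `cluster_means`.
#' @export
ward_cut <- function(tree, k) {
  stopifnot(inherits(tree, "ward_tree"))
  n <- length(tree$items)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n || k != round(k))
    stop("k must be an integer between 1 and ", n, call. = FALSE)
  assignment <- stats::setNames(seq_len(n), tree$items)
  n_merges <- n - k
  for (m in tree$merges[seq_len(n_merges)]) {
    gl <- assignment[[m$left[1L]]]
    gr <- assignment[[m$right[1L]]]
    assignment[assignment == gr] <- gl
  }
  # relabel 1..k by descending cluster mean
  groups <- unique(assignment)
  gmeans <- vapply(groups, function(g) mean(tree$values[assignment == g]),
                   numeric(1))
  ord <- order(gmeans, decreasing = TRUE)
  relabel <- stats::setNames(seq_along(groups), groups[ord])
  assignment <- stats::setNames(relabel[as.character(assignment)],
                                names(assignment))
  structure(list(k = as.integer(k),
                 assignment = assignment,
                 cluster_means = sort(gmeans, decreasing = TRUE)),
            class = "cluster_cut")
}

#' Largest-gap diagnostic for a merge history
#'
#' Reports, for each possible number of clusters, the cost of the merge
#' that would next be undone -- a rough aid for judging where natural
#' cluster boundaries fall. Purely diagnostic; k is always chosen
#' explicitly by the caller.
#'
#' @param tree a [ward_linkage()] result.
#' @return data frame with columns `k` and `next_merge_cost`.
#' @export
merge_cost_profile <- function(tree) {
  stopifnot(inherits(tree, "ward_tree"))
  costs <- vapply(tree$merges, `[[`, numeric(1), "cost")
  n <- length(tree$items)
  # merge step s runs while n - s + 1 clusters remain
  data.frame(k = n - seq_along(costs) + 1L, next_merge_cost = costs)
}

#' Derive characteristic tiers by Ward clustering of mean ratings
#'
#' Clusters per-characteristic mean importance ratings and labels the
#' clusters Tier 1..k in descending order of cluster mean. All 15
#' characteristics, modifiers included, take part in the clustering;
#' modifiers are reported with the tier they co-cluster with but keep
#' category `"modifier"`, which excludes them from classification.
#'
#' @param summaries either a data frame with columns `item_id` (or `id`)
#'   and `mean`, as returned by [aggregate_ratings()], or a named numeric
#'   vector of means.
#' @param k number of tiers (default 4).
#' @param categories optional named character vector id -> `"core"` /
#'   `"modifier"`; defaults to the packaged vocabulary for known ids and
#'   `"core"` otherwise.
#' @param include_modifiers if `FALSE`, modifier items are dropped before
#'   clustering rather than co-clustered.
#' @return A `tier_map` with provenance `"derived"`.
#' @examples
#' chars <- load_default_characteristics()
#' tm <- derive_tiers(stats::setNames(chars$mean, chars$id))
#' @export
derive_tiers <- function(summaries, k = 4, categories = NULL,
                         include_modifiers = TRUE) {
  means <- as_mean_vector(summaries)
  if (is.null(categories)) {
    vocab <- load_default_characteristics()
    categories <- stats::setNames(
      ifelse(names(means) %in% vocab$id[vocab$category == "modifier"],
             "modifier", "core"),
      names(means))
  }
  categories <- categories[names(means)]
  if (!include_modifiers) {
    means <- means[categories != "modifier"]
    categories <- categories[names(means)]
  }
  if (length(means) < k)
    stop("need at least k = ", k, " items to derive ", k, " tiers",
         call. = FALSE)
  cut <- ward_cut(ward_linkage(means), k)
  co_tier <- cut$assignment
  assignment <- ifelse(categories[names(co_tier)] == "modifier",
                       "modifier", as.character(co_tier))
  new_tier_map(
    assignment = stats::setNames(assignment, names(co_tier)),
    co_tier = co_tier,
    category = categories,
    provenance = "derived",
    cluster_means = cut$cluster_means
  )
}

#' Derive disease severity groups by Ward clustering of mean ratings
#'
#' Clusters per-disease mean severity ratings (1--4 scale) into k groups
#' and labels them with the top k labels of the
#' Profound > Severe > Moderate > Mild ladder, in descending order of
#' cluster mean. With k = 3 (the default) the groups are Profound, Severe
#' and Moderate.
#'
#' @param summaries data frame with `item_id`/`disease_id` and `mean`
#'   columns, or a named numeric vector of mean ratings.
#' @param k number of groups (default 3).
#' @return named character vector: disease id -> group label.
#' @export
derive_severity_groups <- function(summaries, k = 3) {
  means <- as_mean_vector(summaries)
  if (length(means) < k)
    stop("need at least k = ", k, " diseases to form ", k, " groups",
         call. = FALSE)
  stopifnot(k >= 1, k <= 4)
  cut <- ward_cut(ward_linkage(means), k)
  ladder <- rev(severity_labels())  # Profound, Severe, Moderate, Mild
  stats::setNames(ladder[cut$assignment], names(cut$assignment))
}

as_mean_vector <- function(summaries) {
  if (is.numeric(summaries)) {
    if (is.null(names(summaries)))
      stop("mean vector must be named by item id", call. = FALSE)
    return(summaries)
  }
  stopifnot(is.data.frame(summaries))
  idcol <- intersect(c("item_id", "disease_id", "id"), names(summaries))[1]
  if (is.na(idcol) || !"mean" %in% names(summaries))
    stop("summaries must have an id column and a 'mean' column", call. = FALSE)
  stats::setNames(summaries$mean, summaries[[idcol]])
}
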