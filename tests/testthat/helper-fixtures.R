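# shared fixtures and small independent oracles

table1_means <- function() {
  chars <- load_default_characteristics()
  stats::setNames(chars$mean, chars$id)
}

table3_means <- function() {
  ref <- load_reference_diseases()
  stats::setNames(ref$mean, ref$disease_id)
}

# naive second implementation of per-item summaries: explicit loops,
# hand-rolled midpoint median
naive_summarise <- function(records, item) {
  vals <- sort(records$value[records$item_id == item])
  n <- length(vals)
  med <- if (n %% 2 == 1) vals[(n + 1) / 2] else
    (vals[n / 2] + vals[n / 2 + 1]) / 2
  list(mean = sum(vals) / n, median = med, min = vals[1], max = vals[n], n = n)
}

# label-invariant partition comparison
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

core_characteristic_ids <- function() {
  chars <- load_default_characteristics()
  chars$id[chars$category == "core"]
}

# exact expectation of the generator's discrete law: normal draw rounded
# to the nearest integer and clamped to the scale bounds
discrete_censored_mean <- function(mu, sd, scale = c(1, 10)) {
  k <- seq(scale[1], scale[2])
  p <- stats::pnorm(k + 0.5, mu, sd) - stats::pnorm(k - 0.5, mu, sd)
  p[1] <- stats::pnorm(scale[1] + 0.5, mu, sd)
  p[length(k)] <- 1 - stats::pnorm(scale[2] - 0.5, mu, sd)
  sum(k * p)
}

# random profile over the full vocabulary, penetrance a mix of
# unspecified and draws in [0, 1]
random_profile <- function(i) {
  ids <- load_default_characteristics()$id
  size <- sample(0:8, 1)
  picked <- if (size) sample(ids, size) else character(0)
  pen <- ifelse(stats::runif(size) < 0.5, NA_real_,
                round(stats::runif(size), 2))
  disease_profile(paste0("rp", i), paste("random profile", i), picked,
                  penetrance = if (size) pen else NULL)
}
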