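# internal helpers

# round half away from zero (display convention for percentages);
# base round() ties to even, which differs at e.g. 18.75
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic 32-bit string hash (djb2), used to derive per-item
# random substreams from a master seed
hash_token <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 5381
  for (b in utf8ToInt(x)) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "sevclass", mustWork = FALSE)
  if (!nzchar(path)) {
    # during development (pkgload) fall back to inst/
    path <- system.file("inst", "extdata", file, package = "sevclass", mustWork = TRUE)
  }
  path
}

severity_labels <- function() c("Mild", "Moderate", "Severe", "Profound")
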