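# Shared internal helpers: seed derivation, label handling, small checks.

# Response labels are the two-level factor used throughout; NR is the
# positive class everywhere (sensitivity/precision refer to NR detection).
response_levels <- c("R", "NR")

as_response <- function(x, allow_na = FALSE) {
  x <- as.character(x)
  bad <- !x %in% response_levels & !(allow_na & is.na(x))
  if (any(bad)) {
    abort(paste0(
      "response labels must be 'R' or 'NR'; found: ",
      paste(unique(x[bad]), collapse = ", ")
    ))
  }
  factor(x, levels = response_levels)
}

# Deterministic substream seeds: every stochastic routine takes one root
# seed and derives per-repeat / per-stage seeds so components are
# independently reproducible. Kept below 2^31 (R integers are 32-bit);
# arithmetic stays in doubles, well inside 2^53.
derive_seed <- function(seed, offset) {
  s <- (abs(as.numeric(seed)) * 48271 + as.numeric(offset) * 16807 + 1) %% 2147483629
  as.integer(s)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# Extract the numeric feature block (mechanism columns) from a tidy
# samples-by-mechanisms tibble that also carries id/annotation columns.
feature_matrix <- function(data, id_cols = c("sample", "cohort", "response")) {
  stopifnot(is.data.frame(data))
  if (!"sample" %in% names(data)) abort("`data` must have a 'sample' column")
  feats <- setdiff(names(data), id_cols)
  num <- vapply(data[feats], is.numeric, logical(1))
  feats <- feats[num]
  if (length(feats) == 0L) abort("`data` contains no numeric feature columns")
  x <- as.matrix(data[feats])
  rownames(x) <- as.character(data$sample)
  x
}
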