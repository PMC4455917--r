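# Shared small fixtures, generated in code. The medium study is memoised
# so several test files can reuse it without regenerating.

tiny_mechanisms <- function() {
  tibble::tibble(
    set = rep(c("M1", "M2"), c(4, 4)),
    description = "",
    gene = c("A", "B", "C", "D", "C", "D", "E", "F"),
    sign = c(1L, 1L, -1L, -1L, 1L, -1L, 1L, 1L)
  )
}

tiny_diff <- function() {
  tibble::tibble(
    gene = c("A", "B", "C", "D", "E", "F"),
    s1 = c(2, 0, 1, -1, 0.5, -0.5),
    s2 = c(-1, 1, 0, 2, 1, 1)
  )
}

small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        cohort_sizes = c(24L, 18L), n_genes = 300, n_mechanisms = 40,
        mech_size_range = c(4, 30), n_informative = 4, effect = 1
      )
      cache <<- suppressMessages(simulate_study(cfg, seed = 11))
    }
    cache
  }
})

quiet_fit <- function(data, ...) {
  suppressWarnings(fit_mechanism_classifier(data, ...))
}
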