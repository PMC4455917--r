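# Strength scoring: the mechanism-activity statistic.
#
# The strength of mechanism m in sample j is the weighted mean of the
# member genes' log2 differential expression, the weights being the
# curated directions of regulation (+1 increase, -1 decrease):
#
#   strength[m, j] = (1 / |G'_m|) * sum_{g in G'_m} sign_g * d[g, j]
#
# where G'_m is the subset of m's genes measured in this cohort. The
# denominator is the number of genes *used*, so scores stay on the log2
# fold-change scale even when platforms measure different subsets.

#' Compute mechanism strength scores for one cohort
#'
#' @param diff Wide differential-expression tibble (`gene` + sample
#'   columns), as produced by [median_center()]. Must be complete.
#' @param mechanisms Long-format mechanism tibble
#'   (see [validate_mechanisms()]).
#' @param min_genes Mechanisms with fewer than this many member genes
#'   present in `diff` are omitted (default 4) and recorded in the
#'   `dropped` attribute.
#' @return A wide tibble `mechanism` + one numeric column per sample, in
#'   mechanism order of first appearance. Attributes: `support`, a tibble
#'   (`mechanism`, `n_genes`) with the per-mechanism gene counts used, and
#'   `dropped`, the names of mechanisms below coverage.
#' @export
#' @examples
#' d <- tibble::tibble(gene = c("A", "B", "C", "D"), s1 = c(2, 0, 1, -1))
#' m <- tibble::tibble(
#'   set = "M1", gene = c("A", "B", "C", "D"),
#'   sign = c(1L, 1L, -1L, -1L)
#' )
#' strength_scores(d, m, min_genes = 4) # (2 + 0 - 1 + 1) / 4 = 0.5
strength_scores <- function(diff, mechanisms, min_genes = 4) {
  mechanisms <- validate_mechanisms(mechanisms)
  if (nrow(mechanisms) == 0L) abort("empty mechanism collection")
  check_scalar_number(min_genes, "min_genes", lower = 1)
  x <- as.matrix(diff[-1])
  rownames(x) <- diff$gene
  if (anyNA(x) || any(!is.finite(x))) abort("differential matrix must be finite and complete")

  present <- mechanisms[mechanisms$gene %in% diff$gene, ]
  sets <- unique(mechanisms$set)
  support <- tapply(present$set, factor(present$set, levels = sets), length)
  support[is.na(support)] <- 0L
  keep <- sets[support >= min_genes]
  if (length(keep) == 0L) abort("all mechanisms fall below the coverage threshold")
  used <- present[present$set %in% keep, ]

  # signed incidence (mechanisms x genes) %*% expression, then divide by
  # the per-mechanism gene count actually used
  gidx <- match(used$gene, rownames(x))
  midx <- match(used$set, keep)
  w <- matrix(0, nrow = length(keep), ncol = nrow(x),
              dimnames = list(keep, rownames(x)))
  w[cbind(midx, gidx)] <- used$sign
  scores <- (w %*% x) / as.numeric(support[keep])

  out <- tibble::tibble(mechanism = keep, !!!as.data.frame(scores, check.names = FALSE))
  attr(out, "support") <- tibble::tibble(
    mechanism = keep, n_genes = as.integer(support[keep])
  )
  attr(out, "dropped") <- setdiff(sets, keep)
  out
}

#' Per-mechanism gene support of a strength matrix
#'
#' @param strengths Result of [strength_scores()].
#' @return Tibble (`mechanism`, `n_genes`).
#' @export
strength_support <- function(strengths) {
  s <- attr(strengths, "support")
  if (is.null(s)) abort("`strengths` carries no support attribute")
  s
}

#' Stack per-cohort strength matrices into a classifier feature table
#'
#' Transposes each cohort's mechanism-by-sample strength matrix and binds
#' cohorts row-wise, keeping only mechanisms scored in every cohort (with
#' a globally coverage-filtered collection these coincide).
#'
#' @param strength_list Named list of [strength_scores()] results; names
#'   are cohort ids.
#' @param annotations Optional tibble with `sample` and `response`
#'   columns to join onto the result.
#' @return A tibble with columns `sample`, `cohort`, then one numeric
#'   column per mechanism (and `response` when annotations are given).
#' @export
stack_strengths <- function(strength_list, annotations = NULL) {
  if (is.null(names(strength_list)) || any(names(strength_list) == "")) {
    abort("`strength_list` must be a named list (names = cohort ids)")
  }
  shared <- Reduce(intersect, lapply(strength_list, function(s) s$mechanism))
  if (length(shared) == 0L) abort("no mechanism is scored in every cohort")
  rows <- purrr::imap(strength_list, function(s, id) {
    m <- as.matrix(s[-1])
    rownames(m) <- s$mechanism
    t_m <- t(m[shared, , drop = FALSE])
    tibble::tibble(
      sample = rownames(t_m), cohort = id,
      !!!as.data.frame(t_m, check.names = FALSE)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(annotations)) {
    out <- dplyr::inner_join(
      dplyr::select(annotations, "sample", "response"), out,
      by = "sample"
    )
    out <- dplyr::relocate(out, "sample", "cohort", "response")
  }
  out
}

#' Write a strength matrix and its support table
#'
#' @param strengths Result of [strength_scores()].
#' @param path Output TSV path for the scores; the support table goes to
#'   `<path>.support.tsv`.
#' @return `path`, invisibly.
#' @export
write_strengths <- function(strengths, path) {
  readr::write_tsv(strengths, path, progress = FALSE)
  readr::write_tsv(strength_support(strengths), paste0(path, ".support.tsv"),
                   progress = FALSE)
  invisible(path)
}
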