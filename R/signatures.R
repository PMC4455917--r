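# Re-evaluation of previously published gene-list classifiers.
#
# The original studies published gene lists but no scoring formula, so
# each signature is re-trained with a clustering scorer: training samples
# are clustered into two groups on the signature genes, each cluster is
# called by its majority response label, and test samples are scored by
# their distance to the two cluster medians. A k-nearest-neighbour scorer
# (score 1 = predicted NR, 0 = predicted R) covers signatures defined
# that way. All tie rules favour the NR call, keeping specificity
# estimates conservative.

#' Read a signature file
#'
#' TSV with header `name<TAB>scorer<TAB>k<TAB>genes`, genes
#' comma-separated; `scorer` is `nearest_cluster_median` or `knn`.
#'
#' @param path Path to the TSV.
#' @return Tibble (`name`, `scorer`, `k`, `genes` (list-column)).
#' @export
read_signatures <- function(path) {
  raw <- readr::read_tsv(path, col_types = "ccic", progress = FALSE)
  names(raw)[1:4] <- c("name", "scorer", "k", "genes")
  bad <- !raw$scorer %in% c("nearest_cluster_median", "knn")
  if (any(bad)) {
    abort(paste0("unknown scorer(s): ", paste(unique(raw$scorer[bad]), collapse = ", ")))
  }
  raw$genes <- strsplit(raw$genes, ",", fixed = TRUE) |> lapply(trimws)
  raw
}

# samples x genes matrix restricted to signature genes, erroring on
# genes absent from the expression table
signature_matrix <- function(expr, genes) {
  missing <- setdiff(genes, expr$gene)
  if (length(missing)) {
    abort(paste0("signature gene(s) absent from data: ", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(expr[match(genes, expr$gene), -1, drop = FALSE])
  rownames(m) <- genes
  t(m)
}

#' Fit a two-cluster signature scorer
#'
#' Clusters the training samples (restricted to the signature genes) into
#' two groups by average-linkage hierarchical clustering on correlation
#' distance (Euclidean distance when fewer than 2 genes, where
#' correlation across genes is undefined). Each cluster's response call
#' is its majority training label, ties called NR; if both clusters get
#' the same call, the cluster with the higher NR fraction is re-called NR.
#'
#' @param expr Median-centered wide expression tibble (training samples).
#' @param labels Named response vector (`"R"`/`"NR"`), names = sample ids
#'   covering the expression columns.
#' @param genes Character vector of signature genes (all must be present).
#' @param method Linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return Object of class `mech_signature_fit`: per-cluster median
#'   profiles and response calls.
#' @export
fit_cluster_signature <- function(expr, labels, genes, method = "average") {
  m <- signature_matrix(expr, genes)
  samples <- rownames(m)
  lab <- as_response(labels[samples])
  if (nrow(m) < 2L) abort("need at least 2 training samples")
  if (length(unique(lab)) < 2L) abort("training labels contain a single class")
  d <- if (ncol(m) >= 2L) {
    as.dist(1 - cor(t(m)))
  } else {
    dist(m)
  }
  cl <- cutree(hclust(d, method = method), k = 2)
  call_of <- function(v) {
    n_nr <- sum(v == "NR"); n_r <- sum(v == "R")
    if (n_nr >= n_r) "NR" else "R" # tie -> NR
  }
  calls <- vapply(1:2, function(g) call_of(lab[cl == g]), "")
  if (calls[1] == calls[2]) {
    frac_nr <- vapply(1:2, function(g) mean(lab[cl == g] == "NR"), 0)
    nr_cluster <- if (frac_nr[1] >= frac_nr[2]) 1L else 2L
    calls <- c("R", "R"); calls[nr_cluster] <- "NR"
    inform("both clusters had the same majority call; higher-NR-fraction cluster re-called NR")
  }
  medians <- vapply(1:2, function(g) {
    apply(m[cl == g, , drop = FALSE], 2, median)
  }, numeric(ncol(m)))
  structure(
    list(
      genes = genes,
      medians = medians, # genes x 2
      calls = calls,
      clusters = cl
    ),
    class = "mech_signature_fit"
  )
}

#' Score test samples against the nearest cluster median
#'
#' Score = Euclidean distance to the R-called median minus distance to
#' the NR-called median (higher = more NR-like); the predicted label is
#' the call of the nearest median, ties predicted NR.
#'
#' @param fit A `mech_signature_fit`.
#' @param expr Wide expression tibble holding the test samples.
#' @return Tibble (`sample`, `score`, `predicted`).
#' @export
score_nearest_median <- function(fit, expr) {
  m <- signature_matrix(expr, fit$genes)
  nr_col <- which(fit$calls == "NR")
  r_col <- which(fit$calls == "R")
  d_nr <- sqrt(colSums((t(m) - fit$medians[, nr_col])^2))
  d_r <- sqrt(colSums((t(m) - fit$medians[, r_col])^2))
  tibble::tibble(
    sample = rownames(m),
    score = unname(d_r - d_nr),
    predicted = unname(ifelse(d_nr <= d_r, "NR", "R")) # equidistant -> NR
  )
}

#' k-nearest-neighbour signature scoring
#'
#' Majority vote of the `k` nearest training samples (Euclidean distance
#' on the signature genes); voting ties predict NR. Predicted
#' non-responders score 1, predicted responders 0, so the score takes
#' only two values.
#'
#' @param train_expr,test_expr Wide expression tibbles.
#' @param labels Named response vector covering the training samples.
#' @param genes Signature genes.
#' @param k Number of neighbours (default 3), at most the training size.
#' @return Tibble (`sample`, `score`, `predicted`).
#' @export
knn_signature_score <- function(train_expr, test_expr, labels, genes, k = 3) {
  tr <- signature_matrix(train_expr, genes)
  te <- signature_matrix(test_expr, genes)
  lab <- as_response(labels[rownames(tr)])
  if (k > nrow(tr)) abort("k exceeds the number of training samples")
  pred <- vapply(seq_len(nrow(te)), function(i) {
    d <- sqrt(colSums((t(tr) - te[i, ])^2))
    nn <- order(d)[seq_len(k)]
    votes <- lab[nn]
    if (sum(votes == "NR") >= sum(votes == "R")) "NR" else "R" # tie -> NR
  }, "")
  tibble::tibble(
    sample = rownames(te),
    score = as.numeric(pred == "NR"),
    predicted = pred
  )
}

#' Evaluate a published signature by leave-one-sample-out CV
#'
#' Pools the supplied cohorts (median-centered, genes restricted to those
#' measured everywhere), optionally drops a signature's own training
#' cohort to avoid feature-selection bias, then leave-one-sample-out:
#' each sample is scored by a scorer trained on all others.
#'
#' @param expr_list Named list of median-centered wide expression tibbles
#'   (one per cohort).
#' @param annotations Tibble with `sample`, `cohort`, `response` covering
#'   the pooled samples.
#' @param genes Signature genes; signatures whose genes are not all
#'   measured in every cohort are rejected (error lists the genes).
#' @param scorer `"nearest_cluster_median"` or `"knn"`.
#' @param k Neighbours for the knn scorer.
#' @param exclude_cohorts Cohorts to drop before evaluation (e.g. the
#'   signature's original training cohort).
#' @return List: `scores` (pooled LOSO score table) and `report`
#'   (one-row [performance_report()]).
#' @export
evaluate_signature <- function(expr_list, annotations, genes,
                               scorer = c("nearest_cluster_median", "knn"),
                               k = 3, exclude_cohorts = character()) {
  scorer <- match.arg(scorer)
  expr_list <- expr_list[setdiff(names(expr_list), exclude_cohorts)]
  if (length(expr_list) == 0L) abort("no cohorts left after exclusion")
  shared <- Reduce(intersect, lapply(expr_list, function(e) e$gene))
  missing <- setdiff(genes, shared)
  if (length(missing)) {
    abort(paste0(
      "signature gene(s) not measured in every cohort: ",
      paste(missing, collapse = ", ")
    ))
  }
  pooled <- purrr::reduce(
    purrr::map(expr_list, function(e) e[match(shared, e$gene), ]),
    function(a, b) dplyr::bind_cols(a, b[-1])
  )
  ann <- annotations[annotations$sample %in% names(pooled)[-1] &
                       !annotations$cohort %in% exclude_cohorts, ]
  labels <- setNames(as.character(ann$response), ann$sample)
  samples <- ann$sample
  scored <- purrr::map_dfr(samples, function(s) {
    train <- pooled[c("gene", setdiff(samples, s))]
    test <- pooled[c("gene", s)]
    if (scorer == "nearest_cluster_median") {
      fit <- fit_cluster_signature(train, labels, genes)
      score_nearest_median(fit, test)
    } else {
      knn_signature_score(train, test, labels, genes, k = k)
    }
  })
  scored$response <- labels[scored$sample]
  scored$cohort <- setNames(ann$cohort, ann$sample)[scored$sample]
  list(scores = scored, report = performance_report(scored))
}
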