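# Batch-aware resampling: cohort-balanced k-fold plans, repeated k-fold
# CV, leave-one-batch-out, leave-one-sample-out, and the label-permutation
# null. Thresholds are always re-selected from the training split alone,
# so held-out samples never influence any trained component.

#' Cohort-balanced fold plan
#'
#' Shuffles samples within each cohort, then deals the concatenated,
#' randomly rotated sequence round-robin into `k` folds. Each cohort is
#' split approximately equally (per-cohort fold sizes differ by at most
#' one) and the folds partition all samples.
#'
#' @param samples Tibble with columns `sample` and `cohort`.
#' @param k Number of folds (default 10), at most the number of samples.
#' @param seed Integer seed; the same seed reproduces the same plan.
#' @return Tibble (`sample`, `cohort`, `fold`).
#' @export
make_folds <- function(samples, k = 10, seed = 1) {
  if (!all(c("sample", "cohort") %in% names(samples))) {
    abort("`samples` needs columns sample and cohort")
  }
  n <- nrow(samples)
  check_scalar_number(k, "k", lower = 2)
  if (k > n) abort(sprintf("k = %d exceeds the %d available samples", k, n))
  set.seed(seed)
  ord <- unlist(lapply(
    split(seq_len(n), samples$cohort),
    function(idx) if (length(idx) == 1L) idx else sample(idx)
  ), use.names = FALSE)
  start <- sample.int(k, 1L)
  fold <- integer(n)
  fold[ord] <- ((seq_along(ord) - 1L + start) %% k) + 1L
  tibble::tibble(
    sample = samples$sample,
    cohort = samples$cohort,
    fold = fold
  )
}

# Train on `train`, score `test`; a lasso fit that selects nothing has a
# constant linear predictor and cannot be rescaled -- such folds score
# every sample at the midpoint 5 (all tied, carrying no ranking
# information) and the threshold rule then flags everything.
fit_or_constant <- function(train, test, opts) {
  model <- tryCatch(
    fit_mechanism_classifier(
      train,
      target_sensitivity = opts$target_sensitivity,
      penalty = opts$penalty, nfolds = opts$nfolds,
      standardize = opts$standardize, seed = opts$seed
    ),
    error = function(e) {
      if (grepl("degenerate fit", conditionMessage(e))) NULL else stop(e)
    }
  )
  if (is.null(model)) {
    return(tibble::tibble(
      sample = as.character(test$sample),
      cohort = if ("cohort" %in% names(test)) as.character(test$cohort) else NA_character_,
      response = as.character(test$response),
      score = 5,
      predicted = "NR"
    ))
  }
  predict(model, test)
}

cv_opts <- function(target_sensitivity = 0.6, penalty = "lambda.1se",
                    nfolds = 5, standardize = FALSE, seed = 1) {
  list(
    target_sensitivity = target_sensitivity, penalty = penalty,
    nfolds = nfolds, standardize = standardize, seed = seed
  )
}

# One full k-fold pass: returns the pooled out-of-fold score table.
# Errors with class "mechsig_degenerate_split" when a training split is
# single-class, so callers can redraw the plan.
kfold_once <- function(data, plan, opts) {
  scored <- vector("list", max(plan$fold))
  for (f in sort(unique(plan$fold))) {
    test_ids <- plan$sample[plan$fold == f]
    in_test <- data$sample %in% test_ids
    train <- data[!in_test, , drop = FALSE]
    test <- data[in_test, , drop = FALSE]
    if (length(unique(train$response)) < 2L) {
      abort("training split contains a single class",
            class = "mechsig_degenerate_split")
    }
    scored[[f]] <- fit_or_constant(train, test, opts)
  }
  dplyr::bind_rows(scored)
}

# Draw a plan, rerunning with derived seeds when a split is degenerate.
kfold_with_redraw <- function(data, k, seed, opts, redraw_cap = 100) {
  for (attempt in seq_len(redraw_cap)) {
    plan <- make_folds(data[c("sample", "cohort")], k = k,
                       seed = derive_seed(seed, attempt - 1L))
    res <- tryCatch(
      kfold_once(data, plan, opts),
      mechsig_degenerate_split = function(e) NULL
    )
    if (!is.null(res)) {
      if (attempt > 1L) {
        inform(sprintf("fold plan redrawn %d time(s) for degenerate splits", attempt - 1L))
      }
      return(res)
    }
  }
  abort(sprintf("no viable fold plan after %d redraws", redraw_cap))
}

summarise_repeats <- function(reports) {
  stats_cols <- c("auroc", "sensitivity", "specificity", "precision", "likelihood_ratio")
  purrr::map_dfr(stats_cols, function(s) {
    v <- reports[[s]]
    v <- v[!is.na(v)]
    tibble::tibble(
      statistic = s,
      median = median(v),
      lower = quantile(v, 0.025, names = FALSE, type = 7),
      upper = quantile(v, 0.975, names = FALSE, type = 7)
    )
  })
}

#' Repeated cohort-balanced k-fold cross-validation
#'
#' Per repeat: draw a cohort-balanced fold plan, train the full recipe
#' (lasso fit, rescale, threshold) on nine of ten folds and score the
#' held-out fold, pool the out-of-fold scores, and compute a performance
#' report. Repeats whose fold plan produces a single-class training split
#' are redrawn (with derived seeds, capped). Summaries are the median and
#' the 2.5/97.5 percentiles of each statistic across repeats.
#'
#' @param data Feature tibble: `sample`, `cohort`, `response` plus one
#'   numeric column per mechanism (see [stack_strengths()]).
#' @param k Folds per repeat (default 10).
#' @param repeats Number of CV repeats (default 100).
#' @param seed Root seed; per-repeat seeds are derived substreams.
#' @param target_sensitivity,penalty,nfolds,standardize Passed to
#'   [fit_mechanism_classifier()] for every training split.
#' @return Object of class `mech_cv`: `reports` (one row per repeat),
#'   `summary` (median + percentile interval per statistic), `scores`
#'   (pooled score table of the representative repeat whose AUROC is
#'   closest to the median), and the run settings.
#' @export
crossval_kfold <- function(data, k = 10, repeats = 100, seed = 1,
                           target_sensitivity = 0.6, penalty = "lambda.1se",
                           nfolds = 5, standardize = FALSE) {
  if (!all(c("sample", "cohort", "response") %in% names(data))) {
    abort("`data` needs columns sample, cohort, response")
  }
  check_scalar_number(repeats, "repeats", lower = 1)
  reports <- vector("list", repeats)
  pooled <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    rseed <- derive_seed(seed, 1000 + r)
    opts <- cv_opts(target_sensitivity, penalty, nfolds, standardize, seed = rseed)
    scored <- kfold_with_redraw(data, k, rseed, opts)
    reports[[r]] <- dplyr::bind_cols(tibble::tibble(rep = r), performance_report(scored))
    pooled[[r]] <- scored
  }
  reports <- dplyr::bind_rows(reports)
  rep_star <- reports$rep[which.min(abs(reports$auroc - median(reports$auroc)))]
  structure(
    list(
      reports = reports,
      summary = summarise_repeats(reports),
      scores = pooled[[rep_star]],
      representative_rep = rep_star,
      k = k, repeats = repeats, seed = seed
    ),
    class = "mech_cv"
  )
}

#' Leave-one-sample-out cross-validation
#'
#' Equivalent to a single repeat of [crossval_kfold()] with `k` equal to
#' the number of samples; deterministic up to the (irrelevant) fold order.
#'
#' @inheritParams crossval_kfold
#' @return A `mech_cv` object with one report row.
#' @export
crossval_loso <- function(data, seed = 1, target_sensitivity = 0.6,
                          penalty = "lambda.1se", nfolds = 5,
                          standardize = FALSE) {
  crossval_kfold(
    data,
    k = nrow(data), repeats = 1, seed = seed,
    target_sensitivity = target_sensitivity, penalty = penalty,
    nfolds = nfolds, standardize = standardize
  )
}

#' Leave-one-batch-out cross-validation
#'
#' Trains on every combination of all-but-one cohort and tests on the
#' held-out cohort. Because strength scores are median-referenced within
#' each cohort, the held-out cohort's features are already expressed
#' against its own internal reference; nothing is recomputed from training
#' data. Held-out cohorts with a single class get `NA` statistics.
#'
#' @inheritParams crossval_kfold
#' @return Object of class `mech_lobo`: `reports` (one row per held-out
#'   cohort plus a `mean` summary row), `scores` (all held-out score
#'   tables, pooled), `models` (one `mech_classifier` per held-out
#'   cohort).
#' @export
crossval_lobo <- function(data, seed = 1, target_sensitivity = 0.6,
                          penalty = "lambda.1se", nfolds = 5,
                          standardize = FALSE) {
  cohorts <- unique(data$cohort)
  if (length(cohorts) < 2L) abort("leave-one-batch-out needs at least 2 cohorts")
  opts <- cv_opts(target_sensitivity, penalty, nfolds, standardize, seed = seed)
  models <- list()
  scored <- list()
  reports <- list()
  for (co in cohorts) {
    train <- data[data$cohort != co, , drop = FALSE]
    test <- data[data$cohort == co, , drop = FALSE]
    if (length(unique(train$response)) < 2L) {
      abort(sprintf("training cohorts for held-out '%s' contain a single class", co))
    }
    model <- fit_mechanism_classifier(
      train,
      target_sensitivity = opts$target_sensitivity, penalty = opts$penalty,
      nfolds = opts$nfolds, standardize = opts$standardize,
      seed = derive_seed(seed, match(co, cohorts))
    )
    sc <- predict(model, test)
    models[[co]] <- model
    scored[[co]] <- sc
    reports[[co]] <- if (length(unique(sc$response)) < 2L) {
      tibble::tibble(cohort = co, auroc = NA_real_)
    } else {
      dplyr::bind_cols(tibble::tibble(cohort = co), performance_report(sc))
    }
  }
  reports <- dplyr::bind_rows(reports)
  num <- vapply(reports, is.numeric, logical(1))
  mean_row <- dplyr::bind_cols(
    tibble::tibble(cohort = "mean"),
    tibble::as_tibble(as.list(colMeans(reports[num], na.rm = TRUE)))
  )
  structure(
    list(
      reports = dplyr::bind_rows(reports, mean_row),
      scores = dplyr::bind_rows(scored),
      models = models,
      seed = seed
    ),
    class = "mech_lobo"
  )
}

#' Label-permutation null distribution of the CV AUROC
#'
#' Randomly permutes the response labels across the pooled samples before
#' each repeat (class counts preserved), then runs one full
#' cohort-balanced k-fold CV on the permuted labels. The resulting AUROC
#' distribution is the null against which the observed CV performance is
#' judged.
#'
#' @inheritParams crossval_kfold
#' @param reference_auroc Optional observed AUROC; when given, the
#'   empirical exceedance count (null repeats strictly above it) is
#'   reported.
#' @return Object of class `mech_permnull`: `aurocs`, `median_auroc`,
#'   `exceedance`, `reference_auroc`, and the run settings.
#' @export
permutation_null <- function(data, k = 10, repeats = 100, seed = 1,
                             reference_auroc = NULL,
                             target_sensitivity = 0.6, penalty = "lambda.1se",
                             nfolds = 5, standardize = FALSE) {
  if (!all(c("sample", "cohort", "response") %in% names(data))) {
    abort("`data` needs columns sample, cohort, response")
  }
  aurocs <- numeric(repeats)
  for (r in seq_len(repeats)) {
    rseed <- derive_seed(seed, 5000 + r)
    set.seed(rseed)
    permuted <- data
    permuted$response <- sample(data$response)
    opts <- cv_opts(target_sensitivity, penalty, nfolds, standardize, seed = rseed)
    scored <- kfold_with_redraw(permuted, k, derive_seed(rseed, 7), opts)
    aurocs[r] <- auroc(
      scored$score[scored$response == "NR"],
      scored$score[scored$response == "R"]
    )
  }
  structure(
    list(
      aurocs = aurocs,
      median_auroc = median(aurocs),
      reference_auroc = reference_auroc,
      exceedance = if (is.null(reference_auroc)) NA_integer_ else sum(aurocs > reference_auroc),
      k = k, repeats = repeats, seed = seed
    ),
    class = "mech_permnull"
  )
}

#' @export
print.mech_cv <- function(x, ...) {
  cat(sprintf("Repeated %d-fold CV, %d repeat(s)\n", x$k, x$repeats))
  print(x$summary)
  invisible(x)
}

#' @export
print.mech_lobo <- function(x, ...) {
  cat("Leave-one-batch-out CV\n")
  print(dplyr::select(
    x$reports, "cohort", dplyr::any_of(c(
      "auroc", "sensitivity", "specificity", "precision", "likelihood_ratio"
    ))
  ))
  invisible(x)
}

#' @export
print.mech_permnull <- function(x, ...) {
  cat(sprintf(
    "Permutation null: median AUROC %.3f over %d repeats%s\n",
    x$median_auroc, x$repeats,
    if (is.null(x$reference_auroc)) "" else {
      sprintf("; %d repeat(s) above reference %.3f", x$exceedance, x$reference_auroc)
    }
  ))
  invisible(x)
}

#' @method tidy mech_cv
#' @export
tidy.mech_cv <- function(x, ...) x$reports

#' @method glance mech_cv
#' @export
glance.mech_cv <- function(x, ...) {
  tidyr::pivot_wider(
    x$summary,
    names_from = "statistic",
    values_from = c("median", "lower", "upper"),
    names_glue = "{statistic}_{.value}"
  ) |>
    dplyr::mutate(k = x$k, repeats = x$repeats)
}

#' @method tidy mech_lobo
#' @export
tidy.mech_lobo <- function(x, ...) x$reports

#' @method tidy mech_permnull
#' @export
tidy.mech_permnull <- function(x, ...) {
  tibble::tibble(rep = seq_along(x$aurocs), auroc = x$aurocs)
}

#' @method glance mech_permnull
#' @export
glance.mech_permnull <- function(x, ...) {
  tibble::tibble(
    median_auroc = x$median_auroc,
    exceedance = x$exceedance,
    reference_auroc = x$reference_auroc %||% NA_real_,
    repeats = x$repeats, k = x$k
  )
}

#' @describeIn crossval_kfold Patient-stratification plot of the
#'   representative repeat: samples ordered by out-of-fold score, coloured
#'   by clinical response, faceted by nothing; cohort shown in the rug.
#' @param object A `mech_cv` object.
#' @param ... Unused.
#' @method autoplot mech_cv
#' @export
autoplot.mech_cv <- function(object, ...) {
  df <- object$scores |>
    dplyr::arrange(.data$score) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$score, fill = .data$response)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(
      x = "Patients (sorted by classifier score)", y = "Classifier score",
      fill = "Response"
    ) +
    ggplot2::theme_minimal()
}
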