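# The mechanism classifier: lasso-penalized logistic regression on
# strength scores, affinely rescaled so training scores span [0.5, 9.5],
# clipped to [0, 10] on test samples, and thresholded so that a target
# fraction (60% by default) of training non-responders fall above the
# decision threshold.

#' Fit the lasso logistic model on mechanism strengths
#'
#' L1-penalized logistic regression with NR as the positive class. The
#' penalty is chosen by internal stratified k-fold cross-validation
#' minimizing binomial deviance, taking the sparser one-standard-error
#' solution by default.
#'
#' @param x Numeric matrix, samples x mechanisms (finite).
#' @param y Response labels (`"R"`/`"NR"`), length `nrow(x)`; both classes
#'   must have at least 2 samples.
#' @param penalty `"lambda.1se"` (default, sparser) or `"lambda.min"`.
#' @param nfolds Internal CV folds for penalty selection (default 5).
#' @param lambda Optional fixed penalty value; when given, the internal
#'   CV is skipped and the model is fit at exactly this penalty.
#' @param standardize Standardize columns before fitting? Default `FALSE`:
#'   strength scores already share log2 fold-change units.
#' @param seed Integer seed for the internal CV fold assignment.
#' @return List: `coefficients` (named, length `ncol(x)`, exact zeros for
#'   unselected mechanisms), `intercept`, `lambda`, `penalty`.
#' @export
fit_lasso <- function(x, y, penalty = c("lambda.1se", "lambda.min"),
                      nfolds = 5, standardize = FALSE, seed = 1,
                      lambda = NULL) {
  penalty <- match.arg(penalty)
  y <- as_response(y)
  if (!is.matrix(x) || !is.numeric(x)) abort("`x` must be a numeric matrix")
  if (any(!is.finite(x))) abort("`x` contains non-finite strength values")
  if (nrow(x) != length(y)) abort("`x` and `y` disagree in length")
  tab <- table(y)
  if (any(tab < 2)) {
    abort(sprintf(
      "need at least 2 samples per class (got R = %d, NR = %d)",
      tab[["R"]], tab[["NR"]]
    ))
  }
  if (!is.null(lambda)) {
    # put the requested penalty on the path so no interpolation happens
    lam_seq <- sort(unique(exp(seq(log(lambda * 1000), log(lambda), length.out = 30))),
                    decreasing = TRUE)
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                          standardize = standardize, lambda = lam_seq)
    cf <- as.numeric(coef(fit, s = lambda))
    return(list(
      coefficients = setNames(cf[-1], colnames(x)),
      intercept = cf[1],
      lambda = lambda,
      penalty = "fixed"
    ))
  }
  nfolds <- min(nfolds, min(tab))
  if (nfolds < 3) nfolds <- 3
  # stratified fold ids: deal each class round-robin after a shuffle
  set.seed(derive_seed(seed, 101))
  foldid <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    foldid[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  # glmnet warns on every internal fold when a class is small; with the
  # cohort sizes this model targets that is the norm, not a defect
  cv <- withCallingHandlers(
    glmnet::cv.glmnet(
      x, y,
      family = "binomial", alpha = 1,
      foldid = foldid, standardize = standardize,
      type.measure = "deviance"
    ),
    warning = function(w) {
      if (grepl("fewer than 8|dangerous ground", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  lam <- cv[[penalty]]
  cf <- as.numeric(coef(cv, s = lam))
  list(
    coefficients = setNames(cf[-1], colnames(x)),
    intercept = cf[1],
    lambda = lam,
    penalty = penalty
  )
}

#' Affine rescaling of a fitted linear predictor
#'
#' Solves for the positive-slope affine map sending the minimum training
#' linear predictor to `lower` and the maximum to `upper`.
#'
#' @param lp Numeric vector of training linear predictors (non-constant).
#' @param lower,upper Target span, default 0.5 and 9.5.
#' @return Named numeric vector `c(slope, offset)`.
#' @export
#' @examples
#' rescale_parameters(c(-2, 0, 3)) # slope 1.8, offset 4.1
rescale_parameters <- function(lp, lower = 0.5, upper = 9.5) {
  rng <- range(lp)
  if (diff(rng) < 1e-12) {
    abort("training linear predictor is constant; degenerate fit cannot be rescaled")
  }
  slope <- (upper - lower) / diff(rng)
  offset <- lower - slope * rng[1]
  c(slope = slope, offset = offset)
}

#' Select the decision threshold from training non-responder scores
#'
#' Picks the largest threshold such that at least `target_sensitivity` of
#' the training NR scores lie strictly above it. With distinct scores this
#' is the `floor((1 - target) * n)`-th ascending order statistic; ties are
#' resolved toward the lower threshold (higher sensitivity). When every
#' admissible threshold would have to sit below the minimum NR score, a
#' value strictly below that minimum is returned.
#'
#' @param scores Numeric classifier scores.
#' @param labels Response labels aligned with `scores`; at least one NR.
#' @param target_sensitivity Fraction of training NRs that must score
#'   above the threshold (default 0.6).
#' @return The threshold (scalar).
#' @export
#' @examples
#' select_threshold(c(2, 4, 6, 8, 10), rep("NR", 5), 0.6) # 4
select_threshold <- function(scores, labels, target_sensitivity = 0.6) {
  labels <- as_response(labels)
  nr <- scores[labels == "NR"]
  if (length(nr) == 0L) abort("no non-responders in the training set")
  check_scalar_number(target_sensitivity, "target_sensitivity", lower = 0, upper = 1)
  m <- min(nr)
  below_min <- if (m > 0) max(m - 1, m / 2) else m - 1
  cand <- sort(c(below_min, unique(nr)), decreasing = TRUE)
  for (t in cand) {
    if (mean(nr > t) >= target_sensitivity) return(t)
  }
  below_min
}

#' Fit the full mechanism classifier
#'
#' Runs the complete training recipe on a stacked feature table: lasso
#' logistic fit, affine rescaling of coefficients and intercept so the
#' training scores span exactly \[0.5, 9.5\], and threshold selection at
#' the target training NR sensitivity.
#'
#' @param data Tibble with id columns `sample` (required), `cohort`
#'   (optional) and `response` (`"R"`/`"NR"`), plus one numeric column per
#'   mechanism (as from [stack_strengths()]).
#' @param target_sensitivity Training NR sensitivity for the threshold
#'   (default 0.6).
#' @inheritParams fit_lasso
#' @return An object of class `mech_classifier`: rescaled `coefficients`
#'   (nonzero only) and `constant`, the raw logit-scale fit, the rescale
#'   map, `threshold`, and the training score table.
#' @export
fit_mechanism_classifier <- function(data, target_sensitivity = 0.6,
                                     penalty = "lambda.1se", nfolds = 5,
                                     standardize = FALSE, seed = 1) {
  x <- feature_matrix(data)
  if (!"response" %in% names(data)) abort("`data` must have a 'response' column")
  y <- as_response(data$response)
  raw <- fit_lasso(x, y,
    penalty = penalty, nfolds = nfolds,
    standardize = standardize, seed = seed
  )
  lp <- drop(x %*% raw$coefficients) + raw$intercept
  map <- rescale_parameters(lp)
  coefs <- raw$coefficients * map[["slope"]]
  constant <- raw$intercept * map[["slope"]] + map[["offset"]]
  train_scores <- lp * map[["slope"]] + map[["offset"]]
  threshold <- select_threshold(train_scores, y, target_sensitivity)
  training <- tibble::tibble(
    sample = as.character(data$sample),
    cohort = if ("cohort" %in% names(data)) as.character(data$cohort) else NA_character_,
    response = as.character(y),
    score = train_scores,
    predicted = ifelse(train_scores > threshold, "NR", "R")
  )
  structure(
    list(
      coefficients = coefs[coefs != 0],
      constant = constant,
      raw_coefficients = raw$coefficients,
      raw_intercept = raw$intercept,
      rescale = map,
      threshold = threshold,
      target_sensitivity = target_sensitivity,
      lambda = raw$lambda,
      penalty = raw$penalty,
      standardize = standardize,
      mechanisms = colnames(x),
      training = training,
      seed = seed
    ),
    class = "mech_classifier"
  )
}

#' Score samples with a fitted mechanism classifier
#'
#' Computes `constant + sum(coefficients * strength)` and clips the result
#' to \[0, 10\] (sub-zero scores to 0, above-ten scores to 10). Samples
#' score above the threshold are predicted NR.
#'
#' @param object A `mech_classifier`.
#' @param data Feature tibble (`sample` plus mechanism columns); every
#'   mechanism with a nonzero coefficient must be present.
#' @param ... Unused.
#' @return Tibble (`sample`, `cohort` if present, `response` if present,
#'   `score`, `predicted`).
#' @export
predict.mech_classifier <- function(object, data, ...) {
  need <- names(object$coefficients)
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(paste0(
      "data lacks classifier mechanism(s): ", paste(missing, collapse = ", ")
    ))
  }
  x <- as.matrix(data[need])
  raw_score <- drop(x %*% object$coefficients) + object$constant
  score <- pmin(pmax(raw_score, 0), 10)
  out <- tibble::tibble(
    sample = as.character(data$sample),
    score = score,
    predicted = ifelse(score > object$threshold, "NR", "R")
  )
  if ("cohort" %in% names(data)) out <- tibble::add_column(out, cohort = as.character(data$cohort), .after = "sample")
  if ("response" %in% names(data)) out <- tibble::add_column(out, response = as.character(data$response), .before = "score")
  out
}

#' Per-gene contribution to the classifier score
#'
#' Decomposes the linear model down to genes: each gene contributes
#' `coefficient_m * sign_g / |G'_m|` through every selected mechanism `m`
#' containing it, where `G'_m` is the mechanism's gene support in the
#' given universe. Genes in no selected mechanism contribute 0.
#'
#' @param object A `mech_classifier`.
#' @param mechanisms Long-format mechanism tibble used in training.
#' @param gene_universe Character vector: the genes measured (support is
#'   computed against this universe).
#' @return Tibble (`gene`, `contribution`) over `gene_universe`, sorted
#'   by decreasing absolute contribution.
#' @export
gene_contributions <- function(object, mechanisms, gene_universe) {
  mechanisms <- validate_mechanisms(mechanisms)
  sel <- names(object$coefficients)
  mem <- mechanisms[mechanisms$set %in% sel & mechanisms$gene %in% gene_universe, ]
  contrib <- setNames(numeric(length(gene_universe)), gene_universe)
  if (nrow(mem) > 0L) {
    support <- table(mem$set)
    per_row <- object$coefficients[mem$set] * mem$sign / as.numeric(support[mem$set])
    agg <- tapply(per_row, mem$gene, sum)
    contrib[names(agg)] <- agg
  }
  tibble::tibble(gene = names(contrib), contribution = as.numeric(contrib)) |>
    dplyr::arrange(dplyr::desc(abs(.data$contribution)))
}

#' @export
print.mech_classifier <- function(x, ...) {
  cat(sprintf(
    "Mechanism classifier: %d mechanisms, constant %.3f, threshold %.3f (target NR sensitivity %.0f%%)\n",
    length(x$coefficients), x$constant, x$threshold, 100 * x$target_sensitivity
  ))
  invisible(x)
}

#' @describeIn fit_mechanism_classifier Tidy the fitted linear model: one
#'   row per selected mechanism plus the constant, on the rescaled score
#'   scale (`estimate`) and the raw logit scale (`raw_estimate`).
#' @param x A `mech_classifier`.
#' @param ... Unused.
#' @method tidy mech_classifier
#' @export
tidy.mech_classifier <- function(x, ...) {
  tibble::tibble(
    term = c("(Constant)", names(x$coefficients)),
    estimate = c(x$constant, unname(x$coefficients)),
    raw_estimate = c(x$raw_intercept, unname(x$raw_coefficients[names(x$coefficients)]))
  )
}

#' @describeIn fit_mechanism_classifier One-row model summary.
#' @method glance mech_classifier
#' @export
glance.mech_classifier <- function(x, ...) {
  tr <- x$training
  tibble::tibble(
    n_mechanisms = length(x$coefficients),
    lambda = x$lambda,
    threshold = x$threshold,
    target_sensitivity = x$target_sensitivity,
    n_train = nrow(tr),
    n_train_nr = sum(tr$response == "NR"),
    train_auroc = auroc(tr$score[tr$response == "NR"], tr$score[tr$response == "R"])
  )
}

#' @describeIn fit_mechanism_classifier Coefficient plot: selected
#'   mechanisms ordered by rescaled coefficient.
#' @method autoplot mech_classifier
#' @export
autoplot.mech_classifier <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$term != "(Constant)") |>
    dplyr::mutate(term = stats::reorder(.data$term, .data$estimate))
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$term,
                                   fill = .data$estimate > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "Coefficient (score scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Write / read a mechanism classifier as JSON
#'
#' Serializes every model component at full precision; reading the file
#' back reproduces the model bit-exactly.
#'
#' @param object A `mech_classifier`.
#' @param path JSON path.
#' @return `path` invisibly; `read_classifier()` returns the model.
#' @export
write_classifier <- function(object, path) {
  payload <- unclass(object)
  # named numeric vectors must go out as JSON objects, not bare arrays
  payload$coefficients <- as.list(payload$coefficients)
  payload$raw_coefficients <- as.list(payload$raw_coefficients)
  payload$rescale <- as.list(payload$rescale)
  payload$training <- as.list(payload$training)
  # 17 significant digits: doubles survive the JSON round trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$coefficients <- unlist(p$coefficients)
  p$raw_coefficients <- unlist(p$raw_coefficients)
  p$rescale <- unlist(p$rescale)
  p$training <- tibble::as_tibble(p$training)
  structure(p, class = "mech_classifier")
}
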