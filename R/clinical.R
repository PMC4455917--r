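# Clinical response calling from DAS28 and the DAS28 measurement-noise
# ceiling on classifier AUROC.
#
# DAS28 is the 28-joint disease activity score (range roughly 0-10).
# Improvement is delta = baseline - followup (positive = better). The
# EULAR response grid classifies (delta, attained DAS28) into
# good / moderate / none; "none" maps to non-responder here.

# EULAR grid thresholds (van Gestel criteria): delta cutoffs 1.2 / 0.6,
# attained-DAS28 cutoffs 3.2 / 5.1. Implemented from the standard
# definition, which the study invokes by name.
EULAR_DELTA_HI <- 1.2
EULAR_DELTA_LO <- 0.6
EULAR_LOW_DAS <- 3.2
EULAR_HIGH_DAS <- 5.1

#' EULAR response category
#'
#' Vectorized good/moderate/none classification from baseline and
#' follow-up DAS28: good iff improvement > 1.2 and attained DAS28 <= 3.2;
#' moderate iff (improvement > 1.2 and attained > 3.2) or
#' (0.6 < improvement <= 1.2 and attained <= 5.1); none otherwise.
#'
#' @param baseline,followup DAS28 scores (finite, non-negative).
#' @return A factor with levels `good`, `moderate`, `none`.
#' @export
#' @examples
#' eular_category(6.0, 3.0) # good
#' eular_category(6.0, 5.6) # none
#' eular_category(5.0, 4.0) # moderate
eular_category <- function(baseline, followup) {
  if (any(!is.finite(baseline)) || any(!is.finite(followup)) ||
      any(baseline < 0) || any(followup < 0)) {
    abort("DAS28 scores must be finite and non-negative")
  }
  delta <- baseline - followup
  out <- dplyr::case_when(
    delta > EULAR_DELTA_HI & followup <= EULAR_LOW_DAS ~ "good",
    delta > EULAR_DELTA_HI ~ "moderate",
    delta > EULAR_DELTA_LO & followup <= EULAR_HIGH_DAS ~ "moderate",
    TRUE ~ "none"
  )
  factor(out, levels = c("good", "moderate", "none"))
}

#' Derive responder / non-responder labels from DAS28 records
#'
#' Criteria:
#' \describe{
#'   \item{`eular_moderate_good`}{NR iff the EULAR category is none;
#'     moderate and good are R (the usual trial convention).}
#'   \item{`eular_good_only`}{R iff good, NR iff none; moderate patients
#'     get `NA` (excluded), as in cohorts that labeled only good as R.}
#'   \item{`delta_1.2`}{Threshold on improvement alone: NR iff
#'     delta < 1.2, or delta <= 1.2 when `delta_inclusive = TRUE`
#'     (cohorts differ in whether 1.2 itself counts as non-response).}
#' }
#'
#' @param records Tibble with columns `subject`, `das28_baseline`,
#'   `das28_followup`. `delta` is always recomputed as baseline minus
#'   follow-up, never trusted from the input.
#' @param criterion One of the tags above.
#' @param delta_inclusive For `delta_1.2`: treat delta equal to 1.2 as NR.
#' @return Tibble (`subject`, `delta`, `label`, `criterion`); `label` is
#'   `"R"`, `"NR"` or `NA` for excluded subjects.
#' @export
response_label <- function(records,
                           criterion = c("eular_moderate_good", "eular_good_only", "delta_1.2"),
                           delta_inclusive = FALSE) {
  criterion <- match.arg(criterion)
  need <- c("subject", "das28_baseline", "das28_followup")
  if (!all(need %in% names(records))) {
    abort(paste0("`records` needs columns: ", paste(need, collapse = ", ")))
  }
  delta <- records$das28_baseline - records$das28_followup
  label <- switch(criterion,
    eular_moderate_good = {
      cat_ <- eular_category(records$das28_baseline, records$das28_followup)
      ifelse(cat_ == "none", "NR", "R")
    },
    eular_good_only = {
      cat_ <- eular_category(records$das28_baseline, records$das28_followup)
      dplyr::case_when(
        cat_ == "good" ~ "R",
        cat_ == "none" ~ "NR",
        TRUE ~ NA_character_
      )
    },
    delta_1.2 = {
      if (delta_inclusive) ifelse(delta <= EULAR_DELTA_HI, "NR", "R")
      else ifelse(delta < EULAR_DELTA_HI, "NR", "R")
    }
  )
  tibble::tibble(
    subject = records$subject,
    delta = delta,
    label = label,
    criterion = criterion
  )
}

#' DAS28 measurement-noise ceiling on classifier AUROC
#'
#' DAS28 has a known measurement standard deviation of about 0.6. Even a
#' classifier that knew each patient's true improvement exactly could not
#' perfectly predict response calls made from *noisy* DAS28 measurements.
#' This simulation quantifies that ceiling: per repetition, independent
#' Gaussian noise (sd `sd`) is added to every baseline and follow-up
#' score, response labels are re-derived from the noisy scores, and the
#' AUROC of the original improvement (negated, so larger = more NR-like)
#' against the noisy labels is computed. The median over repetitions is
#' the maximum expected AUROC of any DAS28-based classifier.
#'
#' @param records Tibble with `subject`, `das28_baseline`,
#'   `das28_followup`.
#' @param sd Measurement noise standard deviation (DAS28 units),
#'   default 0.6. Noise is applied independently to baseline and
#'   follow-up, so the improvement's noise sd is `sd * sqrt(2)`.
#' @param reps Number of noise repetitions (default 1000).
#' @param criterion Response criterion tag passed to [response_label()].
#' @param seed Integer seed; per-rep noise uses derived substreams.
#' @param delta_inclusive Passed to [response_label()].
#' @return An object of class `das28_ceiling`: list with `median_auroc`,
#'   `aurocs` (length `reps`, `NA` for skipped single-class reps),
#'   `n_skipped`, `sd`, `criterion`.
#' @export
das28_noise_ceiling <- function(records, sd = 0.6, reps = 1000,
                                criterion = "eular_moderate_good",
                                seed = 1, delta_inclusive = FALSE) {
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0) {
    abort("`sd` must be a single non-negative number")
  }
  check_scalar_number(reps, "reps", lower = 1)
  n <- nrow(records)
  if (n < 2L) abort("need at least 2 DAS28 records")
  delta <- records$das28_baseline - records$das28_followup
  score <- -delta # larger score = less improvement = more NR-like

  aurocs <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, r))
    nb <- pmax(records$das28_baseline + rnorm(n, 0, sd), 0)
    nf <- pmax(records$das28_followup + rnorm(n, 0, sd), 0)
    noisy <- records
    noisy$das28_baseline <- nb
    noisy$das28_followup <- nf
    lab <- response_label(noisy, criterion, delta_inclusive = delta_inclusive)$label
    ok <- !is.na(lab)
    if (length(unique(lab[ok])) < 2L) next # single-class rep: skip
    aurocs[r] <- auroc(score[ok & lab == "NR"], score[ok & lab == "R"])
  }
  n_skipped <- sum(is.na(aurocs))
  if (n_skipped == reps) {
    abort("every repetition produced a single class; records are degenerate")
  }
  if (n_skipped > 0) {
    inform(sprintf("%d of %d repetitions had a single noisy class and were skipped",
                   n_skipped, reps))
  }
  structure(
    list(
      median_auroc = median(aurocs, na.rm = TRUE),
      aurocs = aurocs, n_skipped = n_skipped,
      sd = sd, criterion = criterion, reps = reps, seed = seed
    ),
    class = "das28_ceiling"
  )
}

#' @export
print.das28_ceiling <- function(x, ...) {
  cat(sprintf(
    "DAS28 noise ceiling: median AUROC %.3f (sd = %.2f, %d reps, %d skipped, criterion %s)\n",
    x$median_auroc, x$sd, x$reps, x$n_skipped, x$criterion
  ))
  invisible(x)
}

#' @method tidy das28_ceiling
#' @export
tidy.das28_ceiling <- function(x, ...) {
  tibble::tibble(rep = seq_along(x$aurocs), auroc = x$aurocs)
}

#' @method glance das28_ceiling
#' @export
glance.das28_ceiling <- function(x, ...) {
  tibble::tibble(
    median_auroc = x$median_auroc, sd = x$sd,
    reps = x$reps, n_skipped = x$n_skipped, criterion = x$criterion
  )
}
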