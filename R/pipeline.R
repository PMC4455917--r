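# End-to-end orchestration: one config (list or YAML file) drives
# ingest -> strength scoring -> training -> cross-validation -> reports,
# with every artifact written to an output directory and all randomness
# flowing from a single root seed.

#' Run the full pipeline from a configuration
#'
#' The configuration is a named list (or path to a YAML file holding
#' one) with entries:
#' \describe{
#'   \item{`cohorts`}{Named list: cohort id -> expression TSV path.}
#'   \item{`mechanisms`}{Path to a signed-GMT file.}
#'   \item{`annotations`}{Path to the sample-annotation TSV.}
#'   \item{`out`}{Output directory.}
#'   \item{`seed`}{Root seed (required).}
#'   \item{`min_genes`}{Coverage threshold, default 4.}
#'   \item{`target_sensitivity`}{Default 0.6.}
#'   \item{`log2_transform`}{Apply log2(x+1) on ingest, default `FALSE`.}
#'   \item{`crossval`}{Optional list: `scheme` (`"kfold"`, `"lobo"`,
#'     `"loso"` or `"permutation"`), `k`, `repeats`.}
#' }
#'
#' Artifacts written: per-cohort strength TSVs (+ support), the fitted
#' model JSON, the training score table, a performance report JSON, ROC
#' points TSV, CV outputs when requested, and a run log echoing the
#' config and package versions. All tables carry a schema-version
#' comment line; numeric outputs are deterministic given config + seed.
#'
#' @param config Named list or YAML path.
#' @return Invisibly, a list with the fitted model, the feature table,
#'   the performance report and any CV result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML path")
  for (field in c("cohorts", "mechanisms", "annotations", "out", "seed")) {
    if (is.null(config[[field]])) abort(paste0("config lacks required field '", field, "'"))
  }
  paths <- c(unlist(config$cohorts), config$mechanisms, config$annotations)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("config references missing file(s): ", paste(missing, collapse = ", ")))
  }
  min_genes <- config$min_genes %||% 4
  target_sens <- config$target_sensitivity %||% 0.6
  seed <- as.integer(config$seed)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    paste0("mechsig pipeline run, package version ",
           as.character(utils::packageVersion("mechsig"))),
    paste0("R version: ", R.version.string),
    paste0("config: ", jsonlite::toJSON(config, auto_unbox = TRUE))
  )

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste0("FAILED at stage: ", name)),
                 file.path(out, "run_log.txt.incomplete"))
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  mechanisms <- stage("mechanism_kb", {
    resolve_conflicts(read_signed_gmt(config$mechanisms))
  })
  annotations <- stage("ingest", read_sample_annotations(config$annotations))
  cohorts <- stage("ingest", {
    purrr::imap(config$cohorts, function(p, id) {
      drop_incomplete_genes(
        read_expression_matrix(p, log2_transform = isTRUE(config$log2_transform))
      )
    })
  })
  features <- stage("strength", {
    universes <- lapply(cohorts, function(e) e$gene)
    mechs <- filter_by_coverage(mechanisms, universes, min_genes = min_genes)
    strengths <- lapply(
      lapply(cohorts, median_center),
      strength_scores, mechanisms = mechs, min_genes = min_genes
    )
    for (cid in names(strengths)) {
      write_table_versioned(strengths[[cid]],
                            file.path(out, paste0("strengths_", cid, ".tsv")))
      write_table_versioned(strength_support(strengths[[cid]]),
                            file.path(out, paste0("support_", cid, ".tsv")))
    }
    stack_strengths(strengths, annotations = annotations)
  })
  model <- stage("train", {
    m <- fit_mechanism_classifier(
      features,
      target_sensitivity = target_sens, seed = seed
    )
    write_classifier(m, file.path(out, "model.json"))
    write_table_versioned(m$training, file.path(out, "training_scores.tsv"))
    m
  })
  report <- stage("report", {
    rep_ <- performance_report(model$training)
    jsonlite::write_json(as.list(rep_), file.path(out, "performance.json"),
                         auto_unbox = TRUE, digits = NA)
    tr <- model$training
    roc <- roc_curve(tr$score[tr$response == "NR"], tr$score[tr$response == "R"])
    write_table_versioned(roc, file.path(out, "roc.tsv"))
    rep_
  })
  cv <- NULL
  if (!is.null(config$crossval)) {
    cv <- stage("crossval", {
      scheme <- config$crossval$scheme %||% "kfold"
      k <- config$crossval$k %||% 10
      repeats <- config$crossval$repeats %||% 100
      res <- switch(scheme,
        kfold = crossval_kfold(features, k = k, repeats = repeats, seed = seed,
                               target_sensitivity = target_sens),
        lobo = crossval_lobo(features, seed = seed,
                             target_sensitivity = target_sens),
        loso = crossval_loso(features, seed = seed,
                             target_sensitivity = target_sens),
        permutation = permutation_null(features, k = k, repeats = repeats,
                                       seed = seed,
                                       target_sensitivity = target_sens),
        abort(paste0("unknown crossval scheme '", scheme, "'"))
      )
      if (inherits(res, "mech_cv")) {
        write_table_versioned(res$reports, file.path(out, "cv_reports.tsv"))
        write_table_versioned(res$scores, file.path(out, "cv_scores.tsv"))
        jsonlite::write_json(res$summary, file.path(out, "cv_summary.json"),
                             auto_unbox = TRUE, digits = NA)
      } else if (inherits(res, "mech_lobo")) {
        write_table_versioned(res$reports, file.path(out, "lobo_reports.tsv"))
        write_table_versioned(res$scores, file.path(out, "lobo_scores.tsv"))
      } else if (inherits(res, "mech_permnull")) {
        write_table_versioned(tidy(res), file.path(out, "permutation_null.tsv"))
      }
      res
    })
  }
  writeLines(c(log_lines, "status: complete"), file.path(out, "run_log.txt"))
  invisible(list(model = model, features = features, report = report, crossval = cv))
}

SCHEMA_VERSION <- "mechsig_schema: 1.0"

#' Write / read a schema-versioned TSV
#'
#' Pipeline tables open with a `# mechsig_schema: <version>` comment
#' line; `read_table_versioned()` skips it, so tables round-trip.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path` (write) or a tibble (read).
#' @export
write_table_versioned <- function(x, path) {
  readr::write_lines(paste0("# ", SCHEMA_VERSION), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_table_versioned
#' @export
read_table_versioned <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}
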