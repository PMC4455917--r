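# Cohort expression ingest: reading gene x sample log2 matrices, probe ->
# gene collapsing, technical-replicate averaging, and median-referenced
# differential expression.
#
# Expression travels as a wide tibble: first column `gene` (probe or gene
# id), one numeric column per sample. Matrices are assumed already
# normalized and on the log2 scale; `log2_transform = TRUE` applies
# log2(x + 1) for raw-scale inputs.

#' Read an expression matrix TSV
#'
#' Expects genes (or probes) in rows and samples in columns: a header row
#' of sample ids, first column the row id. Duplicate row ids are permitted
#' (they are resolved by [collapse_probes()]); duplicate sample ids are an
#' error.
#'
#' @param path Path to the TSV.
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` to all values
#'   (for raw-intensity inputs). Default `FALSE`: values are already log2.
#' @return A wide expression tibble (`gene` + one column per sample).
#' @export
read_expression_matrix <- function(path, log2_transform = FALSE) {
  header <- strsplit(readr::read_lines(path, n_max = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 1L) abort("empty expression file")
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids)) {
    abort(paste0(
      "duplicate sample id(s): ",
      paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")
    ))
  }
  # malformed cells/rows are surfaced through problems() below, so the
  # readr parse warning would be redundant noise
  x <- suppressWarnings(readr::read_tsv(
    path,
    col_types = paste0("c", strrep("d", length(sample_ids))),
    name_repair = "minimal",
    progress = FALSE
  ))
  prob <- readr::problems(x)
  if (nrow(prob) > 0L) {
    abort(sprintf(
      "malformed expression matrix: %s at row %d, column %d",
      prob$expected[1], prob$row[1], prob$col[1]
    ))
  }
  names(x) <- c("gene", sample_ids)
  if (log2_transform && ncol(x) > 1L) {
    x[-1] <- lapply(x[-1], function(v) log2(v + 1))
  }
  x
}

#' Read a probe-to-gene map
#'
#' Format: `probe<TAB>gene1,gene2,...` without a header. Probes mapping to
#' no gene may have an empty second field.
#'
#' @param path Path to the map TSV.
#' @return A long tibble (`probe`, `gene`), one row per probe-gene pair;
#'   unmapped probes appear with `gene = NA`.
#' @export
read_probe_map <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = c("probe", "genes"),
    col_types = "cc",
    progress = FALSE
  )
  tidyr::separate_rows(raw, "genes", sep = ",") |>
    dplyr::mutate(gene = dplyr::na_if(trimws(.data$genes), "")) |>
    dplyr::select("probe", "gene")
}

#' Read a sample annotation TSV
#'
#' Columns: `sample`, `subject`, `cohort`, `response`, `das28_baseline`,
#' `das28_followup` (header required; empty fields allowed). Response must
#' be `R`, `NR` or empty (unknown).
#'
#' @param path Path to the annotation TSV.
#' @return A tibble with the columns above; `response` as character with
#'   `NA` for unknown.
#' @export
read_sample_annotations <- function(path) {
  ann <- readr::read_tsv(path, col_types = "ccccdd", progress = FALSE)
  names(ann) <- c("sample", "subject", "cohort", "response",
                  "das28_baseline", "das28_followup")[seq_len(ncol(ann))]
  if ("response" %in% names(ann)) {
    ann$response <- dplyr::na_if(ann$response, "")
    as_response(ann$response, allow_na = TRUE)
  }
  ann
}

#' Collapse probes to genes
#'
#' Probes mapping to more than one gene are discarded entirely; unmapped
#' probes are discarded; where several probes map to one gene, the gene's
#' profile is their arithmetic mean.
#'
#' @param expr Wide expression tibble with probe ids in `gene`.
#' @param probe_map Long tibble (`probe`, `gene`) as from
#'   [read_probe_map()].
#' @return A wide expression tibble keyed by gene id.
#' @export
collapse_probes <- function(expr, probe_map) {
  stopifnot(is.data.frame(expr), is.data.frame(probe_map))
  map <- probe_map[!is.na(probe_map$gene), c("probe", "gene")]
  map <- map[!duplicated(map), ]
  multi <- unique(map$probe[map$probe %in% map$probe[duplicated(map$probe)]])
  map <- map[!map$probe %in% multi, ]
  joined <- dplyr::inner_join(
    dplyr::rename(expr, probe = "gene"), map,
    by = "probe"
  )
  if (nrow(joined) == 0L) abort("no probe could be mapped to a gene")
  out <- joined |>
    dplyr::select(-"probe") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean), .groups = "drop")
  out
}

#' Average technical replicates
#'
#' Drops excluded samples, then replaces samples sharing a subject id with
#' their per-gene mean; output columns are subject ids. If `response` is
#' supplied (named by sample), replicate groups whose members carry
#' conflicting response labels raise an error.
#'
#' @param expr Wide expression tibble.
#' @param sample_map Tibble (`sample`, `subject`) covering every retained
#'   sample.
#' @param exclude Character vector of sample ids to drop first.
#' @param response Optional named character vector (names = sample ids)
#'   of response labels used only for the conflict check.
#' @return A wide expression tibble with subject ids as sample columns.
#' @export
average_technical_replicates <- function(expr, sample_map, exclude = character(),
                                         response = NULL) {
  samples <- setdiff(names(expr)[-1], exclude)
  missing <- setdiff(samples, sample_map$sample)
  if (length(missing)) {
    abort(paste0("sample(s) missing from `sample_map`: ", paste(missing, collapse = ", ")))
  }
  subj <- setNames(sample_map$subject, sample_map$sample)[samples]
  if (!is.null(response)) {
    by_subj <- split(response[samples], subj)
    bad <- names(by_subj)[vapply(by_subj, function(v) {
      length(unique(v[!is.na(v)])) > 1L
    }, logical(1))]
    if (length(bad)) {
      abort(paste0(
        "conflicting response labels within replicate group(s): ",
        paste(bad, collapse = ", ")
      ))
    }
  }
  groups <- split(samples, factor(subj, levels = unique(subj)))
  out <- tibble::tibble(gene = expr$gene)
  for (s in names(groups)) {
    cols <- as.matrix(expr[groups[[s]]])
    out[[s]] <- rowMeans(cols)
  }
  out
}

#' Median-reference an expression cohort
#'
#' Computes each gene's log2 differential expression against the
#' within-cohort population median: `d[g, j] = x[g, j] - median_j(x[g, .])`
#' with the conventional midpoint median for even sample counts. This is
#' the per-cohort common reference that makes strength scores comparable
#' across platforms.
#'
#' @param expr Wide expression tibble (complete: no missing values; genes
#'   with `NA`s raise an error - collapse probes first).
#' @return A wide tibble of the same shape whose rows have median zero.
#' @export
median_center <- function(expr) {
  stopifnot(is.data.frame(expr))
  if (ncol(expr) < 2L) abort("median_center needs at least one sample")
  m <- as.matrix(expr[-1])
  if (anyNA(m)) {
    bad <- expr$gene[rowSums(is.na(m)) > 0]
    abort(paste0(
      "missing values for gene(s): ", paste(head(bad, 5), collapse = ", "),
      if (length(bad) > 5) ", ..." else ""
    ))
  }
  med <- apply(m, 1, median)
  out <- expr
  out[-1] <- m - med
  out
}

#' Drop genes with missing values
#'
#' Convenience filter applied per cohort before [median_center()] when a
#' platform reports incomplete rows; dropped genes simply leave that
#' cohort's gene universe.
#'
#' @param expr Wide expression tibble.
#' @return `expr` without rows containing `NA`s (warns with the count).
#' @export
drop_incomplete_genes <- function(expr) {
  m <- as.matrix(expr[-1])
  bad <- rowSums(is.na(m)) > 0
  if (any(bad)) {
    warn(sprintf("dropping %d gene(s) with missing values", sum(bad)))
  }
  expr[!bad, ]
}
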