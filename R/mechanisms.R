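# Signed gene-set ("mechanism") collections.
#
# A mechanism is a set of genes known to move up (+1) or down (-1) in
# expression when the activity of an upstream biological entity changes.
# Collections are plain tibbles in long form, one row per (set, gene):
#   set         chr  set name, unique within the collection
#   description chr  free text (constant within a set)
#   gene        chr  opaque gene identifier (callers supply matched IDs)
#   sign        int  +1 or -1

new_mechanisms <- function(set, description, gene, sign) {
  tibble::tibble(
    set = as.character(set),
    description = as.character(description),
    gene = as.character(gene),
    sign = as.integer(sign)
  )
}

#' Validate a mechanism collection
#'
#' Checks the long-format contract: required columns, signs in \{-1, +1\},
#' no gene listed twice within a set, non-empty sets.
#'
#' @param mechanisms A tibble with columns `set`, `gene`, `sign` (and
#'   optionally `description`).
#' @return The input, invisibly, with `description` filled in if absent.
#' @export
validate_mechanisms <- function(mechanisms) {
  if (!is.data.frame(mechanisms)) abort("`mechanisms` must be a data frame")
  need <- c("set", "gene", "sign")
  miss <- setdiff(need, names(mechanisms))
  if (length(miss)) abort(paste0("`mechanisms` lacks column(s): ", paste(miss, collapse = ", ")))
  if (!"description" %in% names(mechanisms)) mechanisms$description <- ""
  if (nrow(mechanisms) == 0L) return(invisible(tibble::as_tibble(mechanisms)))
  if (!all(mechanisms$sign %in% c(-1L, 1L))) {
    abort("mechanism signs must all be +1 or -1")
  }
  dup <- duplicated(mechanisms[c("set", "gene")])
  if (any(dup)) {
    abort(paste0(
      "gene(s) listed more than once within a set: ",
      paste(unique(paste0(mechanisms$set[dup], "/", mechanisms$gene[dup])), collapse = ", "),
      "; run resolve_conflicts() first"
    ))
  }
  invisible(tibble::as_tibble(mechanisms))
}

#' Read a signed-GMT mechanism file
#'
#' Signed GMT is a GMT dialect carrying a direction per gene: one set per
#' line, tab-separated, `name<TAB>description<TAB>gene:+1<TAB>gene:-1 ...`.
#' Lines starting with `#` and blank lines are ignored.
#'
#' @param path Path to a signed-GMT file (UTF-8).
#' @return A long-format mechanism tibble (`set`, `description`, `gene`,
#'   `sign`), one row per gene, line order and within-line gene order
#'   preserved.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines("M1\tdemo\tTNF:+1\tIL6:+1\tALB:-1", tf)
#' read_signed_gmt(tf)
read_signed_gmt <- function(path) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(new_mechanisms(character(), character(), character(), integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- purrr::map2(parts, lineno, function(p, ln) {
    if (length(p) < 3L) {
      abort(sprintf("line %d: expected name, description and at least one gene token", ln))
    }
    tok <- p[-(1:2)]
    m <- regmatches(tok, regexec("^(.+):([+-]1)$", tok))
    bad <- lengths(m) != 3L
    if (any(bad)) {
      abort(sprintf(
        "line %d: malformed gene:sign token '%s' (signs must be +1 or -1)",
        ln, tok[bad][1]
      ))
    }
    tibble::tibble(
      set = p[1], description = p[2],
      gene = vapply(m, `[`, "", 2L),
      sign = as.integer(vapply(m, `[`, "", 3L))
    )
  })
  out <- dplyr::bind_rows(rows)
  starts <- vapply(rows, function(r) r$set[1], "")
  if (anyDuplicated(starts)) {
    abort(paste0("duplicate set name(s): ", paste(unique(starts[duplicated(starts)]), collapse = ", ")))
  }
  validate_mechanisms(out)
  out
}

#' Write a mechanism collection as signed GMT
#'
#' Inverse of [read_signed_gmt()]: `read_signed_gmt(write_signed_gmt(x, f))`
#' reproduces `x` exactly for valid collections.
#'
#' @param mechanisms Long-format mechanism tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signed_gmt <- function(mechanisms, path) {
  mechanisms <- validate_mechanisms(mechanisms)
  sets <- split(mechanisms, factor(mechanisms$set, levels = unique(mechanisms$set)))
  lines <- vapply(sets, function(s) {
    paste(c(
      s$set[1], s$description[1],
      paste0(s$gene, ":", ifelse(s$sign > 0, "+1", "-1"))
    ), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a long-format mechanism TSV
#'
#' Two-column-plus-sign long format: a header row then
#' `name<TAB>gene<TAB>sign` with sign written as `+1`/`-1`.
#'
#' @param path Path to the TSV.
#' @return A long-format mechanism tibble.
#' @export
read_mechanisms_tsv <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(raw) < 3L) abort("long-format mechanism TSV needs columns: name, gene, sign")
  names(raw)[1:3] <- c("set", "gene", "sign")
  sgn <- suppressWarnings(as.integer(raw$sign))
  if (any(is.na(sgn) | !sgn %in% c(-1L, 1L))) {
    abort("long-format mechanism TSV: sign column must be +1 or -1")
  }
  out <- new_mechanisms(raw$set, "", raw$gene, sgn)
  validate_mechanisms(out)
  out
}

#' Deduplicate and resolve conflicting gene signs
#'
#' Within each set, repeated (gene, sign) rows are collapsed to one; a gene
#' listed with both signs carries no usable direction and is dropped from
#' that set with a warning. Set order and first-appearance gene order are
#' preserved.
#'
#' @param mechanisms Long-format mechanism tibble, possibly with duplicates.
#' @return A valid mechanism tibble.
#' @export
resolve_conflicts <- function(mechanisms) {
  if (!is.data.frame(mechanisms) || !all(c("set", "gene", "sign") %in% names(mechanisms))) {
    abort("`mechanisms` must have columns set, gene, sign")
  }
  if (!"description" %in% names(mechanisms)) mechanisms$description <- ""
  mechanisms <- tibble::as_tibble(mechanisms)
  dedup <- mechanisms[!duplicated(mechanisms[c("set", "gene", "sign")]), ]
  both <- dedup |>
    dplyr::count(.data$set, .data$gene) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(both) > 0L) {
    warn(paste0(
      "dropping gene(s) listed with both signs: ",
      paste(paste0(both$set, "/", both$gene), collapse = ", ")
    ))
    dedup <- dplyr::anti_join(dedup, both, by = c("set", "gene"))
  }
  out <- dedup[order(match(dedup$set, unique(mechanisms$set))), ]
  validate_mechanisms(out)
  tibble::as_tibble(out)
}

#' Filter mechanisms by gene coverage across cohorts
#'
#' Keeps exactly the sets having at least `min_genes` member genes present
#' in *every* supplied gene universe (one universe per cohort/platform),
#' mirroring the requirement that a mechanism be measurable on all study
#' platforms before it can serve as a classifier feature.
#'
#' @param mechanisms Long-format mechanism tibble.
#' @param gene_universes List of character vectors, one per cohort: the
#'   genes measured on that cohort's platform.
#' @param min_genes Minimum member genes required in each universe
#'   (default 4).
#' @return The filtered mechanism tibble, original set order preserved.
#' @export
filter_by_coverage <- function(mechanisms, gene_universes, min_genes = 4) {
  mechanisms <- validate_mechanisms(mechanisms)
  if (!is.list(gene_universes) || length(gene_universes) == 0L) {
    abort("`gene_universes` must be a non-empty list of gene-id vectors")
  }
  check_scalar_number(min_genes, "min_genes", lower = 1)
  counts <- vapply(gene_universes, function(u) {
    n <- tapply(mechanisms$gene %in% u, mechanisms$set, sum)
    n[unique(mechanisms$set)]
  }, numeric(length(unique(mechanisms$set))))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  min_count <- apply(counts, 1, min)
  keep <- unique(mechanisms$set)[min_count >= min_genes]
  dplyr::filter(mechanisms, .data$set %in% keep)
}
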