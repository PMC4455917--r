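# Synthetic multi-cohort study generator.
#
# Emulates the statistical structure the analysis assumes: several
# cohorts of log2 expression measured on overlapping platform gene
# subsets, per-cohort batch offsets, class signal injected through a
# small number of informative signed mechanisms (two oppositely-signed
# groups, mirroring higher metabolic / lower cytokine activity in
# non-responders), responder:non-responder imbalance of about 2.5:1, and
# per-patient baseline/follow-up DAS28 scores consistent with the labels.
# All generators are pure functions of (config, seed).

#' Simulation configuration
#'
#' Defaults reproduce the scale of the study design this package targets:
#' four cohorts of 44/15/30/27 patients, 27% non-responders, 200
#' mechanisms of which 10 carry class signal at 0.5 log2 units (half
#' raised, half lowered in non-responders), per-gene noise sd 1.
#'
#' @param cohort_sizes Integer vector of per-cohort sample counts.
#' @param nr_fraction Non-responder fraction per cohort (default 0.27,
#'   about 2.5:1 R:NR).
#' @param n_genes Gene universe size (default 1200).
#' @param retention Fraction of the universe measured on each cohort's
#'   platform (default 0.9; a fresh random subset per cohort).
#' @param n_mechanisms Number of mechanisms in the generated collection
#'   (default 200).
#' @param mech_size_range Min/max mechanism sizes; sizes are drawn
#'   log-uniformly (default 4-100, echoing the wide support spread of
#'   curated collections).
#' @param n_informative Number of signal-carrying mechanisms (default
#'   10); half get direction +1 (higher strength in NR), half -1.
#' @param effect Class effect size in log2 units added per informative
#'   mechanism (default 0.5).
#' @param baseline_mean,baseline_sd Gene baseline log2 expression
#'   distribution (default 7, 1).
#' @param batch_sd Per-cohort per-gene batch offset sd (default 0.3).
#' @param noise_sd Per-measurement Gaussian noise sd (default 1).
#' @param das28_baseline_mean,das28_baseline_sd Baseline DAS28
#'   distribution (default 5.8, 1), truncated to \[2, 10\].
#' @param das28_delta_r_mean,das28_delta_r_sd Improvement distribution
#'   for responders (default 2.0, 0.8).
#' @param das28_delta_nr_mean,das28_delta_nr_sd Improvement distribution
#'   for non-responders (default 0.3, 0.5).
#' @return A validated `mechsig_sim_config` list.
#' @export
sim_config <- function(cohort_sizes = c(44L, 15L, 30L, 27L),
                       nr_fraction = 0.27,
                       n_genes = 1200,
                       retention = 0.9,
                       n_mechanisms = 200,
                       mech_size_range = c(4, 100),
                       n_informative = 10,
                       effect = 0.5,
                       baseline_mean = 7, baseline_sd = 1,
                       batch_sd = 0.3,
                       noise_sd = 1,
                       das28_baseline_mean = 5.8, das28_baseline_sd = 1,
                       das28_delta_r_mean = 2.0, das28_delta_r_sd = 0.8,
                       das28_delta_nr_mean = 0.3, das28_delta_nr_sd = 0.5) {
  cfg <- list(
    cohort_sizes = as.integer(cohort_sizes),
    nr_fraction = nr_fraction,
    n_genes = as.integer(n_genes),
    retention = retention,
    n_mechanisms = as.integer(n_mechanisms),
    mech_size_range = mech_size_range,
    n_informative = as.integer(n_informative),
    effect = effect,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    batch_sd = batch_sd, noise_sd = noise_sd,
    das28_baseline_mean = das28_baseline_mean,
    das28_baseline_sd = das28_baseline_sd,
    das28_delta_r_mean = das28_delta_r_mean,
    das28_delta_r_sd = das28_delta_r_sd,
    das28_delta_nr_mean = das28_delta_nr_mean,
    das28_delta_nr_sd = das28_delta_nr_sd
  )
  if (length(cfg$cohort_sizes) < 1L || any(cfg$cohort_sizes < 1L)) {
    abort("cohort_sizes must be positive integers")
  }
  if (cfg$nr_fraction <= 0 || cfg$nr_fraction > 1) abort("nr_fraction must be in (0, 1]")
  if (cfg$retention <= 0 || cfg$retention > 1) abort("retention must be in (0, 1]")
  if (cfg$n_informative > cfg$n_mechanisms) abort("n_informative exceeds n_mechanisms")
  if (any(c(cfg$baseline_sd, cfg$batch_sd, cfg$noise_sd, cfg$das28_baseline_sd,
            cfg$das28_delta_r_sd, cfg$das28_delta_nr_sd) < 0)) {
    abort("standard deviations must be non-negative")
  }
  if (cfg$mech_size_range[1] < 1 || cfg$mech_size_range[2] < cfg$mech_size_range[1]) {
    abort("mech_size_range must be an increasing pair of positive sizes")
  }
  structure(cfg, class = "mechsig_sim_config")
}

#' Generate a synthetic mechanism collection
#'
#' Mechanism sizes are drawn log-uniformly within the configured range;
#' member genes are sampled from the universe independently per
#' mechanism, so gene sets overlap as curated collections do. Signs are
#' random. A random subset of `n_informative` mechanisms is marked as
#' signal-carrying, directions alternating +1 / -1.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List: `mechanisms` (long tibble) and `truth`
#'   (tibble `mechanism`, `direction` for informative mechanisms).
#' @export
generate_kb <- function(config, seed = 1) {
  stopifnot(inherits(config, "mechsig_sim_config"))
  if (config$mech_size_range[2] > config$n_genes) {
    abort("largest mechanism size exceeds the gene universe")
  }
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  if (config$n_mechanisms == 0L) {
    return(list(
      mechanisms = new_mechanisms(character(), character(), character(), integer()),
      truth = tibble::tibble(mechanism = character(), direction = integer())
    ))
  }
  set.seed(derive_seed(seed, 11))
  sizes <- round(exp(runif(
    config$n_mechanisms,
    log(config$mech_size_range[1]), log(config$mech_size_range[2])
  )))
  mech_names <- sprintf("M%04d", seq_len(config$n_mechanisms))
  rows <- purrr::map2(mech_names, sizes, function(nm, sz) {
    tibble::tibble(
      set = nm, description = "synthetic mechanism",
      gene = sample(genes, sz),
      sign = sample(c(-1L, 1L), sz, replace = TRUE)
    )
  })
  mechanisms <- dplyr::bind_rows(rows)
  informative <- sample(mech_names, config$n_informative)
  truth <- tibble::tibble(
    mechanism = informative,
    direction = rep_len(c(1L, -1L), length(informative))
  )
  list(mechanisms = mechanisms, truth = truth)
}

#' Generate synthetic expression cohorts
#'
#' Per sample: expression = gene baseline + cohort batch offset + class
#' signal + Gaussian noise, where the class signal adds
#' `effect * direction_m * sign_g` to every gene of every informative
#' mechanism for non-responders (responders stay at baseline). Each
#' cohort retains a fresh random platform subset of the gene universe.
#' Non-responder counts are `round(nr_fraction * n)` per cohort, label
#' order shuffled.
#'
#' @param config A [sim_config()].
#' @param kb Result of [generate_kb()] under the same config.
#' @param seed Integer seed.
#' @return List: `cohorts` (named list of wide expression tibbles) and
#'   `samples` (tibble `sample`, `subject`, `cohort`, `response`).
#' @export
generate_cohorts <- function(config, kb, seed = 1) {
  stopifnot(inherits(config, "mechsig_sim_config"))
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  set.seed(derive_seed(seed, 23))
  baseline <- rnorm(config$n_genes, config$baseline_mean, config$baseline_sd)
  names(baseline) <- genes

  # per-gene additive shift applied to non-responders
  signal <- setNames(numeric(config$n_genes), genes)
  if (nrow(kb$truth) > 0L) {
    inf_mem <- dplyr::inner_join(kb$mechanisms, kb$truth,
                                 by = c(set = "mechanism"))
    per_gene <- tapply(
      config$effect * inf_mem$direction * inf_mem$sign,
      inf_mem$gene, sum
    )
    signal[names(per_gene)] <- per_gene
  }

  cohorts <- list()
  samples <- list()
  for (i in seq_along(config$cohort_sizes)) {
    n <- config$cohort_sizes[i]
    cid <- sprintf("cohort%02d", i)
    set.seed(derive_seed(seed, 100 + i))
    keep <- sort(sample(genes, round(config$retention * config$n_genes)))
    n_nr <- max(1L, round(config$nr_fraction * n))
    labels <- sample(c(rep("NR", n_nr), rep("R", n - n_nr)))
    ids <- sprintf("%s_s%03d", cid, seq_len(n))
    batch <- rnorm(length(keep), 0, config$batch_sd)
    x <- matrix(
      rnorm(length(keep) * n, 0, config$noise_sd),
      nrow = length(keep)
    ) + baseline[keep] + batch
    nr_cols <- which(labels == "NR")
    if (length(nr_cols)) x[, nr_cols] <- x[, nr_cols] + signal[keep]
    dimnames(x) <- list(keep, ids)
    cohorts[[cid]] <- tibble::tibble(
      gene = keep, !!!as.data.frame(x, check.names = FALSE)
    )
    samples[[cid]] <- tibble::tibble(
      sample = ids, subject = ids, cohort = cid, response = labels
    )
  }
  list(cohorts = cohorts, samples = dplyr::bind_rows(samples))
}

#' Generate DAS28 records consistent with response labels
#'
#' Baseline DAS28 is Normal, truncated to \[2, 10\]; the improvement is
#' drawn from the class-specific Normal; follow-up = baseline minus
#' improvement, floored at 0.
#'
#' @param config A [sim_config()].
#' @param samples Tibble with `subject` and `response` columns.
#' @param seed Integer seed.
#' @return Tibble (`subject`, `response`, `das28_baseline`,
#'   `das28_followup`, `delta`).
#' @export
generate_das28 <- function(config, samples, seed = 1) {
  stopifnot(inherits(config, "mechsig_sim_config"))
  n <- nrow(samples)
  set.seed(derive_seed(seed, 37))
  base <- pmin(pmax(
    rnorm(n, config$das28_baseline_mean, config$das28_baseline_sd), 2
  ), 10)
  delta <- ifelse(
    samples$response == "NR",
    rnorm(n, config$das28_delta_nr_mean, config$das28_delta_nr_sd),
    rnorm(n, config$das28_delta_r_mean, config$das28_delta_r_sd)
  )
  followup <- pmax(base - delta, 0)
  tibble::tibble(
    subject = samples$subject,
    response = samples$response,
    das28_baseline = base,
    das28_followup = followup,
    delta = base - followup
  )
}

#' Simulate a complete study and prepare classifier features
#'
#' Convenience wrapper: generates the mechanism collection and cohorts,
#' median-centers each cohort, applies the cross-platform coverage
#' filter, computes per-cohort strength matrices and stacks them into
#' the feature table the classifier and CV schemes consume.
#'
#' @param config A [sim_config()] (defaults used when omitted).
#' @param seed Integer seed.
#' @param min_genes Coverage threshold passed to [filter_by_coverage()]
#'   and [strength_scores()] (default 4).
#' @return List: `mechanisms`, `truth`, `cohorts`, `samples`, `das28`,
#'   `strengths` (per-cohort list), `features` (stacked tibble with
#'   `sample`, `cohort`, `response` + mechanism columns).
#' @export
simulate_study <- function(config = sim_config(), seed = 1, min_genes = 4) {
  kb <- generate_kb(config, seed)
  coh <- generate_cohorts(config, kb, seed)
  das28 <- generate_das28(config, coh$samples, seed)
  universes <- lapply(coh$cohorts, function(e) e$gene)
  mechs <- filter_by_coverage(kb$mechanisms, universes, min_genes = min_genes)
  centered <- lapply(coh$cohorts, median_center)
  strengths <- lapply(centered, strength_scores, mechanisms = mechs,
                      min_genes = min_genes)
  features <- stack_strengths(strengths, annotations = coh$samples)
  list(
    mechanisms = mechs, truth = kb$truth,
    cohorts = coh$cohorts, samples = coh$samples, das28 = das28,
    strengths = strengths, features = features,
    config = config, seed = seed
  )
}

#' Write a simulated study in the package's TSV formats
#'
#' Emits exactly the files the ingest functions read: one expression TSV
#' per cohort, a signed-GMT mechanism file, and a sample-annotation TSV
#' with DAS28 columns.
#'
#' @param study Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cid in names(study$cohorts)) {
    readr::write_tsv(study$cohorts[[cid]], file.path(dir, paste0(cid, ".tsv")),
                     progress = FALSE)
  }
  write_signed_gmt(study$mechanisms, file.path(dir, "mechanisms.gmt"))
  ann <- dplyr::left_join(
    study$samples,
    dplyr::select(study$das28, "subject", "das28_baseline", "das28_followup"),
    by = "subject"
  )
  readr::write_tsv(ann, file.path(dir, "samples.tsv"), progress = FALSE)
  invisible(dir)
}
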