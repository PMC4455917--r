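test_that("generators are pure functions of config and seed", {
  cfg <- sim_config(cohort_sizes = c(10L, 8L), n_genes = 100, n_mechanisms = 12,
                    mech_size_range = c(4, 20), n_informative = 2)
  kb1 <- generate_kb(cfg, seed = 5)
  kb2 <- generate_kb(cfg, seed = 5)
  expect_identical(kb1, kb2)
  co1 <- generate_cohorts(cfg, kb1, seed = 5)
  co2 <- generate_cohorts(cfg, kb2, seed = 5)
  expect_identical(co1, co2)
  d1 <- generate_das28(cfg, co1$samples, seed = 5)
  expect_identical(d1, generate_das28(cfg, co2$samples, seed = 5))
  expect_false(identical(kb1, generate_kb(cfg, seed = 6)))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(cohort_sizes = integer()), "cohort_sizes")
  expect_error(sim_config(nr_fraction = 0), "nr_fraction")
  expect_error(sim_config(n_informative = 10, n_mechanisms = 5), "exceeds")
  expect_error(sim_config(noise_sd = -1), "non-negative")
  cfg <- sim_config(n_genes = 50, mech_size_range = c(4, 100))
  expect_error(generate_kb(cfg, 1), "universe")
})

test_that("an empty knowledge base is representable", {
  cfg <- sim_config(n_mechanisms = 0, n_informative = 0, n_genes = 100,
                    mech_size_range = c(4, 10))
  kb <- generate_kb(cfg, 1)
  expect_equal(nrow(kb$mechanisms), 0L)
  expect_equal(nrow(kb$truth), 0L)
})

test_that("cohorts carry the configured sizes, labels and platform subsets", {
  cfg <- sim_config(cohort_sizes = c(12L, 9L), nr_fraction = 0.3, n_genes = 120,
                    retention = 0.8, n_mechanisms = 10, mech_size_range = c(4, 15),
                    n_informative = 2)
  kb <- generate_kb(cfg, 2)
  co <- generate_cohorts(cfg, kb, 2)
  expect_equal(vapply(co$cohorts, function(e) ncol(e) - 1L, 1L),
               c(cohort01 = 12L, cohort02 = 9L))
  expect_equal(vapply(co$cohorts, nrow, 1L),
               c(cohort01 = 96L, cohort02 = 96L))
  expect_false(identical(co$cohorts[[1]]$gene, co$cohorts[[2]]$gene))
  counts <- table(co$samples$cohort, co$samples$response)
  expect_equal(unname(counts[, "NR"]), c(4, 3)) # round(0.3 * n)
})

test_that("full platform retention equalises mechanism support across cohorts", {
  cfg <- sim_config(cohort_sizes = c(8L, 8L), retention = 1, n_genes = 100,
                    n_mechanisms = 8, mech_size_range = c(4, 12), n_informative = 2)
  st <- simulate_study(cfg, seed = 3)
  sup <- lapply(st$strengths, strength_support)
  expect_identical(sup[[1]], sup[[2]])
})

test_that("informative mechanisms separate classes in strength space", {
  cfg <- sim_config(cohort_sizes = c(30L, 30L), n_genes = 400, n_mechanisms = 20,
                    mech_size_range = c(10, 40), n_informative = 4,
                    effect = 1, noise_sd = 0.2)
  st <- simulate_study(cfg, seed = 9)
  feats <- st$features
  for (i in seq_len(nrow(st$truth))) {
    mech <- st$truth$mechanism[i]
    dir <- st$truth$direction[i]
    diff_means <- mean(feats[[mech]][feats$response == "NR"]) -
      mean(feats[[mech]][feats$response == "R"])
    expect_gt(dir * diff_means, 0.5) # shift of `effect` in the injected direction
  }
})

test_that("zero effect size yields label-independent expression", {
  cfg <- sim_config(cohort_sizes = c(40L, 40L), n_genes = 300, n_mechanisms = 20,
                    mech_size_range = c(4, 30), n_informative = 4, effect = 0)
  st <- simulate_study(cfg, seed = 4)
  feats <- st$features
  mechs <- st$truth$mechanism
  gaps <- vapply(mechs, function(m) {
    abs(mean(feats[[m]][feats$response == "NR"]) - mean(feats[[m]][feats$response == "R"]))
  }, 0)
  expect_lt(max(gaps), 0.5) # no systematic shift beyond noise
})

test_that("DAS28 generation reproduces the labels under the EULAR criterion", {
  cfg <- sim_config(cohort_sizes = c(60L))
  samples <- tibble::tibble(
    subject = paste0("p", 1:60),
    response = rep(c("NR", "R"), c(16, 44))
  )
  recs <- generate_das28(cfg, samples, seed = 8)
  expect_true(all(recs$das28_baseline >= 2 & recs$das28_baseline <= 10))
  expect_true(all(recs$das28_followup >= 0))
  expect_equal(recs$delta, recs$das28_baseline - recs$das28_followup)
  lab <- response_label(recs, "eular_moderate_good")
  expect_gt(mean(lab$label == recs$response), 0.8)
})

test_that("written studies round-trip through the ingest readers", {
  st <- small_study()
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expr <- read_expression_matrix(file.path(dir, "cohort01.tsv"))
  expect_equal(as.matrix(expr[-1]), as.matrix(st$cohorts$cohort01[-1]),
               tolerance = 1e-12)
  mechs <- read_signed_gmt(file.path(dir, "mechanisms.gmt"))
  expect_equal(mechs[c("set", "gene", "sign")],
               st$mechanisms[c("set", "gene", "sign")])
  ann <- readr::read_tsv(file.path(dir, "samples.tsv"), show_col_types = FALSE)
  expect_equal(nrow(ann), nrow(st$samples))
})
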