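test_that("fold plans balance every cohort and partition all samples", {
  samples <- tibble::tibble(
    sample = paste0("s", 1:116),
    cohort = rep(c("c1", "c2", "c3", "c4"), c(44, 15, 30, 27))
  )
  plan <- make_folds(samples, k = 10, seed = 3)
  expect_setequal(plan$sample, samples$sample)
  counts <- table(plan$cohort, plan$fold)
  expect_true(all(counts["c1", ] %in% c(4, 5)))
  expect_true(all(counts["c2", ] %in% c(1, 2)))
  expect_true(all(counts["c3", ] == 3))
  expect_true(all(counts["c4", ] %in% c(2, 3)))
  # global fold sizes also differ by at most one
  expect_lte(diff(range(table(plan$fold))), 1)
})

test_that("fold plans are deterministic in the seed and reject k > n", {
  samples <- tibble::tibble(sample = paste0("s", 1:8), cohort = rep("c", 8))
  expect_identical(make_folds(samples, 2, seed = 9), make_folds(samples, 2, seed = 9))
  expect_false(identical(make_folds(samples, 4, seed = 1)$fold,
                         make_folds(samples, 4, seed = 2)$fold))
  p2 <- make_folds(tibble::tibble(sample = paste0("s", 1:4), cohort = "c"), 2, seed = 1)
  expect_equal(unname(c(table(p2$fold))), c(2, 2))
  expect_error(make_folds(samples, 20, seed = 1), "exceeds")
})

test_that("per-cohort balance holds across many random draws", {
  samples <- tibble::tibble(
    sample = paste0("s", 1:57),
    cohort = rep(c("a", "b", "c"), c(31, 17, 9))
  )
  for (seed in 1:200) {
    plan <- make_folds(samples, k = 10, seed = seed)
    counts <- table(plan$cohort, plan$fold)
    expect_true(all(apply(counts, 1, function(r) diff(range(r)) <= 1)))
  }
})

test_that("held-out samples never influence the trained model", {
  st <- small_study()
  feats <- st$features
  plan <- make_folds(feats[c("sample", "cohort")], k = 4, seed = 8)
  held <- plan$sample[plan$fold == 1]
  train <- feats[!feats$sample %in% held, ]
  m1 <- quiet_fit(train, seed = 21)
  # refit after physically deleting the held-out rows from a copy
  copy <- feats[!feats$sample %in% held, ]
  m2 <- quiet_fit(copy, seed = 21)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$threshold, m2$threshold)
})

test_that("repeated k-fold scores every sample once per repeat and summarises over repeats", {
  st <- small_study()
  cv <- suppressWarnings(crossval_kfold(st$features, k = 4, repeats = 3, seed = 6))
  expect_equal(nrow(cv$reports), 3)
  expect_setequal(cv$scores$sample, st$features$sample)
  expect_equal(anyDuplicated(cv$scores$sample), 0L)
  expect_equal(sort(unique(cv$summary$statistic)),
               sort(c("auroc", "sensitivity", "specificity", "precision", "likelihood_ratio")))
  expect_true(all(cv$summary$lower <= cv$summary$median & cv$summary$median <= cv$summary$upper,
                  na.rm = TRUE))
  # determinism: same seed, same reports
  cv2 <- suppressWarnings(crossval_kfold(st$features, k = 4, repeats = 3, seed = 6))
  expect_equal(cv$reports, cv2$reports)
})

test_that("leave-one-sample-out equals k-fold with k = n", {
  st <- small_study()
  feats <- st$features[1:30, ]
  a <- suppressWarnings(crossval_loso(feats, seed = 13))
  b <- suppressWarnings(crossval_kfold(feats, k = nrow(feats), repeats = 1, seed = 13))
  expect_equal(
    dplyr::arrange(a$scores, sample)$score,
    dplyr::arrange(b$scores, sample)$score
  )
})

test_that("leave-one-batch-out produces one report per cohort plus the mean row", {
  st <- small_study()
  lobo <- suppressWarnings(crossval_lobo(st$features, seed = 10))
  expect_equal(nrow(lobo$reports), length(unique(st$features$cohort)) + 1L)
  expect_equal(lobo$reports$cohort[nrow(lobo$reports)], "mean")
  expect_setequal(lobo$scores$sample, st$features$sample)
  # strong simulated signal: both held-out cohorts stratify well
  expect_true(all(lobo$reports$auroc[1:2] > 0.7))
})

test_that("two identical cohorts give near-identical held-out performance", {
  st <- small_study()
  c1 <- st$features[st$features$cohort == "cohort01", ]
  dup <- c1
  dup$cohort <- "copy"
  dup$sample <- paste0(dup$sample, "_b")
  both <- dplyr::bind_rows(c1, dup)
  lobo <- suppressWarnings(crossval_lobo(both, seed = 14))
  auc <- lobo$reports$auroc[1:2]
  expect_equal(auc[1], auc[2], tolerance = 0.12)
})

test_that("the permutation null preserves class counts and centres at 0.5", {
  st <- small_study()
  pn <- suppressWarnings(permutation_null(st$features, k = 4, repeats = 5, seed = 17))
  expect_equal(length(pn$aurocs), 5)
  expect_true(all(pn$aurocs >= 0 & pn$aurocs <= 1))
  expect_true(abs(pn$median_auroc - 0.5) < 0.2)
  # a reference above every achievable AUROC has zero exceedance
  pn2 <- suppressWarnings(permutation_null(st$features, k = 4, repeats = 3, seed = 18,
                                           reference_auroc = 1.1))
  expect_equal(pn2$exceedance, 0L)
})

test_that("permuted labels keep the original class counts", {
  st <- small_study()
  set.seed(1)
  permuted <- st$features
  permuted$response <- sample(permuted$response)
  expect_equal(table(permuted$response), table(st$features$response))
})
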