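# two well-separated blobs with opposite gene *profiles* (correlation
# distance ignores per-sample offsets, so the classes must differ in
# shape): NR samples follow +pattern, R samples -pattern
blob_expr <- function(n_per = 6, gap = 4, sd = 0.3, seed = 31, n_genes = 5) {
  set.seed(seed)
  n <- 2 * n_per
  ids <- paste0("s", seq_len(n))
  pattern <- gap * rep_len(c(1, -1), n_genes)
  m <- matrix(rnorm(n_genes * n, sd = sd), n_genes, n)
  m[, seq_len(n_per)] <- m[, seq_len(n_per)] + pattern
  m[, -seq_len(n_per)] <- m[, -seq_len(n_per)] - pattern
  expr <- tibble::tibble(gene = paste0("g", seq_len(n_genes)),
                         !!!as.data.frame(m, col.names = ids))
  names(expr) <- c("gene", ids)
  labels <- setNames(rep(c("NR", "R"), each = n_per), ids)
  list(expr = expr, labels = labels)
}

test_that("well-separated blobs cluster into label-pure groups with matching calls", {
  b <- blob_expr()
  fit <- fit_cluster_signature(b$expr, b$labels, paste0("g", 1:5))
  cl_nr <- fit$clusters[names(b$labels)[b$labels == "NR"]]
  cl_r <- fit$clusters[names(b$labels)[b$labels == "R"]]
  expect_equal(length(unique(cl_nr)), 1L)
  expect_equal(length(unique(cl_r)), 1L)
  expect_equal(unname(fit$calls[unique(cl_nr)]), "NR")
  expect_equal(unname(fit$calls[unique(cl_r)]), "R")
})

test_that("a single-gene signature still clusters (Euclidean fallback)", {
  b <- blob_expr(n_genes = 1)
  fit <- fit_cluster_signature(b$expr, b$labels, "g1")
  expect_length(fit$calls, 2L)
  expect_setequal(fit$calls, c("NR", "R"))
})

test_that("missing signature genes are reported by name", {
  b <- blob_expr()
  expect_error(fit_cluster_signature(b$expr, b$labels, c("g1", "nope")), "nope")
})

test_that("nearest-median scores are antisymmetric and tie toward NR", {
  b <- blob_expr()
  fit <- fit_cluster_signature(b$expr, b$labels, paste0("g", 1:5))
  sc <- score_nearest_median(fit, b$expr)
  # a sample equal to the NR median gets label NR and a positive score
  nr_idx <- which(fit$calls == "NR")
  probe <- tibble::tibble(gene = fit$genes, probe1 = fit$medians[, nr_idx])
  p <- score_nearest_median(fit, probe)
  expect_equal(p$predicted, "NR")
  expect_gt(p$score, 0)

  # relabelling the medians (calls swapped, medians fixed) flips the sign
  swapped <- fit
  swapped$calls <- rev(fit$calls)
  sc2 <- score_nearest_median(swapped, b$expr)
  expect_equal(sc$score, -sc2$score)

  # equidistant sample predicts NR
  mid <- tibble::tibble(gene = fit$genes, m = rowMeans(fit$medians))
  expect_equal(score_nearest_median(fit, mid)$predicted, "NR")
})

test_that("knn votes with NR-favouring ties and binary scores", {
  b <- blob_expr()
  # test sample identical to an NR training sample, k = 1
  test1 <- b$expr[c("gene", "s1")]
  names(test1) <- c("gene", "t1")
  out <- knn_signature_score(b$expr, test1, b$labels, paste0("g", 1:5), k = 1)
  expect_equal(out$score, 1)
  # k = n with majority R forces score 0
  lab2 <- setNames(rep(c("NR", "R"), c(2, 10)), names(b$labels))
  out2 <- knn_signature_score(b$expr, test1, lab2, paste0("g", 1:5), k = 12)
  expect_equal(out2$score, 0)
  expect_error(
    knn_signature_score(b$expr, test1, b$labels, paste0("g", 1:5), k = 99),
    "exceeds"
  )
})

test_that("LOSO evaluation recovers signal genes and yields few ROC thresholds for knn", {
  b <- blob_expr(n_per = 8)
  expr_list <- list(c1 = b$expr)
  ann <- tibble::tibble(
    sample = names(b$labels), cohort = "c1", response = unname(b$labels)
  )
  res <- evaluate_signature(expr_list, ann, paste0("g", 1:5),
                            scorer = "nearest_cluster_median")
  expect_equal(nrow(res$scores), 16)
  expect_gt(res$report$auroc, 0.9)

  res_knn <- evaluate_signature(expr_list, ann, paste0("g", 1:5), scorer = "knn", k = 3)
  expect_true(all(res_knn$scores$score %in% c(0, 1)))
  roc <- roc_curve(
    res_knn$scores$score[res_knn$scores$response == "NR"],
    res_knn$scores$score[res_knn$scores$response == "R"]
  )
  expect_lte(nrow(roc), 3) # binary scores: at most two distinct thresholds
})

test_that("cohort exclusion drops a signature's training cohort from evaluation", {
  b1 <- blob_expr(seed = 41, n_per = 6)
  b2 <- blob_expr(seed = 42, n_per = 5)
  ids2 <- paste0(names(b2$labels), "_b")
  names(b2$expr) <- c("gene", ids2)
  labels2 <- setNames(unname(b2$labels), ids2)
  ann <- tibble::tibble(
    sample = c(names(b1$labels), ids2),
    cohort = rep(c("c1", "c2"), c(12, 10)),
    response = c(unname(b1$labels), unname(labels2))
  )
  res <- evaluate_signature(
    list(c1 = b1$expr, c2 = b2$expr), ann, paste0("g", 1:5),
    scorer = "nearest_cluster_median", exclude_cohorts = "c1"
  )
  expect_true(all(res$scores$cohort == "c2"))
  expect_equal(nrow(res$scores), 10)
})

test_that("signature files parse scorer, k and gene lists", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "name\tscorer\tk\tgenes",
    "SigA\tnearest_cluster_median\tNA\tTNF,IL6,ALB",
    "SigB\tknn\t3\tA,B"
  ), tf)
  sigs <- read_signatures(tf)
  expect_equal(sigs$genes[[1]], c("TNF", "IL6", "ALB"))
  expect_equal(sigs$k[2], 3L)
  writeLines(c("name\tscorer\tk\tgenes", "S\tbogus\t1\tA"), tf)
  expect_error(read_signatures(tf), "unknown scorer")
})
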