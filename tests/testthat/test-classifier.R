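make_feature_table <- function(x, y, cohort = "c1") {
  tibble::tibble(
    sample = paste0("s", seq_len(nrow(x))),
    cohort = cohort,
    response = y,
    !!!as.data.frame(x)
  )
}

test_that("an infinite penalty shrinks to the intercept-only logit of prevalence", {
  set.seed(1)
  x <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("m", 1:6)))
  y <- rep(c("NR", "R"), c(10, 30))
  fit <- fit_lasso(x, y, lambda = 1e6)
  expect_true(all(fit$coefficients == 0))
  expect_equal(fit$intercept, log((10 / 40) / (30 / 40)), tolerance = 1e-4)
})

test_that("a separating mechanism is selected with a positive coefficient", {
  set.seed(2)
  n <- 60
  y <- rep(c("NR", "R"), each = n / 2)
  x <- matrix(rnorm(n * 5, sd = 0.3), n, 5, dimnames = list(NULL, paste0("m", 1:5)))
  x[, 3] <- x[, 3] + ifelse(y == "NR", 1.5, 0)
  fit <- fit_lasso(x, y, seed = 4)
  expect_gt(fit$coefficients[["m3"]], 0)
})

test_that("duplicating a feature column leaves fitted scores unchanged", {
  set.seed(3)
  n <- 50
  y <- rep(c("NR", "R"), c(20, 30))
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("m", 1:3)))
  x[, 1] <- x[, 1] + ifelse(y == "NR", 1.2, 0)
  xdup <- cbind(x, m1b = x[, 1])
  f1 <- fit_lasso(x, y, lambda = 0.05)
  f2 <- fit_lasso(xdup, y, lambda = 0.05)
  lp1 <- drop(x %*% f1$coefficients) + f1$intercept
  lp2 <- drop(xdup %*% f2$coefficients) + f2$intercept
  expect_equal(lp1, lp2, tolerance = 1e-4)
})

test_that("rescaling solves the two-point affine map", {
  map <- rescale_parameters(c(-2, 0, 3))
  expect_equal(unname(map["slope"]), 1.8)
  expect_equal(unname(map["offset"]), 4.1)
  ident <- rescale_parameters(c(0.5, 9.5))
  expect_equal(unname(ident), c(1, 0))
  expect_error(rescale_parameters(c(2, 2, 2)), "degenerate")
})

test_that("threshold selection implements the order-statistic rule with NR-favouring ties", {
  expect_equal(select_threshold(c(2, 4, 6, 8, 10), rep("NR", 5), 0.6), 4)
  # all-equal scores: threshold strictly below the common value
  thr <- select_threshold(c(5, 5, 5), rep("NR", 3), 0.6)
  expect_lt(thr, 5)
  # target 1 puts the threshold below the minimum NR score
  expect_lt(select_threshold(c(2, 4, 6), rep("NR", 3), 1), 2)
  expect_error(select_threshold(c(1, 2), c("R", "R"), 0.6), "no non-responders")
})

test_that("training NR sensitivity meets the target on random distinct-score instances", {
  set.seed(12)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    scores <- sample(seq(0, 10, 0.01), n)
    thr <- select_threshold(scores, rep("NR", n), 0.6)
    expect_gte(mean(scores > thr), 0.6)
  }
})

test_that("the fitted classifier spans [0.5, 9.5] on training data and clips test scores", {
  st <- small_study()
  m <- quiet_fit(st$features, seed = 5)
  expect_equal(min(m$training$score), 0.5, tolerance = 1e-9)
  expect_equal(max(m$training$score), 9.5, tolerance = 1e-9)
  expect_gt(m$threshold, 0)
  expect_lt(m$threshold, 10)
  # training NR sensitivity meets the target
  tr <- m$training
  expect_gte(mean(tr$score[tr$response == "NR"] > m$threshold), m$target_sensitivity)

  # extreme synthetic samples (pushed along the coefficient direction)
  # clip to [0, 10]
  mech_cols <- names(m$coefficients)
  dir <- sign(m$coefficients)
  shifted <- st$features
  shifted[mech_cols] <- purrr::imap(shifted[mech_cols], ~ .x + 50 * dir[[.y]])
  up <- predict(m, shifted)
  down <- st$features
  down[mech_cols] <- purrr::imap(down[mech_cols], ~ .x - 50 * dir[[.y]])
  dn <- predict(m, down)
  expect_true(all(up$score <= 10) && all(dn$score >= 0))
  expect_true(any(up$score == 10) && any(dn$score == 0))
})

test_that("rescaling preserves sample ranking (AUROC invariance)", {
  st <- small_study()
  m <- quiet_fit(st$features, seed = 5)
  x <- mechsig:::feature_matrix(st$features)
  lp_raw <- drop(x %*% m$raw_coefficients) + m$raw_intercept
  expect_equal(order(lp_raw), order(m$training$score))
  y <- st$features$response
  expect_equal(
    auroc(lp_raw[y == "NR"], lp_raw[y == "R"]),
    auroc(m$training$score[y == "NR"], m$training$score[y == "R"])
  )
})

test_that("scoring fails loudly when a classifier mechanism is missing", {
  st <- small_study()
  m <- quiet_fit(st$features, seed = 5)
  mech <- names(m$coefficients)[1]
  crippled <- st$features[setdiff(names(st$features), mech)]
  expect_error(predict(m, crippled), mech)
})

test_that("single-class labels are rejected", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_lasso(x, rep("R", 10)), "per class")
})

test_that("gene contributions decompose coefficients over mechanism support", {
  m <- quiet_fit(small_study()$features, seed = 5)
  # hand-built model for the formula check
  fake <- m
  fake$coefficients <- c(M1 = 4, M2 = -2)
  mechs <- tibble::tibble(
    set = rep(c("M1", "M2"), c(4, 2)),
    description = "",
    gene = c("A", "B", "C", "D", "A", "E"),
    sign = c(1L, 1L, -1L, 1L, 1L, -1L)
  )
  universe <- c("A", "B", "C", "D", "E", "F")
  gc <- gene_contributions(fake, mechs, universe)
  val <- setNames(gc$contribution, gc$gene)
  expect_equal(val[["B"]], 1) # 4 * (+1) / 4
  expect_equal(val[["C"]], -1) # 4 * (-1) / 4
  expect_equal(val[["A"]], 1 - 1) # 4/4 + (-2)/2 cancels
  expect_equal(val[["E"]], 1) # -2 * (-1) / 2
  expect_equal(val[["F"]], 0) # in no selected mechanism
})

test_that("tidy/glance expose the linear model like a coefficient table", {
  m <- quiet_fit(small_study()$features, seed = 5)
  td <- tidy(m)
  expect_equal(td$term[1], "(Constant)")
  expect_equal(td$estimate[1], m$constant)
  gl <- glance(m)
  expect_equal(gl$n_mechanisms, length(m$coefficients))
  expect_true(gl$train_auroc >= 0 && gl$train_auroc <= 1)
})

test_that("the model JSON round-trips bit-exactly", {
  m <- quiet_fit(small_study()$features, seed = 5)
  tf <- withr::local_tempfile(fileext = ".json")
  write_classifier(m, tf)
  m2 <- read_classifier(tf)
  expect_identical(m$coefficients, m2$coefficients)
  expect_identical(m$constant, m2$constant)
  expect_identical(m$threshold, m2$threshold)
  p1 <- predict(m, small_study()$features)
  p2 <- predict(m2, small_study()$features)
  expect_identical(p1$score, p2$score)
})
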