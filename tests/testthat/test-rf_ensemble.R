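test_that("balanced subsampling downsamples every class to the minority size", {
  set.seed(1)
  tab <- data.frame(
    VT = rnorm(550),
    age_class = factor(rep(c("Young", "Others"), c(50, 500)),
                       levels = c("Young", "Others"))
  )
  bal <- balanced_subsample(tab)
  expect_identical(nrow(bal), 100L)
  expect_true(all(table(bal$age_class) == 50))
  expect_identical(bal, tab[attr(bal, "idx"), , drop = FALSE],
                   ignore_attr = TRUE)

  # already balanced input keeps per-class counts
  bal2 <- balanced_subsample(tab[1:100, ][c(1:50, 51:100), ])
  expect_true(all(table(bal2$age_class) == 50))

  tab$age_class <- factor(tab$age_class, levels = c("Young", "Others", "Old"))
  expect_error(balanced_subsample(tab), "Old")
})

test_that("majority-class inclusion follows the hypergeometric rate", {
  tab <- data.frame(
    VT = 0,
    age_class = factor(rep(c("A", "B"), c(2, 1000)), levels = c("A", "B"))
  )
  set.seed(2)
  hits <- integer(1002)
  n_draws <- 1000
  for (i in seq_len(n_draws)) {
    idx <- attr(balanced_subsample(tab), "idx")
    hits[idx] <- hits[idx] + 1L
  }
  b_hits <- hits[3:1002]
  p <- 2 / 1000
  expect_equal(mean(b_hits) / n_draws, p, tolerance = 1e-12) # exactly m per draw
  se <- sqrt(n_draws * p * (1 - p))
  within3 <- mean(abs(b_hits - n_draws * p) <= 3 * se)
  expect_gte(within3, 0.98)
})

test_that("a separable toy problem is learned almost perfectly", {
  tab <- separable_table(n_per_class = 100, gap = 10)
  cfg <- ensemble_config("AGE2", n_iterations = 1, n_trees = 200, seed = 3)
  set.seed(3)
  bal <- balanced_subsample(tab)
  it <- train_iteration(bal, tab, cfg)
  expect_lte(it$oob_error, 0.05)
  expect_true(all(rowSums(it$confusion) == table(bal$age_class)))
  expect_true(all(it$gini >= 0))
})

test_that("label-permuted data sits at the chance floor", {
  tab <- separable_table(n_per_class = 100, gap = 10)
  set.seed(4)
  tab$age_class <- sample(tab$age_class)
  cfg <- ensemble_config("AGE2", n_iterations = 1, n_trees = 200, seed = 4)
  set.seed(4)
  it <- train_iteration(balanced_subsample(tab), tab, cfg)
  expect_gte(it$oob_error, 0.4)
  expect_lte(it$oob_error, 0.6)
})

test_that("single-class balanced tables are rejected", {
  tab <- separable_table()
  tab$age_class <- factor("Young", levels = c("Young", "Others"))
  cfg <- ensemble_config("AGE2", n_iterations = 1, n_trees = 50)
  expect_error(train_iteration(tab, tab, cfg), "single class|empty")
})

test_that("one-iteration ensembles equal their single iteration", {
  tab <- separable_table(n_per_class = 60, gap = 3, seed = 6)
  cfg <- ensemble_config("AGE2", n_iterations = 1, n_trees = 100, seed = 9)
  res <- run_ensemble(tab, cfg)
  set.seed(substream_seed(9, "iter1"))
  bal <- balanced_subsample(tab)
  it <- train_iteration(bal, tab, cfg)
  expect_equal(res$accuracy, 100 * (1 - it$oob_error))
  expect_equal(unname(res$gini_aggregate), unname(it$gini))
  expect_equal(unname(res$mismatch_counts),
               as.integer(it$full_predictions != tab$age_class))
})

test_that("ensembles are deterministic under the master seed", {
  tab <- separable_table(n_per_class = 60, gap = 3, seed = 7)
  cfg <- ensemble_config("AGE2", n_iterations = 5, n_trees = 100, seed = 11)
  a <- run_ensemble(tab, cfg)
  b <- run_ensemble(tab, cfg)
  expect_identical(a$accuracy, b$accuracy)
  expect_identical(a$gini_matrix, b$gini_matrix)
  expect_identical(a$mismatch_counts, b$mismatch_counts)
})

test_that("swapping the positive class swaps sensitivity and specificity", {
  tab <- separable_table(n_per_class = 60, gap = 3, seed = 8)
  base <- ensemble_config("AGE2", n_iterations = 5, n_trees = 100, seed = 12)
  swapped <- ensemble_config("AGE2", n_iterations = 5, n_trees = 100,
                             seed = 12, positive_class = "Others")
  a <- run_ensemble(tab, base)
  b <- run_ensemble(tab, swapped)
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(a$specificity, b$sensitivity)
  expect_equal(a$accuracy, b$accuracy)
})

test_that("mean Gini importance ranks a signal predictor above pure noise", {
  set.seed(13)
  n <- 300
  tab <- data.frame(
    VT = c(rnorm(n / 2, 0), rnorm(n / 2, 3)),
    noise = rnorm(n),
    age_class = factor(rep(c("Young", "Others"), each = n / 2),
                       levels = c("Young", "Others"))
  )
  res <- run_ensemble(tab, ensemble_config("AGE2", n_iterations = 20,
                                           n_trees = 150, seed = 13))
  expect_gt(res$gini_aggregate["VT"], res$gini_aggregate["noise"])
  expect_gte(mean(res$gini_matrix[, "VT"] > res$gini_matrix[, "noise"]), 0.9)
})

test_that("regression forest pseudo-R2 has the right ceiling and floor", {
  ft <- default_features()
  cfg <- ensemble_config("AGE2", n_trees = 250, seed = 17)
  # age duplicated as a predictor: self-prediction
  self_tab <- ft
  self_tab$age_copy <- self_tab$age
  attr(self_tab, "predictors") <- c(attr(ft, "predictors"), "age_copy")
  expect_gt(regression_forest_variance_explained(self_tab, cfg), 95)
  # pure-noise predictors only
  set.seed(17)
  noise_tab <- data.frame(n1 = rnorm(nrow(ft)), n2 = rnorm(nrow(ft)),
                          age = ft$age)
  expect_lt(regression_forest_variance_explained(noise_tab, cfg), 5)
  expect_identical(regression_forest_variance_explained(noise_tab, cfg),
                   regression_forest_variance_explained(noise_tab, cfg))
  noise_tab$age <- 5
  expect_error(regression_forest_variance_explained(noise_tab, cfg),
               "constant")
})

test_that("majority-vote prediction on new data honours its contracts", {
  tab <- separable_table(n_per_class = 80, gap = 10, seed = 19)
  cfg1 <- ensemble_config("AGE2", n_iterations = 1, n_trees = 100, seed = 19,
                          keep_forests = TRUE)
  res1 <- run_ensemble(tab, cfg1)
  new_tab <- separable_table(n_per_class = 30, gap = 10, seed = 23)
  pred <- predict_dataset(res1, new_tab)
  # one forest: the vote is that forest's prediction
  direct <- stats::predict(res1$forests[[1]],
                           nestage:::forest_frame(new_tab, c("VT", "VM")))
  expect_identical(as.character(pred$predicted_class), as.character(direct))
  expect_true(all(pred$vote_fraction == 1))

  # strong signal: held-out match rate is high, proportion-positive sane
  cfg5 <- ensemble_config("AGE2", n_iterations = 5, n_trees = 100, seed = 19,
                          keep_forests = TRUE)
  res5 <- run_ensemble(tab, cfg5)
  pred5 <- predict_dataset(res5, new_tab)
  expect_gte(mean(pred5$predicted_class == new_tab$age_class), 0.9)
  expect_equal(attr(pred5, "prop_positive"),
               mean(pred5$predicted_class == "Young"))

  expect_error(predict_dataset(res5, new_tab[, c("nest_id", "VM"),
                                             drop = FALSE]), "VT")
  res_nf <- run_ensemble(tab, ensemble_config("AGE2", n_iterations = 1,
                                              n_trees = 50, seed = 19))
  expect_error(predict_dataset(res_nf, new_tab), "keep_forests")
})

test_that("pooled aggregation matches metrics of the summed confusion matrix", {
  tab <- separable_table(n_per_class = 60, gap = 3, seed = 29)
  cfg <- ensemble_config("AGE2", n_iterations = 5, n_trees = 100, seed = 29,
                         aggregate = "pooled")
  res <- run_ensemble(tab, cfg)
  m <- confusion_metrics(res$pooled_confusion, positive = "Young")
  expect_equal(res$accuracy, unname(m["accuracy"]))
  expect_equal(res$sensitivity, unname(m["sensitivity"]))
  expect_equal(res$specificity, unname(m["specificity"]))
})

test_that("the aggregated accuracy stabilises within tens of iterations", {
  ft <- default_features()
  res <- run_ensemble(ft, ensemble_config("AGE2", n_iterations = 60,
                                          n_trees = 150, seed = 37))
  acc <- res$per_iteration$accuracy
  # per-iteration OOB accuracies are exchangeable draws: a quarter of the
  # loop already estimates the aggregate to within about a point
  expect_lt(abs(mean(acc[1:15]) - mean(acc)), 1.5)
  expect_lt(sd(acc) / sqrt(length(acc)), 0.5)
})
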