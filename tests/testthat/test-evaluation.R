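test_that("confusion metrics follow the defining formulas", {
  cm <- matrix(c(74, 26, 31, 69), 2, 2, byrow = TRUE,
               dimnames = list(c("Young", "Others"), c("Young", "Others")))
  m <- confusion_metrics(cm, "Young")
  expect_equal(unname(m["sensitivity"]), 74)
  expect_equal(unname(m["specificity"]), 69)
  expect_equal(unname(m["accuracy"]), 71.5)

  perfect <- matrix(c(50, 0, 0, 50), 2, 2,
                    dimnames = list(c("Young", "Others"), c("Young", "Others")))
  expect_equal(unname(confusion_metrics(perfect, "Young")), c(100, 100, 100))

  # symmetry: the positive label swap exchanges sensitivity and specificity
  m2 <- confusion_metrics(cm, "Others")
  expect_equal(unname(m["sensitivity"]), unname(m2["specificity"]))
  expect_equal(unname(m["specificity"]), unname(m2["sensitivity"]))

  none_pos <- matrix(c(0, 0, 10, 90), 2, 2, byrow = TRUE,
                     dimnames = list(c("Young", "Others"), c("Young", "Others")))
  expect_error(confusion_metrics(none_pos, "Young"), "positive")
})

test_that("confusion metrics agree with brute-force recounts of raw pairs", {
  set.seed(41)
  for (i in seq_len(200)) {
    n <- sample(10:60, 1)
    truth <- factor(sample(c("Young", "Others"), n, TRUE,
                           prob = c(0.4, 0.6)), levels = c("Young", "Others"))
    pred <- factor(sample(c("Young", "Others"), n, TRUE),
                   levels = c("Young", "Others"))
    if (!all(table(truth) > 0)) next
    m <- confusion_metrics(table(truth, pred), "Young")
    expect_equal(unname(m["accuracy"]), 100 * mean(truth == pred),
                 tolerance = 1e-9)
    expect_equal(unname(m["sensitivity"]),
                 100 * mean(pred[truth == "Young"] == "Young"),
                 tolerance = 1e-9)
    expect_equal(unname(m["specificity"]),
                 100 * mean(pred[truth == "Others"] == "Others"),
                 tolerance = 1e-9)
  }
})

test_that("OOB error converts to accuracy by the stated formula", {
  expect_equal(accuracy_from_oob(0.29), 71)
  expect_identical(accuracy_from_oob(0), 100)
  expect_identical(accuracy_from_oob(1), 0)
  expect_error(accuracy_from_oob(1.2), "\\[0, 1\\]")
  expect_error(accuracy_from_oob(-0.1), "\\[0, 1\\]")
})

test_that("consistency flagging is exact at the half-iterations boundary", {
  nests <- data.frame(nest_id = c("a", "b", "c", "d"),
                      year = c(2001, 2001, 2002, 2002),
                      true_age = c(3, 4, 10, 10))
  counts <- c(a = 1500, b = 1499, c = 3000, d = 0)
  rep <- misclassification_report(counts, nests, 3000)
  expect_identical(rep$per_nest$flagged, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(rep$per_year$error_pct[rep$per_year$year == 2001], 50)
  expect_equal(rep$per_year$error_pct[rep$per_year$year == 2002], 50)
  expect_equal(rep$per_age$error_pct[rep$per_age$age == 4], 0)
  expect_equal(rep$per_age$error_pct[rep$per_age$age == 3], 100)
  # a year with no flagged nests reports 0% error
  counts0 <- c(a = 0, b = 0, c = 0, d = 0)
  rep0 <- misclassification_report(counts0, nests, 3000)
  expect_true(all(rep0$per_year$error_pct == 0))
  expect_error(misclassification_report(c(a = 3001), nests[1, ], 3000),
               "\\[0, n_iterations\\]")
})

test_that("chi-square on young proportions matches the closed-form Pearson statistic", {
  # identical groups: no heterogeneity at all
  eq <- compare_young_proportions(
    data.frame(label = c("rings", "tool"), n_young = c(20, 20),
               n_total = c(95, 95)))
  expect_equal(eq$chi2, 0, tolerance = 1e-12)
  expect_equal(eq$p, 1, tolerance = 1e-12)
  expect_identical(eq$df, 1L)

  # hand computation: O = [[10,90],[90,10]], all E = 50 -> X2 = 4*32 = 128
  two <- compare_young_proportions(
    data.frame(label = c("g1", "g2"), n_young = c(10, 90),
               n_total = c(100, 100)))
  expect_equal(two$chi2, 128, tolerance = 1e-9)
  expect_identical(two$df, 1L)

  # order invariance
  flip <- compare_young_proportions(
    data.frame(label = c("g2", "g1"), n_young = c(90, 10),
               n_total = c(100, 100)))
  expect_equal(flip$chi2, two$chi2, tolerance = 1e-12)

  expect_error(compare_young_proportions(
    data.frame(label = "x", n_young = 1, n_total = 2)), "two groups")
  expect_warning(compare_young_proportions(
    data.frame(label = c("a", "b"), n_young = c(0, 1), n_total = c(2, 200))),
    "expected")
})

test_that("chi-square agrees with an independent sum((O-E)^2/E) on random tables", {
  set.seed(43)
  for (i in seq_len(300)) {
    k <- sample(2:7, 1)
    n_total <- sample(20:200, k, TRUE)
    n_young <- rbinom(k, n_total, runif(1, 0.1, 0.9))
    if (any(colSums(cbind(n_young, n_total - n_young)) == 0)) next
    res <- compare_young_proportions(
      data.frame(label = paste0("g", 1:k), n_young = n_young,
                 n_total = n_total))
    O <- cbind(n_young, n_total - n_young)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    expect_equal(res$chi2, sum((O - E)^2 / E), tolerance = 1e-9)
    expect_identical(res$df, k - 1L)
    expect_equal(res$p, stats::pchisq(res$chi2, k - 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("a one-point learning-curve grid degenerates to a plain ensemble run", {
  tab <- separable_table(n_per_class = 60, gap = 3, seed = 47)
  cfg <- ensemble_config("AGE2", n_iterations = 3, n_trees = 100, seed = 47)
  lc <- learning_curve(tab, cfg, sizes = nrow(tab), reps = 1)
  cfg_direct <- cfg
  cfg_direct$seed <- substream_seed(47, sprintf("lc-%d-%d", nrow(tab), 1L))
  direct <- run_ensemble(tab, cfg_direct)
  expect_equal(lc$accuracy, direct$accuracy)
  expect_identical(nrow(lc), 1L)
  expect_error(learning_curve(tab, cfg, sizes = nrow(tab) + 1),
               "exceeds")
})
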