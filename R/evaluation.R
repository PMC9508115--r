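#' Accuracy, sensitivity and specificity from a 2x2 confusion matrix
#'
#' Rows are true classes and columns predicted classes. Sensitivity is the
#' percentage of positives correctly classified, specificity the percentage
#' of negatives correctly classified; accuracy the percentage correct
#' overall.
#'
#' @param confusion 2x2 matrix/table of counts with matching row/column
#'   names.
#' @param positive label of the positive class.
#' @return named numeric vector `accuracy`, `sensitivity`, `specificity`
#'   (percent).
#' @export
confusion_metrics <- function(confusion, positive) {
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(2, 2))) abort_arg("need a 2x2 confusion matrix")
  if (any(confusion < 0)) abort_arg("confusion counts must be non-negative")
  if (!positive %in% rownames(confusion)) {
    abort_arg(sprintf("positive class '%s' not among classes %s", positive,
                      paste(rownames(confusion), collapse = ", ")))
  }
  pos <- rownames(confusion) == positive
  tp <- confusion[pos, pos]; fn <- confusion[pos, !pos]
  fp <- confusion[!pos, pos]; tn <- confusion[!pos, !pos]
  if (tp + fn == 0) abort_arg("no positive cases: sensitivity undefined")
  if (tn + fp == 0) abort_arg("no negative cases: specificity undefined")
  c(accuracy = 100 * (tp + tn) / sum(confusion),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp))
}

#' Convert an out-of-bag error rate to an accuracy percentage
#'
#' @param oob_error OOB error rate in `[0, 1]`.
#' @return `100 * (1 - oob_error)`.
#' @export
#' @examples
#' accuracy_from_oob(0.29) # 71
accuracy_from_oob <- function(oob_error) {
  if (any(!is.finite(oob_error)) || any(oob_error < 0) || any(oob_error > 1)) {
    abort_arg("`oob_error` must lie in [0, 1]")
  }
  100 * (1 - oob_error)
}

#' Misclassification-consistency report
#'
#' Flags the nests that were misclassified in at least half of the
#' bootstrap iterations (a count of exactly `n_iterations / 2` flags), then
#' summarises the percentage of flagged nests per year and per true age —
#' the per-year / per-age error profile of the tool.
#'
#' @param mismatch_counts named integer vector (per nest) of iterations
#'   whose full-dataset prediction disagreed with the true class, e.g.
#'   `ensemble_result$mismatch_counts`.
#' @param nests data.frame with `nest_id`, `year` and an age column
#'   (`true_age` preferred, else `age`), matched by `nest_id`.
#' @param n_iterations total bootstrap iterations.
#' @return a `misclassification_report`: list with `per_nest` (nest_id,
#'   year, age, mismatch_count, flagged), `per_year` and `per_age`
#'   (percent-error tables) and `threshold`.
#' @export
misclassification_report <- function(mismatch_counts, nests, n_iterations) {
  check_count(n_iterations, "n_iterations")
  if (any(mismatch_counts < 0) || any(mismatch_counts > n_iterations)) {
    abort_arg("mismatch counts must lie in [0, n_iterations]")
  }
  j <- match(names(mismatch_counts), nests$nest_id)
  if (anyNA(j)) abort_arg("some mismatch counts have no matching nest row")
  age_col <- if ("true_age" %in% names(nests)) "true_age" else "age"
  per_nest <- data.frame(
    nest_id = names(mismatch_counts),
    year = nests$year[j],
    age = nests[[age_col]][j],
    mismatch_count = as.integer(mismatch_counts),
    flagged = mismatch_counts >= n_iterations / 2,
    stringsAsFactors = FALSE
  )
  per_year <- stats::aggregate(flagged ~ year, per_nest,
                               function(f) 100 * mean(f))
  names(per_year)[2] <- "error_pct"
  per_age <- stats::aggregate(flagged ~ age, per_nest,
                              function(f) 100 * mean(f))
  names(per_age)[2] <- "error_pct"
  structure(
    list(per_nest = per_nest, per_year = per_year, per_age = per_age,
         threshold = n_iterations / 2, n_iterations = n_iterations),
    class = "misclassification_report"
  )
}

#' @export
print.misclassification_report <- function(x, ...) {
  cat(sprintf("Misclassification consistency: %d / %d nests flagged (>= %g of %d iterations)\n",
              sum(x$per_nest$flagged), nrow(x$per_nest), x$threshold,
              x$n_iterations))
  invisible(x)
}

#' Accuracy as a function of training-set size
#'
#' For each requested size `n`, draws `reps` independent class-stratified
#' subsamples of `n` nests, runs the balanced ensemble on each, and reports
#' the mean and SD of the aggregated accuracy — the learning curve that
#' tells a field programme how many known-age nests it needs.
#'
#' @param table labelled feature table.
#' @param config an [ensemble_config()]; use a reduced `n_iterations`
#'   (e.g. 100) for desk-scale runtimes.
#' @param sizes integer vector of training-set sizes.
#' @param reps subsamples per size.
#' @return a `learning_curve` data.frame with one row per (size, rep) and
#'   columns `n`, `rep`, `accuracy`; per-size summary in
#'   `attr(, "summary")`.
#' @export
learning_curve <- function(table, config, sizes, reps = 10) {
  stopifnot(inherits(config, "ensemble_config"))
  check_count(reps, "reps")
  if (is.null(table$age_class)) {
    table$age_class <- age_to_class(table$age, config$scheme)
  }
  table <- table[!is.na(table$age_class), , drop = FALSE]
  if (any(sizes > nrow(table))) {
    abort_arg(sprintf("requested size exceeds the %d available nests",
                      nrow(table)))
  }
  y <- factor(table$age_class)
  rows <- expand.grid(rep = seq_len(reps), n = as.integer(sizes))
  acc <- numeric(nrow(rows))
  for (k in seq_len(nrow(rows))) {
    n <- rows$n[k]; r <- rows$rep[k]
    sub_seed <- substream_seed(config$seed, sprintf("lc-%d-%d", n, r))
    set.seed(sub_seed)
    # stratified draw: per-class shares of n, largest remainders first
    cnt <- table(y)
    target <- stats::setNames(n * as.numeric(cnt) / length(y), names(cnt))
    base <- floor(target)
    base[base < 1] <- 1
    extra <- n - sum(base)
    if (extra > 0) {
      ord <- order(target - floor(target), decreasing = TRUE)
      base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
    } else if (extra < 0) {
      ord <- order(base, decreasing = TRUE)
      for (i in seq_len(-extra)) base[ord[i]] <- base[ord[i]] - 1
    }
    idx <- sort(unlist(lapply(levels(y), function(cl) {
      sample(which(y == cl), base[cl])
    }), use.names = FALSE))
    sub <- table[idx, , drop = FALSE]
    attr(sub, "predictors") <- table_predictors(table)
    cfg <- config
    cfg$seed <- sub_seed
    acc[k] <- run_ensemble(sub, cfg)$accuracy
  }
  out <- data.frame(n = rows$n, rep = rows$rep, accuracy = acc)
  agg <- stats::aggregate(accuracy ~ n, out,
                          function(a) c(mean = mean(a), sd = stats::sd(a)))
  summary <- data.frame(n = agg$n, mean_accuracy = agg$accuracy[, "mean"],
                        sd_accuracy = agg$accuracy[, "sd"])
  attr(out, "summary") <- summary
  class(out) <- c("learning_curve", "data.frame")
  out
}

#' Compare proportions of young breeders across groups
#'
#' Pearson chi-square test of homogeneity (no continuity correction) on the
#' k x 2 table of (young, not-young) counts — the test used to compare the
#' share of young breeders among colonies or between estimation methods.
#'
#' @param groups data.frame with columns `label`, `n_young`, `n_total`.
#' @return a `proportion_comparison`: list with `groups` (plus
#'   `prop_young`), `chi2`, `df`, `p`, `expected`.
#' @export
compare_young_proportions <- function(groups) {
  groups <- as.data.frame(groups)
  if (nrow(groups) < 2) abort_arg("need at least two groups to compare")
  if (any(groups$n_total <= 0) || any(groups$n_young < 0) ||
      any(groups$n_young > groups$n_total)) {
    abort_arg("need 0 <= n_young <= n_total and n_total > 0 in every group")
  }
  tab <- cbind(young = groups$n_young,
               other = groups$n_total - groups$n_young)
  rownames(tab) <- groups$label
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ht$expected < 1)) {
    warning("expected cell count below 1; chi-square approximation is weak")
  }
  groups$prop_young <- groups$n_young / groups$n_total
  structure(
    list(groups = groups, chi2 = unname(ht$statistic),
         df = as.integer(ht$parameter), p = unname(ht$p.value),
         expected = ht$expected),
    class = "proportion_comparison"
  )
}

#' @export
print.proportion_comparison <- function(x, ...) {
  cat(sprintf("Chi-square test of young-breeder proportions: X2 = %.3f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}
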