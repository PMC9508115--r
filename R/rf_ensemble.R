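#' Configuration of a balanced-bootstrap forest ensemble
#'
#' @param scheme age-class scheme name (or [age_class_scheme()] object) the
#'   ensemble classifies into.
#' @param version predictor subset (`"full"`, `"M4.1"`..`"M4.4"`); recorded
#'   for provenance, the columns themselves come from the feature table.
#' @param n_iterations bootstrap iterations of the balanced-subsample loop
#'   (field default 3000).
#' @param n_trees trees per forest (default 500).
#' @param mtry variables tried per split; `NULL` uses the forest default
#'   (`floor(sqrt(p))` for classification).
#' @param seed master seed; iteration `i` runs on the substream
#'   `"iter<i>"`, so results do not depend on execution order.
#' @param positive_class label treated as positive for sensitivity;
#'   defaults to `"Young"` when the scheme has it, else the first class.
#' @param keep_forests store the fitted forests so [predict_dataset()] can
#'   vote on new data (memory grows with `n_iterations`).
#' @param oob_only_predictions when tallying full-dataset predictions, use
#'   each forest's out-of-bag vote for rows that were in its training
#'   subset (avoids in-bag optimism in the mismatch counts).
#' @param aggregate `"mean_oob"` (mean of per-iteration OOB metrics, the
#'   default) or `"pooled"` (metrics from the summed OOB confusion matrix).
#' @return an `ensemble_config` list.
#' @export
ensemble_config <- function(scheme = "AGE2", version = "full",
                            n_iterations = 3000, n_trees = 500,
                            mtry = NULL, seed = 1,
                            positive_class = NULL,
                            keep_forests = FALSE,
                            oob_only_predictions = FALSE,
                            aggregate = c("mean_oob", "pooled")) {
  scheme <- age_class_scheme_of(scheme)
  check_count(n_iterations, "n_iterations")
  check_count(n_trees, "n_trees")
  if (is.null(positive_class)) {
    positive_class <- if ("Young" %in% scheme$labels) "Young" else scheme$labels[1]
  }
  if (!positive_class %in% scheme$labels) {
    abort_arg(sprintf("positive_class '%s' is not a class of scheme %s",
                      positive_class, scheme$name))
  }
  structure(
    list(scheme = scheme, version = version,
         n_iterations = as.integer(n_iterations),
         n_trees = as.integer(n_trees), mtry = mtry,
         seed = as.integer(seed), positive_class = positive_class,
         keep_forests = isTRUE(keep_forests),
         oob_only_predictions = isTRUE(oob_only_predictions),
         aggregate = match.arg(aggregate)),
    class = "ensemble_config"
  )
}

#' Balanced subsample of a labelled table
#'
#' Downsamples every class, uniformly without replacement, to the size of
#' the smallest class, removing class-imbalance bias before a forest is
#' trained. Uses the current RNG state.
#'
#' @param table labelled feature table.
#' @param class_col name of the class-label column.
#' @return the subsampled table; selected row indices in `attr(, "idx")`.
#' @export
balanced_subsample <- function(table, class_col = "age_class") {
  y <- table[[class_col]]
  if (is.null(y)) abort_arg(sprintf("no `%s` column to balance on", class_col))
  if (!is.factor(y)) y <- factor(y) # keep declared levels: an empty class errors
  idx <- balanced_subsample_idx(y)
  out <- table[idx, , drop = FALSE]
  attr(out, "idx") <- idx
  out
}

balanced_subsample_idx <- function(y) {
  counts <- table(y)
  if (any(counts == 0)) {
    abort_arg(paste("empty class(es):",
                    paste(names(counts)[counts == 0], collapse = ", ")))
  }
  m <- min(counts)
  idx <- unlist(lapply(levels(y), function(cl) {
    rows <- which(y == cl)
    if (length(rows) == 1) rows else sample(rows, m)
  }), use.names = FALSE)
  sort(idx)
}

# Forests get factors integer-coded (Year's 24 levels, Clutch's 5); split
# finding then treats them as ordered codes, which keeps trees cheap.
forest_frame <- function(table, predictors) {
  x <- table[, predictors, drop = FALSE]
  for (j in seq_along(x)) {
    if (is.factor(x[[j]])) x[[j]] <- as.integer(as.character(x[[j]]))
    if (is.character(x[[j]])) x[[j]] <- as.integer(factor(x[[j]]))
  }
  x
}

table_predictors <- function(table, config = NULL) {
  p <- attr(table, "predictors")
  if (is.null(p)) {
    p <- setdiff(names(table),
                 c("nest_id", "year", "colony", "age", "age_class", "true_age"))
  }
  p
}

#' Train a single balanced-iteration forest
#'
#' Fits one classification forest on a balanced subset and records its
#' out-of-bag error, OOB confusion matrix, per-predictor Gini importance
#' (mean decrease in Gini impurity) and its predicted class for every row
#' of the full table. Uses the current RNG state.
#'
#' @param balanced balanced training table (see [balanced_subsample()]).
#' @param full the full feature table the predictions are tallied on.
#' @param config an [ensemble_config()].
#' @return list with `oob_error`, `confusion` (rows = true class),
#'   `gini`, `full_predictions`, and the forest itself under `forest`.
#' @export
train_iteration <- function(balanced, full, config) {
  predictors <- table_predictors(full)
  y <- droplevels(factor(balanced$age_class))
  if (nlevels(y) < 2) abort_arg("balanced table has a single class; nothing to learn")
  x <- forest_frame(balanced, predictors)
  rf <- if (is.null(config$mtry)) {
    randomForest::randomForest(x = x, y = y, ntree = config$n_trees)
  } else {
    randomForest::randomForest(x = x, y = y, ntree = config$n_trees,
                               mtry = config$mtry)
  }
  oob_pred <- rf$predicted
  oob_error <- mean(oob_pred != y)
  confusion <- table(true = y, predicted = oob_pred)
  full_pred <- stats::predict(rf, forest_frame(full, predictors))
  idx <- attr(balanced, "idx")
  if (config$oob_only_predictions && !is.null(idx)) {
    full_pred[idx] <- as.character(oob_pred)
  }
  list(oob_error = oob_error, confusion = confusion,
       gini = rf$importance[, "MeanDecreaseGini"],
       full_predictions = full_pred, forest = rf)
}

one_vs_rest <- function(confusion, positive) {
  pos_t <- rownames(confusion) == positive
  pos_p <- colnames(confusion) == positive
  tp <- sum(confusion[pos_t, pos_p])
  fn <- sum(confusion[pos_t, !pos_p])
  tn <- sum(confusion[!pos_t, !pos_p])
  fp <- sum(confusion[!pos_t, pos_p])
  c(sensitivity = 100 * tp / (tp + fn), specificity = 100 * tn / (tn + fp))
}

#' Run the balanced-subsample bootstrap ensemble
#'
#' The core procedure: `n_iterations` times, draw a balanced subsample
#' (every class downsampled to the smallest class's size), train a
#' classification forest on it, record its out-of-bag metrics and Gini
#' importances, and use it to predict the class of every nest in the
#' original table. Aggregates across iterations: accuracy is the mean of
#' per-iteration `100 * (1 - OOB error)`, sensitivity/specificity are means
#' of the per-iteration one-vs-rest rates for the positive class, Gini
#' importance is the per-predictor mean, and `mismatch_counts` tallies, per
#' nest, the iterations whose full-dataset prediction disagreed with the
#' true class.
#'
#' @param table labelled feature table from [build_feature_table()]; when
#'   it lacks an `age_class` column one is derived from `age` under the
#'   config's scheme.
#' @param config an [ensemble_config()].
#' @return an `ensemble_result`: list with `accuracy`, `sensitivity`,
#'   `specificity` (percent), `gini_aggregate`, `gini_matrix`
#'   (iterations x predictors), `mismatch_counts` (named by nest id),
#'   `pooled_confusion`, `n_iterations`, `class_counts`, `config`, and
#'   `forests` when `keep_forests = TRUE`.
#' @export
run_ensemble <- function(table, config) {
  stopifnot(inherits(config, "ensemble_config"))
  if (is.null(table$age_class)) {
    if (is.null(table$age)) abort_arg("table has neither `age_class` nor `age`")
    table$age_class <- age_to_class(table$age, config$scheme)
  }
  keep <- !is.na(table$age_class)
  table <- table[keep, , drop = FALSE]
  predictors <- table_predictors(table)
  attr(table, "predictors") <- predictors
  y <- factor(table$age_class)

  n_it <- config$n_iterations
  acc <- sens <- spec <- numeric(n_it)
  gini <- matrix(NA_real_, n_it, length(predictors),
                 dimnames = list(NULL, predictors))
  mismatch <- integer(nrow(table))
  pooled <- NULL
  forests <- if (config$keep_forests) vector("list", n_it)
  for (i in seq_len(n_it)) {
    set.seed(substream_seed(config$seed, sprintf("iter%d", i)))
    bal <- balanced_subsample(table)
    it <- tryCatch(
      train_iteration(bal, table, config),
      error = function(e) {
        stop(sprintf("ensemble iteration %d failed: %s", i,
                     conditionMessage(e)), call. = FALSE)
      }
    )
    acc[i] <- 100 * (1 - it$oob_error)
    ss <- one_vs_rest(it$confusion, config$positive_class)
    sens[i] <- ss["sensitivity"]
    spec[i] <- ss["specificity"]
    gini[i, names(it$gini)] <- it$gini
    mismatch <- mismatch + (as.character(it$full_predictions) != as.character(y))
    pooled <- if (is.null(pooled)) unclass(it$confusion) else pooled + unclass(it$confusion)
    if (config$keep_forests) forests[[i]] <- it$forest
  }
  names(mismatch) <- table$nest_id
  if (config$aggregate == "pooled") {
    accuracy <- 100 * sum(diag(pooled)) / sum(pooled)
    ss <- one_vs_rest(pooled, config$positive_class)
    sensitivity <- ss["sensitivity"]; specificity <- ss["specificity"]
  } else {
    accuracy <- mean(acc); sensitivity <- mean(sens); specificity <- mean(spec)
  }
  structure(
    list(accuracy = unname(accuracy), sensitivity = unname(sensitivity),
         specificity = unname(specificity),
         per_iteration = data.frame(accuracy = acc, sensitivity = sens,
                                    specificity = spec),
         gini_aggregate = colMeans(gini), gini_matrix = gini,
         mismatch_counts = mismatch, pooled_confusion = pooled,
         n_iterations = n_it, class_counts = table(y),
         true_class = stats::setNames(as.character(y), table$nest_id),
         config = config, forests = forests),
    class = "ensemble_result"
  )
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(
    "Balanced-bootstrap forest ensemble (%s, %d iterations x %d trees)\n",
    x$config$scheme$name, x$n_iterations, x$config$n_trees))
  cat(sprintf("  accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%% (positive: %s)\n",
              x$accuracy, x$sensitivity, x$specificity, x$config$positive_class))
  gi <- sort(x$gini_aggregate, decreasing = TRUE)
  cat("  Gini importance:", paste(sprintf("%s=%.2f", names(gi), gi),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Variance explained by a regression forest on continuous age
#'
#' Fits one regression random forest with age (years) as a continuous
#' response and returns the out-of-bag pseudo-R^2,
#' `100 * (1 - OOB MSE / Var(age))`, in percent. May be negative when the
#' forest does worse than the mean.
#'
#' @param table labelled feature table with a numeric `age` column.
#' @param config an [ensemble_config()] (only `n_trees`, `mtry`, `seed`
#'   are used).
#' @return variance explained, percent.
#' @export
regression_forest_variance_explained <- function(table, config) {
  age <- table$age
  keep <- !is.na(age)
  table <- table[keep, , drop = FALSE]
  age <- age[keep]
  if (length(unique(age)) < 2) abort_arg("`age` is constant; R^2 undefined")
  x <- forest_frame(table, table_predictors(table))
  set.seed(substream_seed(config$seed, "m0"))
  rf <- if (is.null(config$mtry)) {
    randomForest::randomForest(x = x, y = age, ntree = config$n_trees)
  } else {
    randomForest::randomForest(x = x, y = age, ntree = config$n_trees,
                               mtry = config$mtry)
  }
  oob_mse <- mean((rf$predicted - age)^2)
  100 * (1 - oob_mse / mean((age - mean(age))^2))
}

#' Predict age classes for new nests by majority vote
#'
#' Votes every stored forest of a trained ensemble on the new table; each
#' nest's class is the modal prediction, with ties broken deterministically
#' in favour of the non-positive class (conservative toward the rarer
#' 'Young' call).
#'
#' @param result an `ensemble_result` trained with `keep_forests = TRUE`.
#' @param new_table feature table carrying the training predictors (the
#'   egg-only and no-year versions make this possible when environment or
#'   year covariates are unavailable).
#' @return data.frame with `nest_id`, `predicted_class`, `vote_fraction`;
#'   the proportion predicted positive is in `attr(, "prop_positive")`.
#' @export
predict_dataset <- function(result, new_table) {
  stopifnot(inherits(result, "ensemble_result"))
  if (is.null(result$forests) || !length(result$forests) ||
      is.null(result$forests[[1]])) {
    abort_arg("ensemble was trained with keep_forests = FALSE; retrain to predict")
  }
  predictors <- colnames(result$gini_matrix)
  missing_cols <- setdiff(predictors, names(new_table))
  if (length(missing_cols)) {
    abort_arg(paste("new table lacks predictor columns:",
                    paste(missing_cols, collapse = ", ")))
  }
  x <- forest_frame(new_table, predictors)
  labels <- result$config$scheme$labels
  votes <- matrix(0L, nrow(x), length(labels), dimnames = list(NULL, labels))
  for (rf in result$forests) {
    p <- as.character(stats::predict(rf, x))
    for (cl in unique(p)) votes[p == cl, cl] <- votes[p == cl, cl] + 1L
  }
  pos <- result$config$positive_class
  # tie-break order: non-positive classes first, in scheme order
  pref <- c(setdiff(labels, pos), pos)
  pick <- apply(votes, 1, function(v) {
    top <- names(v)[v == max(v)]
    pref[pref %in% top][1]
  })
  out <- data.frame(
    nest_id = if (!is.null(new_table$nest_id)) new_table$nest_id
              else seq_len(nrow(x)),
    predicted_class = factor(pick, levels = labels),
    vote_fraction = votes[cbind(seq_len(nrow(x)), match(pick, labels))] /
      length(result$forests),
    stringsAsFactors = FALSE
  )
  attr(out, "prop_positive") <- mean(pick == pos)
  out
}
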