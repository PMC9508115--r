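#' Egg volume from linear dimensions
#'
#' The standard field formula for gull eggs:
#' `Volume (cm^3) = 0.000476 * length * width^2`, with length and width in
#' millimetres.
#'
#' @param length_mm egg length in mm (> 0), vectorised.
#' @param width_mm egg maximum breadth in mm (> 0), vectorised.
#' @return egg volume(s) in cm^3.
#' @export
#' @examples
#' egg_volume(60, 45) # 57.834
egg_volume <- function(length_mm, width_mm) {
  if (any(!is.finite(length_mm)) || any(!is.finite(width_mm)) ||
      any(length_mm <= 0) || any(width_mm <= 0)) {
    abort_arg("egg dimensions must be positive finite numbers (mm)")
  }
  0.000476 * length_mm * width_mm^2
}

#' Per-nest egg-volume aggregates
#'
#' Computes the two nest-level predictors used throughout the pipeline:
#' total egg volume per nest `VT` (sum over the clutch) and mean egg volume
#' per nest `VM = VT / clutch`.
#'
#' @param eggs data.frame or matrix with columns `length_mm`, `width_mm`,
#'   one row per egg in the clutch.
#' @return list with `vt`, `vm` (cm^3) and `clutch`.
#' @export
nest_features <- function(eggs) {
  eggs <- as.data.frame(eggs)
  if (nrow(eggs) == 0) abort_arg("empty egg list: a clutch has at least one egg")
  if (!all(c("length_mm", "width_mm") %in% names(eggs))) {
    abort_arg("`eggs` needs columns `length_mm` and `width_mm`")
  }
  v <- egg_volume(eggs$length_mm, eggs$width_mm)
  list(vt = sum(v), vm = mean(v), clutch = nrow(eggs))
}

#' Per-capita food availability
#'
#' Fish landings divided by the combined breeding population of the study
#' species and its main competitor (density-dependent food access). The
#' study-species count is carried in the signature for provenance but the
#' denominator is the two-species total.
#'
#' @param food fish landings (mass units).
#' @param la_popsize study-species breeding pairs (unused in the quotient;
#'   kept so callers pass the full population record).
#' @param popsize total breeding pairs of both species (> 0).
#' @return `food / popsize`, vectorised.
#' @export
food_per_capita <- function(food, la_popsize = NULL, popsize) {
  if (any(!is.finite(popsize)) || any(popsize <= 0)) {
    abort_arg("`popsize` must be positive: cannot divide landings by zero birds")
  }
  food / popsize
}

#' z-transformation
#'
#' Centres and scales to unit sample SD (denominator n - 1).
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @param name label used in the zero-variance error message.
#' @return standardized vector with mean 0 and SD 1.
#' @export
z_transform <- function(x, name = deparse(substitute(x))) {
  if (length(x) < 2) abort_arg(sprintf("`%s`: need at least 2 values to standardize", name))
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    abort_arg(sprintf("`%s` has zero variance: z-transform undefined", name))
  }
  (x - mean(x)) / s
}

#' Age-class schemes
#'
#' The four discretisations of breeder age used by the classification
#' ensembles, from finest to coarsest:
#' * `AGE14`: ages 3..15 each their own class, 16+ pooled as `"16+"`.
#' * `AGE6`: ages 3,4,5,6 separate, 7-15 pooled `"Middle-aged"`, 16+ `"Old"`.
#' * `AGE3`: 3-4 `"Young"`, 5-15 `"Middle-aged"`, 16+ `"Old"`.
#' * `AGE2`: 3-4 `"Young"`, 5+ `"Others"`.
#'
#' Every age >= 3 maps to exactly one class under each scheme.
#'
#' @param name one of `"AGE14"`, `"AGE6"`, `"AGE3"`, `"AGE2"`.
#' @return an object of class `age_scheme`: list with `name`, `labels` and
#'   a vectorised `classify(age)` function.
#' @export
#' @examples
#' age_to_class(4, age_class_scheme("AGE2")) # "Young"
age_class_scheme <- function(name = c("AGE2", "AGE3", "AGE6", "AGE14")) {
  name <- match.arg(name)
  scheme <- switch(name,
    AGE14 = list(
      labels = c(as.character(3:15), "16+"),
      classify = function(a) ifelse(a >= 16, "16+", as.character(a))
    ),
    AGE6 = list(
      labels = c("3", "4", "5", "6", "Middle-aged", "Old"),
      classify = function(a) ifelse(a >= 16, "Old",
                             ifelse(a >= 7, "Middle-aged", as.character(a)))
    ),
    AGE3 = list(
      labels = c("Young", "Middle-aged", "Old"),
      classify = function(a) ifelse(a >= 16, "Old",
                             ifelse(a >= 5, "Middle-aged", "Young"))
    ),
    AGE2 = list(
      labels = c("Young", "Others"),
      classify = function(a) ifelse(a >= 5, "Others", "Young")
    )
  )
  structure(list(name = name, labels = scheme$labels,
                 classify = scheme$classify),
            class = "age_scheme")
}

#' Map ages to class labels under a scheme
#'
#' @param age integer age(s) in years, all >= 3.
#' @param scheme an [age_class_scheme()] or its name.
#' @return factor of class labels with the scheme's level order.
#' @export
age_to_class <- function(age, scheme) {
  if (is.character(scheme)) scheme <- age_class_scheme(scheme)
  stopifnot(inherits(scheme, "age_scheme"))
  if (any(!is.finite(age)) || any(age < 3)) {
    abort_arg("ages below 3 (recruitment age) cannot be classified")
  }
  factor(scheme$classify(age), levels = scheme$labels)
}

# Predictor column sets for the model versions. 'full' (used by the
# M0-M3 analyses) carries everything M4.1 does.
version_predictors <- function(version) {
  all10 <- c("VM", "VT", "Clutch", "Year", "Food", "Foodpc",
             "La_Popsize", "Popsize", "WNAO", "ANAO")
  switch(version,
    full    = all10,
    M4.1    = all10,
    M4.2    = setdiff(all10, "Year"),
    M4.3    = c("VM", "VT", "Clutch", "Year"),
    M4.4    = c("VM", "VT", "Clutch"),
    abort_arg(sprintf("unknown model version '%s'", version))
  )
}

#' Assemble the nest-level feature table
#'
#' Computes `VT` and `VM` from the wide egg-dimension columns, joins the
#' annual covariates, z-scores per-capita food once over the environment
#' years (then joins it to nests; it is never re-standardized per subset),
#' and keeps the predictor columns of the requested model version:
#' * `M4.1` / `full`: VM, VT, Clutch, Year, Food, Foodpc, La_Popsize,
#'   Popsize, WNAO, ANAO;
#' * `M4.2`: M4.1 without Year;
#' * `M4.3`: VM, VT, Clutch, Year;
#' * `M4.4`: VM, VT, Clutch.
#'
#' Nests with a missing egg measurement inside the clutch are dropped with a
#' message. `Clutch` and `Year` are unordered factors.
#'
#' @param nests nest table as produced by [generate_dataset()] (or read from
#'   `nests.csv`).
#' @param environment annual covariate table; may be `NULL` for the
#'   egg-only versions `M4.3` / `M4.4`.
#' @param version predictor subset, see above.
#' @param scheme optional [age_class_scheme()] (or name); when given and
#'   ages are available, an `age_class` label column is added.
#' @return data.frame with id columns (`nest_id`, `year`, `colony`), the
#'   version's predictors, and `age` / `age_class` labels where available.
#'   The predictor names are stored in `attr(, "predictors")`.
#' @export
build_feature_table <- function(nests, environment = NULL,
                                version = c("full", "M4.1", "M4.2", "M4.3", "M4.4"),
                                scheme = NULL) {
  version <- match.arg(version)
  predictors <- version_predictors(version)
  needs_env <- any(c("Food", "Foodpc", "La_Popsize", "Popsize",
                     "WNAO", "ANAO") %in% predictors)
  if (needs_env && is.null(environment)) {
    abort_arg(sprintf("version %s needs the environment table", version))
  }
  if (needs_env) {
    missing_years <- setdiff(unique(nests$year), environment$year)
    if (length(missing_years)) {
      abort_arg(paste("nest years missing from environment table:",
                      paste(sort(missing_years), collapse = ", ")))
    }
  }

  # per-nest VT / VM from the first `clutch` egg columns
  n <- nrow(nests)
  vt <- vm <- rep(NA_real_, n)
  complete <- rep(TRUE, n)
  for (i in seq_len(n)) {
    k <- nests$clutch[i]
    len <- as.numeric(nests[i, sprintf("egg%d_length_mm", seq_len(k))])
    wid <- as.numeric(nests[i, sprintf("egg%d_width_mm", seq_len(k))])
    if (anyNA(len) || anyNA(wid)) {
      complete[i] <- FALSE
      next
    }
    v <- egg_volume(len, wid)
    vt[i] <- sum(v)
    vm[i] <- mean(v)
  }
  if (any(!complete)) {
    message(sprintf("dropping %d nest(s) with missing egg measurements",
                    sum(!complete)))
  }
  nests <- nests[complete, , drop = FALSE]
  out <- data.frame(
    nest_id = nests$nest_id,
    year = nests$year,
    colony = if ("colony" %in% names(nests)) nests$colony else NA_character_,
    VM = vm[complete],
    VT = vt[complete],
    Clutch = factor(nests$clutch, levels = 1:5),
    Year = factor(nests$year),
    stringsAsFactors = FALSE
  )
  if (needs_env) {
    env <- environment
    env$Foodpc <- z_transform(food_per_capita(env$food, env$la_popsize,
                                              env$popsize), name = "Foodpc")
    j <- match(out$year, env$year)
    out$Food <- env$food[j]
    out$Foodpc <- env$Foodpc[j]
    out$La_Popsize <- env$la_popsize[j]
    out$Popsize <- env$popsize[j]
    out$WNAO <- env$wnao[j]
    out$ANAO <- env$anao[j]
  }
  age_col <- if ("true_age" %in% names(nests)) "true_age" else "age"
  if (age_col %in% names(nests)) {
    out$age <- nests[[age_col]]
    if (!is.null(scheme)) {
      known <- !is.na(out$age)
      out$age_class <- factor(NA_character_,
                              levels = age_class_scheme_of(scheme)$labels)
      out$age_class[known] <- age_to_class(out$age[known],
                                           age_class_scheme_of(scheme))
    }
  }
  out <- out[, c("nest_id", "year", "colony", predictors,
                 intersect(c("age", "age_class"), names(out)))]
  attr(out, "predictors") <- predictors
  attr(out, "version") <- version
  if (!is.null(scheme)) attr(out, "scheme") <- age_class_scheme_of(scheme)$name
  out
}

age_class_scheme_of <- function(scheme) {
  if (is.character(scheme)) age_class_scheme(scheme) else scheme
}
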