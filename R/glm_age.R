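#' Candidate GLM specifications for egg-volume analysis
#'
#' Enumerates the candidate set of Gaussian GLMs. Stage `"age-only"` crosses
#' the response with the seven competing age parameterizations — linear
#' (`LINEAR`), quadratic (`QUADRATIC`, young and old both poorer),
#' logarithmic (`LOG`, only young poorer) and the four categorical schemes
#' (`AGE14`, `AGE6`, `AGE3`, `AGE2`) — plus an age-free null (`NONE`);
#' clutch size is included in every model. Stage `"environmental"` fixes the
#' winning age form and adds additive combinations of `Year`, `Foodpc` and
#' one NAO index (`WNAO` and `ANAO` never co-occur), optionally with
#' age-by-annual-variable interactions (main effects always retained).
#'
#' @param stage `"age-only"` or `"environmental"`.
#' @param response `"VM"` (mean egg volume) or `"VT"` (total egg volume).
#' @param age_form for the environmental stage, the age form carried over.
#' @param include_interactions add age x (Foodpc, NAO) interaction variants
#'   in the environmental stage.
#' @param interact_year also add age x Year interaction variants (off by
#'   default: 24 extra levels per age term rarely count as parsimonious).
#' @return list of `model_spec` objects (fields `response`, `age_form`,
#'   `covariates`, `interactions`).
#' @export
candidate_specs <- function(stage = c("age-only", "environmental"),
                            response = c("VM", "VT"),
                            age_form = NULL,
                            include_interactions = TRUE,
                            interact_year = FALSE) {
  stage <- match.arg(stage)
  response <- match.arg(response)
  new_spec <- function(form, covs, inter = list()) {
    structure(list(response = response, age_form = form,
                   covariates = covs, interactions = inter),
              class = "model_spec")
  }
  if (stage == "age-only") {
    forms <- c("NONE", "LINEAR", "QUADRATIC", "LOG",
               "AGE14", "AGE6", "AGE3", "AGE2")
    return(lapply(forms, new_spec, covs = "Clutch"))
  }
  if (is.null(age_form)) {
    abort_arg("environmental stage needs the winning `age_form`")
  }
  specs <- list()
  for (year_in in c(FALSE, TRUE)) {
    for (food_in in c(FALSE, TRUE)) {
      for (nao in c(NA, "WNAO", "ANAO")) {
        covs <- c("Clutch",
                  if (year_in) "Year",
                  if (food_in) "Foodpc",
                  if (!is.na(nao)) nao)
        specs <- c(specs, list(new_spec(age_form, covs)))
        if (include_interactions && age_form != "NONE") {
          annual <- c(if (food_in) "Foodpc",
                      if (!is.na(nao)) nao,
                      if (year_in && interact_year) "Year")
          for (v in annual) {
            specs <- c(specs,
                       list(new_spec(age_form, covs,
                                     inter = list(c(age_form, v)))))
          }
        }
      }
    }
  }
  specs
}

age_form_terms <- function(form) {
  switch(form,
    NONE      = character(0),
    LINEAR    = "age",
    QUADRATIC = c("age", "I(age^2)"),
    LOG       = "log(age)",
    AGE14     = , AGE6 = , AGE3 = , AGE2 = ".age_class",
    abort_arg(sprintf("unknown age form '%s'", form))
  )
}

#' Model formula of a candidate spec
#'
#' @param spec a `model_spec` from [candidate_specs()].
#' @return a formula; categorical age forms reference a `.age_class` column
#'   that [fit_glm()] materialises from `age`.
#' @export
spec_formula <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  rhs <- c(age_form_terms(spec$age_form), spec$covariates)
  for (inter in spec$interactions) {
    at <- age_form_terms(inter[1])
    rhs <- c(rhs, sprintf("(%s):%s", paste(at, collapse = " + "), inter[2]))
  }
  if (!length(rhs)) rhs <- "1"
  stats::as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")))
}

#' @export
format.model_spec <- function(x, ...) {
  rhs <- c(if (x$age_form != "NONE") x$age_form, x$covariates,
           vapply(x$interactions, function(i) paste(i, collapse = ":"), ""))
  paste(x$response, "~", paste(rhs, collapse = " + "))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Fit one candidate Gaussian GLM
#'
#' Identity-link Gaussian fit via [stats::glm()]; the reported AIC follows
#' the usual Gaussian-likelihood convention in which the residual variance
#' counts as a parameter.
#'
#' @param spec a `model_spec`.
#' @param table a feature table from [build_feature_table()] with an `age`
#'   column (for age forms other than `NONE`).
#' @return object of class `age_glm_fit`: list with `spec`, `label`, `fit`
#'   (the glm object), `coefficients`, `n_params`, `logLik`, `aic`.
#' @export
fit_glm <- function(spec, table) {
  stopifnot(inherits(spec, "model_spec"))
  needed <- c(spec$response, spec$covariates,
              if (spec$age_form != "NONE") "age")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols)) {
    abort_arg(paste("feature table lacks columns:",
                    paste(missing_cols, collapse = ", ")))
  }
  data <- table
  if (spec$age_form %in% c("AGE14", "AGE6", "AGE3", "AGE2")) {
    data$.age_class <- age_to_class(data$age, spec$age_form)
    data$.age_class <- droplevels(data$.age_class)
  }
  fit <- stats::glm(spec_formula(spec), family = stats::gaussian(), data = data)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    abort_arg(paste("rank-deficient design; aliased terms:",
                    paste(aliased, collapse = ", ")))
  }
  ll <- stats::logLik(fit)
  structure(
    list(spec = spec, label = format(spec), fit = fit,
         coefficients = stats::coef(fit),
         n_params = attr(ll, "df"), logLik = as.numeric(ll),
         aic = stats::AIC(fit)),
    class = "age_glm_fit"
  )
}

#' Rank fitted models by AIC
#'
#' @param fits list of `age_glm_fit` objects.
#' @return a `model_selection_table` data.frame with columns `model`, `k`,
#'   `logLik`, `AIC`, `dAIC`, sorted by ascending AIC (top row dAIC = 0).
#' @export
aic_rank <- function(fits) {
  if (inherits(fits, "age_glm_fit")) fits <- list(fits)
  if (!length(fits)) abort_arg("need at least one fitted model to rank")
  tab <- data.frame(
    model = vapply(fits, function(f) f$label, ""),
    k = vapply(fits, function(f) as.numeric(f$n_params), 0),
    logLik = vapply(fits, function(f) f$logLik, 0),
    AIC = vapply(fits, function(f) f$aic, 0),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$AIC), , drop = FALSE]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[order(vapply(fits, function(f) f$aic, 0))]
  class(tab) <- c("model_selection_table", "data.frame")
  tab
}

#' Age-only model selection in one call
#'
#' Fits the eight age-only candidates (seven age forms plus the age-free
#' null, all with clutch size) and ranks them by AIC.
#'
#' @param table feature table with `age`, the response and `Clutch`.
#' @param response `"VM"` or `"VT"`.
#' @return a `model_selection_table`; the winning age form is in
#'   `attr(, "best_age_form")`.
#' @export
select_age_model <- function(table, response = c("VM", "VT")) {
  response <- match.arg(response)
  specs <- candidate_specs("age-only", response = response)
  fits <- lapply(specs, fit_glm, table = table)
  tab <- aic_rank(fits)
  attr(tab, "best_age_form") <- attr(tab, "fits")[[1]]$spec$age_form
  tab
}
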