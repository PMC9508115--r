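#' Configuration for the synthetic colony generator
#'
#' Bundles every knob of the generative model used to emulate a long-term
#' colony monitoring scheme for a long-lived gull: an age pyramid over
#' breeder ages `age_min`..`age_max`, clutch sizes 1-5, per-egg volumes with
#' a concave quadratic maternal-age effect plus annual environmental effects,
#' and a multi-year environmental covariate table (NAO indices, fish
#' landings, breeding population sizes).
#'
#' The per-egg mean volume (cm^3) for a mother of age `a` in year `t` is
#' \deqn{\mu = \beta_0 + \beta_{age} a + \beta_{age2} a^2 +
#'       \beta_{wnao} WNAO_t + \beta_{food} Foodpc_t + u_t + b_i}
#' with year effects \eqn{u_t \sim N(0, \sigma_{year}^2)}, individual
#' effects \eqn{b_i \sim N(0, \sigma_{ind}^2)}, and i.i.d. egg noise
#' \eqn{N(0, \sigma_{egg}^2)} truncated to positive volumes. `Foodpc` is the
#' z-scored per-capita food availability over the simulated years.
#'
#' Defaults describe a plausible colony: volumes in the 40-55 cm^3 range
#' typical of a mid-sized gull, peak performance near age 12
#' (vertex at `-beta_age / (2 * beta_age2)`), modal clutch of 3 (~60% of
#' nests), and a right-skewed age pyramid (truncated geometric with annual
#' survival 0.9, so newly recruited 3-4 year olds are the commonest breeders).
#'
#' @param n_years number of breeding seasons simulated.
#' @param nests_per_year monitored nests per season.
#' @param colonies character vector of colony labels nests are spread over.
#' @param age_min,age_max breeder age bounds in years (recruitment at 3).
#' @param survival_rate annual survival shaping the pyramid,
#'   `P(age = a) proportional to survival_rate^(a - age_min)`.
#' @param beta0 baseline mean egg volume (cm^3).
#' @param beta_age linear age coefficient (cm^3 per year).
#' @param beta_age2 quadratic age coefficient (cm^3 per year^2); negative
#'   for the concave young-poor / old-poor pattern.
#' @param beta_wnao effect of the winter NAO index (cm^3 per index unit).
#' @param beta_food effect of z-scored per-capita food (cm^3 per SD).
#' @param sigma_year SD of random year effects (cm^3).
#' @param sigma_ind SD of between-mother heterogeneity (cm^3).
#' @param sigma_egg within-clutch egg noise SD (cm^3).
#' @param clutch_probs probability vector over clutch sizes 1-5; the default
#'   puts ~60% of nests at the modal clutch of 3.
#' @param shape_ratio egg width/length ratio used to back-solve dimensions
#'   from volume.
#' @param food_median median of the log-normal fish-landings distribution.
#' @param food_sdlog log-scale SD of fish landings.
#' @param year_start calendar year of the first season.
#' @param prop_unknown_age fraction of nests whose mother age is masked in
#'   the `age` column (ground truth stays in `true_age`).
#' @param seed master RNG seed; all stages derive named substreams from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_years = 4, nests_per_year = 20, seed = 1)
#' ds <- generate_dataset(cfg)
#' head(ds$nests)
sim_config <- function(n_years = 24,
                       nests_per_year = 100,
                       colonies = c("BN", "SR", "TP", "BP"),
                       age_min = 3, age_max = 28,
                       survival_rate = 0.9,
                       beta0 = 45, beta_age = 1.2, beta_age2 = -0.05,
                       beta_wnao = 0.5, beta_food = 0.8,
                       sigma_year = 1, sigma_ind = 2, sigma_egg = 2,
                       clutch_probs = c(0.05, 0.15, 0.60, 0.15, 0.05),
                       shape_ratio = 0.68,
                       food_median = 1000, food_sdlog = 0.3,
                       year_start = 1994,
                       prop_unknown_age = 0,
                       seed = 1) {
  check_count(n_years, "n_years")
  check_count(nests_per_year, "nests_per_year")
  check_number(age_min, "age_min", lower = 3)
  check_number(age_max, "age_max")
  if (age_min >= age_max) abort_arg("`age_min` must be < `age_max`")
  check_number(survival_rate, "survival_rate")
  if (survival_rate <= 0 || survival_rate >= 1) {
    abort_arg("`survival_rate` must be in (0, 1)")
  }
  if (length(clutch_probs) != 5 || any(clutch_probs < 0) ||
      abs(sum(clutch_probs) - 1) > 1e-8) {
    abort_arg("`clutch_probs` must be 5 non-negative probabilities summing to 1")
  }
  for (s in c("sigma_year", "sigma_ind", "sigma_egg")) {
    check_number(get(s), s, lower = 0)
  }
  check_number(shape_ratio, "shape_ratio")
  if (shape_ratio <= 0 || shape_ratio >= 1) {
    abort_arg("`shape_ratio` must be in (0, 1): eggs are longer than wide")
  }
  check_number(food_median, "food_median", lower = 0)
  check_number(prop_unknown_age, "prop_unknown_age", lower = 0, upper = 1)
  ages <- age_min:age_max
  mu_age <- beta0 + beta_age * ages + beta_age2 * ages^2
  if (any(mu_age <= 0)) {
    abort_arg(sprintf(
      "age-effect coefficients give non-positive mean volume at age %d",
      ages[which.min(mu_age)]
    ))
  }
  structure(
    list(
      n_years = as.integer(n_years), nests_per_year = as.integer(nests_per_year),
      colonies = as.character(colonies),
      age_min = as.integer(age_min), age_max = as.integer(age_max),
      survival_rate = survival_rate,
      beta0 = beta0, beta_age = beta_age, beta_age2 = beta_age2,
      beta_wnao = beta_wnao, beta_food = beta_food,
      sigma_year = sigma_year, sigma_ind = sigma_ind, sigma_egg = sigma_egg,
      clutch_probs = clutch_probs, shape_ratio = shape_ratio,
      food_median = food_median, food_sdlog = food_sdlog,
      year_start = as.integer(year_start),
      prop_unknown_age = prop_unknown_age,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate the annual environmental covariate table
#'
#' NAO indices are i.i.d. standard normal, fish landings are log-normal with
#' configured median, and breeding population sizes follow a smooth logistic
#' colonisation trajectory (study species) on top of a noisy, roughly
#' stationary competitor population; `popsize` is the two-species total.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to the config's "environment" substream.
#' @return a data.frame with columns `year`, `anao`, `wnao`, `food`,
#'   `la_popsize`, `popsize`, one row per contiguous year.
#' @export
simulate_environment <- function(config,
                                 seed = substream_seed(config$seed, "environment")) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_years
  set.seed(seed)
  t <- seq_len(n)
  anao <- stats::rnorm(n)
  wnao <- stats::rnorm(n)
  food <- stats::rlnorm(n, meanlog = log(config$food_median),
                        sdlog = config$food_sdlog)
  # study species colonises and grows logistically; competitor ~ stationary
  la <- 12000 / (1 + exp(-0.3 * (t - n / 2))) *
    stats::rlnorm(n, 0, 0.05)
  yl <- 4000 * stats::rlnorm(n, 0, 0.10)
  data.frame(
    year = config$year_start + t - 1L,
    anao = anao, wnao = wnao, food = food,
    la_popsize = pmax(1, round(la)),
    popsize = pmax(1, round(la)) + pmax(1, round(yl))
  )
}

#' Draw breeder ages from a truncated geometric age pyramid
#'
#' `P(age = a)` is proportional to `survival_rate^(a - age_min)` on
#' `[age_min, age_max]`: young, newly recruited breeders dominate and
#' frequencies decay geometrically with age, mimicking the right-skewed age
#' structure of a surveyed colony.
#'
#' @param n number of ages to draw.
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to the config's "ages" substream.
#' @return integer vector of ages in `[age_min, age_max]`.
#' @export
simulate_ages <- function(n, config,
                          seed = substream_seed(config$seed, "ages")) {
  stopifnot(inherits(config, "sim_config"))
  check_count(n, "n")
  ages <- config$age_min:config$age_max
  w <- config$survival_rate^(ages - config$age_min)
  set.seed(seed)
  sample(ages, n, replace = TRUE, prob = w / sum(w))
}

# Back-solve (length, width) in mm from a volume in cm^3 so that
# 0.000476 * length * width^2 reproduces the volume exactly, with
# width = shape_ratio * length.
dims_from_volume <- function(volume, shape_ratio) {
  length_mm <- (volume / (0.000476 * shape_ratio^2))^(1 / 3)
  data.frame(length_mm = length_mm, width_mm = shape_ratio * length_mm)
}

#' Simulate one nest record
#'
#' Draws a clutch size from the configured distribution and per-egg volumes
#' around the mean structure described in [sim_config()]; egg dimensions are
#' back-solved from volume so the standard volume formula round-trips
#' exactly. Uses the current RNG state (no reseeding): callers own the
#' stream, which is how [generate_dataset()] keeps nests on one substream.
#'
#' @param age mother age in years.
#' @param env list or one-row data.frame with `wnao` and `foodpc` (z-scored
#'   per-capita food) for the nest's year.
#' @param year_effect the year's random effect (cm^3).
#' @param config a [sim_config()].
#' @param ind_effect individual effect (cm^3); drawn `N(0, sigma_ind)` when
#'   `NULL`.
#' @return list with `age`, `clutch`, `volumes` (cm^3) and `eggs`
#'   (data.frame of `length_mm`, `width_mm`).
#' @export
simulate_nest <- function(age, env, year_effect = 0, config,
                          ind_effect = NULL) {
  stopifnot(inherits(config, "sim_config"))
  check_number(age, "age", lower = config$age_min, upper = config$age_max)
  clutch <- sample.int(5L, 1L, prob = config$clutch_probs)
  if (is.null(ind_effect)) ind_effect <- stats::rnorm(1, 0, config$sigma_ind)
  mu <- config$beta0 + config$beta_age * age + config$beta_age2 * age^2 +
    config$beta_wnao * env$wnao + config$beta_food * env$foodpc +
    year_effect + ind_effect
  if (mu <= 0) {
    abort_arg(sprintf(
      "configuration yields non-positive mean egg volume (%.2f) at age %s",
      mu, age
    ))
  }
  volumes <- mu + stats::rnorm(clutch, 0, config$sigma_egg)
  for (tries in seq_len(100)) {
    bad <- volumes <= 0
    if (!any(bad)) break
    volumes[bad] <- mu + stats::rnorm(sum(bad), 0, config$sigma_egg)
  }
  if (any(volumes <= 0)) abort_arg("could not draw positive egg volumes")
  list(
    age = as.integer(age), clutch = clutch, volumes = volumes,
    eggs = dims_from_volume(volumes, config$shape_ratio)
  )
}

#' Generate a full synthetic colony dataset
#'
#' Produces the two tables the inference pipeline consumes: a nest table
#' (one row per monitored nest, wide egg-dimension columns) and an annual
#' environment table. Ground-truth mother age is always kept in `true_age`;
#' the `age` column is `NA` for the configured fraction of
#' prediction-only nests, so label-blind runs are possible.
#'
#' Randomness flows from `config$seed` through named substreams
#' (`environment`, `year_effects`, `ages`, `nests`), so the same
#' configuration is bit-reproducible and each stage can be replayed alone.
#'
#' @param config a [sim_config()].
#' @return an object of class `colony_dataset`: list with `nests`,
#'   `environment` (data.frames) and `config`.
#' @seealso [write_dataset()] to serialise both tables to CSV.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  env <- simulate_environment(config)
  set.seed(substream_seed(config$seed, "year_effects"))
  year_effects <- stats::rnorm(config$n_years, 0, config$sigma_year)
  n_total <- config$n_years * config$nests_per_year
  ages <- simulate_ages(n_total, config)
  env$foodpc <- z_transform(env$food / env$popsize)

  set.seed(substream_seed(config$seed, "nests"))
  year_idx <- rep(seq_len(config$n_years), each = config$nests_per_year)
  colony <- sample(config$colonies, n_total, replace = TRUE)
  egg_cols <- as.vector(t(outer(1:5, c("length_mm", "width_mm"),
                                function(i, s) sprintf("egg%d_%s", i, s))))
  egg_mat <- matrix(NA_real_, n_total, 10, dimnames = list(NULL, egg_cols))
  clutch <- integer(n_total)
  for (i in seq_len(n_total)) {
    yi <- year_idx[i]
    nest <- simulate_nest(ages[i], env[yi, ], year_effects[yi], config)
    clutch[i] <- nest$clutch
    for (e in seq_len(nest$clutch)) {
      egg_mat[i, sprintf("egg%d_length_mm", e)] <- nest$eggs$length_mm[e]
      egg_mat[i, sprintf("egg%d_width_mm", e)] <- nest$eggs$width_mm[e]
    }
  }
  age_obs <- ages
  if (config$prop_unknown_age > 0) {
    hide <- stats::runif(n_total) < config$prop_unknown_age
    age_obs[hide] <- NA_integer_
  }
  nests <- data.frame(
    nest_id = sprintf("N%05d", seq_len(n_total)),
    year = env$year[year_idx],
    colony = colony,
    age = age_obs,
    clutch = clutch,
    egg_mat,
    true_age = ages,
    stringsAsFactors = FALSE
  )
  structure(
    list(nests = nests, environment = env[, c("year", "anao", "wnao", "food",
                                              "la_popsize", "popsize")],
         config = config),
    class = "colony_dataset"
  )
}

#' Write a colony dataset to `nests.csv` and `environment.csv`
#'
#' @param dataset a `colony_dataset` from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return invisibly, the two file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "colony_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("nests.csv", "environment.csv"))
  tryCatch({
    utils::write.csv(dataset$nests, paths[1], row.names = FALSE)
    utils::write.csv(dataset$environment, paths[2], row.names = FALSE)
  }, error = function(e) {
    stop(sprintf("failed writing dataset under '%s': %s", dir, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(paths)
}

#' @export
print.colony_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic colony dataset: %d nests over %d years (%s), %d colonies\n",
    nrow(x$nests), x$config$n_years,
    paste(range(x$environment$year), collapse = "-"),
    length(x$config$colonies)
  ))
  invisible(x)
}
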