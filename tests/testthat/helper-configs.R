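# Shared configurations and cached fixtures for the test suite.

# Small colony for fast structural checks.
small_config <- function(seed = 1, ...) {
  sim_config(n_years = 6, nests_per_year = 30, seed = seed, ...)
}

# Strong-signal colony: larger concave age effect, less noise. Used where a
# test needs a clearly learnable age signal.
strong_config <- function(seed = 1, ...) {
  sim_config(beta_age = 2, beta_age2 = -0.08,
             sigma_year = 0.5, sigma_ind = 1.5, sigma_egg = 1.5,
             seed = seed, ...)
}

# Zero-age-effect colony for null calibrations.
null_config <- function(seed = 1, ...) {
  sim_config(beta_age = 0, beta_age2 = 0, seed = seed, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Default 24-year x 100-nest colony, generated once per test run.
default_dataset <- function() {
  cached("default_ds", generate_dataset(sim_config(seed = 101)))
}

default_features <- function(scheme = "AGE2") {
  cached(paste0("default_ft_", scheme), {
    ds <- default_dataset()
    build_feature_table(ds$nests, ds$environment, "full", scheme)
  })
}

# A labelled toy feature table with a single separating predictor.
separable_table <- function(n_per_class = 100, gap = 10, seed = 5) {
  set.seed(seed)
  data.frame(
    nest_id = sprintf("T%04d", seq_len(2 * n_per_class)),
    VT = c(rnorm(n_per_class, 0), rnorm(n_per_class, gap)),
    VM = rnorm(2 * n_per_class),
    age_class = factor(rep(c("Young", "Others"), each = n_per_class),
                       levels = c("Young", "Others"))
  )
}
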