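# Shared fixtures. The default-scale PGNN fit is expensive (~45 s), so it is
# trained once per test run and memoised here.

.fixture_env <- new.env(parent = emptyenv())

fixture_doe <- function(seed = 11L, noise_sd = 2) {
  key <- sprintf("doe_%d_%g", seed, noise_sd)
  if (is.null(.fixture_env[[key]])) {
    kin <- kinetics_config(noise_sd = noise_sd, seed = seed)
    .fixture_env[[key]] <- generate_doe_dataset(kinetics = kin, seed = seed)
  }
  .fixture_env[[key]]
}

# default-config PGNN on the default synthetic DoE (noise sd 2%), 75:25 split
fixture_pgnn <- function(seed = 11L) {
  key <- sprintf("pgnn_%d", seed)
  if (is.null(.fixture_env[[key]])) {
    doe <- fixture_doe(seed)
    parts <- split_data(doe, 0.75, seed = seed)
    fit <- train_pgnn(parts$train, model_config("pgnn", seed = seed))
    .fixture_env[[key]] <- list(fit = fit, train = parts$train,
                                test = parts$test, doe = doe)
  }
  .fixture_env[[key]]
}

# small DoE for cheap model tests
small_doe <- function(seed = 3L, noise_sd = 1) {
  generate_doe_dataset(
    levels = list(voltage = c(8, 10), frequency = c(1, 3), flow = 2,
                  time = c(5, 15, 30, 60)),
    kinetics = kinetics_config(noise_sd = noise_sd, seed = seed),
    replicates = 3L, seed = seed)
}

# the "well-separated" literature world: four sensitivity components 10x
# apart with tight spreads, doses inside the linear regime
separated_db_config <- function(seed = 7L) {
  literature_db_config(types = "gamma", n_studies = 40L,
                       beta_meanlog = log(c(0.05, 0.5, 5, 50)),
                       beta_sdlog = rep(0.005, 4),
                       dose_min = 2, dose_max = 40, dose_points = 8L,
                       seed = seed)
}
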