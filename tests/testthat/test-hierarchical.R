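# A small shared fixture: 6 agents, 40 trials, mid-range truth.
small_sim <- local({
  generate_group_dataset(rep(0, 4), rep(0.3, 4), n_participants = 6,
                         n_trials = 40, seed = 123, group = "toy")
})

test_that("configuration and input validation", {
  expect_error(mcmc_config(chains = 1), "2 chains")
  expect_error(mcmc_config(seed = NA), "seed")
  expect_error(fit_hierarchical_group(
    group_dataset(list(small_sim$dataset$participants[[1]])),
    mcmc_config(chains = 2, burnin = 10, draws = 20, seed = 1)),
    ">= 2 participants")
})

test_that("prior-only run recovers the stated priors", {
  fit <- suppressWarnings(fit_hierarchical_group(
    small_sim$dataset,
    mcmc_config(chains = 2, burnin = 500, draws = 20000, seed = 4),
    likelihood = FALSE))
  for (p in paste0("mu_", c("A", "w", "a", "c"))) {
    x <- as.vector(fit$draws[, , p])
    expect_lt(abs(mean(x)), 0.08)       # ~N(0,1) within Monte Carlo error
    expect_lt(abs(stats::sd(x) - 1), 0.08)
  }
  for (p in paste0("sigma_", c("A", "w", "a", "c"))) {
    x <- as.vector(fit$draws[, , p])
    expect_lt(abs(mean(x) - 0.75), 0.06)  # U(0, 1.5) moments
    expect_lt(abs(stats::sd(x) - 1.5 / sqrt(12)), 0.05)
    expect_true(all(x > 0 & x < 1.5))
    # Kolmogorov-Smirnov-style distance against the uniform CDF
    d <- max(abs(sort(x) / 1.5 - (seq_along(x) - 0.5) / length(x)))
    expect_lt(d, 0.05)
  }
})

test_that("fitting a small synthetic group converges and is reproducible", {
  cfg <- mcmc_config(chains = 3, burnin = 500, draws = 800, seed = 10)
  fit <- fit_hierarchical_group(small_sim$dataset, cfg)
  expect_true(fit$converged)
  expect_true(all(dim(fit$draws) == c(3, 800, 8 + 4 * 6)))
  s <- posterior_summary(fit, "mu_c")
  expect_true(is.finite(s$mean) && s$sd > 0)
  # identical config twice: identical draws
  fit2 <- fit_hierarchical_group(small_sim$dataset, cfg)
  expect_identical(fit$draws, fit2$draws)
  # point estimates live inside the natural ranges
  ip <- individual_posterior_params(fit)
  expect_true(all(ip[, "A"] >= 0 & ip[, "A"] <= 1))
  expect_true(all(ip[, "w"] >= 0 & ip[, "w"] <= 5))
})

test_that("posterior precision improves with more trials per agent", {
  # same agents (shared per-participant streams), 10 versus 100 trials;
  # every group-level mean must be sharper with the longer task
  cfg <- mcmc_config(chains = 2, burnin = 500, draws = 1000, seed = 12)
  short <- generate_group_dataset(rep(0, 4), rep(0.3, 4), 8, 10, seed = 77)
  long <- generate_group_dataset(rep(0, 4), rep(0.3, 4), 8, 100, seed = 77)
  f_short <- suppressWarnings(fit_hierarchical_group(short$dataset, cfg))
  f_long <- suppressWarnings(fit_hierarchical_group(long$dataset, cfg))
  mus <- paste0("mu_", c("A", "w", "a", "c"))
  expect_true(all(posterior_summary(f_long, mus)$sd <
                    posterior_summary(f_short, mus)$sd))
})

test_that("draw and summary exports round-trip", {
  cfg <- mcmc_config(chains = 2, burnin = 100, draws = 200, seed = 3)
  fit <- suppressWarnings(fit_hierarchical_group(small_sim$dataset, cfg))
  csv <- withr::local_tempfile(fileext = ".csv")
  export_draws_csv(fit, csv)
  long <- utils::read.csv(csv)
  expect_equal(nrow(long), 2 * 200 * (8 + 24))
  one <- long[long$parameter == "mu_a" & long$chain == 1, ]
  expect_equal(one$value[order(one$iteration)], fit$draws[1, , "mu_a"])
  js <- withr::local_tempfile(fileext = ".json")
  export_summary_json(fit, js)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$parameters$mean[back$parameters$parameter == "mu_a"],
               mean(fit$draws[, , "mu_a"]), tolerance = 1e-8)
  expect_equal(back$provenance$config$seed, 3)
})
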