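# Shared small study + stage-1 fits for the informed-prior pathway.
mix_world <- local({
  st <- generate_two_group_study(c(0, 0, 0, -0.8), rep(0.3, 4),
                                 c(0, 0, 0, 0.8), rep(0.3, 4),
                                 n_per_group = c(6, 6), n_trials = 60,
                                 seed = 202)
  cfg <- mcmc_config(chains = 2, burnin = 400, draws = 800, seed = 14)
  f1 <- suppressWarnings(fit_hierarchical_group(st$group1, cfg))
  f2 <- suppressWarnings(fit_hierarchical_group(st$group2, cfg))
  list(st = st, f1 = f1, f2 = f2)
})

test_that("informed priors are moment-matched to the stage-1 posteriors", {
  pr <- suppressWarnings(build_informed_priors(mix_world$f1, mix_world$f2))
  s1 <- posterior_summary(mix_world$f1, paste0("mu_", c("A", "w", "a", "c")))
  expect_equal(unname(pr$mu_mean[1, ]), s1$mean)
  expect_equal(unname(pr$mu_sd[1, ]), s1$sd)
  g2 <- posterior_summary(mix_world$f2, paste0("sigma_", c("A", "w", "a", "c")))
  expect_equal(unname(pr$sigma_mean[2, ]), g2$mean)
  expect_true(all(pr$sigma_sd > 0))
})

test_that("prior-only mixture memberships sit at one half", {
  pr <- suppressWarnings(build_informed_priors(mix_world$f1, mix_world$f2))
  fit <- suppressWarnings(fit_latent_mixture(
    mix_world$st$pooled, pr,
    mcmc_config(chains = 2, burnin = 200, draws = 2500, seed = 15),
    likelihood = FALSE))
  expect_true(all(abs(fit$membership - 0.5) < 0.06))
  expect_lt(abs(fit$psi$mean - 0.5), 0.05)
})

test_that("separated groups are classified back to their origins", {
  pr <- suppressWarnings(build_informed_priors(mix_world$f1, mix_world$f2))
  fit <- suppressWarnings(fit_latent_mixture(
    mix_world$st$pooled, pr,
    mcmc_config(chains = 3, burnin = 400, draws = 1500, seed = 16)))
  expect_true(all(fit$membership >= 0 & fit$membership <= 1))
  expect_true(isTRUE(fit$label_check))
  expect_false(fit$parameter_inference)  # double-use caveat honored
  # base-rate consistency: psi mean tracks the average membership
  expect_lt(abs(fit$psi$mean - mean(fit$membership)), 0.12)
  cls <- classify_members(fit, truth = mix_world$st$labels)
  expect_gte(cls$accuracy, 9 / 12)  # 1.6-probit separation in mu_c
})

test_that("classification rules and edge cases", {
  fake <- structure(list(membership = c(a = 0.9, b = 0.1, c = 0.5)),
                    class = "igt_mixture")
  cls <- classify_members(fake)
  expect_equal(unname(cls$labels), c("2", "1", "unclassified"))
  cls2 <- classify_members(fake, truth = c(2, 1, 1))
  expect_equal(cls2$accuracy, 1)  # the tie is excluded from accuracy
  fake2 <- structure(list(membership = c(0.1, 0.6)), class = "igt_mixture")
  expect_equal(classify_members(fake2, truth = c(1, 2))$accuracy, 1)
  expect_error(classify_members(fake2, truth = 1), "per participant")
})

test_that("degenerate or missing stage-1 posteriors are rejected", {
  f_bad <- mix_world$f1
  f_bad$draws[, , "mu_A"] <- 0  # zero-SD posterior
  expect_error(suppressWarnings(build_informed_priors(f_bad, mix_world$f2)),
               "degenerate")
  expect_error(fit_latent_mixture(
    group_dataset(list(mix_world$st$pooled$participants[[1]])), NULL,
    mcmc_config(chains = 2, burnin = 10, draws = 10, seed = 1)),
    ">= 2 participants")
})

test_that("informed priors export to the CLI JSON format", {
  pr <- suppressWarnings(build_informed_priors(mix_world$f1, mix_world$f2))
  path <- withr::local_tempfile(fileext = ".json")
  export_priors_json(pr, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(matrix(back$mu_mean, 2, 4), unname(pr$mu_mean))
  expect_equal(matrix(back$sigma_sd, 2, 4), unname(pr$sigma_sd))
})
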