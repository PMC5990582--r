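test_that("degenerate SDs give identical individuals; ranges always hold", {
  sim0 <- generate_group_dataset(c(0.3, -0.2, 0.1, 0), rep(0, 4), 5, 20,
                                 seed = 1)
  expect_true(all(apply(sim0$truth$params, 2, function(x) diff(range(x)) == 0)))
  sim <- generate_group_dataset(rep(0, 4), rep(1, 4), 30, 5, seed = 2)
  pp <- sim$truth$params
  expect_true(all(pp[, "A"] >= 0 & pp[, "A"] <= 1))
  expect_true(all(pp[, "w"] >= 0 & pp[, "w"] <= 5))
  expect_true(all(pp[, "a"] >= 0 & pp[, "a"] <= 1))
  expect_true(all(pp[, "c"] >= 0 & pp[, "c"] <= 5))
  expect_error(generate_group_dataset(rep(0, 4), c(-1, 0, 0, 0), 3, 5,
                                      seed = 3), "sigma")
})

test_that("regeneration is bit-identical and stable under group growth", {
  s1 <- generate_group_dataset(rep(0, 4), rep(0.3, 4), 6, 30, seed = 99)
  s2 <- generate_group_dataset(rep(0, 4), rep(0.3, 4), 6, 30, seed = 99)
  expect_identical(s1$truth$probit, s2$truth$probit)
  expect_identical(lapply(s1$dataset$participants, `[[`, "deck"),
                   lapply(s2$dataset$participants, `[[`, "deck"))
  # per-participant streams: the first 4 agents survive enlarging the group
  s3 <- generate_group_dataset(rep(0, 4), rep(0.3, 4), 8, 30, seed = 99)
  expect_identical(s3$truth$probit[1:6, ], s1$truth$probit)
  expect_identical(s3$dataset$participants[[2]]$deck,
                   s1$dataset$participants[[2]]$deck)
})

test_that("generated datasets survive the CSV validation roundtrip", {
  sim <- generate_group_dataset(rep(0, 4), rep(0.3, 4), 4, 25, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_igt_csv(sim$dataset, path)
  back <- read_igt_csv(path)
  expect_equal(length(back), 4)
  expect_identical(back$participants[[3]]$deck,
                   sim$dataset$participants[[3]]$deck)
})

test_that("two-group studies withhold labels from the pooled data", {
  st <- generate_two_group_study(rep(0, 4), rep(0.3, 4), rep(0, 4),
                                 rep(0.3, 4), seed = 7)
  expect_equal(length(st$pooled), 38)
  expect_equal(sum(vapply(st$pooled$participants,
                          function(p) length(p$deck), integer(1))), 3800)
  expect_true(all(vapply(st$pooled$participants,
                         function(p) is.null(p$group), logical(1))))
  expect_equal(st$labels, rep(1:2, each = 19))
  expect_false(is.null(st$group1$participants[[1]]$group))
})

test_that("strong learners climb toward the good decks across blocks", {
  rises <- vapply(1:10, function(s) {
    sim <- generate_group_dataset(c(0, 0, -0.5, 0.5), rep(0.2, 4), 10, 100,
                                  seed = 1000 + s)
    good <- sapply(sim$dataset$participants,
                   function(p) block_proportions(p)$good)
    mean(good[10, ]) > mean(good[1, ])
  }, logical(1))
  expect_gte(sum(rises), 9)
})

test_that("recovery report flags coverage and vanishes for an oracle fit", {
  sim <- generate_group_dataset(rep(0, 4), rep(0.3, 4), 3, 10, seed = 11)
  # hand-built "posterior": a point mass at the truth
  ids <- rownames(sim$truth$probit)
  nm <- igtbayes:::hier_param_names(ids)
  vals <- c(sim$truth$mu_probit, sim$truth$sigma_probit,
            as.vector(t(sim$truth$probit)))
  draws <- array(rep(vals, each = 2 * 100), dim = c(2, 100, length(nm)),
                 dimnames = list(NULL, NULL, nm))
  fake_fit <- structure(
    list(draws = draws, rhat = stats::setNames(rep(1, length(nm)), nm),
         converged = TRUE, ids = ids, n_participants = 3,
         dataset_name = "fake", config = mcmc_config(seed = 1),
         outcome_scale = 100, likelihood = TRUE),
    class = "igt_hfit")
  rec <- recovery_report(sim$truth, fake_fit)
  expect_true(all(abs(rec$group_level$bias) < 1e-12))
  expect_true(all(rec$group_level$covered == 1))
  expect_true(all(rec$individual_rmse < 1e-12))
})
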